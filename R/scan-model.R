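# Acquisition model: alternating low-energy (reference ion, RI) and
# high-energy (product ion scan, PIS) MS/MS events inside retention-time
# segments, one segment per isomer group.

#' Describe one acquisition time segment
#'
#' A time segment holds the MS/MS parameters used for one isomer group: the
#' shared precursor m/z, the retention-time window, and the two alternating
#' MS/MS events — a low excitation-amplitude event that leaves the precursor
#' intact (the reference ion, RI) and a high excitation-amplitude event that
#' fragments it (the product-ion scan, PIS).
#'
#' @param segment_id Integer id of the segment (1-based).
#' @param group Label of the isomer group acquired in this segment
#'   (e.g. `"CQAs"`); used to match ratio tables and synthetic peaks.
#' @param rt_window Numeric length-2, retention-time window in minutes.
#' @param precursor_mz Precursor m/z (Th) isolated in both events.
#' @param ri_scan_range,pis_scan_range Numeric length-2 scan ranges (m/z) of
#'   the RI and PIS events.
#' @param ri_exa,pis_exa Excitation amplitudes (arbitrary units) of the RI and
#'   PIS events; `ri_exa` must be lower than `pis_exa`.
#' @param isolation_width Precursor isolation width (Th).
#' @param q_value Ion-trap q value (dimensionless).
#' @param excitation_time_ms Excitation time (ms).
#' @return A `segment_config` list.
#' @export
segment_config <- function(segment_id, group, rt_window, precursor_mz,
                           ri_scan_range, ri_exa, pis_scan_range, pis_exa,
                           isolation_width = 3, q_value = 0.25,
                           excitation_time_ms = 50) {
  stopifnot(length(rt_window) == 2L, rt_window[1] < rt_window[2],
            length(ri_scan_range) == 2L, length(pis_scan_range) == 2L,
            precursor_mz > 0)
  if (ri_exa >= pis_exa)
    stop("RI event excitation amplitude must be below the PIS event's",
         call. = FALSE)
  structure(
    list(segment_id = as.integer(segment_id), group = as.character(group),
         rt_window = as.numeric(rt_window),
         precursor_mz = as.numeric(precursor_mz),
         ri_scan_range = as.numeric(ri_scan_range), ri_exa = as.numeric(ri_exa),
         pis_scan_range = as.numeric(pis_scan_range),
         pis_exa = as.numeric(pis_exa),
         isolation_width = as.numeric(isolation_width),
         q_value = as.numeric(q_value),
         excitation_time_ms = as.numeric(excitation_time_ms)),
    class = "segment_config")
}

#' Assemble an acquisition configuration from time segments
#'
#' @param ... `segment_config` objects (or a single list of them).
#' @return A `leda_config`: a validated list of segments with non-overlapping
#'   retention-time windows.
#' @export
acquisition_config <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && !inherits(segs[[1]], "segment_config"))
    segs <- segs[[1]]
  stopifnot(length(segs) >= 1L,
            all(vapply(segs, inherits, logical(1), "segment_config")))
  win <- t(vapply(segs, function(s) s$rt_window, numeric(2)))
  o <- order(win[, 1])
  segs <- segs[o]; win <- win[o, , drop = FALSE]
  if (nrow(win) > 1L && any(win[-1, 1] < win[-nrow(win), 2]))
    stop("retention-time windows of distinct segments overlap", call. = FALSE)
  names(segs) <- vapply(segs, function(s) as.character(s$segment_id),
                        character(1))
  structure(segs, class = "leda_config")
}

#' Standard two-segment acquisition for caffeoylquinic-acid isomers
#'
#' Returns the acquisition configuration used for the CQA/diCQA isomer groups:
#' segment 1 monitors the mono-acyl precursor at 353 m/z (RI scan 300--365 at
#' ExA 15, PIS scan 95--250 at ExA 25), segment 2 the di-acyl precursor at
#' 515 m/z (RI 450--530 at ExA 10, PIS 140--365 at ExA 30).  Two variants are
#' provided that differ only in the retention-time windows: the conventional
#' long-gradient system (`chromsys = 1`) and the fast short-column system
#' (`chromsys = 2`).
#'
#' @param chromsys Which chromatographic system, 1 or 2.
#' @return A `leda_config` with two segments.
#' @export
cqa_acquisition_config <- function(chromsys = 2) {
  win <- switch(as.character(chromsys),
                "1" = list(c(0, 11), c(11, 25)),
                "2" = list(c(0, 3), c(3, 7.5)),
                stop("chromsys must be 1 or 2", call. = FALSE))
  acquisition_config(
    segment_config(1L, "CQAs", win[[1]], 353,
                   ri_scan_range = c(300, 365), ri_exa = 15,
                   pis_scan_range = c(95, 250), pis_exa = 25),
    segment_config(2L, "diCQAs", win[[2]], 515,
                   ri_scan_range = c(450, 530), ri_exa = 10,
                   pis_scan_range = c(140, 365), pis_exa = 30))
}

#' Read or write an acquisition configuration as YAML
#'
#' @param path File path.
#' @return `read_acquisition_config()` returns a `leda_config`;
#'   `write_acquisition_config()` invisibly returns `path`.
#' @export
read_acquisition_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$segments)) stop("config has no 'segments' key", call. = FALSE)
  segs <- lapply(y$segments, function(s)
    segment_config(s$segment_id, s$group, unlist(s$rt_window), s$precursor_mz,
                   unlist(s$ri_event$scan_range), s$ri_event$exa,
                   unlist(s$pis_event$scan_range), s$pis_event$exa,
                   isolation_width = s$isolation_width %||% 3,
                   q_value = s$q_value %||% 0.25,
                   excitation_time_ms = s$excitation_time_ms %||% 50))
  acquisition_config(segs)
}

#' @rdname read_acquisition_config
#' @param config A `leda_config`.
#' @export
write_acquisition_config <- function(config, path) {
  stopifnot(inherits(config, "leda_config"))
  y <- list(segments = lapply(unclass(config), function(s)
    list(segment_id = s$segment_id, group = s$group,
         rt_window = s$rt_window, precursor_mz = s$precursor_mz,
         ri_event = list(scan_range = s$ri_scan_range, exa = s$ri_exa),
         pis_event = list(scan_range = s$pis_scan_range, exa = s$pis_exa),
         isolation_width = s$isolation_width, q_value = s$q_value,
         excitation_time_ms = s$excitation_time_ms)))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_columns <- c("rt_min", "segment", "event", "precursor_mz", "exa",
                 "ext_ms", "mz", "abundance")

#' Construct / validate an MS/MS run table
#'
#' A run is a long-format data frame with one row per peak (or one all-`NA`
#' peak row for an empty scan) and columns `rt_min`, `segment`, `event`
#' (`"RI"` or `"PIS"`), `precursor_mz`, `exa`, `ext_ms`, `mz`, `abundance`.
#' A scan is the set of rows sharing `(rt_min, event)`; scans are kept in
#' nondecreasing retention-time order.
#'
#' @param df Data frame with the columns above.
#' @return The validated run, classed `msms_run`.
#' @export
msms_run <- function(df) {
  miss <- setdiff(run_columns, names(df))
  if (length(miss))
    stop("run table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[run_columns]
  for (col in setdiff(run_columns, c("segment", "event")))
    df[[col]] <- as.double(df[[col]])
  df$segment <- as.integer(df$segment)
  df$event <- as.character(df$event)
  if (nrow(df)) {
    if (any(df$rt_min < 0)) stop("negative retention times", call. = FALSE)
    if (any(df$abundance < 0, na.rm = TRUE))
      stop("negative abundances", call. = FALSE)
    if (!all(df$event %in% c("RI", "PIS")))
      stop("event must be 'RI' or 'PIS'", call. = FALSE)
    df <- df[order(df$rt_min), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("msms_run", "data.frame")
  df
}

#' Read an MS/MS run
#'
#' Reads a run either from the package's internal line-oriented CSV format
#' (one row per peak, scan metadata repeated on each row) or from an mzML file
#' via the `mzR` package.  For mzML input an acquisition `config` is required:
#' the event kind of each scan is classified by matching its collision energy
#' against the RI/PIS excitation amplitudes of the segment covering its
#' retention time (equality after rounding to 0.1 a.u.).  For internal-format
#' input a supplied `config` is used to re-derive and cross-check the stored
#' event labels the same way.
#'
#' @param path Input file.
#' @param format `"internal"` or `"mzml"`.
#' @param config Optional (internal) / required (mzML) `leda_config`.
#' @return An `msms_run`, scans in nondecreasing retention-time order.
#' @export
read_run <- function(path, format = c("internal", "mzml"), config = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read run file: ", path, call. = FALSE)
  run <- if (format == "internal") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    msms_run(df)
  } else {
    read_run_mzml(path, config)
  }
  if (!is.null(config)) run <- classify_events(run, config)
  run
}

read_run_mzml <- function(path, config) {
  if (is.null(config))
    stop("an acquisition config is required to read mzML runs", call. = FALSE)
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML support requires the 'mzR' package", call. = FALSE)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  hd <- hd[hd$msLevel >= 2L, , drop = FALSE]
  if (!nrow(hd))
    return(msms_run(data.frame(rt_min = numeric(), segment = integer(),
                               event = character(), precursor_mz = numeric(),
                               exa = numeric(), ext_ms = numeric(),
                               mz = numeric(), abundance = numeric())))
  rows <- lapply(seq_len(nrow(hd)), function(i) {
    rt <- hd$retentionTime[i] / 60  # mzML stores seconds
    seg <- segment_at(config, rt)
    pk <- mzR::peaks(fh, hd$seqNum[i])
    if (is.null(dim(pk)) || nrow(pk) == 0L)
      pk <- matrix(NA_real_, 1L, 2L)
    data.frame(rt_min = rt, segment = seg$segment_id, event = NA_character_,
               precursor_mz = hd$precursorMZ[i],
               exa = hd$collisionEnergy[i], ext_ms = seg$excitation_time_ms,
               mz = pk[, 1], abundance = pk[, 2])
  })
  msms_run(classify_events(do.call(rbind, rows), config))
}

segment_at <- function(config, rt) {
  for (s in config)
    if (rt >= s$rt_window[1] && rt <= s$rt_window[2]) return(s)
  stop(sprintf("retention time %.3f min falls in no configured segment", rt),
       call. = FALSE)
}

#' Classify event kinds from excitation amplitudes
#'
#' Assigns `"RI"`/`"PIS"` to every scan by matching its excitation amplitude
#' (rounded to 0.1 a.u.) against the two events of its segment.  Matching by
#' energy rather than by scan order keeps pairing robust to dropped scans.
#'
#' @param run An `msms_run`.
#' @param config A `leda_config`.
#' @return The run with its `event` column (re)assigned.
#' @export
classify_events <- function(run, config) {
  stopifnot(inherits(config, "leda_config"))
  for (s in config) {
    in_seg <- run$segment == s$segment_id
    if (!any(in_seg)) next
    exa <- round(run$exa[in_seg], 1)
    ev <- ifelse(exa == round(s$ri_exa, 1), "RI",
                 ifelse(exa == round(s$pis_exa, 1), "PIS", NA))
    if (anyNA(ev)) {
      bad <- which(in_seg)[which(is.na(ev))[1]]
      stop(sprintf(
        "scan at %.3f min (segment %d): ExA %.1f matches neither event (RI %.1f / PIS %.1f)",
        run$rt_min[bad], s$segment_id, run$exa[bad], s$ri_exa, s$pis_exa),
        call. = FALSE)
    }
    run$event[in_seg] <- ev
  }
  run
}

#' Write an MS/MS run in the internal CSV format
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read round trip reproduces every double bit-for-bit.
#'
#' @param run An `msms_run`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_run <- function(run, path) {
  run <- msms_run(run)
  out <- as.data.frame(lapply(run, function(col) {
    if (is.double(col)) {
      s <- sprintf("%.17g", col)
      s[is.na(col)] <- NA
      s
    } else col
  }), stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Sum the abundance of an ion within an m/z tolerance window
#'
#' Unit-resolution ion-trap peak matching: all peaks within `tolerance` of
#' `target_mz` are summed; absence of the ion is a valid 0, never an error.
#'
#' @param peaks Data frame with `mz` and `abundance` columns (one scan's
#'   peak list); `NA` rows (empty-scan placeholders) are ignored.
#' @param target_mz Target m/z (Th).
#' @param tolerance Half-width of the matching window (Th), > 0.
#' @return Summed abundance (counts).
#' @export
extract_ion <- function(peaks, target_mz, tolerance = 0.5) {
  stopifnot(tolerance > 0)
  keep <- !is.na(peaks$mz) & abs(peaks$mz - target_mz) <= tolerance
  if (!any(keep)) return(0)
  sum(peaks$abundance[keep])
}

#' Drop peaks below a relative-abundance threshold
#'
#' Retains peaks whose abundance is at least `threshold_pct` percent of the
#' most abundant peak in the list (the base peak).
#'
#' @param peaks Data frame with `mz` and `abundance` columns.
#' @param threshold_pct Threshold in percent of the base peak, in \[0, 100\].
#' @return The filtered peak list.
#' @export
filter_relative_abundance <- function(peaks, threshold_pct = 1) {
  stopifnot(threshold_pct >= 0, threshold_pct <= 100)
  if (!nrow(peaks)) return(peaks)
  cut <- threshold_pct / 100 * max(peaks$abundance, na.rm = TRUE)
  out <- peaks[!is.na(peaks$abundance) & peaks$abundance >= cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair product-ion scans with an interpolated reference-ion abundance
#'
#' The RI and PIS events alternate in time, so the reference-ion abundance is
#' never observed at the instant of a product-ion scan.  For every PIS scan
#' this builds one paired data point whose `ri_abundance` is the reference-ion
#' trace (precursor abundance in the RI scans, summed within `tolerance` of
#' the segment's precursor m/z) interpolated to the PIS retention time.
#' Interpolation uses a cubic spline by default (`"fmm"`), evaluated inside
#' the RI time range only — outside it the nearest RI value is used — and is
#' floored at zero; `method = "linear"` selects plain linear interpolation.
#'
#' @param run An `msms_run` sorted by retention time.
#' @param config A `leda_config`.
#' @param tolerance m/z matching tolerance (Th) for the reference ion.
#' @param method `"spline"` (default) or `"linear"`.
#' @return A `paired_points` data frame with columns `rt_min`, `segment`,
#'   `ri_abundance` and a list-column `pis` of product-ion peak lists.
#' @export
pair_events <- function(run, config, tolerance = 0.5,
                        method = c("spline", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "leda_config"))
  out <- list()
  for (s in config) {
    seg <- run[run$segment == s$segment_id, , drop = FALSE]
    if (!nrow(seg)) next
    ri <- seg[seg$event == "RI", , drop = FALSE]
    pis <- seg[seg$event == "PIS", , drop = FALSE]
    if (!nrow(pis)) next
    if (!nrow(ri))
      stop(sprintf("segment %d has PIS scans but no RI scans", s$segment_id),
           call. = FALSE)
    ri_scans <- split(ri, ri$rt_min)
    ri_t <- as.numeric(names(ri_scans))
    ri_a <- vapply(ri_scans, extract_ion, numeric(1),
                   target_mz = s$precursor_mz, tolerance = tolerance)
    o <- order(ri_t); ri_t <- ri_t[o]; ri_a <- ri_a[o]
    pis_scans <- split(pis, pis$rt_min)
    pis_t <- as.numeric(names(pis_scans))
    o <- order(pis_t); pis_t <- pis_t[o]; pis_scans <- pis_scans[o]
    ri_at <- interp_trace(ri_t, ri_a, pis_t, method)
    pk <- lapply(pis_scans, function(sc)
      data.frame(mz = sc$mz, abundance = sc$abundance)[!is.na(sc$mz), ,
                                                       drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      rt_min = pis_t, segment = s$segment_id, ri_abundance = ri_at,
      pis = I(unname(pk)))
  }
  if (!length(out))
    out <- list(data.frame(rt_min = numeric(), segment = integer(),
                           ri_abundance = numeric(), pis = I(list())))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("paired_points", "data.frame")
  res
}

# Interpolate a sampled trace at new times: nearest value outside the sampled
# range, spline (floored at 0) or linear inside it.
interp_trace <- function(t, a, t_new, method = "spline") {
  if (length(t) == 1L) return(rep(a, length(t_new)))
  tc <- pmin(pmax(t_new, min(t)), max(t))
  y <- if (method == "spline" && length(t) >= 4L)
    spline(t, a, xout = tc, method = "fmm")$y
  else
    approx(t, a, xout = tc, rule = 2)$y
  pmax(y, 0)
}
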