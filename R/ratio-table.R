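# Characteristic Pi/Ri ratio tables: the per-isomer MS/MS fingerprints that
# the deconvolution model is built from.

#' Construct a characteristic ratio table
#'
#' For one isomer group sharing a precursor (the reference ion, Ri), the
#' table holds the characteristic abundance ratio of every monitored product
#' ion (Pi) to the Ri, measured on each pure isomer, plus its standard
#' deviation.  Columns are isomers, rows are product ions.
#'
#' @param group_id Isomer-group label (e.g. `"CQAs"`).
#' @param reference_mz Reference-ion (precursor) m/z (Th).
#' @param product_mzs Numeric vector of product-ion m/z values (rows).
#' @param isomer_ids Character vector of isomer labels (columns), length >= 2.
#' @param ratios Matrix (product ion x isomer) of Pi/Ri ratios, >= 0.
#' @param sds Matrix of matching standard deviations, >= 0 (defaults to 0).
#' @return A `ratio_table`.
#' @export
ratio_table <- function(group_id, reference_mz, product_mzs, isomer_ids,
                        ratios, sds = NULL) {
  ratios <- as.matrix(ratios)
  if (is.null(sds)) sds <- matrix(0, nrow(ratios), ncol(ratios))
  sds <- as.matrix(sds)
  stopifnot(length(isomer_ids) >= 2L,
            nrow(ratios) == length(product_mzs),
            ncol(ratios) == length(isomer_ids),
            all(dim(sds) == dim(ratios)))
  if (any(ratios < 0) || any(sds < 0))
    stop("ratios and SDs must be nonnegative", call. = FALSE)
  dimnames(ratios) <- dimnames(sds) <-
    list(as.character(product_mzs), isomer_ids)
  structure(list(group_id = group_id, reference_mz = as.numeric(reference_mz),
                 product_mzs = as.numeric(product_mzs),
                 isomer_ids = as.character(isomer_ids),
                 ratios = ratios, sds = sds),
            class = "ratio_table")
}

#' Read / write ratio tables as CSV
#'
#' CSV columns: `group`, `reference_mz`, `product_mz`, `isomer`, `ratio`,
#' `sd`.  A file may hold several groups; `read_ratio_tables()` returns a
#' named list of `ratio_table` objects, one per group.
#'
#' @param path File path.
#' @return A named list of `ratio_table`s.
#' @export
read_ratio_tables <- function(path) {
  if (!file.exists(path))
    stop("cannot read ratio table: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "reference_mz", "product_mz", "isomer", "ratio", "sd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ratio table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$group), function(g) {
    mzs <- unique(g$product_mz)
    isos <- unique(g$isomer)
    r <- s <- matrix(NA_real_, length(mzs), length(isos))
    for (k in seq_len(nrow(g))) {
      i <- match(g$product_mz[k], mzs); j <- match(g$isomer[k], isos)
      r[i, j] <- g$ratio[k]; s[i, j] <- g$sd[k]
    }
    if (anyNA(r))
      stop("ratio table group '", g$group[1],
           "' is not a complete product x isomer grid", call. = FALSE)
    ratio_table(g$group[1], g$reference_mz[1], mzs, isos, r, s)
  })
  out[unique(df$group)]
}

#' @rdname read_ratio_tables
#' @param tables A `ratio_table` or list of them.
#' @export
write_ratio_tables <- function(tables, path) {
  if (inherits(tables, "ratio_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(tb) {
    g <- expand.grid(i = seq_along(tb$product_mzs),
                     j = seq_along(tb$isomer_ids))
    data.frame(group = tb$group_id, reference_mz = tb$reference_mz,
               product_mz = tb$product_mzs[g$i], isomer = tb$isomer_ids[g$j],
               ratio = tb$ratios[cbind(g$i, g$j)],
               sd = tb$sds[cbind(g$i, g$j)])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' The bundled caffeoylquinic-acid ratio tables
#'
#' Loads the characteristic Pi/Ri ratio tables shipped with the package for
#' the two caffeoylquinic isomer groups: the CQAs (3-, 5-, 4-CQA; reference
#' ion 353 m/z; product ions 191, 179, 173, 135) and the diCQAs (3,4-, 3,5-,
#' 4,5-diCQA; reference ion 515 m/z; product ions 353, 335, 317, 299, 203),
#' as determined from pure-isomer MS/MS measurements.
#'
#' @return Named list with elements `CQAs` and `diCQAs`.
#' @export
cqa_ratio_tables <- function() {
  read_ratio_tables(system.file("extdata", "cqa_ratio_tables.csv",
                                package = "ledar", mustWork = TRUE))
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("Characteristic Pi/Ri ratio table '%s' (Ri %g m/z): %d product ions x %d isomers\n",
              x$group_id, x$reference_mz, nrow(x$ratios), ncol(x$ratios)))
  print(round(x$ratios, 4))
  invisible(x)
}
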