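---
title: "Deconvolution of co-eluting isomers from alternating-energy ion-trap MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolution of co-eluting isomers from alternating-energy ion-trap MS/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ledar)
```

## The problem

Positional isomers such as the caffeoylquinic acids (CQAs) share an elemental
composition, a precursor ion, and most product ions, so neither MS nor plain
MS/MS separates them: a chromatographically unresolved peak of, say, 5-CQA
and 4-CQA produces one merged precursor signal at 353 m/z and one merged
product-ion spectrum.  Full chromatographic separation is possible but slow,
and it must be re-developed for every new isomer family.

`ledar` takes the opposite route: keep the chromatography fast and crude, and
move the specificity into the mass spectrometer.  Isomers fragment through
the same channels but with reproducibly *different yields*.  If those yields
are known for each pure isomer, the mixed MS/MS signal can be decomposed
mathematically.

## The measurement design

An ion trap performs MS/MS as a timed sequence on one precursor, so the
acquisition is organized as retention-time segments (one per isomer group,
each with its own precursor) containing two alternating MS/MS events:

* a **reference-ion (RI) event** at an excitation amplitude (ExA) too low to
  fragment anything — it records the intact precursor, the *reference ion*
  `Ri`, which is proportional to the summed amount of all isomers present;
* a **product-ion scan (PIS) event** at an ExA high enough to fragment the
  precursor completely — it records the product ions `Pi`.

For every product ion, the ratio `Pi/Ri` is a yield of formation that is
independent of the eluting amount.  Measured on pure standards it gives each
isomer a *characteristic ratio column*; measured on a mixture it gives the
data vector of the deconvolution below.  The bundled tables
(`cqa_ratio_tables()`) hold the columns for the three mono-CQAs (reference
ion 353 m/z; products 191, 179, 173, 135) and the three di-CQAs (reference
ion 515 m/z; products 353, 335, 317, 299, 203), with standard deviations of
± 0.01 throughout.

Because RI and PIS events alternate, `Ri` is never observed at the instant
of a PIS scan.  `pair_events()` therefore interpolates the RI trace to each
PIS time.  We use a cubic spline rather than linear interpolation: an
elution peak is strongly curved on the scale of the event cadence (RI every
0.01 min against a peak sigma of a few hundredths of a minute), and the
linear interpolation error — of order `(h/sigma)^2 / 8`, several parts per
thousand at the apex — is the single largest numerical error in the whole
chain, larger than the 1e-4 agreement we demand of noiseless round-trip
tests.  The spline's fourth-order error is orders of magnitude below that
floor, and the interpolated trace is clamped to the observed time range
(nearest value at the edges) and floored at zero.  `method = "linear"` is
retained as an option for very sparse or very spiky data.  Event kinds are
classified by matching each scan's ExA to the segment configuration (after
rounding to 0.1 a.u.) rather than by scan order, so a dropped scan cannot
desynchronize the pairing.

## ERMS breakdown curves

Choosing the two ExA values requires knowing the energetics of
fragmentation, mapped by an energy-resolved MS/MS (ERMS) experiment: MS/MS
spectra at stepwise-increasing ExA.  Three curves summarize it (all in
percent):

* survival yield `SY = 100 * precursor / (precursor + sum(Pi))`;
* product-ion formation `PiF = 100 - SY`;
* product-ion yield `PiY = 100 * sum(Pi) / precursor_max`, where
  `precursor_max` is the precursor level *before* any fragmentation.

`SY` and `PiF` are complements by construction, so they cross exactly at
50%; the ExA of that crossing (`SY_ExA50`, obtained by linear interpolation
of the first downward crossing) characterizes how much energy the compound
needs.  `PiF` overstates CID efficiency because it ignores precursor
ejection and products below the trap's low-mass cut-off; `PiY` exposes
those losses, and its maximum (`PiY_max`, at `ExA_max`) is the natural
operating point for the high-energy event.  `ExA_max` is reported on the
sampled grid (ties broken toward the lower ExA — same yield for less
energy) because interpolating a flat maximum is numerically meaningless.

`precursor_max` is estimated as the mean precursor abundance over the
pre-activation plateau, which we define quantitatively as the grid points
with `SY >= 95%`.  With a shallow survival decay, points just inside that
plateau already sit slightly below the true level, biasing `precursor_max`
low by up to ~1% and `PiY` correspondingly high; the threshold is a
compromise between that bias and having too few plateau points to average.
Grid points with zero total ion current are flagged `NA` and excluded
rather than imputed.

## The deconvolution model

For a mixture of `n` isomers, each retained product ion `i` contributes one
linear equation

    (Pi/Ri)_measured,i  =  sum_x  (Pi/Ri)_x,i * f_x ,

where `(Pi/Ri)_x,i` is isomer `x`'s characteristic ratio and `f_x` its
fraction of the reference-ion signal.  Only product ions whose
characteristic ratio reaches 2% for at least one isomer enter the system
(ions below that carry no discriminating signal above the ± 0.01 ratio
noise); with the bundled tables this keeps all rows — a 4 × 3 system for
the CQAs and a 5 × 3 system for the diCQAs, both overdetermined.
Assembly fails loudly if filtering ever leaves fewer rows than isomers.

The system is solved by non-negative least squares (Lawson–Hanson
active set, via `pracma::lsqnonneg`).  Two modelling choices matter:

* **No sum-to-one constraint.**  An unknown co-eluting compound sharing the
  precursor and product ions would otherwise be forced onto the known
  isomers; instead it appears as an *unassigned* remainder
  `1 - sum(f)` (clipped at zero).  When noise pushes `sum(f)` above 1 the
  fractions are renormalized to 1 and flagged — overshoot has no physical
  reading, undershoot does.
* **Unweighted rows by default.**  The characteristic-ratio SDs are nearly
  uniform (± 0.01), so inverse-variance weighting is almost a no-op on the
  bundled systems; it is available (`weights = "sd"`) for tables with
  heteroscedastic rows.

A condition number above 1e6 sets a `collinear_design` flag.  The diCQA
system is the motivating case for the diagnostic: its columns are dominated
by the shared 353/515 row (condition number ≈ 54 — workable, but fractions
there are noticeably noisier than for the CQAs).

Deconvolution runs in two modes.  **Scan-by-scan** solves the system at
every paired point and apportions the point's `Ri` as `ri * f_x`, yielding
reconstructed per-isomer chromatographic traces plus a residual trace; the
traces conserve `Ri` exactly at every time point.  Baseline points with
`Ri` below 1% of the run's maximum (configurable) are not deconvolved —
solving the system on pure noise assigns meaningless fractions — and their
`Ri` goes to the residual.  **Peak mode** integrates `Ri` and each `Pi`
trace over a window (trapezoidal rule) and solves once on the area ratios;
its fractions are the *peak purity*.  On noiseless data the two modes agree
by construction: the peak-mode solution equals the `Ri`-weighted mean of
the scanwise fractions.

## Quantification

Quantification uses the external-standard method on the `Ri` signal: a
calibration line (ordinary least squares of area on concentration, five
levels spanning 1–20 mg/L with replicate injections) is inverted for the
working-solution concentration, which is multiplied by the dilution factor
(default 20, i.e. a 50 µL aliquot diluted to 1 mL) to back-calculate the
extract concentration.  Detection limits follow the
standard-error-of-response approach: `LOD = 3.3 * SE(intercept) / slope`,
`LOQ = 10 * SE(intercept) / slope`.  A single standard's curve serves all
isomers of a group: isomers share ionization behaviour closely enough that
per-analyte curves (supported, off by default) rarely pay for the extra
standards.  Negative inverted concentrations are reported as 0 and flagged
`<LOD`, never propagated as negative amounts.  Integration windows are
supplied per isomer by configuration; there is no automatic peak detection.

## What the generators emulate — and what they do not

`simulate_run()` produces the acquisition the pipeline expects: alternating
RI/PIS events per segment at a fixed cadence (default 0.3 s per event, so a
peak of sigma 0.05 min yields well over 15 paired points), Gaussian elution
peaks (an exponential tail is available via `tau_min` to stress-test
integration), product abundances formed as elution profile × characteristic
ratio, and independent multiplicative lognormal noise of mean 1 on every
recorded abundance.  Lognormal multiplicative noise matches the observation
that measured ratio SDs are roughly constant relative to signal level.  The
electrospray response is modelled per *amount* — peak area, not apex height,
is proportional to concentration — so simulated peaks of different widths
quantify consistently against one calibration curve.  `simulate_erms()`
generates logistic survival decays with a configurable ion-loss fraction
split over product ions.

The generators deliberately omit: isotope patterns and centroiding (inputs
are assumed centroided), retention-time drift between runs, baseline drift
and chemical background, detector saturation, cross-segment interference,
and any ionization-suppression matrix effect.  Passing tests therefore
demonstrate the correctness of the algorithmic chain under the stated noise
model — not robustness to every artefact of real instrument data, where
characteristic ratios should be re-measured under the exact MS/MS
conditions used.

## Numerical choices and problem sizes

Defaults: m/z matching tolerance ± 0.5 Th (unit-resolution trap); ratio
threshold 0.02; baseline `Ri` gate 1%; retention times in minutes
everywhere; the internal run format is a line-oriented CSV (one row per
peak) written with 17 significant digits so round trips are bit-exact.
Empty scans are kept as all-`NA` placeholder rows so scan counts survive
I/O.

The test and acceptance workloads are sized for a laptop-class single CPU:
Monte-Carlo checks use 100–200 seeds on single-segment runs of a few
hundred scans, the solver-versus-grid-search oracle uses 1,000 mixtures
against an exhaustive 0.001-resolution simplex enumeration (vectorized over
the ~5 × 10^5 grid points), and ERMS recovery uses 1 a.u. grids.  These
sizes keep every stochastic check's sampling error far below the tolerance
it asserts.

## Known limitations

* Attribution is only as good as the ratio table: the method recognizes the
  isomers it is given, and a genuinely unknown isomer is visible only as
  unassigned residual, not identified.
* The diCQA system's near-collinearity means its per-scan fractions carry
  several times the noise of the CQA system's; peak-mode purity is the more
  stable readout there.
* The shared-calibration assumption (equal response factors across isomers)
  is chemically motivated for positional isomers but unverifiable without
  the full standard panel.
* mzML support is read-only and expects MS2 scans carrying retention time,
  precursor m/z and collision energy in their standard locations.
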