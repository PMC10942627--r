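#' Ultrashort-fragment-adjusted total cfDNA concentration
#'
#' Standard cfDNA assays under-recover single-stranded ultrashort fragments
#' (~25-60 bp), which carry a genome-copy content comparable to the
#' nucleosome-protected fragments. The total plasma concentration is
#' therefore scaled by an adjustment factor known only to lie uniformly
#' between 1 (no effect) and 2 (doubling), midpoint 1.5. The adjustment is
#' propagated by [apply_uniform_factor()] (default 10,000 iterations) and the
#' result refitted as lognormal.
#'
#' @param total [lnq], unadjusted total cfDNA in GE/ml (default: the
#'   constants' `total_cfdna`).
#' @param constants a [physiological_constants()] object.
#' @param seed integer seed.
#' @param n_iter bootstrap iterations.
#' @return [lnq] adjusted total in GE/ml.
#' @export
adjusted_total <- function(total = constants$total_cfdna, constants, seed,
                           n_iter = 10000) {
  stopifnot(inherits(constants, "cfdna_constants"))
  rng <- constants$adjustment_range
  apply_uniform_factor(total, low = rng[1], high = rng[2],
                       n_iter = n_iter, seed = seed)
}

#' Measured concentration of one cell type's cfDNA
#'
#' Combines the adjusted total concentration with the deconvolution fraction
#' attributed to the cell type, by the product shape rule.
#'
#' @param total_adjusted [lnq], adjusted total in GE/ml.
#' @param fraction [lnq], fraction of total cfDNA, median in (0, 1].
#' @return [lnq] in GE/ml.
#' @export
celltype_concentration <- function(total_adjusted, fraction) {
  fraction <- as_lnq(fraction)
  if (fraction$median > 1) {
    stop("fraction median must be in (0, 1]", call. = FALSE)
  }
  lnq_mul(as_lnq(total_adjusted), fraction)
}

#' Detectability of a potential cfDNA concentration
#'
#' Classifies the potential concentration's median against the assay
#' detection band (defaults 1-10 GE/ml): at or above the upper bound the
#' signal is visible to genome-wide deconvolution assays; inside the band
#' only to targeted marker assays; below the lower bound to neither.
#'
#' @param potential [lnq] or positive number, concentration in GE/ml.
#' @param constants a [physiological_constants()] object.
#' @return one of `"above_deconvolution"`, `"targeted_only"`,
#'   `"below_detection"`.
#' @export
detection_status <- function(potential, constants) {
  stopifnot(inherits(constants, "cfdna_constants"))
  med <- if (is_lnq(potential)) potential$median else as.numeric(potential)
  band <- constants$detection_band
  if (med >= band[2]) "above_deconvolution"
  else if (med >= band[1]) "targeted_only"
  else "below_detection"
}
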