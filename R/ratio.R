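#' Capture ratio of a cell type
#'
#' The dimensionless ratio measured / potential: the fraction of the DNA of
#' dying cells of this type that appears as measurable plasma cfDNA. Factors
#' combine by the product shape rule.
#'
#' @param measured,potential [lnq] concentrations in GE/ml.
#' @return [lnq], dimensionless.
#' @export
cfdna_ratio <- function(measured, potential) {
  lnq_div(as_lnq(measured), as_lnq(potential))
}

#' Flux results for a cell-type table
#'
#' Runs the full mass balance: the potential concentration for every cell
#' type, the measured concentration and capture ratio for types with a
#' deconvolution fraction, 95% CIs, and detectability. Rows are ordered by
#' descending turnover median (the ordering used to present the flux
#' hierarchy); externally shed types are flagged and never given a ratio.
#'
#' @param records a validated [celltype-table] data.frame.
#' @param constants a [physiological_constants()] object.
#' @param seed integer seed (drives the ultrashort-fragment adjustment).
#' @param n_adjust iterations for the uniform-factor adjustment.
#' @return data.frame with one row per cell type: `name`, `turnover_median`,
#'   `shed_externally`, `potential_median`, `potential_lo`, `potential_hi`,
#'   `measured_median`, `ratio_median`, `ratio_factor`, `ratio_lo`,
#'   `ratio_hi` (NA for unprofiled types), `detection`. The adjusted total
#'   used is attached as attribute `"adjusted_total"`.
#' @examples
#' res <- summarize_flux(reference_celltype_table(),
#'                       physiological_constants(), seed = 1)
#' head(res[, c("name", "potential_median", "ratio_median")])
#' @export
summarize_flux <- function(records, constants, seed, n_adjust = 10000) {
  records <- validate_celltype_table(records)
  total_adj <- adjusted_total(constants$total_cfdna, constants,
                              seed = seed, n_iter = n_adjust)
  n <- nrow(records)
  out <- data.frame(name = character(n), turnover_median = numeric(n),
                    shed_externally = logical(n),
                    potential_median = numeric(n), potential_lo = numeric(n),
                    potential_hi = numeric(n),
                    measured_median = rep(NA_real_, n),
                    ratio_median = rep(NA_real_, n),
                    ratio_factor = rep(NA_real_, n),
                    ratio_lo = rep(NA_real_, n), ratio_hi = rep(NA_real_, n),
                    detection = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    pot <- potential_cfdna(row, constants)
    pot_ci <- ci95(pot)
    out$name[i] <- row$name
    out$turnover_median[i] <- row$turnover_median
    out$shed_externally[i] <- row$shed_externally
    out$potential_median[i] <- pot$median
    out$potential_lo[i] <- pot_ci[1]
    out$potential_hi[i] <- pot_ci[2]
    out$detection[i] <- detection_status(pot, constants)
    frac <- row_fraction(row)
    if (!is.null(frac)) {
      meas <- celltype_concentration(total_adj, frac)
      ratio <- cfdna_ratio(meas, pot)
      r_ci <- ci95(ratio)
      out$measured_median[i] <- meas$median
      out$ratio_median[i] <- ratio$median
      out$ratio_factor[i] <- ratio$factor
      out$ratio_lo[i] <- r_ci[1]
      out$ratio_hi[i] <- r_ci[2]
    }
  }
  out <- out[order(-out$turnover_median), ]
  rownames(out) <- NULL
  attr(out, "adjusted_total") <- total_adj
  out
}

#' Fold range of capture ratios
#'
#' Ratio of the largest to the smallest capture-ratio median across profiled
#' cell types; always `>= 1`.
#'
#' @param results a [summarize_flux()] data.frame.
#' @return positive number.
#' @export
fold_range <- function(results) {
  r <- results$ratio_median[!is.na(results$ratio_median)]
  if (length(r) == 0L) stop("no capture ratios present", call. = FALSE)
  max(r) / min(r)
}

#' Largest capture fraction
#'
#' Returns the capture ratio with the largest median — the headline upper
#' bound on the fraction of dying-cell DNA that reaches plasma. The cell-type
#' name is attached as attribute `"name"`.
#'
#' @param results a [summarize_flux()] data.frame.
#' @return [lnq], dimensionless.
#' @export
max_capture_fraction <- function(results) {
  ok <- !is.na(results$ratio_median)
  if (!any(ok)) stop("no capture ratios present", call. = FALSE)
  i <- which.max(ifelse(ok, results$ratio_median, -Inf))
  out <- lnq(results$ratio_median[i], results$ratio_factor[i])
  attr(out, "name") <- results$name[i]
  out
}

#' Display a capture ratio as a 1:n label
#'
#' Formats a ratio the way flux hierarchies are quoted in the field: the
#' reciprocal rounded to one significant figure, e.g. 0.032 -> "1:30".
#'
#' @param ratio [lnq] or number in (0, 1].
#' @return character label.
#' @export
ratio_label <- function(ratio) {
  med <- if (is_lnq(ratio)) ratio$median else as.numeric(ratio)
  sprintf("1:%s", format(signif(1 / med, 1), big.mark = "", scientific = FALSE))
}
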