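#' Physiological constants of the cfDNA mass balance
#'
#' Bundles the constants entering the flux model: blood plasma volume
#' (3 L), mean plasma lifetime of a cfDNA molecule (tau = half-life / ln 2 =
#' 0.7 h, with a multiplicative factor fitted to the literature half-life
#' range of 15-120 min treated as a ~95% band), haploid genome mass
#' (3.2e-12 g), the total plasma cfDNA concentration (around 1000 genome
#' equivalents (GE) per ml in healthy adults, see [default_total_cfdna()]),
#' the ultrashort-fragment adjustment range (1-2, midpoint 1.5), and the
#' assay detection band (1 GE/ml for targeted marker assays to 10 GE/ml for
#' genome-wide deconvolution).
#'
#' @param plasma_volume_l plasma volume in litres.
#' @param mean_lifetime_h [lnq], mean cfDNA lifetime in hours.
#' @param haploid_genome_mass_g haploid genome mass in grams.
#' @param total_cfdna [lnq], total plasma cfDNA in GE/ml.
#' @param adjustment_range length-2 numeric, uniform range of the
#'   ultrashort-fragment multiplier.
#' @param detection_band length-2 numeric, assay sensitivity bounds in GE/ml.
#' @return An object of class `cfdna_constants`.
#' @export
physiological_constants <- function(plasma_volume_l = 3,
                                    mean_lifetime_h = lnq(0.7, lifetime_factor()),
                                    haploid_genome_mass_g = 3.2e-12,
                                    total_cfdna = default_total_cfdna(),
                                    adjustment_range = c(1, 2),
                                    detection_band = c(1, 10)) {
  stopifnot(plasma_volume_l > 0, haploid_genome_mass_g > 0,
            is_lnq(mean_lifetime_h), is_lnq(total_cfdna),
            length(adjustment_range) == 2L, length(detection_band) == 2L)
  if (adjustment_range[1] > adjustment_range[2] || adjustment_range[1] < 0) {
    stop("invalid adjustment range", call. = FALSE)
  }
  if (detection_band[1] > detection_band[2] || detection_band[1] <= 0) {
    stop("invalid detection band", call. = FALSE)
  }
  structure(list(plasma_volume_l = plasma_volume_l,
                 mean_lifetime_h = mean_lifetime_h,
                 haploid_genome_mass_g = haploid_genome_mass_g,
                 total_cfdna = total_cfdna,
                 adjustment_range = as.numeric(adjustment_range),
                 detection_band = as.numeric(detection_band)),
            class = "cfdna_constants")
}

# Multiplicative factor on tau from the published half-life range 15-120 min
# read as a ~95% interval: s = ln(120/15) / (2 * 1.96).
lifetime_factor <- function() exp(log(120 / 15) / (2 * 1.96))

#' Default total plasma cfDNA concentration
#'
#' Median 1000 GE/ml (healthy individuals under 47). The factor combines the
#' 95% CI of the reported median concentration (reconstructed as
#' 850-1150 GE/ml) with a 1.4 multiplicative factor for inter-individual,
#' sampling-time and analytic variation, via the product shape rule.
#'
#' @return [lnq] in genome equivalents per ml.
#' @export
default_total_cfdna <- function() {
  median_ci <- from_interval(1000, 850, 1150)
  lnq_mul(median_ci, lnq(1, 1.4))
}

#' @rdname physiological_constants
#' @param x object to print.
#' @param ... ignored.
#' @export
print.cfdna_constants <- function(x, ...) {
  cat("cfDNA mass-balance constants\n")
  cat(sprintf("  plasma volume        %g L\n", x$plasma_volume_l))
  cat(sprintf("  mean cfDNA lifetime  %s h\n", format(x$mean_lifetime_h)))
  cat(sprintf("  haploid genome mass  %g g\n", x$haploid_genome_mass_g))
  cat(sprintf("  total plasma cfDNA   %s GE/ml\n", format(x$total_cfdna)))
  cat(sprintf("  adjustment range     [%g, %g]\n", x$adjustment_range[1],
              x$adjustment_range[2]))
  cat(sprintf("  detection band       [%g, %g] GE/ml\n", x$detection_band[1],
              x$detection_band[2]))
  invisible(x)
}

#' Read or write constants as JSON
#'
#' The JSON mirrors the fields of [physiological_constants()]; `lnq` values
#' are stored as `{"median": ..., "factor": ...}` objects. Missing keys fall
#' back to the defaults.
#'
#' @param path JSON file path.
#' @return `constants_from_json()` returns a `cfdna_constants` object.
#' @export
constants_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_cfg_lnq <- function(x) lnq(x$median, x$factor)
  defaults <- physiological_constants()
  physiological_constants(
    plasma_volume_l = cfg$plasma_volume_l %||% defaults$plasma_volume_l,
    mean_lifetime_h = if (!is.null(cfg$mean_lifetime_h))
      as_cfg_lnq(cfg$mean_lifetime_h) else defaults$mean_lifetime_h,
    haploid_genome_mass_g = cfg$haploid_genome_mass_g %||%
      defaults$haploid_genome_mass_g,
    total_cfdna = if (!is.null(cfg$total_cfdna))
      as_cfg_lnq(cfg$total_cfdna) else defaults$total_cfdna,
    adjustment_range = cfg$adjustment_range %||% defaults$adjustment_range,
    detection_band = cfg$detection_band %||% defaults$detection_band
  )
}

#' @rdname constants_from_json
#' @param constants a `cfdna_constants` object.
#' @export
constants_to_json <- function(constants, path) {
  stopifnot(inherits(constants, "cfdna_constants"))
  out <- list(
    plasma_volume_l = constants$plasma_volume_l,
    mean_lifetime_h = unclass(constants$mean_lifetime_h),
    haploid_genome_mass_g = constants$haploid_genome_mass_g,
    total_cfdna = unclass(constants$total_cfdna),
    adjustment_range = constants$adjustment_range,
    detection_band = constants$detection_band
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Potential plasma cfDNA concentration of a cell type
#'
#' The concentration that would be observed if every haploid genome copy of
#' every dying cell reached the plasma and cleared with mean lifetime tau:
#'
#'     X_c = d_c * p_c * tau / V_plasma
#'
#' with turnover d_c in cells/day, ploidy p_c in haploid sets per cell, tau
#' converted to days and the plasma volume to ml, giving X_c in genome
#' equivalents per ml. Uncertainty is the product of the turnover and
#' lifetime factors (ploidy and volume are treated as exact).
#'
#' @param record one row of a [celltype-table] data.frame.
#' @param constants a [physiological_constants()] object.
#' @return [lnq] in GE/ml.
#' @examples
#' tab <- reference_celltype_table()
#' potential_cfdna(tab[tab$name == "erythrocyte_progenitors", ],
#'                 physiological_constants())
#' @export
potential_cfdna <- function(record, constants) {
  stopifnot(inherits(constants, "cfdna_constants"))
  turnover <- row_turnover(record)
  if (record$ploidy < 1) stop("ploidy must be >= 1", call. = FALSE)
  tau_days <- lnq(constants$mean_lifetime_h$median / 24,
                  constants$mean_lifetime_h$factor)
  v_ml <- constants$plasma_volume_l * 1000
  # ploidy and plasma volume are exact scalars: they scale the median only
  lnq_mul(turnover, tau_days) * lnq(record$ploidy / v_ml, 1)
}

#' Convert a GE/ml concentration to mass concentration
#'
#' Multiplies by the haploid genome mass (3.2e-12 g per genome equivalent);
#' the factor is unchanged.
#'
#' @param x [lnq] in GE/ml.
#' @param constants a [physiological_constants()] object.
#' @return [lnq] in g/ml.
#' @export
to_mass_concentration <- function(x, constants) {
  stopifnot(is_lnq(x), inherits(constants, "cfdna_constants"))
  lnq(x$median * constants$haploid_genome_mass_g, x$factor)
}

#' Plasma half-life implied by systemic clearance
#'
#' If the gap between measured and potential cfDNA were explained purely by
#' fast systemic clearance (all dying-cell DNA enters the blood but is
#' removed quickly), the implied mean lifetime is
#' `tau_implied = measured * V_plasma / (d_c * p_c)` and the implied
#' half-life is `tau_implied * ln 2`. Equivalently, the assumed half-life
#' scaled by the capture ratio. Returned in seconds.
#'
#' @param measured [lnq], measured concentration in GE/ml.
#' @param record one row of a [celltype-table] data.frame.
#' @param constants a [physiological_constants()] object.
#' @return [lnq] half-life in seconds.
#' @export
implied_halflife <- function(measured, record, constants) {
  stopifnot(is_lnq(measured), inherits(constants, "cfdna_constants"))
  turnover <- row_turnover(record)
  v_ml <- constants$plasma_volume_l * 1000
  tau_days <- lnq_div(measured, turnover)
  lnq(tau_days$median * v_ml / record$ploidy * log(2) * 86400,
      tau_days$factor)
}
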