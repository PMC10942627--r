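#' Constants for the synthetic world
#'
#' The cohort generator simulates a world in which the mass-balance model is
#' exactly true and correctly specified: the cfDNA lifetime is known exactly
#' (factor 1) and no ultrashort-fragment correction is needed (adjustment
#' range 1-1). Under these constants the pipeline's 95% CIs should achieve
#' nominal coverage on synthetic cohorts.
#'
#' @param total_cfdna [lnq], observed total concentration (replaced by the
#'   cohort's own observation when running the pipeline on a cohort).
#' @return a `cfdna_constants` object.
#' @export
synthetic_constants <- function(total_cfdna = lnq(1000, 1)) {
  physiological_constants(mean_lifetime_h = lnq(0.7, 1),
                          total_cfdna = total_cfdna,
                          adjustment_range = c(1, 1))
}

# One noisy observation of a cohort truth table: multiplicative lognormal
# noise (shape ln(noise_factor)) on every observed quantity, each observed
# value carrying noise_factor as its stated error factor.
observe_cohort <- function(truth, noise_factor, constants, seed) {
  s <- log(noise_factor)
  tau_days <- constants$mean_lifetime_h$median / 24
  v_ml <- constants$plasma_volume_l * 1000
  contrib <- truth$turnover * truth$ploidy * tau_days / v_ml * truth$capture
  total_true <- sum(contrib)
  frac_true <- contrib / total_true
  withr::with_seed(as.integer(seed), {
    n <- nrow(truth)
    turn_obs <- truth$turnover * exp(s * stats::rnorm(n))
    frac_obs <- ifelse(truth$profiled,
                       frac_true * exp(s * stats::rnorm(n)), NA_real_)
    total_obs <- total_true * exp(s * stats::rnorm(1))
  })
  prof_sum <- sum(frac_obs, na.rm = TRUE)
  if (prof_sum > 1) frac_obs <- frac_obs / prof_sum
  records <- data.frame(
    name = truth$name,
    turnover_median = turn_obs,
    turnover_factor = noise_factor,
    ploidy = truth$ploidy,
    shed_externally = FALSE,
    fraction_median = frac_obs,
    fraction_factor = ifelse(is.na(frac_obs), NA_real_, noise_factor),
    stringsAsFactors = FALSE
  )
  list(records = validate_celltype_table(records),
       total_observed = lnq(total_obs, max(noise_factor, 1)))
}

#' Generate a synthetic cohort
#'
#' Draws ground-truth cell types whose turnover and capture fractions span
#' the regimes seen in real plasma (turnover log-uniform over about
#' 1e9-3e11 cells/day; capture fractions log-uniform over 3e-5 to 3e-2,
#' i.e. roughly 1:30000 to 1:30), then produces one noisy observed table:
#' every observed quantity (turnover, deconvolution fraction, total
#' concentration) is perturbed by multiplicative lognormal noise with the
#' given factor. In addition to the `n_types` profiled types, hidden
#' "unprofiled" types carry an equal share of the true cfDNA flux, so
#' observed fractions sum to about one half — as in real plasma, where
#' profiled cell types do not account for the full concentration.
#' `noise_factor = 1` returns the truth unperturbed.
#'
#' @param n_types number of profiled cell types.
#' @param turnover_range length-2, cells/day, log-uniform truth range.
#' @param capture_range length-2, dimensionless, log-uniform truth range.
#' @param noise_factor multiplicative noise factor, `>= 1`.
#' @param seed integer seed.
#' @return object of class `cfdna_cohort`: list with `truth` (data.frame:
#'   `name`, `turnover`, `ploidy`, `capture`, `profiled`), `observed`
#'   ([celltype-table] data.frame), `total_observed` ([lnq]), `constants`,
#'   `noise_factor`, `seed`.
#' @export
generate_cohort <- function(n_types = 8,
                            turnover_range = c(1e9, 3e11),
                            capture_range = c(3e-5, 3e-2),
                            noise_factor = 1.5, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_types >= 1, noise_factor >= 1,
            turnover_range[1] > 0, turnover_range[1] <= turnover_range[2],
            capture_range[1] > 0, capture_range[1] <= capture_range[2])
  constants <- synthetic_constants()
  logunif <- function(n, rng) exp(stats::runif(n, log(rng[1]), log(rng[2])))
  truth <- withr::with_seed(as.integer(seed), {
    turnover <- logunif(n_types, turnover_range)
    capture <- logunif(n_types, capture_range)
    tau_days <- constants$mean_lifetime_h$median / 24
    v_ml <- constants$plasma_volume_l * 1000
    contrib <- turnover * 2 * tau_days / v_ml * capture
    # hidden pool: same total flux as the profiled types, mid-range capture
    cap_mid <- sqrt(capture_range[1] * capture_range[2])
    hidden_turnover <- sum(contrib) * v_ml / (2 * tau_days * cap_mid)
    data.frame(
      name = c(sprintf("type_%02d", seq_len(n_types)), "unprofiled_pool"),
      turnover = c(turnover, hidden_turnover),
      ploidy = 2,
      capture = c(capture, cap_mid),
      profiled = c(rep(TRUE, n_types), FALSE),
      stringsAsFactors = FALSE
    )
  })
  obs <- observe_cohort(truth, noise_factor, constants,
                        seed = derive_seed(seed, 1L))
  structure(list(truth = truth, observed = obs$records,
                 total_observed = obs$total_observed, constants = constants,
                 noise_factor = noise_factor, seed = as.integer(seed)),
            class = "cfdna_cohort")
}

#' @export
print.cfdna_cohort <- function(x, ...) {
  cat(sprintf("<cfdna_cohort> %d profiled types, noise factor %g, seed %d\n",
              sum(x$truth$profiled), x$noise_factor, x$seed))
  invisible(x)
}

#' Run the pipeline on a synthetic cohort
#'
#' Convenience wrapper: runs [summarize_flux()] on the cohort's observed
#' table using the cohort's constants with the observed total concentration.
#'
#' @param cohort a [generate_cohort()] object.
#' @param seed integer seed.
#' @param n_adjust iterations for the adjustment bootstrap.
#' @return a [summarize_flux()] data.frame.
#' @export
pipeline_on_cohort <- function(cohort, seed, n_adjust = 10000) {
  constants <- cohort$constants
  constants$total_cfdna <- cohort$total_observed
  summarize_flux(cohort$observed, constants, seed = seed,
                 n_adjust = n_adjust)
}

#' Parameter-recovery report for the capture-ratio pipeline
#'
#' Re-draws the cohort's observations `n_replicates` times from the same
#' ground truth, runs the full pipeline on each replicate, and compares the
#' estimated capture ratios with the true capture fractions: per-type median
#' bias of the log ratio estimate, pooled empirical coverage of the 95% CIs,
#' and the mean CI width on the log scale.
#'
#' @param cohort a [generate_cohort()] object (carries truth and noise
#'   level).
#' @param n_replicates number of independent re-observations.
#' @param seed integer seed.
#' @param n_adjust iterations for the adjustment bootstrap per replicate.
#' @return list with `per_type` (data.frame: `name`, `true_capture`,
#'   `bias_log`, `coverage`), `coverage` (pooled), `mean_ci_logwidth`,
#'   `n_replicates`.
#' @export
recovery_report <- function(cohort, n_replicates = 500, seed,
                            n_adjust = 10000) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(cohort, "cfdna_cohort"), n_replicates >= 1)
  truth <- cohort$truth[cohort$truth$profiled, ]
  k <- nrow(truth)
  logerr <- matrix(NA_real_, n_replicates, k)
  covered <- matrix(NA, n_replicates, k)
  widths <- numeric(0)
  for (r in seq_len(n_replicates)) {
    obs <- observe_cohort(cohort$truth, cohort$noise_factor,
                          cohort$constants, seed = derive_seed(seed, r))
    constants <- cohort$constants
    constants$total_cfdna <- obs$total_observed
    res <- summarize_flux(obs$records, constants,
                          seed = derive_seed(seed, r) + 1L,
                          n_adjust = n_adjust)
    res <- res[match(truth$name, res$name), ]
    logerr[r, ] <- log(res$ratio_median / truth$capture)
    # small relative guard so zero-width CIs in the noiseless limit are not
    # missed through floating-point round-off
    covered[r, ] <- truth$capture >= res$ratio_lo * (1 - 1e-9) &
      truth$capture <= res$ratio_hi * (1 + 1e-9)
    widths <- c(widths, log(res$ratio_hi / res$ratio_lo))
  }
  per_type <- data.frame(
    name = truth$name,
    true_capture = truth$capture,
    bias_log = apply(logerr, 2, stats::median),
    coverage = colMeans(covered),
    stringsAsFactors = FALSE
  )
  list(per_type = per_type,
       coverage = mean(covered),
       mean_ci_logwidth = mean(widths),
       n_replicates = n_replicates)
}
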