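#' Lognormal quantities with multiplicative uncertainty
#'
#' A `lnq` is a positive estimate whose uncertainty is multiplicative: the
#' quantity is modelled as lognormally distributed with median `median` and
#' multiplication error factor `factor` (f >= 1). The shape parameter of the
#' distribution is `s = ln(factor)`, so a factor of 2 means a 68% (one sigma)
#' probability that the true value lies between half and double the median.
#' This is the universal carrier of every estimate in the cfDNA flux pipeline.
#'
#' @param median positive number, the median of the distribution (units are
#'   carried by context).
#' @param factor multiplication error factor, a number `>= 1`. `factor = 1`
#'   encodes an exact value.
#' @return An object of class `lnq` with elements `median` and `factor`.
#' @examples
#' x <- lnq(100, 2)
#' lnq_shape(x)   # ln 2
#' ci95(x)        # approx (25.7, 389)
#' @export
lnq <- function(median, factor = 1) {
  if (!is.numeric(median) || length(median) != 1L || !is.finite(median) ||
      median <= 0) {
    stop("`median` must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 1) {
    stop("`factor` must be a single finite number >= 1", call. = FALSE)
  }
  structure(list(median = as.numeric(median), factor = as.numeric(factor)),
            class = "lnq")
}

#' @rdname lnq
#' @param x object to test or print.
#' @export
is_lnq <- function(x) inherits(x, "lnq")

as_lnq <- function(x) {
  if (is_lnq(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(lnq(x, 1))
  stop("cannot interpret object as a lognormal quantity", call. = FALSE)
}

#' @rdname lnq
#' @param ... ignored.
#' @export
print.lnq <- function(x, ...) {
  cat(sprintf("<lnq> median %.6g, factor %.4g (95%% CI %.4g-%.4g)\n",
              x$median, x$factor, ci95(x)[1], ci95(x)[2]))
  invisible(x)
}

#' @export
format.lnq <- function(x, ...) {
  sprintf("%.4g (x/ %.3g)", x$median, x$factor)
}

#' Shape parameter of a lognormal quantity
#'
#' Returns `s = ln(factor)`, the standard deviation of the log-transformed
#' variable.
#'
#' @param x a [lnq] quantity.
#' @return non-negative number.
#' @export
lnq_shape <- function(x) {
  stopifnot(is_lnq(x))
  log(x$factor)
}

#' Build a lognormal quantity from a 95% confidence interval
#'
#' Transforms a value reported with a 95% CI into multiplicative-error form by
#' fitting a lognormal whose 95% band has the same width on the log scale:
#' `s = ln(ci_high / ci_low) / (2 * 1.96)`. Asymmetric intervals are
#' symmetrized on the log scale and the stated median is kept.
#'
#' @param median positive number, the reported central value.
#' @param ci_low,ci_high bounds of the reported 95% interval,
#'   `0 < ci_low <= median <= ci_high`.
#' @return A [lnq] quantity.
#' @examples
#' from_interval(100, 25.7, 389)  # factor ~2
#' @export
from_interval <- function(median, ci_low, ci_high) {
  if (!is.numeric(ci_low) || !is.numeric(ci_high) ||
      length(ci_low) != 1L || length(ci_high) != 1L) {
    stop("interval bounds must be single numbers", call. = FALSE)
  }
  if (!(ci_low > 0 && ci_low <= median && median <= ci_high)) {
    stop("require 0 < ci_low <= median <= ci_high", call. = FALSE)
  }
  s <- log(ci_high / ci_low) / (2 * 1.96)
  lnq(median, exp(s))
}

#' 95% confidence interval of a lognormal quantity
#'
#' `(median * exp(-1.96 s), median * exp(+1.96 s))` with `s = ln(factor)`.
#' `ci95()` and [from_interval()] are mutual inverses on the factor.
#'
#' @param x a [lnq] quantity.
#' @return numeric vector `c(low, high)`.
#' @export
ci95 <- function(x) {
  stopifnot(is_lnq(x))
  s <- lnq_shape(x)
  c(x$median * exp(-1.96 * s), x$median * exp(1.96 * s))
}

#' Multiply or divide lognormal quantities
#'
#' Products and ratios of independent lognormal variables are lognormal;
#' medians multiply (or divide) and the shape parameters combine by the
#' root-sum-square rule, so the product factor is
#' `exp(sqrt(ln(f_x)^2 + ln(f_y)^2))`. Operands are treated as independent:
#' `lnq_div(x, x)` has median 1 but a factor above 1.
#'
#' @param x,y [lnq] quantities (bare positive numbers are promoted to exact
#'   quantities with factor 1).
#' @return A [lnq] quantity.
#' @examples
#' lnq_mul(lnq(3, 2), lnq(4, 2))  # median 12, factor 2^sqrt(2)
#' @export
lnq_mul <- function(x, y) {
  x <- as_lnq(x); y <- as_lnq(y)
  lnq(x$median * y$median,
      exp(sqrt(lnq_shape(x)^2 + lnq_shape(y)^2)))
}

#' @rdname lnq_mul
#' @export
lnq_div <- function(x, y) {
  x <- as_lnq(x); y <- as_lnq(y)
  lnq(x$median / y$median,
      exp(sqrt(lnq_shape(x)^2 + lnq_shape(y)^2)))
}

#' @export
Ops.lnq <- function(e1, e2) {
  if (nargs() == 1L) stop("unary operators are not defined for lnq objects")
  switch(.Generic,
         "*" = lnq_mul(e1, e2),
         "/" = lnq_div(e1, e2),
         stop(sprintf("operator '%s' is not defined for lnq objects",
                      .Generic), call. = FALSE))
}

#' Draw random samples from a lognormal quantity
#'
#' @param x a [lnq] quantity.
#' @param n number of draws.
#' @return numeric vector of `n` positive draws with median `x$median` and
#'   log-scale SD `ln(x$factor)`.
#' @export
lnq_sample <- function(x, n) {
  stopifnot(is_lnq(x))
  stats::rlnorm(n, meanlog = log(x$median), sdlog = lnq_shape(x))
}

#' Fit a lognormal quantity to positive samples
#'
#' Fits on the log scale: `median = exp(mean(ln x))`,
#' `factor = exp(sd(ln x))`. With this estimator the fit exactly inverts
#' sampling from a `lnq` in the large-n limit, and it is robust to the heavy
#' right tail of lognormal sums.
#'
#' @param samples numeric vector of at least two positive values.
#' @return A [lnq] quantity.
#' @export
fit_lognormal <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("need at least two samples", call. = FALSE)
  }
  if (any(!is.finite(samples)) || any(samples <= 0)) {
    stop("all samples must be positive and finite", call. = FALSE)
  }
  lx <- log(samples)
  # population SD: the fit is a distribution summary, not an inference step
  s <- sqrt(mean((lx - mean(lx))^2))
  lnq(exp(mean(lx)), exp(s))
}

#' Bootstrap error propagation for sums of lognormal quantities
#'
#' There is no closed form for the distribution of a sum of lognormal
#' variables, so the sum is propagated by resampling: `n_samples` vectors are
#' drawn (one draw per summand), summed per draw, and a lognormal is fitted
#' to the sums with [fit_lognormal()].
#'
#' @param quantities a non-empty list of [lnq] quantities.
#' @param n_samples number of bootstrap draws (default 1000).
#' @param seed integer seed; identical seeds give identical results.
#' @return A [lnq] quantity describing the sum.
#' @export
bootstrap_sum <- function(quantities, n_samples = 1000, seed) {
  if (!is.list(quantities) || length(quantities) == 0L) {
    stop("`quantities` must be a non-empty list", call. = FALSE)
  }
  if (n_samples < 2) stop("`n_samples` must be >= 2", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  quantities <- lapply(quantities, as_lnq)
  withr::with_seed(as.integer(seed), {
    draws <- vapply(quantities, lnq_sample, numeric(n_samples), n = n_samples)
    sums <- if (length(quantities) == 1L) as.numeric(draws) else rowSums(draws)
    fit_lognormal(sums)
  })
}

#' Apply a uniformly distributed multiplicative adjustment
#'
#' Multiplies a quantity by an adjustment factor that is only known to lie
#' uniformly in `[low, high]` (used for the ultrashort-fragment correction of
#' the total cfDNA concentration, range 1-2). The product has no closed form,
#' so `n_iter` pairs (draw of `x`, uniform factor) are multiplied and a
#' lognormal is refitted to the products to allow further propagation.
#'
#' @param x a [lnq] quantity.
#' @param low,high adjustment range, `1 <= low <= high` (default 1-2).
#' @param n_iter bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @return A [lnq] quantity for the adjusted value.
#' @export
apply_uniform_factor <- function(x, low = 1, high = 2, n_iter = 10000, seed) {
  stopifnot(is_lnq(x))
  if (!is.numeric(low) || !is.numeric(high) || low < 0) {
    stop("adjustment bounds must be non-negative numbers", call. = FALSE)
  }
  if (low > high) stop("`low` must not exceed `high`", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    xs <- lnq_sample(x, n_iter)
    u <- stats::runif(n_iter, low, high)
    fit_lognormal(xs * u)
  })
}

# Deterministic child seeds below 2^31, so one pipeline seed can drive
# several independent stochastic operations.
derive_seed <- function(seed, k) {
  base <- ((as.integer(seed) %% 1009L) * 1000003L) %% 2147483L
  base * 1000L + as.integer(k)
}
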