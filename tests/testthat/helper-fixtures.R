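# Small hand-built cell-type table used across tests: one dominant profiled
# type, one minor profiled type, one unprofiled and one externally shed type.
tiny_celltype_table <- function() {
  data.frame(
    name = c("alpha", "beta", "gamma", "delta"),
    turnover_median = c(2e11, 5e7, 2e8, 1e10),
    turnover_factor = c(1.2, 1.8, 2.0, 1.4),
    ploidy = c(2, 16, 2, 2),
    shed_externally = c(FALSE, FALSE, FALSE, TRUE),
    fraction_median = c(0.085, 0.17, NA, NA),
    fraction_factor = c(1.3, 1.25, NA, NA),
    stringsAsFactors = FALSE
  )
}

exact_constants <- function(total = lnq(1000, 1)) {
  physiological_constants(mean_lifetime_h = lnq(0.7, 1),
                          total_cfdna = total,
                          adjustment_range = c(1, 1))
}

expect_lnq_equal <- function(x, median, factor, tol = 1e-10) {
  expect_s3_class(x, "lnq")
  expect_equal(x$median, median, tolerance = tol)
  expect_equal(x$factor, factor, tolerance = tol)
}
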