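test_that("megakaryocyte turnover estimators divide with shape propagation", {
  expect_lnq_equal(mk_turnover_from_marrow(lnq(1e10), lnq(5)), 2e9, 1)
  expect_lnq_equal(mk_turnover_from_marrow(lnq(1e10, 2), lnq(5)), 2e9, 2)
  both <- mk_turnover_from_marrow(lnq(1e10, 1.5), lnq(5, 1.5))
  expect_equal(both$factor, exp(sqrt(2 * log(1.5)^2)), tolerance = 1e-12)
  expect_equal(both$factor, 1.77, tolerance = 1e-2)

  expect_lnq_equal(mk_turnover_from_platelets(lnq(1e11), lnq(2000)), 5e7, 1)
  f2 <- mk_turnover_from_platelets(lnq(1e11, 2), lnq(2000, 2))
  expect_equal(f2$factor, 2^sqrt(2), tolerance = 1e-12)
})

test_that("both estimators are homogeneous of degree 1 / -1", {
  set.seed(4)
  for (i in 1:10) {
    k <- exp(rnorm(1))
    n <- lnq(1e10 * k, 1.4); m <- lnq(5, 1.2)
    expect_equal(mk_turnover_from_marrow(n, m)$median,
                 k * mk_turnover_from_marrow(lnq(1e10, 1.4), m)$median)
    expect_equal(mk_turnover_from_marrow(lnq(1e10), lnq(5 * k))$median,
                 mk_turnover_from_marrow(lnq(1e10), lnq(5))$median / k)
  }
})

test_that("combine_estimates penalizes disagreement between routes", {
  x <- lnq(5e7, 1.6)
  expect_lnq_equal(combine_estimates(x, x), 5e7, 1.6)
  merged <- combine_estimates(lnq(1e9), lnq(4e9))
  expect_lnq_equal(merged, 2e9, 2)
  expect_lnq_equal(combine_estimates(lnq(2, 3), lnq(2, 3)), 2, 3)
})

test_that("hepatocyte turnover combines ploidy groups by death flux", {
  groups <- data.frame(cell_count = c(1e11, 5e10),
                       death_rate = c(0.002, 0.001), ploidy = c(2, 4))
  out <- hepatocyte_turnover(groups)
  expect_lnq_equal(out$turnover, 2.5e8, 1)
  expect_equal(out$effective_ploidy, 2.4)

  single <- hepatocyte_turnover(data.frame(cell_count = 1e10,
                                           death_rate = 0.01, ploidy = 4))
  expect_equal(single$effective_ploidy, 4)

  # equal fluxes at ploidy 2 and 4 average to 3
  eq <- hepatocyte_turnover(data.frame(cell_count = c(1e10, 2e10),
                                       death_rate = c(0.002, 0.001),
                                       ploidy = c(2, 4)))
  expect_equal(eq$effective_ploidy, 3)

  expect_error(hepatocyte_turnover(data.frame()), "non-empty")
  expect_error(hepatocyte_turnover(data.frame(cell_count = 1,
                                              death_rate = 2, ploidy = 2)),
               "cannot exceed 1")
})

test_that("effective ploidy stays inside the group ploidy range", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    g <- data.frame(cell_count = exp(runif(n, 20, 26)),
                    death_rate = runif(n, 1e-4, 5e-3),
                    ploidy = sample(c(2, 4, 8), n, replace = TRUE))
    ep <- hepatocyte_turnover(g)$effective_ploidy
    expect_gte(ep, min(g$ploidy))
    expect_lte(ep, max(g$ploidy))
  }
})

test_that("cell-type tables validate, reject bad rows, and roundtrip", {
  tab <- tiny_celltype_table()
  expect_silent(validate_celltype_table(tab))

  bad <- tab
  bad$fraction_median[4] <- 0.1   # shed type with a fraction
  bad$fraction_factor[4] <- 1.2
  expect_error(validate_celltype_table(bad), "row 4.*shed")

  bad2 <- tab
  bad2$turnover_median[2] <- -1
  expect_error(validate_celltype_table(bad2), "row 2.*turnover")

  bad3 <- tab
  bad3$fraction_median[1] <- 1.2
  expect_error(validate_celltype_table(bad3), "\\(0, 1\\]")

  expect_error(validate_celltype_table(tab[, -3]), "missing columns")

  path <- withr::local_tempfile(fileext = ".csv")
  write_celltype_table(tab, path)
  back <- load_celltype_table(path)
  expect_equal(back, validate_celltype_table(tab))

  # header-only file loads as empty with a warning
  empty <- withr::local_tempfile(fileext = ".csv")
  write_celltype_table(tab[0, ], empty)
  expect_warning(e <- load_celltype_table(empty), "empty")
  expect_equal(nrow(e), 0)

  expect_error(load_celltype_table("no/such/file.csv"), "not found")
})

test_that("reference fixtures are mutually consistent", {
  tab <- reference_celltype_table()
  hep_row <- tab[tab$name == "hepatocytes", ]
  hep <- hepatocyte_turnover(reference_hepatocyte_groups(), seed = 10)
  expect_equal(hep$turnover$median, hep_row$turnover_median)
  expect_equal(hep$effective_ploidy, hep_row$ploidy, tolerance = 1e-4)
  expect_equal(hep$turnover$factor, hep_row$turnover_factor, tolerance = 0.02)

  mk_row <- tab[tab$name == "megakaryocytes", ]
  ins <- reference_megakaryocyte_inputs()
  merged <- combine_estimates(
    mk_turnover_from_marrow(ins$n_marrow, ins$maturation_days),
    mk_turnover_from_platelets(ins$platelet_production, ins$platelets_per_mk))
  expect_equal(merged$median, mk_row$turnover_median)
  expect_equal(merged$factor, mk_row$turnover_factor, tolerance = 0.01)

  # shipped CSV equals the in-code builder
  csv <- system.file("extdata", "celltype_table_synthetic.csv",
                     package = "cfdnaflux")
  expect_equal(load_celltype_table(csv), tab, tolerance = 1e-12)
})
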