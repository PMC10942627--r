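#' Cell-type table schema
#'
#' The pipeline's tabular carrier is a plain data.frame with one row per cell
#' type and columns:
#'
#' * `name` — identifier.
#' * `turnover_median`, `turnover_factor` — cellular turnover d_c in
#'   cells/day with its multiplication error factor.
#' * `ploidy` — average haploid genome sets per dying cell (p_c, `>= 1`).
#' * `shed_externally` — logical; TRUE for epithelia whose dying cells leave
#'   the body (gut lumen, airways, urine, skin) and therefore cannot appear
#'   in plasma.
#' * `fraction_median`, `fraction_factor` — optional (NA when absent)
#'   fraction of total plasma cfDNA attributed to the type by methylome
#'   deconvolution, with its error factor.
#'
#' Externally shed types never carry a measured fraction.
#'
#' @name celltype-table
NULL

celltype_columns <- c("name", "turnover_median", "turnover_factor", "ploidy",
                      "shed_externally", "fraction_median", "fraction_factor")

#' Validate a cell-type table
#'
#' Checks the schema and row invariants of a [celltype-table] data.frame and
#' returns it with columns in canonical order. Violations are reported with
#' row numbers.
#'
#' @param df data.frame to validate.
#' @return the validated data.frame.
#' @export
validate_celltype_table <- function(df) {
  missing_cols <- setdiff(celltype_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("cell-type table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[celltype_columns]
  if (nrow(df) == 0L) return(df)
  df$shed_externally <- as.logical(df$shed_externally)
  problems <- character(0)
  flag <- function(rows, msg) {
    if (any(rows)) {
      problems <<- c(problems,
                     sprintf("row %d: %s", which(rows), msg))
    }
  }
  flag(!is.finite(df$turnover_median) | df$turnover_median <= 0,
       "turnover_median must be positive")
  flag(!is.finite(df$turnover_factor) | df$turnover_factor < 1,
       "turnover_factor must be >= 1")
  flag(!is.finite(df$ploidy) | df$ploidy < 1, "ploidy must be >= 1")
  flag(is.na(df$shed_externally), "shed_externally must be TRUE/FALSE")
  has_frac <- !is.na(df$fraction_median)
  flag(has_frac & (df$fraction_median <= 0 | df$fraction_median > 1),
       "fraction_median must be in (0, 1]")
  flag(has_frac & (is.na(df$fraction_factor) | df$fraction_factor < 1),
       "fraction_factor must be >= 1 when a fraction is given")
  flag(has_frac & df$shed_externally %in% TRUE,
       "externally shed cell types cannot carry a measured cfDNA fraction")
  if (length(problems) > 0L) {
    stop("invalid cell-type table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df
}

#' Read and write cell-type tables
#'
#' CSV dialect: comma-separated, UTF-8, "." decimal, header required; empty
#' cells in the fraction columns mean "not profiled in plasma".
#'
#' @param path file path.
#' @return `load_celltype_table()` returns a validated [celltype-table]
#'   data.frame (empty, with a warning, for a header-only file).
#' @export
load_celltype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("turnover_median", "turnover_factor", "ploidy",
                "fraction_median", "fraction_factor")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  df <- validate_celltype_table(df)
  if (nrow(df) == 0L) warning("cell-type table is empty: ", path)
  df
}

#' @rdname load_celltype_table
#' @param df a [celltype-table] data.frame.
#' @export
write_celltype_table <- function(df, path) {
  df <- validate_celltype_table(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

row_turnover <- function(row) lnq(row$turnover_median, row$turnover_factor)
row_fraction <- function(row) {
  if (is.na(row$fraction_median)) return(NULL)
  lnq(row$fraction_median, row$fraction_factor)
}

#' Megakaryocyte turnover estimators
#'
#' Megakaryocyte turnover is not measured directly; it is estimated two ways
#' and the two routes are merged with [combine_estimates()].
#' `mk_turnover_from_marrow()` divides the marrow megakaryocyte pool by the
#' maturation time (around five days); `mk_turnover_from_platelets()` divides
#' daily platelet production by the platelet yield per megakaryocyte.
#' Uncertainty propagates by the product shape rule.
#'
#' @param n_megakaryocytes [lnq], cells in the marrow pool.
#' @param maturation_time [lnq], days from progenitor to platelet release.
#' @return [lnq] turnover in cells/day.
#' @export
mk_turnover_from_marrow <- function(n_megakaryocytes, maturation_time) {
  lnq_div(as_lnq(n_megakaryocytes), as_lnq(maturation_time))
}

#' @rdname mk_turnover_from_marrow
#' @param platelet_production [lnq], platelets produced per day.
#' @param platelets_per_mk [lnq], platelets yielded per megakaryocyte.
#' @export
mk_turnover_from_platelets <- function(platelet_production, platelets_per_mk) {
  lnq_div(as_lnq(platelet_production), as_lnq(platelets_per_mk))
}

#' Merge two independent estimates of the same quantity
#'
#' Median is the geometric mean of the two medians. The factor is the largest
#' of the two within-estimate factors and the spread factor
#' `sqrt(larger median / smaller median)`, so disagreement between estimation
#' routes widens the uncertainty rather than being averaged away.
#'
#' @param a,b [lnq] estimates in the same units.
#' @return [lnq] merged estimate.
#' @export
combine_estimates <- function(a, b) {
  a <- as_lnq(a); b <- as_lnq(b)
  spread <- sqrt(max(a$median, b$median) / min(a$median, b$median))
  lnq(sqrt(a$median * b$median), max(a$factor, b$factor, spread))
}

#' Hepatocyte turnover from ploidy groups
#'
#' Hepatocytes are polyploid to varying degrees; turnover is built by
#' combining, per ploidy class, the number of cells and their death rate.
#' The turnover median is the exact sum of group fluxes
#' `count_i * death_rate_i`; its factor is propagated by [bootstrap_sum()]
#' over the group-flux lognormals (groups with no `factor` column are exact).
#' The effective ploidy is the death-flux-weighted mean ploidy and is treated
#' as exact.
#'
#' @param groups data.frame with columns `cell_count` (cells), `death_rate`
#'   (fraction/day, `<= 1`), `ploidy` (haploid sets), and optionally `factor`
#'   (multiplicative error on the group flux).
#' @param seed integer seed for the bootstrap (only consulted when any group
#'   carries a factor above 1).
#' @param n_samples bootstrap draws.
#' @return list with `turnover` ([lnq] cells/day) and `effective_ploidy`.
#' @export
hepatocyte_turnover <- function(groups, seed = 1L, n_samples = 1000) {
  if (!is.data.frame(groups) || nrow(groups) == 0L) {
    stop("`groups` must be a non-empty data.frame", call. = FALSE)
  }
  needed <- c("cell_count", "death_rate", "ploidy")
  if (!all(needed %in% names(groups))) {
    stop("`groups` needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  with(groups, {
    if (any(cell_count <= 0) || any(death_rate <= 0) || any(ploidy <= 0)) {
      stop("all ploidy-group fields must be positive", call. = FALSE)
    }
    if (any(death_rate > 1)) {
      stop("death_rate is a fraction per day and cannot exceed 1",
           call. = FALSE)
    }
  })
  flux <- groups$cell_count * groups$death_rate
  total <- sum(flux)
  eff_ploidy <- sum(flux * groups$ploidy) / total
  factors <- if ("factor" %in% names(groups)) groups$factor else rep(1, nrow(groups))
  factor <- if (all(factors <= 1)) {
    1
  } else {
    qs <- Map(lnq, flux, factors)
    bootstrap_sum(qs, n_samples = n_samples, seed = seed)$factor
  }
  list(turnover = lnq(total, factor), effective_ploidy = eff_ploidy)
}
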