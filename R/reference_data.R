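#' Reconstructed reference cell-type table
#'
#' A synthetic reconstruction of the cell-type inputs of the mass balance:
#' turnover rates follow published whole-body turnover estimates (erythroid
#' progenitors dominate at 2e11 cells/day; megakaryocyte turnover combines
#' the marrow-pool and platelet-production routes; hepatocyte turnover and
#' effective ploidy come from ploidy-group combination), the externally shed
#' epithelia (gut, lung, kidney, bladder, skin) carry no plasma fraction, and
#' deconvolution fractions are consistent with reported plasma methylome
#' compositions and with the published capture-ratio anchors (about 1:30 for
#' megakaryocytes and endothelium, about 1:30000 for erythroid progenitors).
#' The same table ships as a CSV at
#' `system.file("extdata", "celltype_table_synthetic.csv", package = "cfdnaflux")`.
#'
#' @return a validated [celltype-table] data.frame.
#' @export
reference_celltype_table <- function() {
  df <- data.frame(
    name = c("erythrocyte_progenitors", "granulocytes", "gut_epithelium",
             "lymphocytes", "monocytes_macrophages", "skin_epidermis",
             "lung_epithelium", "hepatocytes", "kidney_epithelium",
             "skeletal_myocytes", "endothelial_cells", "breast_epithelium",
             "bladder_epithelium", "megakaryocytes", "adipocytes",
             "pancreatic_beta_cells", "cardiomyocytes"),
    turnover_median = c(2.0e11, 6.0e10, 1.0e10, 1.0e10, 7.0e9, 1.0e9,
                        5.0e8, 2.725e8, 2.0e8, 2.0e8, 1.0e8, 1.0e8,
                        5.0e7, 5.0e7, 5.0e7, 2.0e5, 8.0e4),
    turnover_factor = c(1.2, 1.6, 1.4, 2.0, 1.8, 1.5,
                        2.0, 1.48, 2.0, 2.2, 2.0, 2.5,
                        2.2, 1.81, 2.0, 2.5, 2.5),
    ploidy = c(2, 2, 2, 2, 2, 2, 2, 2.3853, 2, 2, 2, 2, 2, 16, 2, 2, 4),
    shed_externally = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
                        TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                        TRUE, FALSE, FALSE, FALSE, FALSE),
    fraction_median = c(0.085, 0.32, NA, 0.12, 0.10, NA,
                        NA, 0.01, NA, NA, 0.044, NA,
                        NA, 0.17, NA, NA, NA),
    fraction_factor = c(1.3, 1.2, NA, 1.3, 1.3, NA,
                        NA, 1.5, NA, NA, 1.4, NA,
                        NA, 1.25, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  validate_celltype_table(df)
}

#' Reconstructed hepatocyte ploidy groups
#'
#' Synthetic reconstruction of the hepatocyte ploidy-class inputs: cell
#' counts and daily death rates for diploid, tetraploid and octoploid
#' hepatocytes. Feeding these to [hepatocyte_turnover()] reproduces the
#' hepatocyte row of [reference_celltype_table()] (turnover 2.725e8
#' cells/day, effective ploidy ~2.385).
#'
#' @return data.frame with columns `cell_count`, `death_rate`, `ploidy`,
#'   `factor`.
#' @export
reference_hepatocyte_groups <- function() {
  data.frame(
    cell_count = c(1.5e11, 4.5e10, 5.0e9),
    death_rate = c(0.0015, 0.0010, 0.0005),
    ploidy = c(2, 4, 8),
    factor = c(1.6, 1.6, 1.6)
  )
}

#' Reconstructed megakaryocyte turnover inputs
#'
#' The two estimation routes with synthetic-reconstruction input values:
#' a marrow pool of 2.5e8 megakaryocytes maturing in about five days, and
#' 1e11 platelets produced per day at about 2000 platelets per
#' megakaryocyte. Both routes give 5e7 cells/day; [combine_estimates()]
#' merges them into the megakaryocyte row of [reference_celltype_table()].
#'
#' @return list with [lnq] elements `n_marrow`, `maturation_days`,
#'   `platelet_production`, `platelets_per_mk`.
#' @export
reference_megakaryocyte_inputs <- function() {
  list(n_marrow = lnq(2.5e8, 1.7),
       maturation_days = lnq(5, 1.3),
       platelet_production = lnq(1e11, 1.3),
       platelets_per_mk = lnq(2000, 1.5))
}
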