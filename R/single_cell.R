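# Cell-level expressing-fraction and composition summaries.
#
# The cell table is a plain data.frame: one row per cell with metadata
# columns (cell_id, cell_type and/or detailed_type, patient_id, tissue)
# and one integer raw-count column per transcript feature.  Labels and
# counts are inputs (clustering and quantification are upstream).

.check_cells <- function(cells, feature, meta = character()) {
  stopifnot(is.data.frame(cells))
  miss <- setdiff(c(feature, meta), names(cells))
  if (length(miss))
    stop("cell table missing column(s): ", paste(miss, collapse = ", "))
  if (length(feature)) {
    cnt <- cells[[feature]]
    if (any(cnt < 0) || any(cnt != floor(cnt)))
      stop("feature '", feature,
           "' must hold non-negative integer counts")
  }
  invisible(cells)
}

#' Cell-type composition of expressing cells
#'
#' Among cells expressing a feature (raw count at or above
#' `min_count`), the percentage breakdown by cell type.  Percentages
#' sum to 100.
#'
#' @param cells cell table data.frame.
#' @param feature name of the feature count column.
#' @param min_count minimum raw count to call a cell expressing
#'   (default 1).
#' @param type_col cell-type column to break down by.
#' @return data.frame with `cell_type`, `n_cells`, `percentage`.
#' @export
composition_of_expressing_cells <- function(cells, feature,
                                            min_count = 1L,
                                            type_col = "cell_type") {
  .check_cells(cells, feature, type_col)
  expr <- cells[cells[[feature]] >= min_count, , drop = FALSE]
  if (nrow(expr) == 0L)
    stop("no cell expresses '", feature, "' at min_count = ", min_count)
  tab <- table(expr[[type_col]])
  data.frame(cell_type = names(tab),
             n_cells = as.integer(tab),
             percentage = 100 * as.integer(tab) / sum(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of cells expressing a feature, per cell type
#'
#' Cell types represented by more than `min_cells_per_type` cells are
#' summarized (the default reproduces the "more than 600 cells"
#' inclusion rule, i.e. strictly greater); smaller types are omitted
#' and reported in the `omitted` attribute.  A cell expresses the
#' feature when its raw count is at least 1.
#'
#' @param cells cell table data.frame.
#' @param feature feature count column.
#' @param min_cells_per_type exclusive cell-count filter (default 600).
#' @param type_col cell-type column (typically the detailed labels).
#' @param min_count expressing threshold on raw counts.
#' @return data.frame with `cell_type`, `n_cells`, `n_expressing`,
#'   `fraction`; attribute `omitted` lists excluded types.
#' @export
fraction_expressing_by_celltype <- function(cells, feature,
                                            min_cells_per_type = 600L,
                                            type_col = "cell_type",
                                            min_count = 1L) {
  .check_cells(cells, feature, type_col)
  sp <- split(cells[[feature]], cells[[type_col]])
  n <- lengths(sp)
  keep <- n > min_cells_per_type
  out <- data.frame(
    cell_type = names(sp)[keep],
    n_cells = as.integer(n[keep]),
    n_expressing = vapply(sp[keep], function(v)
      sum(v >= min_count), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  out$fraction <- out$n_expressing / out$n_cells
  attr(out, "omitted") <- names(sp)[!keep]
  out
}

#' Stratify cells into high/low expression groups
#'
#' Cells with raw count at or above `high_threshold` form the high
#' group; cells below it (including zeros) the low group.  The default
#' threshold of 10 raw reads reproduces the high/low split used for
#' tumor-cell strata; `tumor_only` restricts the stratification to
#' tumor cells from tumor-tissue samples, as that comparison uses only
#' primary tumor cells.
#'
#' @param cells cell table data.frame.
#' @param feature feature count column.
#' @param high_threshold raw-count threshold for the high group.
#' @param tumor_only restrict to `cell_type == "tumor"` and
#'   `tissue == "tumor"` rows.
#' @return the (possibly restricted) cell table with an
#'   `expression_group` factor column (`"high"`/`"low"`).
#' @export
stratify_cells_by_expression <- function(cells, feature,
                                         high_threshold = 10L,
                                         tumor_only = FALSE) {
  .check_cells(cells, feature)
  if (tumor_only) {
    .check_cells(cells, feature, c("cell_type", "tissue"))
    cells <- cells[cells$cell_type == "tumor" &
                   cells$tissue == "tumor", , drop = FALSE]
  }
  cells$expression_group <- factor(
    ifelse(cells[[feature]] >= high_threshold, "high", "low"),
    levels = c("high", "low"))
  cells
}

#' Per-patient percentage of cells in an expressing type set
#'
#' For each patient, the percentage of that patient's cells whose cell
#' type belongs to `type_set` (the cell types found to express the
#' feature of interest, e.g. tumor, AT2 and fibroblast), followed by a
#' Student t test of the per-patient percentages between tumor and
#' normal tissue.
#'
#' @param cells cell table with `patient_id`, `tissue` and the type
#'   column.
#' @param type_set character vector of cell types; unknown types
#'   trigger a warning and contribute nothing.
#' @param type_col cell-type column.
#' @return list with `per_patient` (data.frame `patient_id`, `tissue`,
#'   `n_cells`, `percentage`) and `comparison` (a
#'   [group_compare()] result, or `NULL` if either tissue group has
#'   fewer than 2 patients).
#' @export
patient_expressing_type_percentage <- function(cells, type_set,
                                               type_col = "cell_type") {
  .check_cells(cells, character(), c(type_col, "patient_id", "tissue"))
  unknown <- setdiff(type_set, unique(cells[[type_col]]))
  if (length(unknown))
    warning("type(s) not present in the cell table: ",
            paste(unknown, collapse = ", "))
  sp <- split(cells, cells$patient_id)
  per <- do.call(rbind, lapply(sp, function(d) data.frame(
    patient_id = d$patient_id[1L],
    tissue = d$tissue[1L],
    n_cells = nrow(d),
    percentage = 100 * sum(d[[type_col]] %in% type_set) / nrow(d),
    stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  cmp <- NULL
  if (length(unique(per$tissue)) == 2L &&
      all(table(per$tissue) >= 2L))
    cmp <- group_compare(per$percentage, groups = per$tissue,
                         test = "student_t")
  list(per_patient = per, comparison = cmp)
}

#' Read a cell table from MTX + metadata, or a single TSV
#'
#' @param path a cells x metadata+counts TSV (header required), or an
#'   MTX file when `cells` and `features` are given.
#' @param cells for MTX input: TSV of per-cell metadata, one row per
#'   matrix column, with at least `cell_id`.
#' @param features for MTX input: TSV with a `feature_id` column, one
#'   row per matrix row.
#' @return cell table data.frame.
#' @export
read_cell_table <- function(path, cells = NULL, features = NULL) {
  if (!file.exists(path)) stop("cell input not found: ", path)
  if (is.null(cells))
    return(read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE))
  m <- as.matrix(Matrix::readMM(path))
  cmeta <- read.table(cells, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  fmeta <- read.table(features, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  stopifnot(nrow(fmeta) == nrow(m), nrow(cmeta) == ncol(m))
  counts <- as.data.frame(t(m))
  names(counts) <- fmeta$feature_id
  cbind(cmeta, counts)
}
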