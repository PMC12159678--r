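# Expressing-cell composition, per-type fractions, stratification.

mini_cells <- function(types, counts, patient = "P1", tissue = "tumor") {
  data.frame(cell_id = sprintf("c%03d", seq_along(types)),
             patient_id = patient, tissue = tissue, cell_type = types,
             feat = counts, stringsAsFactors = FALSE)
}

test_that("composition of expressing cells sums to 100 and follows the counts", {
  cells <- mini_cells(c(rep("tumor", 6), rep("fibroblast", 3),
                        "epithelial", rep("immune", 5)),
                      c(rep(1L, 10), rep(0L, 5)))
  comp <- composition_of_expressing_cells(cells, "feat")
  expect_equal(sum(comp$percentage), 100, tolerance = 1e-9)
  expect_equal(comp$percentage[match(c("tumor", "fibroblast",
                                       "epithelial"), comp$cell_type)],
               c(60, 30, 10))
  single <- composition_of_expressing_cells(
    mini_cells("tumor", 5L), "feat")
  expect_equal(single$percentage, 100)
  # permutation invariance
  perm <- cells[sample(nrow(cells)), ]
  comp2 <- composition_of_expressing_cells(perm, "feat")
  expect_equal(comp2[order(comp2$cell_type), ],
               comp[order(comp$cell_type), ], ignore_attr = TRUE)
  expect_error(composition_of_expressing_cells(
    mini_cells("tumor", 0L), "feat"), "no cell expresses")
})

test_that("the per-type cell-count filter is strictly exclusive at 600", {
  cells <- rbind(mini_cells(rep("small", 599), rep(1L, 599)),
                 mini_cells(rep("edge", 600), rep(1L, 600)),
                 mini_cells(rep("big", 601), rep(c(1L, 0L),
                                                 c(300, 301))))
  fr <- fraction_expressing_by_celltype(cells, "feat")
  expect_equal(fr$cell_type, "big")
  expect_setequal(attr(fr, "omitted"), c("small", "edge"))
  expect_equal(fr$fraction, 300 / 601)
  all_on <- fraction_expressing_by_celltype(
    mini_cells(rep("t", 700), rep(2L, 700)), "feat")
  expect_equal(all_on$fraction, 1)
})

test_that("adding non-expressing cells only dilutes, and omitted types never matter", {
  cells <- mini_cells(rep("big", 700), rep(c(1L, 0L), c(350, 350)))
  f0 <- fraction_expressing_by_celltype(cells, "feat")$fraction
  more <- rbind(cells, mini_cells(rep("big", 100), rep(0L, 100)))
  f1 <- fraction_expressing_by_celltype(more, "feat")$fraction
  expect_lt(f1, f0)
  with_small <- rbind(cells, mini_cells(rep("tiny", 50), rep(1L, 50)))
  expect_equal(fraction_expressing_by_celltype(with_small, "feat")[
    , c("cell_type", "fraction")],
    fraction_expressing_by_celltype(cells, "feat")[
      , c("cell_type", "fraction")])
})

test_that("high/low stratification splits at 10 raw reads and partitions all cells", {
  cells <- mini_cells(rep("tumor", 4), c(10L, 9L, 0L, 25L))
  st <- stratify_cells_by_expression(cells, "feat")
  expect_equal(as.character(st$expression_group),
               c("high", "low", "low", "high"))
  allz <- stratify_cells_by_expression(
    mini_cells(rep("tumor", 5), rep(0L, 5)), "feat")
  expect_true(all(allz$expression_group == "low"))
  expect_equal(sum(table(st$expression_group)), nrow(cells))
  # tumor_only keeps primary tumor cells only
  mixed <- rbind(mini_cells("tumor", 20L, tissue = "tumor"),
                 mini_cells("tumor", 20L, tissue = "normal"),
                 mini_cells("immune", 20L, tissue = "tumor"))
  st2 <- stratify_cells_by_expression(mixed, "feat", tumor_only = TRUE)
  expect_equal(nrow(st2), 1L)
})

test_that("per-patient expressing-type percentages and the tissue contrast work", {
  cells <- rbind(
    mini_cells(c(rep("tumor", 4), rep("immune", 6)),
               rep(0L, 10), patient = "P1"),
    mini_cells(rep("immune", 10), rep(0L, 10), patient = "P2"))
  pp <- patient_expressing_type_percentage(cells, "tumor")
  expect_equal(pp$per_patient$percentage[
    pp$per_patient$patient_id == "P1"], 40)
  all_types <- patient_expressing_type_percentage(
    cells, c("tumor", "immune"))
  expect_true(all(all_types$per_patient$percentage == 100))
  expect_warning(patient_expressing_type_percentage(cells, "melanocyte"),
                 "not present")
})

test_that("the MTX + metadata reader reassembles the cell table", {
  m <- Matrix::Matrix(matrix(c(0, 2, 5, 0, 1, 0), nrow = 2,
                             dimnames = NULL), sparse = TRUE)
  d <- tempfile(); dir.create(d)
  Matrix::writeMM(m, file.path(d, "counts.mtx"))
  write.table(data.frame(cell_id = c("c1", "c2", "c3"),
                         cell_type = c("tumor", "immune", "tumor")),
              file.path(d, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(feature_id = c("long", "short")),
              file.path(d, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ct <- read_cell_table(file.path(d, "counts.mtx"),
                        cells = file.path(d, "cells.tsv"),
                        features = file.path(d, "features.tsv"))
  expect_equal(ct$long, c(0, 5, 1))
  expect_equal(ct$short, c(2, 0, 0))
  expect_equal(ct$cell_type, c("tumor", "immune", "tumor"))
})
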