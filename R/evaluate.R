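#' Ground-truth recovery statistics for a corrected simulated sample
#'
#' Given a simulated sample and the correction run on its cell libraries,
#' decomposes what the correction removed for a set of genes into
#' ambient-derived and native counts, using the simulator's exact per-count
#' truth. In cell types that do not express the genes, every removed count
#' is ambient-derived; in the expressing type, removal beyond a cell's
#' ambient content eats into native expression. Attribution within a cell
#' is ambient-first: of `r` removed counts, `min(r, ambient)` are counted
#' as ambient and the remainder as native.
#'
#' @param sim a `fastcar_sim`.
#' @param result the `fastcar_result` from running the correction on
#'   `cell_libraries(sim)`.
#' @param genes gene IDs to account for (e.g. [marker_genes()] of one type).
#' @param expressing_type cell-type label that natively expresses `genes`;
#'   all other cell types are treated as non-expressing.
#' @return A one-row tibble: `sample`, `ambient_total_nonexpr`,
#'   `ambient_removed_nonexpr`, `native_total_expr`, `native_removed_expr`.
#' @export
recovery_stats <- function(sim, result, genes,
                           expressing_type = "type1") {
  stopifnot(inherits(sim, "fastcar_sim"), inherits(result, "fastcar_result"))
  cells <- sim$libraries$barcode[sim$libraries$is_cell]
  before <- sim$matrix$counts[, cells, drop = FALSE]
  after <- result$matrix$counts
  if (!identical(colnames(after), cells)) {
    stop_data("result does not cover the simulated cell libraries in order")
  }
  removed <- before - after

  is_expr <- sim$libraries$cell_type[sim$libraries$is_cell] == expressing_type
  nonexpr <- cells[!is_expr]
  expr <- cells[is_expr]

  amb_ne <- sim$ambient[genes, nonexpr, drop = FALSE]
  rem_ne <- removed[genes, nonexpr, drop = FALSE]
  # ambient-first attribution; in non-expressing cells native == 0 anyway
  amb_removed <- sum(pmin(as.matrix(rem_ne), as.matrix(amb_ne)))

  amb_e <- as.matrix(sim$ambient[genes, expr, drop = FALSE])
  rem_e <- as.matrix(removed[genes, expr, drop = FALSE])
  native_removed <- sum(pmax(0, rem_e - amb_e))

  tibble(
    sample = sim$sample,
    ambient_total_nonexpr = sum(amb_ne),
    ambient_removed_nonexpr = amb_removed,
    native_total_expr = sum(sim$native[genes, expr]),
    native_removed_expr = native_removed
  )
}

#' Between-group pseudo-bulk log-fold-change in non-expressing cell types
#'
#' The false-positive signature of sample-specific ambient RNA: a
#' between-group fold change of a gene measured in cell types that do not
#' express it. Cells of the excluded (expressing) type are dropped; the
#' remaining cells of each sample are pooled into one pseudo-bulk library,
#' normalised to counts per million, averaged within group, and compared as
#' `log2((A + 0.5) / (B + 0.5))` per gene.
#'
#' @param matrices named list of per-sample cell [count_matrix()] objects
#'   (uncorrected or corrected).
#' @param study the `simulate_two_group_study()` output the matrices belong
#'   to (provides cell-type labels and group assignments).
#' @param genes gene IDs to measure.
#' @param exclude_type expressing cell type excluded from the pseudo-bulk.
#' @return A tibble with one row per gene: `gene_id`, `mean_cpm_a`,
#'   `mean_cpm_b`, `lfc`.
#' @export
nonexpressing_group_lfc <- function(matrices, study, genes,
                                    exclude_type = "type1") {
  stopifnot(length(matrices) == length(study))
  cpm <- vapply(names(study), function(s) {
    sim <- study[[s]]
    keep <- sim$libraries$is_cell & sim$libraries$cell_type != exclude_type
    bcs <- intersect(sim$libraries$barcode[keep], matrices[[s]]$barcodes)
    m <- matrices[[s]]$counts[, bcs, drop = FALSE]
    total <- sum(m)
    if (total == 0) return(rep(0, length(genes)))
    as.numeric(Matrix::rowSums(m[genes, , drop = FALSE])) / total * 1e6
  }, numeric(length(genes)))
  cpm <- matrix(cpm, nrow = length(genes))
  groups <- vapply(study, `[[`, character(1), "group")
  mean_a <- rowMeans(cpm[, groups == "A", drop = FALSE])
  mean_b <- rowMeans(cpm[, groups == "B", drop = FALSE])
  tibble(
    gene_id = genes,
    mean_cpm_a = mean_a,
    mean_cpm_b = mean_b,
    lfc = log2((mean_a + 0.5) / (mean_b + 0.5))
  )
}
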