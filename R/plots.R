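#' Heatmap of would-be removal across the threshold grid
#'
#' Tiles genes against candidate empty-library thresholds, filled by the
#' `g_max` that would be subtracted; the visual half of threshold
#' selection. Genes with nothing to remove anywhere on the grid are
#' dropped; at most `max_genes` genes (largest final `g_max`) are shown.
#'
#' @param object a [profile_removal_grid()] result.
#' @param max_genes maximum number of genes to display.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot removal_profile
#' @export
autoplot.removal_profile <- function(object, max_genes = 40, ...) {
  top <- dplyr::slice_max(
    dplyr::filter(
      dplyr::summarise(dplyr::group_by(object, .data$gene_id),
                       peak = max(.data$g_max), .groups = "drop"),
      .data$peak > 0),
    order_by = .data$peak, n = max_genes, with_ties = FALSE)
  dat <- dplyr::filter(object, .data$gene_id %in% top$gene_id)
  dat$gene_id <- factor(dat$gene_id, levels = rev(top$gene_id))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$empty_threshold), y = .data$gene_id,
    fill = log10(.data$g_max + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(gMax + 1)") +
    ggplot2::labs(x = "empty-library UMI threshold (thE)", y = NULL,
                  title = "Ambient counts removed per gene across thresholds") +
    ggplot2::theme_minimal()
}

#' Violin diagnostic for one gene's would-be removal
#'
#' Shows the per-cell counts of one gene by cell type, before and after
#' subtracting the `g_max` implied by a threshold: adequate removal mostly
#' flattens the gene in non-expressing cell types while leaving the
#' expressing type's distribution high.
#'
#' @param cell_matrix the cell [count_matrix()].
#' @param labels label tibble (`barcode`, `cell_type`).
#' @param gene gene ID to plot.
#' @param g_max counts to subtract (e.g. from an ambient profile at the
#'   candidate threshold).
#' @return A ggplot.
#' @export
plot_gene_removal <- function(cell_matrix, labels, gene, g_max) {
  stopifnot(inherits(cell_matrix, "count_matrix"))
  gi <- which(cell_matrix$genes$gene_id == gene)
  if (length(gi) != 1) {
    stop_data(sprintf("gene '%s' not found on the gene axis", gene))
  }
  labs <- labels[labels$barcode %in% cell_matrix$barcodes, , drop = FALSE]
  v <- as.numeric(cell_matrix$counts[gi, labs$barcode])
  dat <- dplyr::bind_rows(
    tibble(cell_type = labs$cell_type, count = v, phase = "before"),
    tibble(cell_type = labs$cell_type, count = pmax(0, v - g_max),
           phase = "after"))
  dat$phase <- factor(dat$phase, levels = c("before", "after"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cell_type,
                                    y = log10(.data$count + 1),
                                    fill = .data$phase)) +
    ggplot2::geom_violin(scale = "width", position = "dodge") +
    ggplot2::labs(x = NULL, y = "log10(UMI + 1)",
                  title = sprintf("%s before/after removing gMax = %d", gene,
                                  as.integer(g_max))) +
    ggplot2::theme_minimal()
}

#' Pseudo-bulk heatmap of selected genes with the ambient pool appended
#'
#' Scaled log10 pseudo-bulk expression per (sample, cell type) group, with
#' an extra column per sample for the summed ambient counts -- makes the
#' sample-specificity of the ambient pool visible next to the cell types it
#' contaminates.
#'
#' @param pseudobulk long tibble from [pseudobulk_aggregate()].
#' @param ambient optional tibble mapping `sample` to an ambient profile
#'   (columns `sample`, `gene_id`, `ambient_total`), shown as cell type
#'   `"ambient"`.
#' @param genes gene IDs to display (default: 25 genes with the largest
#'   total pseudo-bulk count).
#' @return A ggplot.
#' @export
plot_pseudobulk_heatmap <- function(pseudobulk, ambient = NULL, genes = NULL) {
  dat <- dplyr::select(pseudobulk, "gene_id", "sample", "cell_type", "count")
  if (!is.null(ambient)) {
    dat <- dplyr::bind_rows(dat, tibble(
      gene_id = ambient$gene_id, sample = ambient$sample,
      cell_type = "ambient", count = as.numeric(ambient$ambient_total)))
  }
  if (is.null(genes)) {
    top <- dplyr::slice_max(
      dplyr::summarise(dplyr::group_by(dat, .data$gene_id),
                       total = sum(.data$count), .groups = "drop"),
      order_by = .data$total, n = 25, with_ties = FALSE)
    genes <- top$gene_id
  }
  dat <- dplyr::filter(dat, .data$gene_id %in% genes)
  dat <- dplyr::mutate(dplyr::group_by(dat, .data$gene_id, .data$cell_type),
                       scaled = as.numeric(scale(log10(.data$count + 1))))
  dat$scaled[is.nan(dat$scaled)] <- 0
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                    fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(. ~ .data$cell_type) +
    ggplot2::scale_fill_gradient2(name = "scaled\nlog10 count") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pseudo-bulk expression by sample and cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
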