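#' Removal profile across a grid of empty-library thresholds
#'
#' The threshold-selection workflow: before committing to an
#' `empty_threshold`, profile what would be removed at each candidate value.
#' The higher the threshold, the more libraries count as ambient and the
#' more counts are removed of each gene; this function records, for every
#' gene and every grid point, the `g_max` that would be subtracted, the
#' occurrence fraction `fr_c`, and whether the gene would be corrected at a
#' given `contamination_chance`.
#'
#' @param full_matrix the full/raw droplet [count_matrix()].
#' @param thresholds strictly increasing integer vector of candidate
#'   empty-library thresholds; default `seq(0, 500, by = 25)` (500 is the
#'   ceiling above which live lowly-expressing cells risk entering the
#'   ambient set).
#' @param contamination_chance frAA used for the `would_correct` flag.
#' @return A `removal_profile`: long tibble with columns `gene_id`,
#'   `gene_name`, `empty_threshold`, `g_max`, `fr_c`, `would_correct`,
#'   `n_ambient`; attribute `contamination_chance`.
#' @examples
#' sim <- simulate_sample(simulation_config(
#'   n_genes = 60, n_cell_types = 3, n_cells_per_type = 20,
#'   n_empty_droplets = 200, n_housekeeping = 10, seed = 1))
#' rp <- profile_removal_grid(sim$matrix, thresholds = c(50, 100, 150))
#' dplyr::filter(rp, g_max > 0)
#' @export
profile_removal_grid <- function(full_matrix, thresholds = seq(0, 500, by = 25),
                                 contamination_chance = 0.005) {
  stopifnot(inherits(full_matrix, "count_matrix"))
  if (length(thresholds) == 0) {
    stop_usage("thresholds grid must not be empty")
  }
  if (any(thresholds < 0) || any(diff(thresholds) <= 0)) {
    stop_usage("thresholds must be strictly increasing and non-negative")
  }
  totals <- library_sizes(full_matrix)
  ord <- order(totals)
  sorted_totals <- totals[ord]
  m_sorted <- full_matrix$counts[, ord, drop = FALSE]
  ng <- nrow(m_sorted)

  pieces <- vector("list", length(thresholds))
  for (g in seq_along(thresholds)) {
    th <- thresholds[g]
    n_amb <- findInterval(th, sorted_totals)
    if (n_amb > 0) {
      amb <- m_sorted[, seq_len(n_amb), drop = FALSE]
      g_max <- sparse_row_max(amb)
      fr_c <- unname(Matrix::rowSums(amb > 0)) / n_amb
    } else {
      g_max <- numeric(ng)
      fr_c <- numeric(ng)
    }
    pieces[[g]] <- tibble(
      gene_id = full_matrix$genes$gene_id,
      gene_name = full_matrix$genes$gene_name,
      empty_threshold = th,
      g_max = as.integer(g_max),
      fr_c = fr_c,
      would_correct = fr_c > contamination_chance & g_max > 0,
      n_ambient = as.integer(n_amb)
    )
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "contamination_chance") <- contamination_chance
  class(out) <- c("removal_profile", class(out))
  out
}

#' Per-cell-type removal summary for one gene
#'
#' The numeric substrate of the violin diagnostic: whether the removal at a
#' threshold is adequate is gauged by comparing what would be removed to the
#' gene's level in cells expected to express it, and to its level in
#' non-expressing cells. For each cell type this summarises the gene's
#' per-cell counts before and after subtracting the `g_max` implied by
#' `empty_threshold` (clamped at zero).
#'
#' @param full_matrix the full/raw droplet [count_matrix()] used for ambient
#'   profiling.
#' @param cell_matrix the cell-library [count_matrix()]; same gene axis.
#' @param labels tibble with columns `barcode` and `cell_type` covering the
#'   cell libraries; unlabeled barcodes are excluded with a warning.
#' @param gene gene ID (or unique gene name) to summarise.
#' @param empty_threshold thE at which the would-be removal is evaluated.
#' @return A `gene_removal_summary` tibble: one row per cell type and phase
#'   (`before` / `after`) with `n`, `frac_positive`, `min`, `q1`, `median`,
#'   `q3`, `max`, `mean`; attributes `gene_id`, `g_max`, `empty_threshold`.
#'   Cell types present in `labels` but without cells yield all-zero rows
#'   with `n = 0`.
#' @export
gene_removal_summary <- function(full_matrix, cell_matrix, labels, gene,
                                 empty_threshold = 100) {
  stopifnot(inherits(full_matrix, "count_matrix"),
            inherits(cell_matrix, "count_matrix"))
  ids <- cell_matrix$genes$gene_id
  gi <- which(ids == gene)
  if (length(gi) == 0) {
    gi <- which(cell_matrix$genes$gene_name == gene)
  }
  if (length(gi) != 1) {
    stop_data(sprintf("gene '%s' not found (or not unique) on the gene axis", gene))
  }

  profile <- compute_ambient_profile(full_matrix, empty_threshold)
  g_max <- profile$g_max[match(ids[gi], profile$gene_id)]

  labs <- labels[labels$barcode %in% cell_matrix$barcodes, , drop = FALSE]
  unlabeled <- setdiff(cell_matrix$barcodes, labs$barcode)
  if (length(unlabeled) > 0) {
    warn(sprintf("%d cell barcodes lack labels and are excluded from the summary",
                 length(unlabeled)))
  }
  counts <- as.numeric(cell_matrix$counts[gi, labs$barcode])
  groups <- unique(labels$cell_type)

  summarise_counts <- function(v) {
    if (length(v) == 0) {
      tibble(n = 0L, frac_positive = 0, min = 0, q1 = 0, median = 0,
             q3 = 0, max = 0, mean = 0)
    } else {
      q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      tibble(n = length(v), frac_positive = mean(v > 0),
             min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
             mean = mean(v))
    }
  }

  pieces <- lapply(groups, function(gr) {
    v <- counts[labs$cell_type == gr]
    dplyr::bind_rows(
      dplyr::mutate(summarise_counts(v), cell_type = gr, phase = "before"),
      dplyr::mutate(summarise_counts(pmax(0, v - g_max)), cell_type = gr,
                    phase = "after")
    )
  })
  out <- dplyr::relocate(dplyr::bind_rows(pieces), "cell_type", "phase")
  attr(out, "gene_id") <- ids[gi]
  attr(out, "g_max") <- g_max
  attr(out, "empty_threshold") <- empty_threshold
  class(out) <- c("gene_removal_summary", class(out))
  out
}

#' Pseudo-bulk aggregation by sample and cell type
#'
#' Sums UMI counts over the cells of each (sample, cell type) group -- the
#' unit on which between-group differential expression is run and on which
#' sample-specific ambient contamination shows up as a false group effect.
#'
#' @param cell_matrix a [count_matrix()] of cell libraries.
#' @param labels tibble with columns `barcode`, `cell_type`, `sample`
#'   covering the cells; unlabeled barcodes are excluded with a warning.
#' @return A long tibble: `gene_id`, `gene_name`, `sample`, `cell_type`,
#'   `count`, with one row per gene and group (groups with zero counts for
#'   a gene included). Every labeled cell contributes to exactly one group,
#'   so group totals conserve the labeled submatrix total.
#' @export
pseudobulk_aggregate <- function(cell_matrix, labels) {
  stopifnot(inherits(cell_matrix, "count_matrix"))
  if (!all(c("barcode", "cell_type", "sample") %in% names(labels))) {
    stop_format("labels must have columns barcode, cell_type, sample")
  }
  labs <- labels[labels$barcode %in% cell_matrix$barcodes, , drop = FALSE]
  unlabeled <- setdiff(cell_matrix$barcodes, labs$barcode)
  if (length(unlabeled) > 0) {
    warn(sprintf("%d cell barcodes lack labels and are excluded from pseudo-bulk",
                 length(unlabeled)))
  }
  m <- cell_matrix$counts[, labs$barcode, drop = FALSE]
  grp <- interaction(labs$sample, labs$cell_type, sep = "\r", drop = TRUE)
  ind <- Matrix::fac2sparse(grp)
  agg <- m %*% Matrix::t(ind)  # genes x groups
  keys <- do.call(rbind, strsplit(colnames(agg), "\r", fixed = TRUE))

  wide <- as.matrix(agg)
  tibble(
    gene_id = rep(cell_matrix$genes$gene_id, times = ncol(wide)),
    gene_name = rep(cell_matrix$genes$gene_name, times = ncol(wide)),
    sample = rep(keys[, 1], each = nrow(wide)),
    cell_type = rep(keys[, 2], each = nrow(wide)),
    count = as.numeric(wide)
  )
}

#' Report the ambient RNA profile without correcting
#'
#' The report-only mode: profile the ambient pool of a sample (per-gene
#' `g_max`, `fr_c`, summed ambient counts, and rank by the latter) to
#' interpret downstream differential expression results, without touching
#' the count matrix.
#'
#' @inheritParams compute_ambient_profile
#' @return A tibble: `gene_id`, `gene_name`, `g_max`, `fr_c`,
#'   `ambient_total`, `rank` (1 = largest `ambient_total`), sorted by rank;
#'   attributes as in [compute_ambient_profile()].
#' @export
ambient_report <- function(x, empty_threshold = 100) {
  profile <- compute_ambient_profile(x, empty_threshold)
  out <- dplyr::mutate(as_tibble(profile),
                       rank = dplyr::min_rank(dplyr::desc(.data$ambient_total)))
  out <- dplyr::arrange(out, .data$rank, .data$gene_id)
  attr(out, "empty_threshold") <- attr(profile, "empty_threshold")
  attr(out, "n_ambient_libraries") <- attr(profile, "n_ambient_libraries")
  out
}

#' Heuristic threshold suggestion from a removal grid
#'
#' The recommended threshold is a visual judgement: remove most of the
#' transcripts likely to affect differential expression while removing as
#' little else as possible. As a clearly-labeled heuristic shortcut, this
#' returns the smallest grid threshold at which a named gene's `g_max`
#' reaches the upper-quartile count of that gene in named non-expressing
#' cell types, or `NA` if no grid point qualifies.
#'
#' @param removal_profile a [profile_removal_grid()] result.
#' @param cell_matrix the cell [count_matrix()].
#' @param labels label tibble (`barcode`, `cell_type`).
#' @param gene gene ID to target.
#' @param nonexpressing_types cell types expected not to express `gene`.
#' @return A one-row tibble: `gene_id`, `suggested_threshold`, `g_max_at`,
#'   `nonexpressing_q3`; `suggested_threshold` is `NA` when the criterion is
#'   never met on the grid.
#' @export
suggest_threshold <- function(removal_profile, cell_matrix, labels, gene,
                              nonexpressing_types) {
  stopifnot(inherits(removal_profile, "removal_profile"),
            inherits(cell_matrix, "count_matrix"))
  gi <- which(cell_matrix$genes$gene_id == gene)
  if (length(gi) != 1) {
    stop_data(sprintf("gene '%s' not found on the gene axis", gene))
  }
  labs <- labels[labels$barcode %in% cell_matrix$barcodes &
                   labels$cell_type %in% nonexpressing_types, , drop = FALSE]
  if (nrow(labs) == 0) {
    stop_data("no labeled cells in the given non-expressing cell types")
  }
  v <- as.numeric(cell_matrix$counts[gi, labs$barcode])
  q3 <- quantile(v, 0.75, names = FALSE)
  rows <- removal_profile[removal_profile$gene_id == gene, , drop = FALSE]
  hit <- rows[rows$g_max >= q3, , drop = FALSE]
  tibble(
    gene_id = gene,
    suggested_threshold = if (nrow(hit) > 0) min(hit$empty_threshold) else NA_real_,
    g_max_at = if (nrow(hit) > 0) hit$g_max[which.min(hit$empty_threshold)] else NA_integer_,
    nonexpressing_q3 = q3
  )
}
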