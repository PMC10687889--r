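#' Apply clamped ambient subtraction to a cell matrix
#'
#' For every gene selected by [genes_to_correct()], the gene's `g_max` (its
#' maximal count in any single ambient library) is subtracted from the
#' gene's count in every cell library; results that would go negative are
#' clamped to zero. All other genes are untouched, the input is not
#' mutated, and no structural fill-in occurs (a stored zero stays zero
#' under clamped subtraction).
#'
#' @param cell_matrix a [count_matrix()] holding the libraries identified as
#'   live, single cells. Its gene axis (IDs and order) must be identical to
#'   that of the matrix the profile was computed from.
#' @param profile an [compute_ambient_profile()] result.
#' @param contamination_chance frAA gate passed to [genes_to_correct()].
#' @return A list with elements `matrix` (the corrected [count_matrix()])
#'   and `report` (a `correction_report` tibble: per gene `g_max`, `fr_c`,
#'   `ambient_total`, `corrected`, `counts_removed`, `cells_affected`,
#'   `cells_zeroed`; totals and parameters as attributes).
#' @examples
#' sim <- simulate_sample(simulation_config(
#'   n_genes = 60, n_cell_types = 3, n_cells_per_type = 20,
#'   n_empty_droplets = 200, n_housekeeping = 10, seed = 1))
#' prof <- compute_ambient_profile(sim$matrix)
#' res <- correct_matrix(cell_libraries(sim), prof)
#' dplyr::filter(res$report, corrected)
#' @export
correct_matrix <- function(cell_matrix, profile, contamination_chance = 0.005) {
  stopifnot(inherits(cell_matrix, "count_matrix"),
            inherits(profile, "ambient_profile"))
  ids <- cell_matrix$genes$gene_id
  if (length(ids) != nrow(profile) || any(ids != profile$gene_id)) {
    bad <- if (length(ids) != nrow(profile)) {
      sprintf("gene axis length differs (%d vs %d)", length(ids), nrow(profile))
    } else {
      i <- which(ids != profile$gene_id)[1]
      sprintf("first discordant gene at position %d: '%s' vs '%s'",
              i, ids[i], profile$gene_id[i])
    }
    stop_data(paste0("cell matrix and ambient profile gene axes differ: ", bad))
  }

  selected <- genes_to_correct(profile, contamination_chance)
  sel_idx <- match(selected, ids)
  gmax <- numeric(length(ids))
  gmax[sel_idx] <- profile$g_max[sel_idx]

  m <- cell_matrix$counts
  old_x <- m@x
  rows <- m@i + 1L
  new_x <- pmax(0, old_x - gmax[rows])
  removed_entry <- old_x - new_x

  counts_removed <- numeric(length(ids))
  cells_affected <- numeric(length(ids))
  cells_zeroed <- numeric(length(ids))
  touched <- removed_entry > 0
  if (any(touched)) {
    tr <- rows[touched]
    by_gene <- rowsum(removed_entry[touched], tr)
    counts_removed[as.integer(rownames(by_gene))] <- by_gene[, 1]
    cells_affected <- tabulate(tr, nbins = length(ids))
    zeroed <- touched & new_x == 0
    cells_zeroed <- tabulate(rows[zeroed], nbins = length(ids))
  }

  corrected <- m
  corrected@x <- new_x
  corrected <- Matrix::drop0(corrected)
  out_matrix <- count_matrix(corrected,
                             gene_ids = ids,
                             gene_names = cell_matrix$genes$gene_name,
                             barcodes = cell_matrix$barcodes,
                             feature_types = cell_matrix$genes$feature_type)

  report <- tibble(
    gene_id = ids,
    gene_name = cell_matrix$genes$gene_name,
    g_max = profile$g_max,
    fr_c = profile$fr_c,
    ambient_total = profile$ambient_total,
    corrected = ids %in% selected,
    counts_removed = as.integer(counts_removed),
    cells_affected = as.integer(cells_affected),
    cells_zeroed = as.integer(cells_zeroed)
  )
  attr(report, "params") <- list(
    empty_threshold = attr(profile, "empty_threshold"),
    contamination_chance = contamination_chance
  )
  attr(report, "n_ambient_libraries") <- attr(profile, "n_ambient_libraries")
  attr(report, "total_counts_before") <- sum(old_x)
  attr(report, "total_counts_after") <- sum(new_x)
  class(report) <- c("correction_report", class(report))

  list(matrix = out_matrix, report = report)
}

#' Run the full ambient RNA correction for one sample
#'
#' Composes [compute_ambient_profile()] on the full/raw droplet matrix with
#' [correct_matrix()] on the cell matrix. The tool operates on one sample
#' per invocation: ambient pools are sample-specific, so multi-sample
#' studies loop over samples. Passing the same matrix for both roles is
#' permitted (then all libraries are corrected).
#'
#' Thresholds above about 500 UMIs trigger a warning: at such levels,
#' lowly-expressing live cells (e.g. T cells) may enter the "ambient" set,
#' inflate `g_max` for their genes, and over-correct those genes to zero.
#'
#' @param full_matrix the full/raw droplet [count_matrix()] including empty
#'   droplets.
#' @param cell_matrix the [count_matrix()] of cell libraries; same gene axis
#'   as `full_matrix`.
#' @param empty_threshold thE; default 100 UMIs/library.
#' @param contamination_chance frAA; default 0.005.
#' @return A `fastcar_result`: list with `matrix` (corrected cell matrix),
#'   `profile`, `report`, and `params`. Methods: [tidy()], [glance()],
#'   `print()`.
#' @examples
#' sim <- simulate_sample(simulation_config(
#'   n_genes = 60, n_cell_types = 3, n_cells_per_type = 20,
#'   n_empty_droplets = 200, n_housekeeping = 10, seed = 1))
#' res <- run_fastcar(sim$matrix, cell_libraries(sim))
#' glance(res)
#' @export
run_fastcar <- function(full_matrix, cell_matrix,
                        empty_threshold = 100, contamination_chance = 0.005) {
  if (empty_threshold > 500) {
    warn(sprintf(paste0(
      "empty_threshold = %s exceeds about 500 UMIs: lowly expressing live ",
      "cells may be included in the ambient profile, raising g_max and ",
      "over-correcting their genes"), format(empty_threshold)))
  }
  profile <- compute_ambient_profile(full_matrix, empty_threshold)
  res <- correct_matrix(cell_matrix, profile, contamination_chance)
  structure(
    list(
      matrix = res$matrix,
      profile = profile,
      report = res$report,
      params = list(empty_threshold = empty_threshold,
                    contamination_chance = contamination_chance)
    ),
    class = "fastcar_result"
  )
}

#' @export
print.fastcar_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<fastcar_result> thE = %s, frAA = %s\n",
           "  %d ambient libraries; %d genes corrected\n",
           "  counts: %.0f -> %.0f (%.0f removed)\n"),
    format(g$empty_threshold), format(g$contamination_chance),
    g$n_ambient_libraries, g$n_genes_corrected,
    g$total_counts_before, g$total_counts_after, g$total_counts_removed))
  invisible(x)
}

#' Per-gene correction report as a tibble
#'
#' @param x a `fastcar_result`.
#' @param ... unused.
#' @return The per-gene `correction_report` tibble.
#' @method tidy fastcar_result
#' @export
tidy.fastcar_result <- function(x, ...) {
  out <- x$report
  class(out) <- setdiff(class(out), "correction_report")
  out
}

#' One-row summary of a correction run
#'
#' @param x a `fastcar_result`.
#' @param ... unused.
#' @return A one-row tibble with parameters, ambient library count, number
#'   of corrected genes, and count totals before/after correction.
#' @method glance fastcar_result
#' @export
glance.fastcar_result <- function(x, ...) {
  before <- attr(x$report, "total_counts_before")
  after <- attr(x$report, "total_counts_after")
  tibble(
    empty_threshold = x$params$empty_threshold,
    contamination_chance = x$params$contamination_chance,
    n_ambient_libraries = attr(x$report, "n_ambient_libraries"),
    n_genes_corrected = sum(x$report$corrected),
    total_counts_before = before,
    total_counts_after = after,
    total_counts_removed = before - after
  )
}

#' Write a correction report as TSV plus a one-line JSON summary
#'
#' @param result a `fastcar_result`.
#' @param tsv_path output path for the per-gene table.
#' @param json_path optional output path for the one-line JSON run summary
#'   (parameters, totals, ambient library count).
#' @return `tsv_path`, invisibly.
#' @export
write_correction_report <- function(result, tsv_path, json_path = NULL) {
  stopifnot(inherits(result, "fastcar_result"))
  readr::write_tsv(tidy(result), tsv_path, progress = FALSE)
  if (!is.null(json_path)) {
    g <- glance(result)
    jsonlite::write_json(as.list(g), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
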