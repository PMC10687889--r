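#' Select ambient (empty-droplet) libraries
#'
#' Libraries whose total UMI count is at or below the empty-library threshold
#' are taken to contain only ambient RNA. The rule is inclusive: a library
#' with exactly `empty_threshold` UMIs is selected.
#'
#' @param x a [count_matrix()], normally the full/raw droplet matrix.
#' @param empty_threshold integer UMI ceiling (thE) defining an empty
#'   library; default 100.
#' @return Character vector of selected barcodes, in matrix order. May be
#'   empty.
#' @export
select_ambient_libraries <- function(x, empty_threshold = 100) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is.numeric(empty_threshold) || length(empty_threshold) != 1 ||
      is.na(empty_threshold) || empty_threshold < 0) {
    stop_usage("empty_threshold must be a single non-negative number")
  }
  x$barcodes[library_sizes(x) <= empty_threshold]
}

# Row-wise max of a dgCMatrix restricted over its stored entries; absent
# rows get 0. Base of the gMax computation.
sparse_row_max <- function(m) {
  out <- numeric(nrow(m))
  if (length(m@x) > 0) {
    rows <- m@i + 1L
    mx <- vapply(split(m@x, rows), max, numeric(1))
    out[as.integer(names(mx))] <- mx
  }
  out
}

#' Profile the ambient RNA pool from low-UMI libraries
#'
#' For every gene, over the libraries whose total UMI is at or below
#' `empty_threshold`, records:
#' \describe{
#'   \item{g_max}{the highest count of the gene seen in any single ambient
#'     library -- the amount later subtracted from every cell for corrected
#'     genes;}
#'   \item{fr_c}{the fraction of ambient libraries containing at least one
#'     UMI of the gene;}
#'   \item{ambient_total}{the summed counts of the gene across ambient
#'     libraries.}
#' }
#'
#' @param x a [count_matrix()]; must be the full/raw droplet matrix so that
#'   empty droplets are present.
#' @inheritParams select_ambient_libraries
#' @return An `ambient_profile`: a tibble with columns `gene_id`,
#'   `gene_name`, `g_max`, `fr_c`, `ambient_total`, carrying attributes
#'   `empty_threshold` and `n_ambient_libraries`. With zero ambient
#'   libraries a warning is raised and the profile is all zeros (correction
#'   becomes a no-op).
#' @examples
#' sim <- simulate_sample(simulation_config(
#'   n_genes = 60, n_cell_types = 3, n_cells_per_type = 20,
#'   n_empty_droplets = 200, n_housekeeping = 10, seed = 1))
#' prof <- compute_ambient_profile(sim$matrix, empty_threshold = 100)
#' head(dplyr::arrange(prof, dplyr::desc(ambient_total)))
#' @export
compute_ambient_profile <- function(x, empty_threshold = 100) {
  stopifnot(inherits(x, "count_matrix"))
  sel <- library_sizes(x) <= empty_threshold
  n_amb <- sum(sel)
  if (n_amb == 0) {
    warn(sprintf(
      "no library has total UMI <= %s; ambient profile is all zeros and correction will be a no-op",
      format(empty_threshold)))
    g_max <- numeric(nrow(x$counts))
    occ <- numeric(nrow(x$counts))
    tot <- numeric(nrow(x$counts))
    fr_c <- numeric(nrow(x$counts))
  } else {
    amb <- x$counts[, sel, drop = FALSE]
    g_max <- sparse_row_max(amb)
    occ <- Matrix::rowSums(amb > 0)
    tot <- Matrix::rowSums(amb)
    fr_c <- unname(occ) / n_amb
  }
  out <- tibble(
    gene_id = x$genes$gene_id,
    gene_name = x$genes$gene_name,
    g_max = as.integer(g_max),
    fr_c = fr_c,
    ambient_total = as.integer(tot)
  )
  attr(out, "empty_threshold") <- empty_threshold
  attr(out, "n_ambient_libraries") <- as.integer(n_amb)
  class(out) <- c("ambient_profile", class(out))
  out
}

#' Genes selected for correction
#'
#' A gene is corrected when its ambient occurrence fraction `fr_c` strictly
#' exceeds the allowed contamination chance (frAA) and it was seen at all in
#' the ambient libraries (`g_max > 0`). The default 0.005 mirrors the
#' minimum-expressing-fraction cut-offs of sc-DGE methods: genes present in
#' fewer than 5 out of each 1000 ambient libraries are ignored. A gene with
#' `fr_c` exactly equal to the threshold is not corrected.
#'
#' @param profile an [compute_ambient_profile()] result.
#' @param contamination_chance fraction in \[0, 1\] (frAA); default 0.005.
#' @return Character vector of gene IDs to correct.
#' @export
genes_to_correct <- function(profile, contamination_chance = 0.005) {
  stopifnot(inherits(profile, "ambient_profile"))
  if (!is.numeric(contamination_chance) || length(contamination_chance) != 1 ||
      is.na(contamination_chance) ||
      contamination_chance < 0 || contamination_chance > 1) {
    stop_usage("contamination_chance must be a single number in [0, 1]")
  }
  profile$gene_id[profile$fr_c > contamination_chance & profile$g_max > 0]
}
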