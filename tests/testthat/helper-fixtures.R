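# Programmatic fixtures and independent dense oracles.
#
# The oracles deliberately use dense matrices and explicit loops so they
# share no code path with the sparse implementation they check.

rand_count_matrix <- function(n_genes, n_libs, density = 0.1, max_count = 10) {
  nnz <- max(1L, round(n_genes * n_libs * density))
  i <- sample.int(n_genes, nnz, replace = TRUE)
  j <- sample.int(n_libs, nnz, replace = TRUE)
  x <- sample.int(max_count, nnz, replace = TRUE)
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_genes, n_libs))
  count_matrix(m,
               gene_ids = sprintf("G%04d", seq_len(n_genes)),
               gene_names = sprintf("Gene-%04d", seq_len(n_genes)),
               barcodes = sprintf("BC%05d", seq_len(n_libs)))
}

# Dense loop-based ambient profile: per-gene max / occupancy / total over
# libraries with total UMI <= th.
dense_profile_oracle <- function(dense, th) {
  totals <- colSums(dense)
  amb <- dense[, totals <= th, drop = FALSE]
  n_amb <- ncol(amb)
  ng <- nrow(dense)
  g_max <- integer(ng)
  occ <- integer(ng)
  tot <- integer(ng)
  for (g in seq_len(ng)) {
    row <- amb[g, ]
    g_max[g] <- if (n_amb > 0) max(0L, row) else 0L
    occ[g] <- sum(row > 0)
    tot[g] <- sum(row)
  }
  list(g_max = as.integer(g_max),
       fr_c = if (n_amb > 0) occ / n_amb else rep(0, ng),
       ambient_total = as.integer(tot),
       n_ambient = n_amb)
}

# Dense loop-based clamped subtraction for the given per-gene subtraction
# amounts (0 = untouched).
dense_correct_oracle <- function(dense, gmax) {
  out <- dense
  for (g in seq_len(nrow(dense))) {
    if (gmax[g] > 0) {
      out[g, ] <- pmax(0, dense[g, ] - gmax[g])
    }
  }
  out
}

dense_of <- function(x) {
  unname(as.matrix(x$counts))
}

# Small, fast simulator configuration for unit tests.
small_sim_config <- function(...) {
  defaults <- list(
    n_genes = 120, n_cell_types = 4, markers_per_type = 3,
    n_cells_per_type = 50, n_empty_droplets = 1500,
    cell_depth_mean = 400, cell_depth_sdlog = 0.25,
    empty_depth_mean = 25, contamination_fraction = 0.1,
    n_housekeeping = 20, seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

cell_labels_of <- function(sim) {
  dplyr::filter(sim$libraries, is_cell)
}
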