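#' Configure the droplet-data simulator
#'
#' The simulator emulates the structure a per-sample ambient correction
#' assumes: K cell types with type-specific marker genes and a shared
#' housekeeping block; a sample-specific ambient pool mixed from the type
#' profiles (mRNA released by lysed cells); empty droplets drawing counts
#' only from that pool at low depth; and cell libraries whose counts are
#' native expression plus ambient contamination, with exact per-count
#' ground truth.
#'
#' Defaults describe one realistic sample: 600 genes, 8 cell types with 5
#' markers each, 250 cells per type (2,000 cells), 20,000 empty droplets,
#' lognormal cell depth around 1,000 UMIs, and a 10% ambient share of each
#' cell's counts. The empty-droplet depth defaults to
#' `contamination_fraction * cell_depth_mean` (100 UMIs): every droplet
#' captures the same ambient soup whether or not it holds a cell, so an
#' empty droplet's total is the same soup load that contaminates a cell.
#' That physical consistency is what makes the empties' per-gene maximum a
#' sound envelope for the ambient content of cells.
#'
#' @param n_genes total number of genes.
#' @param n_cell_types number of cell types (K).
#' @param markers_per_type marker genes exclusive to each type.
#' @param n_cells_per_type cells simulated per type.
#' @param n_empty_droplets empty droplets per sample.
#' @param cell_depth_mean expected UMIs per cell (lognormal location, on the
#'   natural scale).
#' @param cell_depth_sdlog lognormal sdlog of cell depth.
#' @param empty_depth_mean expected UMIs per empty droplet (Poisson mean);
#'   must be well below `cell_depth_mean`. Default
#'   `contamination_fraction * cell_depth_mean`, the per-droplet soup
#'   capture implied by the contamination model.
#' @param ambient_mixture per-type lysis weights defining the ambient pool
#'   composition; non-negative, normalised to sum to 1. Default: equal.
#' @param contamination_fraction expected share of a cell's counts drawn
#'   from the ambient pool, in \[0, 1).
#' @param n_housekeeping size of the shared housekeeping block expressed in
#'   all types (lets over-correction of ubiquitous genes be exercised).
#' @param marker_fraction share of a type's expression profile carried by
#'   its own markers.
#' @param housekeeping_fraction share carried by the housekeeping block;
#'   the remainder is spread thinly over all remaining genes.
#' @param seed integer RNG seed recorded in the config; all simulation
#'   draws are deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 600,
                              n_cell_types = 8,
                              markers_per_type = 5,
                              n_cells_per_type = 250,
                              n_empty_droplets = 20000,
                              cell_depth_mean = 1000,
                              cell_depth_sdlog = 0.2,
                              empty_depth_mean = NULL,
                              ambient_mixture = NULL,
                              contamination_fraction = 0.1,
                              n_housekeeping = 60,
                              marker_fraction = 0.5,
                              housekeeping_fraction = 0.35,
                              seed = 1L) {
  if (markers_per_type * n_cell_types + n_housekeeping > n_genes) {
    stop_usage(sprintf(
      "infeasible config: %d marker + %d housekeeping genes exceed n_genes = %d",
      markers_per_type * n_cell_types, n_housekeeping, n_genes))
  }
  if (contamination_fraction < 0 || contamination_fraction >= 1) {
    stop_usage("contamination_fraction must lie in [0, 1)")
  }
  if (is.null(empty_depth_mean)) {
    empty_depth_mean <- contamination_fraction * cell_depth_mean
  }
  if (empty_depth_mean >= cell_depth_mean) {
    stop_usage("empty_depth_mean must be below cell_depth_mean")
  }
  if (is.null(ambient_mixture)) {
    ambient_mixture <- rep(1 / n_cell_types, n_cell_types)
  }
  if (length(ambient_mixture) != n_cell_types || any(ambient_mixture < 0) ||
      sum(ambient_mixture) <= 0) {
    stop_usage("ambient_mixture must be n_cell_types non-negative weights")
  }
  ambient_mixture <- ambient_mixture / sum(ambient_mixture)
  if (marker_fraction + housekeeping_fraction >= 1 &&
      n_genes > markers_per_type * n_cell_types + n_housekeeping) {
    stop_usage("marker_fraction + housekeeping_fraction must leave mass for background genes")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_cell_types = as.integer(n_cell_types),
      markers_per_type = as.integer(markers_per_type),
      n_cells_per_type = as.integer(n_cells_per_type),
      n_empty_droplets = as.integer(n_empty_droplets),
      cell_depth_mean = cell_depth_mean,
      cell_depth_sdlog = cell_depth_sdlog,
      empty_depth_mean = empty_depth_mean,
      ambient_mixture = ambient_mixture,
      contamination_fraction = contamination_fraction,
      n_housekeeping = as.integer(n_housekeeping),
      marker_fraction = marker_fraction,
      housekeeping_fraction = housekeeping_fraction,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Per-type expression profiles implied by a simulation config
#'
#' Columns are cell types, rows genes; each column sums to 1. Marker genes
#' carry `marker_fraction` of their own type's mass and 0 elsewhere; the
#' housekeeping block carries `housekeeping_fraction` in every type; the
#' remaining genes share the leftover mass thinly and ubiquitously.
#'
#' @param config a [simulation_config()].
#' @return A `n_genes` x `n_cell_types` matrix of probabilities, with
#'   gene IDs as row names and cell-type labels as column names.
#' @export
type_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ng <- config$n_genes
  k <- config$n_cell_types
  mk <- config$markers_per_type
  hk <- config$n_housekeeping
  n_bg <- ng - k * mk - hk

  genes <- sim_gene_ids(config)
  types <- sim_type_labels(config)
  p <- matrix(0, nrow = ng, ncol = k, dimnames = list(genes, types))

  mf <- config$marker_fraction
  hf <- config$housekeeping_fraction
  bf <- 1 - mf - hf
  if (n_bg == 0) {
    # no background genes: fold their mass into the housekeeping block
    hf <- hf + bf
    bf <- 0
  }
  for (t in seq_len(k)) {
    idx <- ((t - 1) * mk + 1):(t * mk)
    p[idx, t] <- mf / mk
    hk_idx <- (k * mk + 1):(k * mk + hk)
    p[hk_idx, t] <- hf / hk
    if (n_bg > 0) {
      bg_idx <- (k * mk + hk + 1):ng
      p[bg_idx, t] <- bf / n_bg
    }
  }
  p
}

sim_gene_ids <- function(config) {
  k <- config$n_cell_types
  mk <- config$markers_per_type
  hk <- config$n_housekeeping
  n_bg <- config$n_genes - k * mk - hk
  c(
    paste0("MARK-T", rep(seq_len(k), each = mk), "-", rep(seq_len(mk), k)),
    sprintf("HK-%03d", seq_len(hk)),
    if (n_bg > 0) sprintf("BG-%04d", seq_len(n_bg))
  )
}

sim_type_labels <- function(config) {
  paste0("type", seq_len(config$n_cell_types))
}

#' Marker genes of one simulated cell type
#'
#' @param config a [simulation_config()].
#' @param type cell-type index in `1:n_cell_types`.
#' @return Character vector of that type's marker gene IDs.
#' @export
marker_genes <- function(config, type) {
  stopifnot(inherits(config, "simulation_config"),
            type >= 1, type <= config$n_cell_types)
  mk <- config$markers_per_type
  sim_gene_ids(config)[((type - 1) * mk + 1):(type * mk)]
}

#' Simulate one droplet scRNA-seq sample with ambient ground truth
#'
#' Generative model: each cell type has a fixed expression profile (see
#' [type_profiles()]); the ambient pool is the `ambient_mixture`-weighted
#' average of those profiles. Each cell draws a lognormal total depth, a
#' binomial ambient share of it (expectation `contamination_fraction`), and
#' then native counts multinomially from its type profile and ambient
#' counts multinomially from the pool. Empty droplets draw a Poisson depth
#' around `empty_depth_mean` and all their counts from the pool; the
#' Poisson-depth-plus-multinomial compound is generated in its equivalent
#' factorized form, independent Poisson counts per gene with mean
#' `empty_depth_mean * pool probability`. Everything is deterministic given
#' `config$seed` (offset by `seed_offset`).
#'
#' @param config a [simulation_config()].
#' @param sample_name label recorded for every library of this sample.
#' @param seed_offset integer added to `config$seed` for this draw (used to
#'   give each sample of a study its own stream).
#' @return A `fastcar_sim` list: `matrix` (observed [count_matrix()], cells
#'   then empties), `native` and `ambient` (sparse matrices decomposing the
#'   observed counts exactly), `libraries` (tibble: `barcode`, `is_cell`,
#'   `cell_type`, `sample`), `config`, `sample`.
#' @export
simulate_sample <- function(config, sample_name = "S1", seed_offset = 0L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + as.integer(seed_offset))

  p_types <- type_profiles(config)
  pool <- as.numeric(p_types %*% config$ambient_mixture)
  ng <- config$n_genes
  k <- config$n_cell_types
  n_cells <- k * config$n_cells_per_type
  n_empty <- config$n_empty_droplets
  types <- sim_type_labels(config)

  # cells: explicit integer split of each cell's depth into native + ambient
  depths <- pmax(1L, as.integer(round(rlnorm(
    n_cells, meanlog = log(config$cell_depth_mean), sdlog = config$cell_depth_sdlog))))
  amb_depth <- rbinom(n_cells, depths, config$contamination_fraction)
  nat_depth <- depths - amb_depth
  cell_type_idx <- rep(seq_len(k), each = config$n_cells_per_type)

  native_cells <- matrix(0L, nrow = ng, ncol = n_cells)
  ambient_cells <- matrix(0L, nrow = ng, ncol = n_cells)
  for (j in seq_len(n_cells)) {
    if (nat_depth[j] > 0) {
      native_cells[, j] <- rmultinom(1, nat_depth[j], p_types[, cell_type_idx[j]])
    }
    if (amb_depth[j] > 0) {
      ambient_cells[, j] <- rmultinom(1, amb_depth[j], pool)
    }
  }

  # empty droplets: Poisson factorization of Poisson depth + multinomial
  # split (independent Poisson counts per gene, column-major vector)
  empty_x <- if (n_empty > 0) {
    rpois(ng * n_empty, lambda = pool * config$empty_depth_mean)
  } else {
    integer(0)
  }

  # assemble sparse triplets directly; the Matrix() heuristics are too slow
  # at 20k empty droplets per sample
  n_total <- n_cells + n_empty
  as_sparse <- function(x_vec, n_col, col_offset = 0L) {
    idx <- which(x_vec > 0)
    Matrix::sparseMatrix(
      i = (idx - 1L) %% ng + 1L,
      j = (idx - 1L) %/% ng + 1L + col_offset,
      x = x_vec[idx],
      dims = c(ng, n_total))
  }
  native <- as_sparse(as.vector(native_cells), n_cells)
  ambient <- as_sparse(as.vector(ambient_cells), n_cells) +
    as_sparse(empty_x, n_empty, col_offset = n_cells)
  observed <- native + ambient

  barcodes <- c(
    sprintf("%s-cell-%05d", sample_name, seq_len(n_cells)),
    if (n_empty > 0) sprintf("%s-empty-%05d", sample_name, seq_len(n_empty))
  )
  libraries <- tibble(
    barcode = barcodes,
    is_cell = c(rep(TRUE, n_cells), rep(FALSE, n_empty)),
    cell_type = c(types[cell_type_idx], rep(NA_character_, n_empty)),
    sample = sample_name
  )
  gene_ids <- sim_gene_ids(config)
  colnames(native) <- barcodes
  colnames(ambient) <- barcodes
  rownames(native) <- gene_ids
  rownames(ambient) <- gene_ids

  structure(
    list(
      matrix = count_matrix(observed, gene_ids = gene_ids, barcodes = barcodes),
      native = as(as(native, "generalMatrix"), "CsparseMatrix"),
      ambient = as(as(ambient, "generalMatrix"), "CsparseMatrix"),
      libraries = libraries,
      config = config,
      sample = sample_name
    ),
    class = "fastcar_sim"
  )
}

#' @export
print.fastcar_sim <- function(x, ...) {
  cat(sprintf("<fastcar_sim> sample '%s': %d genes, %d cells + %d empty droplets\n",
              x$sample, nrow(x$matrix$counts), sum(x$libraries$is_cell),
              sum(!x$libraries$is_cell)))
  invisible(x)
}

#' Cell libraries of a simulated sample
#'
#' @param sim a `fastcar_sim`.
#' @return The [count_matrix()] restricted to the simulated cells (ground
#'   truth `is_cell`), in original order.
#' @export
cell_libraries <- function(sim) {
  stopifnot(inherits(sim, "fastcar_sim"))
  subset_barcodes(sim$matrix, sim$libraries$barcode[sim$libraries$is_cell])
}

#' Simulate a two-group study differing only in ambient composition
#'
#' Generates `n_samples_per_group` samples for groups "A" and "B" whose
#' native expression follows the same law; only group A's ambient pool is
#' mixed with different lysis weights. This is the null scenario in which
#' any between-group pseudo-bulk difference in non-expressing cell types is
#' a false positive driven by ambient RNA.
#'
#' @param config base [simulation_config()]; used as-is for group B.
#' @param n_samples_per_group samples per group; default 6.
#' @param group_ambient_shift replacement `ambient_mixture` weights for
#'   group A (length `n_cell_types`, normalised), or `NULL` for no shift
#'   (the two groups are then exchangeable).
#' @return A list of `fastcar_sim` objects with an added `group` element;
#'   sample names are `A1..An, B1..Bn`. Each sample uses its own seed
#'   offset from `config$seed`.
#' @export
simulate_two_group_study <- function(config, n_samples_per_group = 6,
                                     group_ambient_shift = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg_a <- config
  if (!is.null(group_ambient_shift)) {
    if (length(group_ambient_shift) != config$n_cell_types ||
        any(group_ambient_shift < 0) || sum(group_ambient_shift) <= 0) {
      stop_usage("group_ambient_shift must be n_cell_types non-negative weights")
    }
    cfg_a$ambient_mixture <- group_ambient_shift / sum(group_ambient_shift)
  }
  sims <- vector("list", 2 * n_samples_per_group)
  for (i in seq_len(n_samples_per_group)) {
    sims[[i]] <- simulate_sample(cfg_a, sample_name = paste0("A", i),
                                 seed_offset = i)
    sims[[i]]$group <- "A"
    j <- n_samples_per_group + i
    sims[[j]] <- simulate_sample(config, sample_name = paste0("B", i),
                                 seed_offset = j)
    sims[[j]]$group <- "B"
  }
  names(sims) <- vapply(sims, `[[`, character(1), "sample")
  sims
}

#' Write a simulated sample to disk
#'
#' Emits the observed full matrix in 10x triplet layout, the cell-barcode
#' list, a label table (cells only: `barcode`, `cell_type`, `sample`), the
#' per-count ground truth as TSV (`gene_id`, `barcode`, `native`,
#' `ambient`; non-zero entries only), and a JSON echo of the configuration.
#'
#' @param sim a `fastcar_sim`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "fastcar_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_10x_mtx(sim$matrix, file.path(dir, "full_matrix"))
  writeLines(sim$libraries$barcode[sim$libraries$is_cell],
             file.path(dir, "cell_barcodes.tsv"))
  labels <- dplyr::filter(sim$libraries, .data$is_cell)
  readr::write_tsv(labels[, c("barcode", "cell_type", "sample")],
                   file.path(dir, "labels.tsv"), progress = FALSE)

  nat <- Matrix::summary(sim$native)
  amb <- Matrix::summary(sim$ambient)
  truth <- dplyr::full_join(
    tibble(i = nat$i, j = nat$j, native = nat$x),
    tibble(i = amb$i, j = amb$j, ambient = amb$x),
    by = c("i", "j"))
  truth$native[is.na(truth$native)] <- 0
  truth$ambient[is.na(truth$ambient)] <- 0
  truth <- dplyr::arrange(truth, .data$j, .data$i)
  readr::write_tsv(
    tibble(gene_id = rownames(sim$native)[truth$i],
           barcode = colnames(sim$native)[truth$j],
           native = as.integer(truth$native),
           ambient = as.integer(truth$ambient)),
    file.path(dir, "truth.tsv.gz"), progress = FALSE)

  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulator configuration from JSON
#'
#' @param path JSON file with any subset of [simulation_config()]'s
#'   arguments; unspecified fields take the defaults.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: '%s'", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_format(sprintf("malformed JSON config '%s': %s",
                                        path, conditionMessage(e)))
                  })
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_format(sprintf("unknown simulation config field(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  do.call(simulation_config, raw)
}
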