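#' Droplet UMI count matrix
#'
#' A light container for a genes x libraries sparse UMI count matrix, the
#' in-memory form used throughout the package. Counts are stored as a
#' [Matrix::dgCMatrix-class] with gene IDs as row names and library barcodes
#' as column names; gene metadata (ID, symbol, feature type) travels in a
#' tibble.
#'
#' Invariants enforced at construction: all counts are non-negative integers;
#' gene IDs and barcodes are unique and match the matrix extents. Duplicate
#' gene symbols are allowed (IDs are the key); duplicate gene IDs are an
#' error.
#'
#' @param counts a matrix-like object, genes in rows, libraries in columns;
#'   coerced to sparse.
#' @param gene_ids character vector of unique feature identifiers, one per row.
#' @param gene_names character vector of feature symbols, one per row
#'   (defaults to `gene_ids`).
#' @param barcodes character vector of unique library barcodes, one per
#'   column (defaults to `colnames(counts)`).
#' @param feature_types character vector of feature types (defaults to
#'   `"Gene Expression"`).
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (dgCMatrix), `genes` (tibble with columns `gene_id`, `gene_name`,
#'   `feature_type`), and `barcodes` (character).
#' @examples
#' m <- count_matrix(Matrix::Matrix(c(0, 2, 1, 0), 2, 2, sparse = TRUE),
#'                   gene_ids = c("g1", "g2"), barcodes = c("b1", "b2"))
#' dim(m)
#' @export
count_matrix <- function(counts, gene_ids, gene_names = gene_ids,
                         barcodes = colnames(counts),
                         feature_types = "Gene Expression") {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) {
    stop_format("count matrix contains negative values")
  }
  if (any(counts@x != round(counts@x))) {
    stop_format("count matrix contains non-integer values")
  }
  counts <- Matrix::drop0(counts)
  gene_ids <- as.character(gene_ids)
  gene_names <- as.character(gene_names)
  if (is.null(barcodes)) {
    stop_format("barcodes must be provided when counts has no column names")
  }
  barcodes <- as.character(barcodes)
  if (length(gene_ids) != nrow(counts)) {
    stop_format(sprintf(
      "gene identifiers (%d) do not match the gene axis extent (%d)",
      length(gene_ids), nrow(counts)))
  }
  if (length(gene_names) != nrow(counts)) {
    stop_format("gene_names length does not match the gene axis extent")
  }
  if (length(barcodes) != ncol(counts)) {
    stop_format(sprintf(
      "barcodes (%d) do not match the library axis extent (%d)",
      length(barcodes), ncol(counts)))
  }
  dup <- duplicated(gene_ids)
  if (any(dup)) {
    stop_format(sprintf("duplicate gene ID: '%s'", gene_ids[which(dup)[1]]))
  }
  dup <- duplicated(barcodes)
  if (any(dup)) {
    stop_format(sprintf("duplicate barcode: '%s'", barcodes[which(dup)[1]]))
  }
  feature_types <- rep_len(as.character(feature_types), length(gene_ids))
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(
    list(
      counts = counts,
      genes = tibble(gene_id = gene_ids, gene_name = gene_names,
                     feature_type = feature_types),
      barcodes = barcodes
    ),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d libraries, %d non-zero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  cat(sprintf("  total UMI: %.0f\n", sum(x$counts)))
  invisible(x)
}

#' @rdname count_matrix
#' @param x a `count_matrix`.
#' @export
gene_ids <- function(x) x$genes$gene_id

#' Per-library total UMI counts
#'
#' @param x a [count_matrix()].
#' @return Named numeric vector of column (library) sums.
#' @export
library_sizes <- function(x) {
  Matrix::colSums(x$counts)
}

#' Restrict a count matrix to a set of barcodes
#'
#' Typically used to carve the cell libraries out of the full droplet matrix
#' given a list of barcodes called as live, high-quality cells.
#'
#' @param x a [count_matrix()].
#' @param barcodes character vector; must all be present in `x$barcodes`.
#'   The result follows the order of this vector. An empty vector yields a
#'   0-library matrix with the gene axis intact.
#' @return A [count_matrix()] restricted to `barcodes`.
#' @export
subset_barcodes <- function(x, barcodes) {
  stopifnot(inherits(x, "count_matrix"))
  barcodes <- as.character(barcodes)
  missing <- setdiff(barcodes, x$barcodes)
  if (length(missing) > 0) {
    stop_data(sprintf("unknown barcode: '%s' (%d missing in total)",
                      missing[1], length(missing)))
  }
  idx <- match(barcodes, x$barcodes)
  count_matrix(x$counts[, idx, drop = FALSE],
               gene_ids = x$genes$gene_id,
               gene_names = x$genes$gene_name,
               barcodes = barcodes,
               feature_types = x$genes$feature_type)
}

# Resolve a member file within a 10x directory, trying plain and gzipped
# variants of the given stems. Returns NA if none exists.
find_10x_member <- function(dir, stems) {
  for (stem in stems) {
    for (cand in c(file.path(dir, stem), file.path(dir, paste0(stem, ".gz")))) {
      if (file.exists(cand)) return(cand)
    }
  }
  NA_character_
}

read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read a 10x Genomics MatrixMarket count matrix
#'
#' Reads the triplet layout written by Cell Ranger: `matrix.mtx[.gz]` plus
#' `barcodes.tsv[.gz]` and either `features.tsv[.gz]` (v3 dialect, three
#' columns: id, name, type) or `genes.tsv[.gz]` (v2 dialect, two columns).
#' Members may be plain or gzipped.
#'
#' The in-memory contract is always genes x libraries. Cell Ranger writes
#' genes as MatrixMarket rows; if your file is transposed on disk, set
#' `transposed = TRUE`. Files declaring `real` values (e.g. matrices
#' corrected by other tools) are accepted and rounded to the nearest integer
#' (half to even) with a warning.
#'
#' Ambient profiling requires the *full/raw* matrix: the empty droplets that
#' carry the ambient signal are absent from Cell Ranger's filtered output.
#'
#' @param dir path to the directory holding the three members, or a named
#'   list/vector with elements `matrix`, `barcodes`, `features` giving the
#'   file paths explicitly.
#' @param transposed set `TRUE` if the MatrixMarket file stores libraries as
#'   rows (non-standard); the returned object is genes x libraries either
#'   way.
#' @return A [count_matrix()].
#' @export
read_10x_mtx <- function(dir, transposed = FALSE) {
  if (is.list(dir) || (is.character(dir) && !is.null(names(dir)))) {
    paths <- as.list(dir)
    for (member in c("matrix", "barcodes", "features")) {
      if (is.null(paths[[member]]) || !file.exists(paths[[member]])) {
        stop_format(sprintf("file not found for member '%s'", member))
      }
    }
    mtx_path <- paths$matrix
    bc_path <- paths$barcodes
    ft_path <- paths$features
  } else {
    if (!dir.exists(dir)) {
      stop_format(sprintf("file not found: directory '%s' does not exist", dir))
    }
    mtx_path <- find_10x_member(dir, "matrix.mtx")
    bc_path <- find_10x_member(dir, "barcodes.tsv")
    ft_path <- find_10x_member(dir, c("features.tsv", "genes.tsv"))
    if (is.na(mtx_path)) stop_format(
      sprintf("file not found: no matrix.mtx[.gz] in '%s'", dir))
    if (is.na(bc_path)) stop_format(
      sprintf("file not found: no barcodes.tsv[.gz] in '%s'", dir))
    if (is.na(ft_path)) stop_format(
      sprintf("file not found: no features.tsv[.gz] or genes.tsv[.gz] in '%s'", dir))
  }

  header <- {
    con <- if (grepl("\\.gz$", mtx_path)) gzfile(mtx_path, "rt")
           else file(mtx_path, "rt")
    on.exit(close(con), add = TRUE)
    readLines(con, n = 1L)
  }
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate", header)) {
    stop_format(sprintf("'%s' is not a coordinate MatrixMarket file", mtx_path))
  }
  is_real <- grepl("\\breal\\b", header)

  m <- tryCatch(Matrix::readMM(mtx_path), error = function(e) {
    stop_format(sprintf("malformed MatrixMarket file '%s': %s",
                        mtx_path, conditionMessage(e)))
  })
  if (transposed) m <- Matrix::t(m)

  if (length(m@x) && any(m@x < 0)) {
    stop_format(sprintf("negative values in '%s'", mtx_path))
  }
  if (is_real && length(m@x) && any(m@x != round(m@x))) {
    warn("MatrixMarket file holds real values; rounding to nearest integer (half to even)")
    m@x <- round(m@x)
  }

  bc <- read_lines_maybe_gz(bc_path)
  bc <- bc[nzchar(bc)]
  ft_lines <- read_lines_maybe_gz(ft_path)
  ft_lines <- ft_lines[nzchar(ft_lines)]
  ft <- do.call(rbind, strsplit(ft_lines, "\t", fixed = TRUE))
  if (is.null(ft) || ncol(ft) < 1) {
    stop_format(sprintf("empty or malformed feature file '%s'", ft_path))
  }
  ids <- ft[, 1]
  nms <- if (ncol(ft) >= 2) ft[, 2] else ids
  types <- if (ncol(ft) >= 3) ft[, 3] else "Gene Expression"

  if (nrow(m) != length(ids)) {
    stop_format(sprintf(
      "dimension mismatch: matrix has %d gene rows but '%s' lists %d features",
      nrow(m), ft_path, length(ids)))
  }
  if (ncol(m) != length(bc)) {
    stop_format(sprintf(
      "dimension mismatch: matrix has %d library columns but '%s' lists %d barcodes",
      ncol(m), bc_path, length(bc)))
  }
  count_matrix(m, gene_ids = ids, gene_names = nms, barcodes = bc,
               feature_types = types)
}

#' Write a count matrix in 10x MatrixMarket triplet layout
#'
#' Emits `matrix.mtx.gz`, `barcodes.tsv.gz` and `features.tsv.gz` (Cell
#' Ranger v3 dialect) into `dir`, creating it if needed. MatrixMarket values
#' are integers with 1-based triplet indices, genes as rows.
#'
#' @param x a [count_matrix()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_10x_mtx <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_data(sprintf("cannot create output directory '%s'", dir))
  }
  tmp <- tempfile(fileext = ".mtx")
  on.exit(unlink(tmp), add = TRUE)
  Matrix::writeMM(x$counts, tmp)
  lines <- readLines(tmp)
  # writeMM declares "integer" for whole-valued matrices, but degrades an
  # all-ones matrix to "pattern" (indices only): restore explicit 1s, and
  # force the integer header so downstream readers treat counts as counts.
  if (grepl("\\bpattern\\b", lines[1]) && length(lines) > 2) {
    lines[3:length(lines)] <- paste(lines[3:length(lines)], "1")
  }
  lines[1] <- "%%MatrixMarket matrix coordinate integer general"
  con <- gzfile(file.path(dir, "matrix.mtx.gz"), "wt")
  writeLines(lines, con)
  close(con)

  con <- gzfile(file.path(dir, "barcodes.tsv.gz"), "wt")
  writeLines(x$barcodes, con)
  close(con)

  con <- gzfile(file.path(dir, "features.tsv.gz"), "wt")
  writeLines(paste(x$genes$gene_id, x$genes$gene_name, x$genes$feature_type,
                   sep = "\t"), con)
  close(con)
  invisible(dir)
}

#' Read a barcode/cell-type/sample label table
#'
#' A TSV with a header and columns `barcode` and `cell_type` (required) and
#' `sample` (needed for pseudo-bulk aggregation).
#'
#' @param path path to the TSV file.
#' @return A tibble with one row per labeled barcode.
#' @export
read_cell_labels <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("file not found: '%s'", path))
  }
  labels <- readr::read_tsv(path, show_col_types = FALSE,
                            progress = FALSE)
  needed <- setdiff(c("barcode", "cell_type"), names(labels))
  if (length(needed) > 0) {
    stop_format(sprintf("label table '%s' lacks required column(s): %s",
                        path, paste(needed, collapse = ", ")))
  }
  labels
}
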