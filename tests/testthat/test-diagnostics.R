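test_that("gMax jumps only when the holding library enters the ambient set", {
  # gene 1's maximum (7) sits in a library of total 120: invisible at
  # thresholds 50 and 100, visible at 150
  dense <- rbind(c(2, 7, 0),
                 c(30, 113, 10))
  m <- count_matrix(Matrix::Matrix(dense, sparse = TRUE),
                    gene_ids = c("gX", "gY"),
                    barcodes = c("b1", "b2", "b3"))
  rp <- profile_removal_grid(m, thresholds = c(50, 100, 150))
  gx <- rp[rp$gene_id == "gX", ]
  expect_equal(gx$g_max, c(2L, 2L, 7L))
  expect_equal(gx$n_ambient, c(2L, 2L, 3L))
})

test_that("grid removal profiles match per-threshold dense oracles and are monotone", {
  set.seed(31)
  for (rep in 1:3) {
    m <- rand_count_matrix(60, 300, density = runif(1, 0.05, 0.2))
    grid <- c(5, 15, 30, 60, 100)
    rp <- profile_removal_grid(m, thresholds = grid)
    dense <- dense_of(m)
    prev_gmax <- rep(0L, 60)
    prev_namb <- 0L
    for (th in grid) {
      oracle <- dense_profile_oracle(dense, th)
      at <- rp[rp$empty_threshold == th, ]
      expect_identical(as.integer(at$g_max), oracle$g_max)
      expect_equal(at$fr_c, oracle$fr_c)
      expect_equal(at$n_ambient[1], oracle$n_ambient)
      expect_true(all(at$g_max >= prev_gmax))
      expect_gte(at$n_ambient[1], prev_namb)
      prev_gmax <- at$g_max
      prev_namb <- at$n_ambient[1]
    }
  }
})

test_that("a single-point grid equals compute_ambient_profile field for field", {
  set.seed(32)
  m <- rand_count_matrix(40, 200, density = 0.1)
  rp <- profile_removal_grid(m, thresholds = 25)
  prof <- compute_ambient_profile(m, 25)
  expect_identical(rp$g_max, prof$g_max)
  expect_equal(rp$fr_c, prof$fr_c)
  expect_equal(rp$n_ambient[1], attr(prof, "n_ambient_libraries"))
  expect_identical(rp$would_correct,
                   rp$gene_id %in% genes_to_correct(prof, 0.005))
})

test_that("grid validation rejects empty and non-increasing grids", {
  m <- rand_count_matrix(5, 10)
  expect_error(profile_removal_grid(m, numeric()), "empty",
               class = "fastcar_usage_error")
  expect_error(profile_removal_grid(m, c(10, 10)), "increasing",
               class = "fastcar_usage_error")
  expect_error(profile_removal_grid(m, c(-5, 10)), "non-negative",
               class = "fastcar_usage_error")
})

test_that("a gene absent below the largest threshold has an all-zero row", {
  dense <- rbind(c(0, 0, 5),
                 c(10, 20, 400))
  m <- count_matrix(Matrix::Matrix(dense, sparse = TRUE),
                    gene_ids = c("absent", "present"),
                    barcodes = c("b1", "b2", "b3"))
  rp <- profile_removal_grid(m, thresholds = c(10, 20, 50))
  ab <- rp[rp$gene_id == "absent", ]
  expect_true(all(ab$g_max == 0))
  expect_true(all(ab$fr_c == 0))
  expect_true(all(!ab$would_correct))
})

test_that("gene_removal_summary is the identity when gMax is 0", {
  sim <- simulate_sample(small_sim_config())
  cells <- cell_libraries(sim)
  labels <- cell_labels_of(sim)
  # a gene never seen in ambient libraries: all-zero gene cannot exist in
  # the sim, so force gMax = 0 by taking a threshold with no libraries
  gs <- suppressWarnings(gene_removal_summary(
    sim$matrix, cells, labels, gene = "MARK-T1-1", empty_threshold = 0))
  expect_equal(attr(gs, "g_max"), 0L)
  before <- gs[gs$phase == "before", setdiff(names(gs), "phase")]
  after <- gs[gs$phase == "after", setdiff(names(gs), "phase")]
  expect_equal(before, after)
})

test_that("gene_removal_summary reflects simulated contamination structure", {
  sim <- simulate_sample(small_sim_config())
  cells <- cell_libraries(sim)
  labels <- cell_labels_of(sim)
  gene <- "MARK-T1-1"
  gs <- gene_removal_summary(sim$matrix, cells, labels, gene,
                             empty_threshold = 100)
  g_max <- attr(gs, "g_max")
  expect_gt(g_max, 0)

  before <- gs[gs$phase == "before", ]
  after <- gs[gs$phase == "after", ]
  non_expr <- before$cell_type != "type1"
  # ambient-only presence in non-expressing types is mostly wiped
  expect_true(all(after$frac_positive[non_expr] <
                    pmax(0.05, before$frac_positive[non_expr])))
  # the expressing type keeps its signal: mean drops by at most g_max
  t1_before <- before$mean[before$cell_type == "type1"]
  t1_after <- after$mean[after$cell_type == "type1"]
  expect_gte(t1_after, t1_before - g_max)
  expect_gt(t1_after, 0)
})

test_that("unknown genes and unlabeled barcodes are handled", {
  sim <- simulate_sample(small_sim_config())
  cells <- cell_libraries(sim)
  labels <- cell_labels_of(sim)
  expect_error(gene_removal_summary(sim$matrix, cells, labels, "NOPE", 50),
               "not found", class = "fastcar_data_error")
  expect_warning(
    gene_removal_summary(sim$matrix, cells, labels[-1, ], "MARK-T1-1", 50),
    "lack labels")
})

test_that("an empty cell-type group yields an all-zero summary row", {
  sim <- simulate_sample(small_sim_config())
  cells <- cell_libraries(sim)
  labels <- cell_labels_of(sim)
  labels <- dplyr::bind_rows(
    labels, tibble::tibble(barcode = "ghost", is_cell = TRUE,
                           cell_type = "ghost_type", sample = "S1"))
  gs <- gene_removal_summary(sim$matrix, cells, labels, "MARK-T1-1", 100)
  ghost <- gs[gs$cell_type == "ghost_type", ]
  expect_equal(nrow(ghost), 2L)
  expect_true(all(ghost$n == 0))
  expect_true(all(ghost$mean == 0))
})

test_that("pseudobulk with one cell per group is the identity on columns", {
  set.seed(33)
  m <- rand_count_matrix(20, 5, density = 0.5)
  labels <- tibble::tibble(barcode = m$barcodes,
                           cell_type = paste0("ct", 1:5),
                           sample = "s1")
  pb <- pseudobulk_aggregate(m, labels)
  dense <- dense_of(m)
  for (i in 1:5) {
    col <- pb$count[pb$cell_type == paste0("ct", i)]
    expect_equal(col[match(m$genes$gene_id,
                           pb$gene_id[pb$cell_type == paste0("ct", i)])],
                 dense[, i])
  }
})

test_that("pseudobulk sums equal a dense group-by oracle and conserve totals", {
  set.seed(34)
  m <- rand_count_matrix(30, 120, density = 0.2)
  labels <- tibble::tibble(
    barcode = m$barcodes,
    cell_type = sample(c("T", "B", "NK"), 120, replace = TRUE),
    sample = sample(c("s1", "s2"), 120, replace = TRUE))
  pb <- pseudobulk_aggregate(m, labels)

  dense <- dense_of(m)
  colnames(dense) <- m$barcodes
  for (ct in c("T", "B", "NK")) {
    for (s in c("s1", "s2")) {
      sel <- labels$barcode[labels$cell_type == ct & labels$sample == s]
      want <- if (length(sel)) rowSums(dense[, sel, drop = FALSE]) else rep(0, 30)
      got <- pb$count[pb$cell_type == ct & pb$sample == s]
      if (length(got)) {
        expect_equal(got[match(m$genes$gene_id,
                               pb$gene_id[pb$cell_type == ct & pb$sample == s])],
                     unname(want))
      }
    }
  }
  expect_equal(sum(pb$count), sum(dense))
})

test_that("pseudobulk with a single group equals the gene totals", {
  set.seed(35)
  m <- rand_count_matrix(15, 40, density = 0.3)
  labels <- tibble::tibble(barcode = m$barcodes, cell_type = "all",
                           sample = "s1")
  pb <- pseudobulk_aggregate(m, labels)
  expect_equal(pb$count[match(m$genes$gene_id, pb$gene_id)],
               unname(Matrix::rowSums(dense_of(m))))
})

test_that("ambient_report shares the profile fields and ranks by ambient total", {
  set.seed(36)
  m <- rand_count_matrix(50, 300, density = 0.1)
  rep_tab <- ambient_report(m, empty_threshold = 40)
  prof <- compute_ambient_profile(m, 40)
  ord <- match(prof$gene_id, rep_tab$gene_id)
  expect_identical(rep_tab$g_max[ord], prof$g_max)
  expect_equal(rep_tab$fr_c[ord], prof$fr_c)
  expect_identical(rep_tab$ambient_total[ord], prof$ambient_total)

  dense <- dense_of(m)
  oracle <- dense_profile_oracle(dense, 40)
  top_oracle <- max(oracle$ambient_total)
  expect_equal(rep_tab$ambient_total[rep_tab$rank == 1][1], top_oracle)
})

test_that("ambient_report warns and returns zeros with no ambient libraries", {
  m <- count_matrix(Matrix::Matrix(100, 3, 3, sparse = TRUE),
                    gene_ids = c("a", "b", "c"), barcodes = c("x", "y", "z"))
  expect_warning(rep_tab <- ambient_report(m, 5), "no library")
  expect_true(all(rep_tab$ambient_total == 0))
  expect_equal(attr(rep_tab, "n_ambient_libraries"), 0L)
})

test_that("suggest_threshold picks the smallest qualifying grid point", {
  sim <- simulate_sample(small_sim_config())
  cells <- cell_libraries(sim)
  labels <- cell_labels_of(sim)
  rp <- profile_removal_grid(sim$matrix, thresholds = c(10, 25, 50, 100))
  sug <- suggest_threshold(rp, cells, labels, gene = "MARK-T1-1",
                           nonexpressing_types = c("type2", "type3", "type4"))
  expect_equal(nrow(sug), 1L)
  if (!is.na(sug$suggested_threshold)) {
    rows <- rp[rp$gene_id == "MARK-T1-1" & rp$g_max >= sug$nonexpressing_q3, ]
    expect_equal(sug$suggested_threshold, min(rows$empty_threshold))
  }
})
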