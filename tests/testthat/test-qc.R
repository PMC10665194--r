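qc_fixture <- function() {
  # six cells straddling every threshold; survivors enumerated by hand:
  # c1 passes everything; c2 fails umi (250 is removed, strict >250 kept);
  # c3 fails gene (100 removed); c4 fails mt (0.11 > 0.10); c5 fails ribo
  # (0.06 > 0.05); c6 sits exactly on every boundary that is kept.
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:6), embryo_id = "e1",
    umi_count = c(1000, 250, 300, 400, 500, 251),
    gene_count = c(200, 150, 100, 150, 150, 101),
    mt_frac = c(0.05, 0.05, 0.05, 0.11, 0.05, 0.10),
    ribo_frac = c(0.01, 0.01, 0.01, 0.01, 0.06, 0.05),
    doublet_score = 0.1)
  cell_dataset(NULL, cells)
}

test_that("cell filters keep exactly the hand-enumerated survivors", {
  ds <- filter_cells(qc_fixture())
  expect_identical(ds$cells$cell_id, c("c1", "c6"))
  report <- attr(ds, "qc_report")
  expect_identical(report$removed[report$criterion == "umi_min"], 1L)
  expect_identical(report$removed[report$criterion == "total"], 4L)
})

test_that("cell filtering is idempotent and warns when nothing survives", {
  once <- filter_cells(qc_fixture())
  twice <- filter_cells(once)
  expect_identical(once$cells, twice$cells)
  harsh <- pipeline_config(umi_min = 1e6)
  expect_warning(filter_cells(qc_fixture(), harsh), "all cells removed")
})

test_that("gene filter drops rare genes first, then sparse cells", {
  # gene g1 detected in 2 cells, g2 in 3, g3 only in cell c4;
  # with min_cells = 3 only g2 survives, pushing c1 (which expressed g1, g3
  # but not g2... actually c1 expresses g2 too) -- enumerate directly:
  counts <- rbind(g1 = c(1, 1, 0, 0),
                  g2 = c(1, 1, 1, 0),
                  g3 = c(0, 0, 0, 5))
  cells <- tibble::tibble(cell_id = paste0("c", 1:4), embryo_id = "e1")
  ds <- cell_dataset(counts, cells)
  out <- filter_genes(ds, min_cells = 3, min_genes_per_cell = 1)
  expect_identical(out$genes$gene_id, "g2")
  expect_identical(out$cells$cell_id, c("c1", "c2", "c3"))  # c4 lost its gene
  # boundary: detected in exactly min_cells cells is kept
  out2 <- filter_genes(ds, min_cells = 2, min_genes_per_cell = 1)
  expect_setequal(out2$genes$gene_id, c("g1", "g2"))
})

test_that("doublet rules flag scores above 0.2 and subclusters above 15%", {
  # subcluster A: 20 cells, 4 scoring > 0.2 (ratio 0.20 > 0.15) -> all 20
  # flagged; subcluster B: 20 cells, 3 flagged (ratio 0.15, not > 0.15) ->
  # only the 3 score-flagged cells.
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:40), embryo_id = "e1",
    doublet_score = c(rep(0.5, 4), rep(0.05, 16), rep(0.5, 3), rep(0.05, 17)))
  ds <- cell_dataset(NULL, cells)
  flags <- flag_doublet_subclusters(ds, rep(c("A", "B"), each = 20))
  expect_true(all(flags$doublet_flag[1:20]))
  expect_identical(sum(flags$doublet_flag[21:40]), 3L)
  expect_false(any(flags$subcluster_flag[21:40]))
  # a cell exactly at score 0.2 is not flagged
  ds2 <- cell_dataset(NULL, tibble::tibble(cell_id = paste0("x", 1:4),
                                           embryo_id = "e1",
                                           doublet_score = c(0.2, 0.2, 0.2,
                                                             0.2)))
  flags2 <- flag_doublet_subclusters(ds2, rep("A", 4))
  expect_false(any(flags2$doublet_flag))
  # missing scores instruct the user to supply them
  ds3 <- cell_dataset(NULL, tibble::tibble(cell_id = "a", embryo_id = "e1"))
  expect_error(flag_doublet_subclusters(ds3, "A"), "supply externally")
})

test_that("size factors follow the geometric-mean convention", {
  expect_equal(compute_size_factors(c(100, 100, 100)), c(1, 1, 1))
  expect_equal(compute_size_factors(c(100, 400)), c(0.5, 2.0))
  sf <- compute_size_factors(c(120, 530, 88, 1500))
  expect_lt(abs(mean(log(sf))), 1e-12)
  # order invariance and scale equivariance
  expect_equal(compute_size_factors(c(530, 120, 88, 1500))[2], sf[1])
  expect_equal(compute_size_factors(2 * c(120, 530, 88, 1500)), sf)
  expect_error(compute_size_factors(c(10, 0)), "non-positive")
})

test_that("pseudobulk profiles conserve per-embryo totals", {
  counts <- matrix(rpois(60, 5), 6, 10,
                   dimnames = list(paste0("g", 1:6), NULL))
  cells <- tibble::tibble(cell_id = paste0("c", 1:10),
                          embryo_id = rep(c("e1", "e2"), each = 5))
  ds <- cell_dataset(counts, cells)
  pb <- pseudobulk_profiles(ds)
  totals <- tapply(Matrix::colSums(ds$counts), cells$embryo_id, sum)
  expect_equal(colSums(pb)[names(totals)], totals, ignore_attr = TRUE)
  expect_equal(unname(pb[, "e1"]), unname(rowSums(counts[, 1:5])))
  # one cell per embryo: pseudobulk equals that cell's counts
  ds1 <- cell_dataset(counts[, 1:2], tibble::tibble(
    cell_id = c("a", "b"), embryo_id = c("e1", "e2")))
  expect_equal(unname(pseudobulk_profiles(ds1)[, "e1"]), counts[, 1],
               ignore_attr = TRUE)
})

test_that("normalized log profiles match hand computation on a 2-embryo toy", {
  pb <- cbind(e1 = c(10, 0, 30), e2 = c(80, 40, 40))
  # totals 40 and 160; geometric mean 80; size factors 0.5 and 2
  expected <- cbind(e1 = log2(c(10, 0, 30) / 0.5 + 1),
                    e2 = log2(c(80, 40, 40) / 2 + 1))
  expect_equal(normalize_profiles(pb), expected)
})

test_that("PCA staging projection is self-consistent and orthonormal", {
  set.seed(8)
  pb <- matrix(rpois(400 * 12, 20), 400, 12,
               dimnames = list(paste0("g", 1:400), paste0("e", 1:12)))
  model <- fit_pca_reference(pb, n_pcs = 5)
  expect_lt(max(abs(crossprod(model$rotation) - diag(5))), 1e-6)
  reproj <- project_onto_pca(model, pb)
  expect_lt(max(abs(reproj - model$scores)), 1e-8)
  # mean profile projects to the origin
  x <- normalize_profiles(pb)
  mean_profile <- matrix(rowMeans(x), ncol = 1,
                         dimnames = list(rownames(pb), "m"))
  sc <- project_onto_pca(model, mean_profile, normalize = FALSE)
  expect_lt(max(abs(sc)), 1e-8)
  expect_warning(fit_pca_reference(pb, n_pcs = 50), "reduced")
  expect_error(project_onto_pca(model, pb[1:100, ]), "50%")
})

test_that("PC1 of timecourse pseudobulks tracks developmental age", {
  set.seed(15)
  times <- rep(seq(9.5, 13.5, 1), each = 4)
  n_genes <- 300
  base <- runif(n_genes, 2, 6)
  slope <- rnorm(n_genes, 0, 0.25)
  pb <- sapply(times, function(t) {
    rpois(n_genes, exp(base + slope * (t - 11.5)))
  })
  rownames(pb) <- paste0("g", seq_len(n_genes))
  colnames(pb) <- paste0("e", seq_along(times))
  model <- fit_pca_reference(pb, n_pcs = 5)
  r <- cor(model$scores[, 1], times)
  expect_gt(abs(r), 0.9)
  # held-out embryos preserve the simulated stage ordering
  pb2 <- sapply(times, function(t) rpois(n_genes, exp(base + slope *
                                                        (t - 11.5))))
  rownames(pb2) <- rownames(pb)
  colnames(pb2) <- paste0("q", seq_along(times))
  proj <- project_onto_pca(model, pb2)
  expect_gt(abs(cor(proj[, 1], times, method = "spearman")), 0.9)
})
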