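test_that("similarity matrices match the exhaustive oracle", {
  set.seed(19)
  for (rep in 1:4) {
    n <- sample(60:150, 1)
    cells <- tibble::tibble(
      cell_id = paste0("c", seq_len(n)),
      embryo_id = sample(paste0("e", 1:4), n, TRUE),
      dim1 = runif(n), dim2 = runif(n))
    sim <- embryo_similarity(cells)
    oracle <- oracle_similarity(as.matrix(cells[, c("dim1", "dim2")]),
                                cells$embryo_id, sim$k)
    expect_equal(unname(sim$matrix[rownames(oracle), colnames(oracle)]),
                 unname(oracle))
  }
  # 3-embryo 1-D toy, exact
  toy <- tibble::tibble(cell_id = paste0("c", 1:9),
                        embryo_id = rep(c("a", "b", "c"), each = 3),
                        dim1 = c(0, 1, 2, 10, 11, 12, 20, 21, 22), dim2 = 0)
  sim_toy <- suppressWarnings(embryo_similarity(toy, k = 2))
  expect_warning(embryo_similarity(toy, k = 2), "fewer than 5 cells")
  oracle_toy <- oracle_similarity(cbind(toy$dim1, toy$dim2), toy$embryo_id, 2)
  expect_equal(unname(sim_toy$matrix), unname(oracle_toy))
})

test_that("exchangeable positions give entries near 1 and exact conservation", {
  set.seed(23)
  n_emb <- 4; n_per <- 400
  cells <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n_emb * n_per)),
    embryo_id = sample(rep(paste0("e", seq_len(n_emb)), n_per)),
    dim1 = rnorm(n_emb * n_per), dim2 = rnorm(n_emb * n_per))
  sim <- embryo_similarity(cells)
  expect_true(all(abs(sim$matrix - 1) < 0.1))
  # conservation: the n_j/N-weighted mean of every row of cell scores is 1
  w <- sim$n_cells_per_embryo / sum(sim$n_cells_per_embryo)
  row_means <- as.vector(sim$cell_scores %*% w)
  expect_equal(row_means, rep(1, nrow(sim$cell_scores)), tolerance = 1e-12)
})

test_that("disjoint genotype clusters give high within, low cross similarity", {
  des <- embedding_design(
    component_means = matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE),
    component_cov_scale = 0.5,
    component_weights_wt = c(1, 0) + c(-1e-9, 1e-9),
    component_weights_mut = c(0, 1) + c(1e-9, -1e-9),
    seed = 61)
  cells <- simulate_embedding_cohort(des, 3, 100)
  sim <- embryo_similarity(cells)
  geno <- ifelse(startsWith(sim$embryo_ids, "wt"), "wt", "mut")
  within <- sim$matrix[outer(geno, geno, "==")]
  cross <- sim$matrix[outer(geno, geno, "!=")]
  expect_gt(min(within), 1)
  expect_lt(max(cross), 1)
  gsim <- genotype_similarity(sim, geno)
  expect_gt(gsim["wt", "wt"], 1)
  expect_lt(gsim["wt", "mut"], 1)
})

test_that("genotype similarity averages embryo blocks, excluding self-pairs", {
  m <- matrix(c(2, 4, 1, 1,
                6, 8, 1, 1,
                1, 1, 3, 5,
                1, 1, 7, 9), 4, 4, byrow = TRUE,
              dimnames = list(paste0("e", 1:4), paste0("e", 1:4)))
  sim <- structure(list(matrix = m, embryo_ids = paste0("e", 1:4),
                        n_cells_per_embryo = rep(10L, 4), k = 3L,
                        flagged = character(0)),
                   class = "similarity_matrix")
  gs <- genotype_similarity(sim, c("A", "A", "B", "B"))
  expect_equal(gs["A", "A"], mean(c(4, 6)))  # diagonal self-pairs excluded
  expect_equal(gs["B", "B"], mean(c(5, 7)))
  expect_equal(gs["A", "B"], 1)
  # single embryo per genotype: equals the embryo entry
  gs1 <- genotype_similarity(sim, c("A", "B", "C", "D"))
  expect_equal(gs1["A", "B"], m["e1", "e2"])
  expect_equal(gs1["A", "A"], m["e1", "e1"])
})

test_that("time scores average the nearest reference times", {
  ref <- tibble::tibble(dim1 = c(rep(0, 5), rep(10, 5)), dim2 = 0,
                        time = rep(c(12.5, 13.5), each = 5))
  qry <- tibble::tibble(dim1 = c(10, 5), dim2 = 0)
  ts <- time_scores(qry, ref, k = 5)
  expect_equal(ts$time_score[1], 13.5)
  ts10 <- time_scores(qry[2, ], ref, k = 10)
  expect_equal(ts10$time_score, 13.0)  # even 12.5 / 13.5 split
  expect_error(time_scores(qry, ref, k = 11), "reference size")
  # uniform time translation of the reference shifts every score equally
  ref2 <- dplyr::mutate(ref, time = time + 2)
  expect_equal(time_scores(qry, ref2, k = 5)$time_score,
               ts$time_score + 2)
})

test_that("queries at a stage centroid score that stage's time", {
  des <- timecourse_design(cells_per_timepoint = 300, drift_per_day = 2,
                           noise_sd = 0.4, seed = 9)
  atlas <- simulate_reference_timecourse(des)
  centroid <- stage_centroid(des, 12.5)
  set.seed(10)
  qry <- tibble::tibble(dim1 = rnorm(200, centroid[1], 0.1),
                        dim2 = rnorm(200, centroid[2], 0.1))
  ts <- time_scores(qry, atlas, k = 10)
  expect_lt(abs(mean(ts$time_score) - 12.5), 0.1)
  expect_true(all(ts$time_score >= min(atlas$time) &
                    ts$time_score <= max(atlas$time)))
})

test_that("delay test behaves under symmetry, identity and delay", {
  set.seed(30)
  a <- rnorm(100, 12.5, 0.3); b <- rnorm(100, 12.5, 0.3)
  res_ab <- delay_test(a, b)
  res_ba <- delay_test(b, a)
  expect_equal(res_ab$t_statistic, -res_ba$t_statistic)
  expect_equal(res_ab$p_value, res_ba$p_value)
  expect_equal(delay_test(a, a)$p_value, 1)
  # mutant one day younger: overwhelming significance at 500 cells/group
  des <- timecourse_design(cells_per_timepoint = 400, drift_per_day = 2,
                           noise_sd = 0.5, seed = 13)
  atlas <- simulate_reference_timecourse(des)
  set.seed(14)
  place <- function(day, n) {
    c0 <- stage_centroid(des, day)
    tibble::tibble(dim1 = rnorm(n, c0[1], 0.5), dim2 = rnorm(n, c0[2], 0.5),
                   embryo_id = sample(paste0("e", 1:4), n, TRUE))
  }
  wt <- time_scores(place(12.5, 500), atlas)
  mut <- time_scores(place(11.5, 500), atlas)
  res <- delay_test(mut$time_score, wt$time_score)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$delay, 0.5)
  # embryo-level aggregation mode
  res_emb <- delay_test(mut, wt, level = "embryo")
  expect_lt(res_emb$p_value, 0.01)
  # degenerate zero-variance input
  degen <- delay_test(c(1, 1), c(1, 1))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})
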