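# Independent brute-force oracles, written as plain double loops over a full
# distance matrix so they share nothing with the package's chunked kNN engine
# except the tie-break rule (equal distances resolve to the lower index).

oracle_nn <- function(coords, i, k, banned = integer(0)) {
  d <- sqrt(colSums((t(coords) - coords[i, ])^2))
  d[banned] <- Inf
  order(d)[seq_len(k)]
}

oracle_lochness <- function(coords, is_mut, embryo_id, k) {
  n <- nrow(coords)
  mut_frac <- sum(is_mut) / n
  scores <- numeric(n)
  for (i in seq_len(n)) {
    nn <- oracle_nn(coords, i, k, banned = which(embryo_id == embryo_id[i]))
    scores[i] <- (sum(is_mut[nn]) / k) / mut_frac - 1
  }
  scores
}

oracle_similarity <- function(coords, embryo_id, k) {
  n <- nrow(coords)
  lev <- sort(unique(embryo_id))
  n_per <- sapply(lev, function(e) sum(embryo_id == e))
  cell_scores <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(n)) {
    nn <- oracle_nn(coords, i, k, banned = i)
    for (j in seq_along(lev)) {
      obs <- sum(embryo_id[nn] == lev[j]) / k
      cell_scores[i, j] <- obs / (n_per[j] / n)
    }
  }
  sim <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (a in seq_along(lev)) {
    sim[a, ] <- colMeans(cell_scores[embryo_id == lev[a], , drop = FALSE])
  }
  sim
}

oracle_label_transfer <- function(query, reference, labels, k) {
  out_label <- character(nrow(query))
  out_score <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- sqrt(colSums((t(reference) - query[i, ])^2))
    nn <- order(d)[seq_len(k)]
    tab <- table(labels[nn])
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1) {
      md <- sapply(winners, function(l) mean(d[nn][labels[nn] == l]))
      winners <- sort(winners[md == min(md)])
    }
    out_label[i] <- winners[1]
    out_score[i] <- max(tab) / k
  }
  list(label = out_label, score = out_score)
}

# Dense grid search over (intercept, genotype effect, rho) maximising the
# beta-binomial log-likelihood; a coarse pass followed by a refinement pass
# around the best grid point.
oracle_bb_grid <- function(k, n, g, b0_range, b1_range, rho_range = c(1e-4, 0.3)) {
  ll <- function(b0, b1, rho) {
    mu <- plogis(b0 + b1 * g)
    if (rho == 0) return(sum(dbinom(k, n, mu, log = TRUE)))
    theta <- (1 - rho) / rho
    a <- mu * theta
    b <- (1 - mu) * theta
    sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
  }
  search <- function(b0s, b1s, rhos) {
    best <- c(NA, NA, NA, -Inf)
    for (b0 in b0s) for (b1 in b1s) for (r in rhos) {
      v <- ll(b0, b1, r)
      if (is.finite(v) && v > best[4]) best <- c(b0, b1, r, v)
    }
    best
  }
  # rho = 0 (the binomial boundary) is always a candidate
  best <- search(seq(b0_range[1], b0_range[2], length.out = 31),
                 seq(b1_range[1], b1_range[2], length.out = 31),
                 c(0, exp(seq(log(rho_range[1]), log(rho_range[2]),
                              length.out = 31))))
  for (pass in 1:3) {
    w_b0 <- diff(b0_range) / 30 / 3^(pass - 1)
    w_b1 <- diff(b1_range) / 30 / 3^(pass - 1)
    rhos <- if (best[3] == 0) {
      c(0, exp(seq(log(rho_range[1]), log(rho_range[1]) + 2,
                   length.out = 21)))
    } else {
      c(0, exp(seq(log(best[3]) - 0.4 / 3^(pass - 1),
                   log(best[3]) + 0.4 / 3^(pass - 1), length.out = 21)))
    }
    best <- search(seq(best[1] - w_b0, best[1] + w_b0, length.out = 21),
                   seq(best[2] - w_b1, best[2] + w_b1, length.out = 21),
                   rhos)
  }
  list(b0 = best[1], b1 = best[2], rho = best[3], loglik = best[4])
}

# Small well-separated cohort used by several suites.
make_two_blob_cells <- function(n_per_embryo = 60, seed = 42,
                                enriched = TRUE) {
  des <- embedding_design(
    component_means = matrix(c(0, 0, 4, 4), 2, 2, byrow = TRUE),
    component_cov_scale = 0.4,
    component_weights_wt = c(0.8, 0.2),
    component_weights_mut = if (enriched) c(0.3, 0.7) else c(0.8, 0.2),
    enriched_component = if (enriched) 2L else NULL,
    seed = seed)
  simulate_embedding_cohort(des, n_embryos_per_genotype = 3,
                            cells_per_embryo = n_per_embryo)
}

# A pair of synthetic atlases sharing `n_traj` expression programs, each
# with its own additive noise; the shared programs are what reciprocal NNLS
# should recover.
make_atlas_pair <- function(n_traj = 8, n_genes = 400, noise = 0.05,
                            seed = 1) {
  set.seed(seed)
  programs <- matrix(rexp(n_genes * n_traj, 1), n_genes, n_traj)
  # give each trajectory a block of strong marker genes
  per <- floor(n_genes / n_traj)
  for (t in seq_len(n_traj)) {
    programs[((t - 1) * per + 1):(t * per), t] <-
      programs[((t - 1) * per + 1):(t * per), t] + 5
  }
  dimnames(programs) <- list(paste0("g", seq_len(n_genes)),
                             paste0("traj", seq_len(n_traj)))
  a <- programs + matrix(abs(rnorm(length(programs), 0, noise)),
                         n_genes, n_traj)
  b <- programs + matrix(abs(rnorm(length(programs), 0, noise)),
                         n_genes, n_traj)
  dimnames(a) <- dimnames(b) <- dimnames(programs)
  list(a = a, b = b)
}

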