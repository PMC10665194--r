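#' Neighbourhood size for lochNESS and similarity scores
#'
#' `k = max(1, round(sqrt(N) / 2))`, the scaling used throughout the
#' neighbourhood analyses (round-half-even, floored at 1).
#'
#' @param n_total Dataset size N (at least 4).
#' @return Integer neighbourhood size.
#' @export
choose_k <- function(n_total) {
  if (n_total < 4) stop("n_total must be at least 4")
  max(1L, as.integer(round(sqrt(n_total) / 2)))
}

#' Per-cell lochNESS neighbourhood enrichment scores
#'
#' lochNESS measures, for every cell, the fold change of the mutant-cell
#' fraction in its k-nearest-neighbour neighbourhood relative to the
#' dataset-wide mutant fraction, minus one:
#' `score = (mutant neighbours / k) / (m / N) - 1`. Cells from the same
#' embryo as the focal cell are excluded from its neighbourhood. Positive
#' scores mark local mutant enrichment, negative scores depletion; the score
#' is bounded below by -1 (no mutant neighbours) and above by
#' `1 / mut_fraction - 1` (all neighbours mutant).
#'
#' @param data Per-cell data frame with a binary genotype column, an embryo
#'   column, and embedding columns.
#' @param coords Embedding columns (character vector or matrix); `NULL`
#'   selects `dim1..dimd`.
#' @param genotype Name of the genotype column.
#' @param mutant Value of `genotype` regarded as mutant.
#' @param embryo Name of the embryo id column.
#' @param k Neighbourhood size; `NULL` for [choose_k()] on the dataset size.
#'
#' @return An object of class `lochness_result` carrying the per-cell score
#'   vector plus `k`, `n_total`, `n_mut`, `mut_fraction`, the neighbour index
#'   matrix (reused by [lochness_null()]) and the input table.
#' @export
compute_lochness <- function(data, coords = NULL, genotype = "genotype",
                             mutant = "mut", embryo = "embryo_id",
                             k = NULL) {
  m <- embedding_matrix(data, coords)
  is_mut <- data[[genotype]] == mutant
  if (!any(is_mut) || all(is_mut)) {
    stop("the dataset must contain both mutant and non-mutant cells")
  }
  n_total <- nrow(m)
  if (is.null(k)) k <- choose_k(n_total)
  embryo_id <- as.character(data[[embryo]])
  if (max(table(embryo_id)) > n_total - k) {
    stop("an embryo holds more than N - k cells; neighbourhoods excluding ",
         "same-embryo cells cannot be filled")
  }
  nn <- knn_indices(m, m, k, ref_groups = embryo_id,
                    query_groups = embryo_id)
  mut_frac <- sum(is_mut) / n_total
  mut_nn <- matrix(is_mut[nn$index], nrow(nn$index), k)
  scores <- (rowSums(mut_nn) / k) / mut_frac - 1
  stopifnot(all(scores >= -1 - 1e-12),
            all(scores <= 1 / mut_frac - 1 + 1e-12))
  structure(list(scores = scores, k = as.integer(k),
                 n_total = n_total, n_mut = sum(is_mut),
                 mut_fraction = mut_frac,
                 nn_index = nn$index, is_mut = is_mut,
                 data = tibble::as_tibble(data),
                 perm_scores = NULL),
            class = "lochness_result")
}

#' @export
print.lochness_result <- function(x, ...) {
  cat("<lochness_result> ", x$n_total, " cells, k = ", x$k,
      ", mutant fraction ", signif(x$mut_fraction, 3), "\n", sep = "")
  cat("  score range [", signif(min(x$scores), 3), ", ",
      signif(max(x$scores), 3), "], median ",
      signif(stats::median(x$scores), 3), "\n", sep = "")
  if (!is.null(x$perm_scores)) {
    cat("  permutation null: ", ncol(x$perm_scores), " replicates\n",
        sep = "")
  }
  invisible(x)
}

#' @describeIn compute_lochness Per-cell tibble: the input table plus a
#'   `lochness` column (and permutation summaries when available).
#' @param x A `lochness_result`.
#' @param ... Unused.
#' @method tidy lochness_result
#' @export
tidy.lochness_result <- function(x, ...) {
  out <- x$data
  out$lochness <- x$scores
  if (!is.null(x$perm_scores)) {
    out$perm_q95 <- apply(abs(x$perm_scores), 1, stats::quantile, 0.95)
  }
  out
}

#' @describeIn compute_lochness One-row summary (k, N, m, mutant fraction,
#'   deviance when the null is available).
#' @method glance lochness_result
#' @export
glance.lochness_result <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_mut = x$n_mut, k = x$k,
                 mut_fraction = x$mut_fraction,
                 median_score = stats::median(x$scores),
                 deviance = if (is.null(x$perm_scores)) NA_real_ else
                   lochness_deviance(x$scores, x$perm_scores))
}

#' Permutation null for lochNESS
#'
#' Recomputes lochNESS under independent random permutations of the
#' mutant/wild-type cell labels, reusing the neighbour graph (which does not
#' depend on labels). Under permutation the scores form a bell-shaped
#' distribution centred at zero.
#'
#' @param result A `lochness_result` from [compute_lochness()].
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed.
#' @param unit `"cell"` permutes labels over cells (default); `"embryo"`
#'   permutes genotype assignments over whole embryos, preserving
#'   within-embryo label correlation.
#'
#' @return The `lochness_result` with a `perm_scores` matrix (cells x
#'   permutations) attached.
#' @export
lochness_null <- function(result, n_permutations = 100, seed = 1L,
                          unit = c("cell", "embryo")) {
  stopifnot(inherits(result, "lochness_result"))
  unit <- match.arg(unit)
  set.seed(seed)
  n <- result$n_total
  perm <- matrix(NA_real_, n, n_permutations)
  for (r in seq_len(n_permutations)) {
    if (unit == "cell") {
      lab <- sample(result$is_mut)
    } else {
      emb <- as.character(result$data[[if ("embryo_id" %in%
                                           names(result$data)) "embryo_id"
                                       else 1]])
      emb_lv <- unique(emb)
      emb_mut <- vapply(emb_lv, function(e) result$is_mut[match(e, emb)],
                        logical(1))
      shuffled <- stats::setNames(sample(emb_mut), emb_lv)
      lab <- unname(shuffled[emb])
    }
    mut_nn <- matrix(lab[result$nn_index], n, result$k)
    perm[, r] <- (rowSums(mut_nn) / result$k) / (sum(lab) / n) - 1
  }
  result$perm_scores <- perm
  result
}

#' Deviance of lochNESS from its permutation null
#'
#' The average (over permutation replicates) Euclidean distance between the
#' observed score vector and each permuted score vector. By default the
#' distance is normalized per cell (divided by `sqrt(n_cells)`, i.e. an RMS
#' per-cell deviation) so values are comparable across groups of different
#' sizes; `normalize = "none"` gives the raw Euclidean distance.
#'
#' @param observed Observed score vector.
#' @param perm_scores Matrix (cells x permutations) of permuted scores.
#' @param normalize `"rms"` (default) or `"none"`.
#' @return A non-negative scalar.
#' @export
lochness_deviance <- function(observed, perm_scores,
                              normalize = c("rms", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(length(observed) == nrow(perm_scores))
  d <- sqrt(colSums((perm_scores - observed)^2))
  if (normalize == "rms") d <- d / sqrt(length(observed))
  mean(d)
}

#' Screen lochNESS distributions across cell groups
#'
#' Summarises the observed-versus-null behaviour of lochNESS within each
#' group (typically sub-trajectories): median score, deviance from the
#' permutation null, and a two-sample Kolmogorov-Smirnov statistic of the
#' observed scores against the group's pooled permuted scores. Groups are
#' sorted by decreasing deviance; groups with fewer than 20 cells are flagged
#' low-confidence.
#'
#' @param result A `lochness_result` with permutations attached
#'   ([lochness_null()]).
#' @param group Name of the per-cell grouping column in the result's data, or
#'   a vector of per-cell labels.
#' @return A tibble with one row per group.
#' @export
screen_distributions <- function(result, group = "sub_trajectory") {
  stopifnot(inherits(result, "lochness_result"))
  if (is.null(result$perm_scores)) {
    stop("run lochness_null() before screening distributions")
  }
  labels <- if (length(group) == 1 && is.character(group)) {
    if (!group %in% names(result$data)) {
      stop("column `", group, "` was not present when lochNESS was ",
           "computed; pass a per-cell label vector instead")
    }
    result$data[[group]]
  } else {
    group
  }
  stopifnot(length(labels) == result$n_total)
  groups <- sort(unique(as.character(labels)))
  rows <- lapply(groups, function(g) {
    in_g <- labels == g
    obs <- result$scores[in_g]
    perm <- result$perm_scores[in_g, , drop = FALSE]
    ks <- suppressWarnings(stats::ks.test(obs, as.vector(perm)))
    tibble::tibble(group = g, n_cells = sum(in_g),
                   median_score = stats::median(obs),
                   deviance = lochness_deviance(obs, perm),
                   ks_stat = unname(ks$statistic),
                   low_confidence = sum(in_g) < 20)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$deviance))
}

#' Gene expression changes associated with lochNESS
#'
#' Fits, per gene, an overdispersed count regression of expression on the
#' per-cell lochNESS score with a log link and the log size factor as offset
#' (negative-binomial GLM; Poisson fallback on convergence failure). Wald
#' p-values per gene are Benjamini-Hochberg adjusted across genes. Genes with
#' adjusted p below `alpha` are reported as associated with mutant-enriched
#' (positive coefficient) or mutant-depleted (negative) areas.
#'
#' @param counts Genes-by-cells count matrix (sparse or dense).
#' @param scores Per-cell lochNESS scores.
#' @param size_factors Per-cell size factors; `NULL` computes them from
#'   column totals.
#' @param alpha Adjusted-p cutoff for calling associated genes.
#' @return A tibble: `gene_id`, `beta`, `se`, `p_value`, `q_value`,
#'   `status` ("enriched", "depleted", "ns" or "untested").
#' @export
lochness_gene_assoc <- function(counts, scores, size_factors = NULL,
                                alpha = 0.05) {
  if (length(scores) != ncol(counts)) {
    stop("scores must have one entry per cell (column)")
  }
  if (length(scores) < 50) stop("at least 50 cells are required")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (is.null(size_factors)) {
    size_factors <- compute_size_factors(Matrix::colSums(counts))
  }
  off <- log(size_factors)
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  beta <- se <- p <- rep(NA_real_, nrow(counts))
  for (gi in seq_len(nrow(counts))) {
    y <- as.numeric(counts[gi, ])
    if (sum(y) == 0) next
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ scores + offset(off))),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        suppressWarnings(stats::glm(y ~ scores + offset(off),
                                    family = stats::poisson())),
        error = function(e) NULL)
    }
    if (is.null(fit)) next
    sm <- summary(fit)$coefficients
    if (!"scores" %in% rownames(sm)) next
    beta[gi] <- sm["scores", 1]
    se[gi] <- sm["scores", 2]
    p[gi] <- sm["scores", 4]
  }
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  status <- dplyr::case_when(
    !tested ~ "untested",
    q < alpha & beta > 0 ~ "enriched",
    q < alpha & beta < 0 ~ "depleted",
    TRUE ~ "ns")
  tibble::tibble(gene_id = gene_ids, beta = beta, se = se,
                 p_value = p, q_value = q, status = status)
}

#' Local inverse Simpson index (LISI)
#'
#' The effective number of labels represented in each cell's neighbourhood,
#' computed with Gaussian-kernel weights whose per-cell bandwidth is tuned by
#' binary search to a target perplexity. With two labels, values near 2 mean
#' the labels are locally well mixed and values near 1 that the neighbourhood
#' is dominated by one label. By default `perplexity =
#' floor(0.5 * sqrt(N / 3))` (clamped to at least 1, with a warning) and the
#' kernel is evaluated over `K = 3 * perplexity` nearest neighbours.
#'
#' @param data Per-cell data frame with a label column and embedding columns.
#' @param coords Embedding columns; `NULL` selects `dim1..dimd`.
#' @param label Name of the (binary or categorical) label column.
#' @param perplexity Target perplexity; `NULL` for the dataset-size default.
#' @return Numeric per-cell LISI values in `[1, n_labels]`.
#' @export
compute_lisi <- function(data, coords = NULL, label = "genotype",
                         perplexity = NULL) {
  m <- embedding_matrix(data, coords)
  labels <- factor(data[[label]])
  n <- nrow(m)
  if (is.null(perplexity)) perplexity <- floor(0.5 * sqrt(n / 3))
  if (perplexity < 1) {
    warning("perplexity below 1; clamped to 1")
    perplexity <- 1
  }
  K <- min(3 * perplexity, n - 1)
  nn <- knn_indices(m, m, K, self = TRUE)
  target_h <- log(perplexity)
  lisi <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- nn$dist[i, ]^2
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        p_ <- w / sw
        h <- -sum(ifelse(p_ > 0, p_ * log(p_), 0))
      }
      if (abs(h - target_h) < 1e-5) break
      if (h > target_h) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-beta * d2)
    if (sum(w) == 0) { w <- rep(1, K) }
    p_ <- w / sum(w)
    lab_w <- tapply(p_, labels[nn$index[i, ]], sum)
    lab_w[is.na(lab_w)] <- 0
    lisi[i] <- 1 / sum(lab_w^2)
  }
  lisi
}
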