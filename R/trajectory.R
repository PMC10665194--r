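#' Signature genes for a target trajectory
#'
#' The union of the `n_each` most highly expressed genes in the target
#' trajectory and the `n_each` most highly specific genes, where specificity
#' is the target's share of the gene's aggregate signal across trajectories.
#' Ties are broken by gene order; if fewer than `n_each` genes exist, all are
#' used with a warning.
#'
#' @param profiles Genes-by-trajectories matrix of aggregate expression
#'   (e.g. summed log-normalized counts), with dimnames.
#' @param target Target trajectory (column name or index).
#' @param n_each Genes per criterion (default 3000).
#' @return Character vector of selected gene ids.
#' @export
select_signature_genes <- function(profiles, target, n_each = 3000) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("at least 2 trajectories are required")
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("gene", seq_len(nrow(profiles)))
  }
  if (n_each > nrow(profiles)) {
    warning("fewer genes than n_each; using all ", nrow(profiles), " genes")
    n_each <- nrow(profiles)
  }
  expr <- profiles[, target]
  totals <- rowSums(profiles)
  specificity <- ifelse(totals > 0, expr / totals, 0)
  top_expr <- order(-expr)[seq_len(n_each)]         # stable: ties by row order
  top_spec <- order(-specificity)[seq_len(n_each)]
  rownames(profiles)[sort(unique(c(top_expr, top_spec)))]
}

#' Non-negative least-squares prediction of one profile from others
#'
#' Least squares with all slope coefficients constrained non-negative
#' (Lawson-Hanson active set); the intercept is left unconstrained by fitting
#' on mean-centered data and recovering it afterwards.
#'
#' @param target_profile Numeric vector (one gene per entry).
#' @param predictor_profiles Genes-by-trajectories matrix, rows aligned with
#'   `target_profile`.
#' @return A list with `intercept`, `coefficients` (named, all `>= 0`) and
#'   `residual_norm`.
#' @export
nnls_predict <- function(target_profile, predictor_profiles) {
  X <- as.matrix(predictor_profiles)
  y <- as.numeric(target_profile)
  stopifnot(nrow(X) == length(y))
  x_means <- colMeans(X)
  y_mean <- mean(y)
  fit <- pracma::lsqnonneg(sweep(X, 2L, x_means, "-"), y - y_mean)
  beta <- fit$x
  names(beta) <- colnames(X)
  intercept <- y_mean - sum(x_means * beta)
  resid <- y - intercept - as.numeric(X %*% beta)
  list(intercept = intercept, coefficients = beta,
       residual_norm = sqrt(sum(resid^2)))
}

#' Reciprocal NNLS matching of trajectories between two atlases
#'
#' For every trajectory pair (a in atlas A, b in atlas B), predicts a's
#' profile from all of B's trajectories and b's from all of A's, each on the
#' target's own signature gene set, and combines the two directional
#' coefficients as `combined = 2 * (beta_ab + 0.001) * (beta_ba + 0.001)`.
#' High combined scores reflect reciprocal, specific predictivity; each
#' trajectory's best match is the argmax of its combined row.
#'
#' @param profiles_a,profiles_b Genes-by-trajectories aggregate expression
#'   matrices sharing a gene universe (matched by rowname intersection).
#' @param n_each Signature genes per criterion (see
#'   [select_signature_genes()]).
#' @return An object of class `trajectory_match` with matrices `beta_ab`
#'   (A-targets x B-predictors), `beta_ba` (B-targets x A-predictors),
#'   `combined` (A x B) and the per-target `gene_sets`.
#' @export
reciprocal_match <- function(profiles_a, profiles_b, n_each = 3000) {
  profiles_a <- as.matrix(profiles_a)
  profiles_b <- as.matrix(profiles_b)
  shared <- intersect(rownames(profiles_a), rownames(profiles_b))
  if (length(shared) == 0) stop("the atlases share no genes")
  A <- profiles_a[shared, , drop = FALSE]
  B <- profiles_b[shared, , drop = FALSE]
  ta <- colnames(A); tb <- colnames(B)
  beta_ab <- matrix(0, length(ta), length(tb), dimnames = list(ta, tb))
  beta_ba <- matrix(0, length(tb), length(ta), dimnames = list(tb, ta))
  gene_sets <- list()
  for (a in ta) {
    gs <- select_signature_genes(A, a, n_each)
    gene_sets[[paste0("A:", a)]] <- gs
    beta_ab[a, ] <- nnls_predict(A[gs, a], B[gs, , drop = FALSE])$coefficients
  }
  for (b in tb) {
    gs <- select_signature_genes(B, b, n_each)
    gene_sets[[paste0("B:", b)]] <- gs
    beta_ba[b, ] <- nnls_predict(B[gs, b], A[gs, , drop = FALSE])$coefficients
  }
  combined <- 2 * (beta_ab + 0.001) * t(beta_ba + 0.001)
  structure(list(trajectories_a = ta, trajectories_b = tb,
                 beta_ab = beta_ab, beta_ba = beta_ba,
                 combined = combined, gene_sets = gene_sets),
            class = "trajectory_match")
}

#' @export
print.trajectory_match <- function(x, ...) {
  cat("<trajectory_match> ", length(x$trajectories_a), " x ",
      length(x$trajectories_b), " trajectories\n", sep = "")
  best <- best_matches(x)
  print(as.data.frame(best), row.names = FALSE)
  invisible(x)
}

#' Best match per trajectory
#' @param match A `trajectory_match`.
#' @return A tibble: `trajectory_a`, `best_match`, `combined`.
#' @export
best_matches <- function(match) {
  stopifnot(inherits(match, "trajectory_match"))
  idx <- apply(match$combined, 1, which.max)
  tibble::tibble(trajectory_a = match$trajectories_a,
                 best_match = match$trajectories_b[idx],
                 combined = match$combined[cbind(seq_along(idx), idx)])
}

#' @describeIn reciprocal_match Long format: one row per trajectory pair
#'   with both directional coefficients, the combined score and a best-match
#'   flag.
#' @param x A `trajectory_match`.
#' @param ... Unused.
#' @method tidy trajectory_match
#' @export
tidy.trajectory_match <- function(x, ...) {
  long <- expand.grid(trajectory_a = x$trajectories_a,
                      trajectory_b = x$trajectories_b,
                      stringsAsFactors = FALSE)
  long$beta_ab <- x$beta_ab[cbind(long$trajectory_a, long$trajectory_b)]
  long$beta_ba <- x$beta_ba[cbind(long$trajectory_b, long$trajectory_a)]
  long$combined <- x$combined[cbind(long$trajectory_a, long$trajectory_b)]
  best <- best_matches(x)
  long$best_match <- paste(long$trajectory_a, long$trajectory_b) %in%
    paste(best$trajectory_a, best$best_match)
  tibble::as_tibble(long)
}
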