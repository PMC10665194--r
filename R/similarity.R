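#' Embryo-by-embryo neighbourhood similarity scores
#'
#' For each cell `n` and target embryo `j`, the similarity score is the
#' observed over expected fraction of embryo-`j` cells among the cell's `k`
#' nearest neighbours: `(neighbours from j / k) / (n_j / N)`. Only the query
#' cell itself is excluded from its own neighbourhood, so same-embryo
#' neighbours count towards the diagonal. The matrix entry `(i, j)` is the
#' mean score over all cells of embryo `i`; under exchangeable cell positions
#' every entry has expectation 1.
#'
#' @param data Per-cell data frame with an embryo column and embedding
#'   columns.
#' @param coords Embedding columns; `NULL` selects `dim1..dimd`.
#' @param embryo Name of the embryo id column.
#' @param k Neighbourhood size; `NULL` for [choose_k()].
#'
#' @return An object of class `similarity_matrix`: the embryo-level `matrix`
#'   (rows: scored embryo, columns: target embryo), `embryo_ids`,
#'   `n_cells_per_embryo`, `k`, and `flagged` (embryos with fewer than 5
#'   cells, retained but flagged).
#' @export
embryo_similarity <- function(data, coords = NULL, embryo = "embryo_id",
                              k = NULL) {
  m <- embedding_matrix(data, coords)
  embryo_id <- factor(data[[embryo]])
  if (nlevels(embryo_id) < 2) stop("at least 2 embryos are required")
  n <- nrow(m)
  if (is.null(k)) k <- choose_k(n)
  n_per <- table(embryo_id)
  flagged <- names(n_per)[n_per < 5]
  if (length(flagged)) {
    warning("embryos with fewer than 5 cells: ",
            paste(flagged, collapse = ", "))
  }
  nn <- knn_indices(m, m, k, self = TRUE)
  # per-cell neighbour counts by target embryo
  lev <- levels(embryo_id)
  counts <- matrix(0L, n, length(lev), dimnames = list(NULL, lev))
  nn_emb <- matrix(as.integer(embryo_id)[nn$index], n, k)
  for (j in seq_along(lev)) counts[, j] <- rowSums(nn_emb == j)
  stopifnot(all(rowSums(counts) == k))  # conservation identity
  expected <- as.numeric(n_per[lev]) / n
  cell_scores <- sweep(counts / k, 2L, expected, "/")
  sim <- rowsum(cell_scores, embryo_id) / as.vector(n_per)
  structure(list(matrix = sim, embryo_ids = lev,
                 n_cells_per_embryo = as.integer(n_per[lev]),
                 k = as.integer(k), flagged = flagged,
                 cell_scores = cell_scores, cell_embryo = embryo_id),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> ", length(x$embryo_ids), " embryos, k = ", x$k,
      "\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' @describeIn embryo_similarity Long-format view: one row per (scored
#'   embryo, target embryo) pair.
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  long <- tibble::as_tibble(as.table(x$matrix), .name_repair = "minimal")
  names(long) <- c("embryo_i", "embryo_j", "similarity")
  long
}

#' Genotype-by-genotype similarity scores
#'
#' Averages the embryo-level similarity entries within each ordered genotype
#' pair, excluding an embryo's self-pair on the diagonal. Because the
#' underlying observed/expected scores are directional, the output need not
#' be symmetric.
#'
#' @param sim A `similarity_matrix` from [embryo_similarity()].
#' @param genotype Per-embryo genotype labels, in the order of
#'   `sim$embryo_ids` (or a named vector).
#' @return A genotype-by-genotype matrix.
#' @export
genotype_similarity <- function(sim, genotype) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!is.null(names(genotype))) genotype <- genotype[sim$embryo_ids]
  stopifnot(length(genotype) == length(sim$embryo_ids))
  genotype <- as.character(genotype)
  lev <- sort(unique(genotype))
  out <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (a in lev) for (b in lev) {
    ia <- which(genotype == a); ib <- which(genotype == b)
    vals <- sim$matrix[ia, ib, drop = FALSE]
    if (a == b) {
      if (length(ia) == 1) { out[a, b] <- vals[1, 1]; next }
      diag(vals) <- NA
    }
    out[a, b] <- mean(vals, na.rm = TRUE)
  }
  out
}

#' Developmental time scores against a staged reference
#'
#' Each query cell's time score is the mean developmental time of its `k`
#' nearest reference-atlas cells in the shared embedding space, so scores
#' always lie within the reference time range; lower-than-wild-type mean
#' scores indicate developmental delay.
#'
#' @param query Per-cell data frame with embedding columns (shared with the
#'   reference).
#' @param reference A staged reference: data frame with embedding columns and
#'   a `time` column (e.g. from [simulate_reference_timecourse()]).
#' @param k Reference neighbours per query cell (default 10).
#' @param coords Embedding columns; `NULL` selects `dim1..dimd`.
#' @return `query` as a tibble with an added `time_score` column.
#' @export
time_scores <- function(query, reference, k = 10, coords = NULL) {
  if (!"time" %in% names(reference)) {
    stop("reference must have a `time` column")
  }
  if (is.null(coords)) {
    coords <- grep("^dim[0-9]+$", names(reference), value = TRUE)
  }
  ref_m <- embedding_matrix(reference, coords)
  qry_m <- embedding_matrix(query, coords)
  if (k > nrow(ref_m)) {
    stop("k = ", k, " exceeds the reference size ", nrow(ref_m))
  }
  nn <- knn_indices(qry_m, ref_m, k)
  tscore <- rowMeans(matrix(reference$time[nn$index], nrow(qry_m), k))
  out <- tibble::as_tibble(query)
  out$time_score <- tscore
  out
}

#' Test for developmental delay between genotypes
#'
#' Two-sided Welch t-test comparing mutant and wild-type time scores. The
#' default tests at the cell level; `level = "embryo"` first averages scores
#' within embryos and tests embryo means, avoiding pseudoreplication.
#'
#' @param scores_mut,scores_wt Time-score vectors (cell level), or, for the
#'   embryo level, data frames with `embryo_id` and `time_score`.
#' @param level `"cell"` or `"embryo"`.
#' @return A one-row tibble: `t_statistic`, `p_value`, `mean_mut`, `mean_wt`,
#'   `delay` (wt mean minus mutant mean; positive = mutant younger),
#'   `degenerate` flag for zero-variance inputs.
#' @export
delay_test <- function(scores_mut, scores_wt, level = c("cell", "embryo")) {
  level <- match.arg(level)
  if (level == "embryo") {
    agg <- function(df) {
      stopifnot(all(c("embryo_id", "time_score") %in% names(df)))
      tapply(df$time_score, df$embryo_id, mean)
    }
    scores_mut <- as.numeric(agg(scores_mut))
    scores_wt <- as.numeric(agg(scores_wt))
  }
  if (length(scores_mut) < 2 || length(scores_wt) < 2) {
    stop("at least 2 scores per group are required")
  }
  degenerate <- stats::sd(scores_mut) == 0 && stats::sd(scores_wt) == 0
  if (degenerate) {
    equal <- mean(scores_mut) == mean(scores_wt)
    return(tibble::tibble(t_statistic = if (equal) 0 else Inf *
                            sign(mean(scores_mut) - mean(scores_wt)),
                          p_value = if (equal) 1 else 0,
                          mean_mut = mean(scores_mut),
                          mean_wt = mean(scores_wt),
                          delay = mean(scores_wt) - mean(scores_mut),
                          degenerate = TRUE))
  }
  tt <- stats::t.test(scores_mut, scores_wt)
  tibble::tibble(t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 mean_mut = mean(scores_mut), mean_wt = mean(scores_wt),
                 delay = mean(scores_wt) - mean(scores_mut),
                 degenerate = FALSE)
}
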