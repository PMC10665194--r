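#' Transfer labels from a reference by k-nearest-neighbour vote
#'
#' For each query cell, finds its `k` Euclidean nearest reference cells and
#' assigns the most frequent reference label; the assigned score is the
#' winning label's frequency divided by `k`. Vote ties are broken by the
#' smallest mean neighbour distance among the tied labels, then
#' lexicographically, so results are deterministic.
#'
#' @param query Per-cell data frame of cells to annotate, carrying embedding
#'   columns (`dim1..dimd` or as named by `coords`).
#' @param reference Per-cell data frame of labelled reference cells in the
#'   same embedding space.
#' @param label Name of the reference label column.
#' @param coords Embedding columns (character vector), a matrix pair is not
#'   supported — both tables must share column names; `NULL` selects
#'   `dim1..dimd`.
#' @param k Neighbourhood size (default 15).
#'
#' @return `query` with added columns `assigned_label`, `assigned_score`
#'   (in `(0, 1]`), `k_used`, and `low_confidence` (score at or below 0.8,
#'   flagged for review).
#' @export
knn_label_transfer <- function(query, reference, label = "label",
                               coords = NULL, k = 15) {
  if (!label %in% names(reference)) {
    stop("reference has no column `", label, "`")
  }
  if (is.null(coords)) {
    coords <- grep("^dim[0-9]+$", names(reference), value = TRUE)
  }
  ref_m <- embedding_matrix(reference, coords)
  qry_m <- embedding_matrix(query, coords)
  if (k > nrow(ref_m)) {
    stop("k = ", k, " exceeds the reference size ", nrow(ref_m))
  }
  labels <- as.character(reference[[label]])
  nn <- knn_indices(qry_m, ref_m, k)
  assigned <- character(nrow(qry_m))
  score <- numeric(nrow(qry_m))
  for (i in seq_len(nrow(qry_m))) {
    lab_i <- labels[nn$index[i, ]]
    tab <- table(lab_i)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1) {
      mean_d <- vapply(winners, function(l) {
        mean(nn$dist[i, lab_i == l])
      }, numeric(1))
      winners <- winners[mean_d == min(mean_d)]
      winners <- sort(winners)
    }
    assigned[i] <- winners[1]
    score[i] <- max(tab) / k
  }
  out <- tibble::as_tibble(query)
  out$assigned_label <- assigned
  out$assigned_score <- score
  out$k_used <- as.integer(k)
  out$low_confidence <- score <= 0.8
  out
}
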