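# Exact k-nearest-neighbour search with deterministic tie handling.
#
# Distances are squared Euclidean, computed chunk-wise from the expansion
# ||q - r||^2 = ||q||^2 - 2 q.r + ||r||^2 so that each chunk is a single
# dense matrix product. Ties at identical distance are resolved in favour of
# the lower reference index (the order() radix sort is stable).
#
# `exclude` is an optional list-like specification of reference indices that
# must never appear among a query's neighbours:
#   - NULL: no exclusion
#   - "self": query i may not pick reference i (coords must be the same set)
#   - a factor/vector `groups` of length n_ref paired with `query_groups`:
#     reference cells sharing the query's group are excluded.
knn_indices <- function(query, reference, k,
                        self = FALSE,
                        ref_groups = NULL, query_groups = NULL,
                        chunk = 512L) {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  stopifnot(ncol(query) == ncol(reference))
  n_ref <- nrow(reference)
  n_query <- nrow(query)
  if (k > n_ref - as.integer(self)) {
    stop("k = ", k, " exceeds the number of available reference cells")
  }
  if (!is.null(ref_groups)) {
    stopifnot(length(ref_groups) == n_ref, length(query_groups) == n_query)
    ref_groups <- as.character(ref_groups)
    query_groups <- as.character(query_groups)
  }

  ref_sq <- rowSums(reference^2)
  idx <- matrix(NA_integer_, n_query, k)
  dst <- matrix(NA_real_, n_query, k)
  starts <- seq(1L, n_query, by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, n_query)
    q <- query[rows, , drop = FALSE]
    d2 <- sweep(-2 * tcrossprod(q, reference), 2L, ref_sq, "+") + rowSums(q^2)
    d2[d2 < 0] <- 0
    for (j in seq_along(rows)) {
      i <- rows[j]
      di <- d2[j, ]
      if (self) di[i] <- Inf
      if (!is.null(ref_groups)) di[ref_groups == query_groups[i]] <- Inf
      ord <- order(di)[seq_len(k)]
      if (is.infinite(di[ord[k]])) {
        stop("fewer than k eligible neighbours for cell ", i,
             " after exclusions")
      }
      idx[i, ] <- ord
      dst[i, ] <- sqrt(di[ord])
    }
  }
  list(index = idx, dist = dst)
}

# Dirichlet draws via normalized gamma variates; rows are draws.
rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0) || any(!is.finite(alpha))) {
    stop("Dirichlet parameters must be positive and finite")
  }
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# Pull an embedding matrix out of a per-cell data frame. `coords` may be a
# character vector of column names, a numeric matrix (returned as-is), or
# NULL, in which case all columns named dim1, dim2, ... are used.
embedding_matrix <- function(data, coords = NULL) {
  if (is.matrix(coords)) {
    stopifnot(nrow(coords) == nrow(data))
    return(coords)
  }
  if (is.null(coords)) {
    coords <- grep("^dim[0-9]+$", names(data), value = TRUE)
    if (length(coords) == 0) {
      stop("no embedding columns found: expected columns named dim1, dim2, ...",
           " or an explicit `coords` argument")
    }
  }
  missing <- setdiff(coords, names(data))
  if (length(missing)) {
    stop("embedding columns not present in data: ",
         paste(missing, collapse = ", "))
  }
  as.matrix(data[, coords, drop = FALSE])
}
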