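#' Filter low-quality cells
#'
#' Removes cells with UMI count at or below `config$umi_min`, detected genes
#' at or below `config$gene_min`, mitochondrial fraction strictly above
#' `config$mt_max`, or ribosomal fraction strictly above `config$ribo_max`.
#' The order of surviving cells is preserved and per-criterion removal counts
#' are recorded in the `qc_report` attribute.
#'
#' @param dataset A `cell_dataset` with `umi_count`, `gene_count`, `mt_frac`
#'   and `ribo_frac` populated.
#' @param config A [pipeline_config()].
#' @return The filtered `cell_dataset`, with a `qc_report` attribute (tibble
#'   of per-criterion removal counts).
#' @export
filter_cells <- function(dataset, config = pipeline_config()) {
  cells <- dataset$cells
  need <- c("umi_count", "gene_count", "mt_frac", "ribo_frac")
  miss <- need[vapply(need, function(c) all(is.na(cells[[c]])), logical(1))]
  if (length(miss)) {
    stop("filter_cells needs populated columns: ",
         paste(miss, collapse = ", "))
  }
  fail_umi <- cells$umi_count <= config$umi_min
  fail_gene <- cells$gene_count <= config$gene_min
  fail_mt <- cells$mt_frac > config$mt_max
  fail_ribo <- cells$ribo_frac > config$ribo_max
  keep <- !(fail_umi | fail_gene | fail_mt | fail_ribo)
  report <- tibble::tibble(
    criterion = c("umi_min", "gene_min", "mt_max", "ribo_max", "total"),
    removed = c(sum(fail_umi), sum(fail_gene), sum(fail_mt), sum(fail_ribo),
                sum(!keep)))
  if (!any(keep)) {
    warning("all cells removed by quality filters")
  }
  out <- subset_cells(dataset, keep)
  attr(out, "qc_report") <- report
  out
}

#' Filter rarely detected genes, then sparse cells
#'
#' Drops genes detected (count > 0) in fewer than `min_cells` cells, then
#' cells expressing fewer than `min_genes_per_cell` of the remaining genes —
#' in that order, so the gene filter can push cells below the gene threshold.
#'
#' @param dataset A `cell_dataset` with counts.
#' @param min_cells Minimum number of cells a gene must be detected in.
#' @param min_genes_per_cell Minimum genes a cell must express afterwards.
#' @return The filtered `cell_dataset`.
#' @export
filter_genes <- function(dataset, min_cells = 10, min_genes_per_cell = 100) {
  if (is.null(dataset$counts)) stop("dataset has no counts")
  detected_in <- Matrix::rowSums(dataset$counts > 0)
  keep_genes <- detected_in >= min_cells
  counts <- dataset$counts[keep_genes, , drop = FALSE]
  genes <- dataset$genes[keep_genes, , drop = FALSE]
  genes_per_cell <- Matrix::colSums(counts > 0)
  keep_cells <- genes_per_cell >= min_genes_per_cell
  if (!any(keep_cells)) warning("all cells removed by the gene filter")
  cell_dataset(counts[, keep_cells, drop = FALSE],
               dataset$cells[keep_cells, , drop = FALSE], genes,
               lapply(dataset$embeddings,
                      function(m) m[keep_cells, , drop = FALSE]))
}

#' Flag doublets and doublet-derived subclusters
#'
#' A cell is flagged when its own (externally computed) doublet score exceeds
#' `config$doublet_score_max`, or when the fraction of score-flagged cells in
#' its subcluster strictly exceeds `config$doublet_subcluster_frac`, in which
#' case the whole subcluster is flagged.
#'
#' @param dataset A `cell_dataset` whose `cells$doublet_score` is populated.
#' @param subclusters Per-cell subcluster labels covering every cell.
#' @param config A [pipeline_config()].
#' @return A tibble with `cell_id`, `score_flag`, `subcluster_flag` and the
#'   combined `doublet_flag`.
#' @export
flag_doublet_subclusters <- function(dataset, subclusters,
                                     config = pipeline_config()) {
  cells <- dataset$cells
  if (all(is.na(cells$doublet_score))) {
    stop("doublet scores are missing: supply externally computed scores in ",
         "cells$doublet_score")
  }
  if (length(subclusters) != nrow(cells) || anyNA(subclusters)) {
    stop("subcluster labels must cover all cells")
  }
  score_flag <- cells$doublet_score > config$doublet_score_max
  ratio <- tapply(score_flag, subclusters, mean)
  cluster_flag <- ratio > config$doublet_subcluster_frac
  subcluster_flag <- unname(cluster_flag[as.character(subclusters)])
  tibble::tibble(cell_id = cells$cell_id,
                 subcluster = as.character(subclusters),
                 score_flag = score_flag,
                 subcluster_flag = subcluster_flag,
                 doublet_flag = score_flag | subcluster_flag)
}

#' Size factors from per-sample totals
#'
#' `size_factor_j = total_j / geometric_mean(totals)`, so the log size
#' factors sum to zero.
#'
#' @param totals Positive per-sample totals (named or not).
#' @return Per-sample positive size factors.
#' @export
compute_size_factors <- function(totals) {
  bad <- which(totals <= 0)
  if (length(bad)) {
    nm <- if (!is.null(names(totals))) names(totals)[bad[1]] else bad[1]
    stop("sample ", nm, " has a non-positive total")
  }
  totals / exp(mean(log(totals)))
}

#' Pseudobulk expression profiles
#'
#' Sums counts over all cells of each group (embryo by default), yielding a
#' genes-by-groups matrix of aggregate counts.
#'
#' @param dataset A `cell_dataset` with counts.
#' @param group_by Name of the per-cell grouping column.
#' @return A dense matrix, genes in rows, groups in columns (sorted by name).
#' @export
pseudobulk_profiles <- function(dataset, group_by = "embryo_id") {
  if (is.null(dataset$counts)) stop("dataset has no counts")
  groups <- factor(dataset$cells[[group_by]])
  design <- Matrix::sparseMatrix(i = seq_along(groups),
                                 j = as.integer(groups),
                                 x = 1, dims = c(length(groups),
                                                 nlevels(groups)))
  out <- as.matrix(dataset$counts %*% design)
  colnames(out) <- levels(groups)
  rownames(out) <- dataset$genes$gene_id
  out
}

#' Normalize pseudobulk profiles
#'
#' Divides each column by its size factor (from column totals) and applies
#' `log2(x + 1)`.
#'
#' @param profiles Genes-by-samples matrix of aggregate counts.
#' @return Normalized log2 profile matrix.
#' @export
normalize_profiles <- function(profiles) {
  sf <- compute_size_factors(colSums(profiles))
  log2(sweep(profiles, 2L, sf, "/") + 1)
}

#' Fit a PCA staging reference on pseudobulk profiles
#'
#' Centers (without scaling) the normalized log2 profiles and fits a PCA;
#' the model stores the feature order, the center vector and the rotation so
#' external samples can be projected into the same space.
#'
#' @param profiles Genes-by-samples matrix of raw aggregate counts.
#' @param n_pcs Components to retain; clamped to the matrix rank with a
#'   warning if necessary.
#' @param normalize Apply [normalize_profiles()] first (default `TRUE`).
#' @return An object of class `pca_model`.
#' @export
fit_pca_reference <- function(profiles, n_pcs = 50, normalize = TRUE) {
  x <- if (normalize) normalize_profiles(profiles) else profiles
  max_rank <- min(nrow(x), ncol(x) - 1)
  if (n_pcs > max_rank) {
    warning("n_pcs reduced from ", n_pcs, " to the available rank ", max_rank)
    n_pcs <- max_rank
  }
  pc <- stats::prcomp(base::t(x), center = TRUE, scale. = FALSE)
  structure(list(feature_ids = rownames(x),
                 center = pc$center,
                 rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
                 sdev = pc$sdev[seq_len(n_pcs)],
                 n_pcs = n_pcs,
                 scores = pc$x[, seq_len(n_pcs), drop = FALSE]),
            class = "pca_model")
}

#' Project pseudobulk profiles onto a fitted PCA reference
#'
#' @param model A `pca_model` from [fit_pca_reference()].
#' @param profiles Genes-by-samples matrix of raw aggregate counts covering
#'   the model's features; features missing from `profiles` are imputed as
#'   zero with a warning, but fewer than 50% overlap is an error.
#' @param normalize Apply [normalize_profiles()] first (default `TRUE`).
#' @return A samples-by-`n_pcs` score matrix.
#' @export
project_onto_pca <- function(model, profiles, normalize = TRUE) {
  x <- if (normalize) normalize_profiles(profiles) else profiles
  overlap <- intersect(model$feature_ids, rownames(x))
  if (length(overlap) < 0.5 * length(model$feature_ids)) {
    stop("fewer than 50% of the model's features are present in the query")
  }
  if (length(overlap) < length(model$feature_ids)) {
    warning(length(model$feature_ids) - length(overlap),
            " model features missing from the query; imputed as 0")
  }
  full <- matrix(0, length(model$feature_ids), ncol(x),
                 dimnames = list(model$feature_ids, colnames(x)))
  full[overlap, ] <- x[overlap, , drop = FALSE]
  scores <- base::t(full - model$center) %*% model$rotation
  scores
}
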