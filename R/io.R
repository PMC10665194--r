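#' Assemble a cell-level dataset
#'
#' The universal carrier between pipeline stages: a sparse genes-by-cells
#' count matrix, a per-cell metadata tibble, a gene table and a named list of
#' low-dimensional embeddings (one row per cell).
#'
#' @param counts Sparse (or dense) non-negative integer matrix, genes in rows,
#'   cells in columns. May be `NULL` for embedding-only datasets.
#' @param cells Data frame of per-cell metadata. Must contain `cell_id`
#'   (unique) and `embryo_id`; recognised optional columns are `genotype`,
#'   `background`, `major_trajectory`, `sub_trajectory`, `umi_count`,
#'   `gene_count`, `mt_frac`, `ribo_frac`, `doublet_score`. Missing optional
#'   columns are filled with `NA`.
#' @param genes Data frame with columns `gene_id` and `gene_name`; defaults to
#'   the row names of `counts`.
#' @param embeddings Named list of numeric matrices, each with one row per
#'   cell.
#'
#' @return An object of class `cell_dataset`.
#' @export
cell_dataset <- function(counts = NULL, cells, genes = NULL,
                         embeddings = list()) {
  cells <- tibble::as_tibble(cells)
  optional <- c("genotype", "background", "major_trajectory", "sub_trajectory",
                "umi_count", "gene_count", "mt_frac", "ribo_frac",
                "doublet_score")
  if (!all(c("cell_id", "embryo_id") %in% names(cells))) {
    stop("`cells` must contain cell_id and embryo_id columns")
  }
  if (anyDuplicated(cells$cell_id)) stop("cell_id values must be unique")
  if (any(is.na(cells$embryo_id) | cells$embryo_id == "")) {
    stop("embryo_id must be non-empty for every cell")
  }
  char_cols <- c("genotype", "background", "major_trajectory",
                 "sub_trajectory")
  for (col in optional) {
    if (!col %in% names(cells)) {
      cells[[col]] <- if (col %in% char_cols) NA_character_ else NA_real_
    } else if (col %in% char_cols) {
      cells[[col]] <- as.character(cells[[col]])
    } else {
      cells[[col]] <- as.numeric(cells[[col]])
    }
  }
  cells$cell_id <- as.character(cells$cell_id)
  cells$embryo_id <- as.character(cells$embryo_id)
  if (!is.null(counts)) {
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "CsparseMatrix"), "dMatrix")
    if (ncol(counts) != nrow(cells)) {
      stop("counts has ", ncol(counts), " columns but cells has ",
           nrow(cells), " rows")
    }
    if (any(counts@x < 0)) stop("counts must be non-negative")
    if (is.null(genes)) {
      ids <- rownames(counts)
      if (is.null(ids)) ids <- paste0("gene", seq_len(nrow(counts)))
      genes <- tibble::tibble(gene_id = ids, gene_name = ids)
    }
    genes <- tibble::as_tibble(genes)
    if (!"gene_name" %in% names(genes)) genes$gene_name <- genes$gene_id
    if (nrow(genes) != nrow(counts)) {
      stop("genes table has ", nrow(genes), " rows but counts has ",
           nrow(counts))
    }
    rownames(counts) <- genes$gene_id
    colnames(counts) <- cells$cell_id
  } else {
    genes <- tibble::tibble(gene_id = character(), gene_name = character())
  }
  if (length(embeddings)) {
    if (is.null(names(embeddings)) || any(names(embeddings) == "")) {
      stop("embeddings must be a named list")
    }
    embeddings <- lapply(embeddings, function(m) {
      m <- as.matrix(m)
      if (nrow(m) != nrow(cells)) {
        stop("every embedding must have exactly one row per cell")
      }
      rownames(m) <- cells$cell_id
      if (is.null(colnames(m))) colnames(m) <- paste0("dim", seq_len(ncol(m)))
      m
    })
  }
  structure(list(counts = counts, cells = cells, genes = genes,
                 embeddings = embeddings),
            class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  n_genes <- if (is.null(x$counts)) 0L else nrow(x$counts)
  cat("<cell_dataset> ", nrow(x$cells), " cells, ", n_genes, " genes\n",
      sep = "")
  cat("  embryos: ", length(unique(x$cells$embryo_id)), sep = "")
  if (!all(is.na(x$cells$genotype))) {
    tab <- table(x$cells$genotype)
    cat("  genotypes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        sep = "")
  }
  cat("\n")
  if (length(x$embeddings)) {
    dims <- vapply(x$embeddings, ncol, integer(1))
    cat("  embeddings: ",
        paste(names(dims), " (d=", dims, ")", sep = "", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of cells in a dataset
#' @param dataset A `cell_dataset`.
#' @return Integer cell count.
#' @export
n_cells <- function(dataset) nrow(dataset$cells)

#' Subset a dataset to a set of cells
#' @param dataset A `cell_dataset`.
#' @param keep Logical or integer index over cells.
#' @return The subsetted `cell_dataset`.
#' @export
subset_cells <- function(dataset, keep) {
  cells <- dataset$cells[keep, , drop = FALSE]
  counts <- if (is.null(dataset$counts)) NULL else {
    dataset$counts[, keep, drop = FALSE]
  }
  embeddings <- lapply(dataset$embeddings, function(m) m[keep, , drop = FALSE])
  cell_dataset(counts, cells, dataset$genes, embeddings)
}

#' Pipeline configuration
#'
#' Bundles the thresholds and tuning constants used across the pipeline. The
#' defaults are the working values of the whole analysis: cells with UMI count
#' at or below `umi_min` or detected genes at or below `gene_min` are
#' discarded, as are cells with mitochondrial read fraction above `mt_max` or
#' ribosomal fraction above `ribo_max`; doublet calls use the `doublet_*`
#' thresholds; composition tests drop cell types whose normalized mean count
#' per embryo falls below `min_mean_cells` and report significance at `alpha`.
#'
#' @param seed Integer seed from which every stage derives its randomness.
#' @param umi_min,gene_min Per-cell minimum UMI and detected-gene counts
#'   (cells at or below the threshold are removed).
#' @param mt_max,ribo_max Maximum tolerated mitochondrial / ribosomal read
#'   fractions (strict inequality: a cell exactly at the threshold is kept).
#' @param doublet_score_max Per-cell doublet-score cutoff (scores above it are
#'   flagged).
#' @param doublet_subcluster_frac Subclusters whose flagged fraction exceeds
#'   this value are flagged wholesale.
#' @param knn_annotation_k Neighbourhood size for label transfer.
#' @param alpha Nominal significance level.
#' @param n_permutations Label permutations for the lochNESS null.
#' @param n_power_sims Simulations per power-grid point.
#' @param power_threshold Power regarded as sufficient detection.
#' @param timescore_k Neighbourhood size for developmental time scores.
#' @param log2_display_clip Display clip for log2 proportion ratios.
#' @param min_mean_cells Mean normalized count below which a cell type is not
#'   tested.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            umi_min = 250, gene_min = 100,
                            mt_max = 0.10, ribo_max = 0.05,
                            doublet_score_max = 0.2,
                            doublet_subcluster_frac = 0.15,
                            knn_annotation_k = 15L,
                            alpha = 0.05,
                            n_permutations = 100L,
                            n_power_sims = 100L,
                            power_threshold = 0.8,
                            timescore_k = 10L,
                            log2_display_clip = 2.0,
                            min_mean_cells = 10) {
  cfg <- list(seed = as.integer(seed), umi_min = umi_min, gene_min = gene_min,
              mt_max = mt_max, ribo_max = ribo_max,
              doublet_score_max = doublet_score_max,
              doublet_subcluster_frac = doublet_subcluster_frac,
              knn_annotation_k = as.integer(knn_annotation_k), alpha = alpha,
              n_permutations = as.integer(n_permutations),
              n_power_sims = as.integer(n_power_sims),
              power_threshold = power_threshold,
              timescore_k = as.integer(timescore_k),
              log2_display_clip = log2_display_clip,
              min_mean_cells = min_mean_cells)
  fracs <- c("mt_max", "ribo_max", "doublet_subcluster_frac", "alpha",
             "power_threshold")
  for (f in fracs) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) stop(f, " must lie in (0, 1]")
  }
  counts <- c("knn_annotation_k", "n_permutations", "n_power_sims",
              "timescore_k")
  for (f in counts) {
    if (cfg[[f]] < 1) stop(f, " must be at least 1")
  }
  structure(cfg, class = "pipeline_config")
}

# Stage-specific seeds are derived from the global seed by fixed offsets so a
# full pipeline run is reproducible end to end while stages stay decoupled.
stage_seed <- function(config, stage) {
  offsets <- c(simulate = 101L, qc = 211L, annotate = 307L, composition = 401L,
               power = 503L, lochness = 601L, similarity = 701L, delay = 809L,
               match = 907L, expression = 1009L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(config$seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Read a cell dataset from its on-disk layout
#'
#' Expects `matrix.mtx` (Matrix Market coordinate format), `cells.tsv` and
#' `genes.tsv` in `path`, plus an optional `embeddings/` directory of TSV
#' matrices (one file per embedding, named `<name>.tsv`).
#'
#' @param path Directory containing the dataset.
#' @return A `cell_dataset`.
#' @export
read_cell_dataset <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  cells_f <- file.path(path, "cells.tsv")
  genes_f <- file.path(path, "genes.tsv")
  for (f in c(mtx, cells_f, genes_f)) {
    if (!file.exists(f)) stop("missing required file: ", f)
  }
  counts <- tryCatch(Matrix::readMM(mtx),
                     error = function(e) stop("malformed Matrix Market file ",
                                              mtx, ": ", conditionMessage(e)))
  cells <- utils::read.delim(cells_f, sep = "\t", stringsAsFactors = FALSE)
  genes <- utils::read.delim(genes_f, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(cells) != ncol(counts)) {
    stop("cells.tsv has ", nrow(cells), " rows but matrix.mtx has ",
         ncol(counts), " columns")
  }
  if (nrow(genes) != nrow(counts)) {
    stop("genes.tsv has ", nrow(genes), " rows but matrix.mtx has ",
         nrow(counts), " rows")
  }
  embeddings <- list()
  emb_dir <- file.path(path, "embeddings")
  if (dir.exists(emb_dir)) {
    for (f in sort(list.files(emb_dir, pattern = "\\.tsv$",
                              full.names = TRUE))) {
      nm <- sub("\\.tsv$", "", basename(f))
      m <- as.matrix(utils::read.delim(f, sep = "\t"))
      embeddings[[nm]] <- m
    }
  }
  cell_dataset(counts, cells, genes, embeddings)
}

#' Write a cell dataset to disk
#'
#' Emits the `matrix.mtx` + `cells.tsv` + `genes.tsv` (+ `embeddings/*.tsv`)
#' layout with deterministic ordering, so writing the same dataset twice
#' yields byte-identical files. Structural zeros are dropped from the sparse
#' matrix before writing.
#'
#' @param dataset A `cell_dataset`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_cell_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  counts <- dataset$counts
  if (is.null(counts)) {
    counts <- Matrix::Matrix(0, nrow = 0, ncol = nrow(dataset$cells),
                             sparse = TRUE)
  }
  counts <- Matrix::drop0(counts)
  Matrix::writeMM(counts, file.path(path, "matrix.mtx"))
  utils::write.table(dataset$cells, file.path(path, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$genes, file.path(path, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(dataset$embeddings)) {
    emb_dir <- file.path(path, "embeddings")
    dir.create(emb_dir, showWarnings = FALSE)
    for (nm in sort(names(dataset$embeddings))) {
      utils::write.table(dataset$embeddings[[nm]],
                         file.path(emb_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
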