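#' Design for a synthetic composition cohort
#'
#' Describes a multi-embryo cohort at the level of cell-type counts: how many
#' cell types, their baseline proportions, the Dirichlet concentration that
#' controls embryo-to-embryo proportion scatter, replicate numbers, per-embryo
#' cell recovery, and multiplicative genotype effects. The defaults emulate
#' the structure of a whole-embryo single-cell atlas: 20 cell types with
#' abundances spanning roughly 1-20%, 4 replicate embryos per genotype, and
#' about 15,000 cells recovered per embryo.
#'
#' @param n_celltypes Number of cell types.
#' @param base_proportions Baseline proportion vector (sums to 1). Default: a
#'   geometric ladder from ~15% down to ~0.8% over `n_celltypes` types.
#' @param dirichlet_concentration Concentration of the Dirichlet distribution
#'   from which per-embryo proportions are drawn (larger = tighter replicates).
#' @param n_wt_embryos,n_mut_embryos Replicate embryos per genotype group.
#' @param cells_per_embryo_mean,cells_per_embryo_sd Normal law for per-embryo
#'   cell totals, truncated below at 100.
#' @param effect_sizes Named or positional numeric vector in \[-1, 1\]; the
#'   count of cell type `t` in mutant embryos is multiplied by
#'   `1 - effect_sizes[t]` (0.1 = a 10% reduction). Recycled with zeros.
#' @param seed Integer seed.
#'
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_celltypes = 20,
                          base_proportions = NULL,
                          dirichlet_concentration = 8000,
                          n_wt_embryos = 4, n_mut_embryos = 4,
                          cells_per_embryo_mean = 15000,
                          cells_per_embryo_sd = 3000,
                          effect_sizes = numeric(0),
                          seed = 1L) {
  if (is.null(base_proportions)) {
    raw <- 0.05^(seq(0, 1, length.out = n_celltypes))
    base_proportions <- raw / sum(raw)
  }
  n_celltypes <- length(base_proportions)
  if (any(base_proportions < 0) ||
      abs(sum(base_proportions) - 1) > 1e-9) {
    stop("base_proportions must be non-negative and sum to 1")
  }
  if (n_wt_embryos < 1 || n_mut_embryos < 1) {
    stop("at least one embryo per genotype is required")
  }
  if (dirichlet_concentration <= 0) {
    stop("dirichlet_concentration must be positive")
  }
  if (cells_per_embryo_sd < 0) stop("cells_per_embryo_sd must be >= 0")
  eff <- rep(0, n_celltypes)
  type_names <- names(base_proportions)
  if (is.null(type_names)) type_names <- paste0("type", seq_len(n_celltypes))
  names(eff) <- type_names
  if (length(effect_sizes)) {
    if (any(abs(effect_sizes) > 1)) {
      stop("effect sizes must lie in [-1, 1]")
    }
    if (!is.null(names(effect_sizes))) {
      unknown <- setdiff(names(effect_sizes), type_names)
      if (length(unknown)) stop("unknown cell types: ",
                                paste(unknown, collapse = ", "))
      eff[names(effect_sizes)] <- effect_sizes
    } else {
      eff[seq_along(effect_sizes)] <- effect_sizes
    }
  }
  structure(list(n_celltypes = n_celltypes,
                 base_proportions = stats::setNames(base_proportions,
                                                    type_names),
                 dirichlet_concentration = dirichlet_concentration,
                 n_wt_embryos = n_wt_embryos, n_mut_embryos = n_mut_embryos,
                 cells_per_embryo_mean = cells_per_embryo_mean,
                 cells_per_embryo_sd = cells_per_embryo_sd,
                 effect_sizes = eff, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate an embryo-by-cell-type composition cohort
#'
#' Each embryo's total cell recovery is a truncated-normal draw (floor 100);
#' its cell-type proportions are a Dirichlet draw around the baseline; the
#' expected count of each type is proportions times total, with mutant
#' embryos' counts multiplied by `1 - effect_size` per type before rounding.
#'
#' @param design A [cohort_design()].
#' @return A `composition_table` (see [composition_table()]).
#' @export
simulate_composition_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  n_wt <- design$n_wt_embryos
  n_mut <- design$n_mut_embryos
  n_emb <- n_wt + n_mut
  genotype <- rep(c("wt", "mut"), c(n_wt, n_mut))
  embryo_id <- paste0(genotype, ".", c(seq_len(n_wt), seq_len(n_mut)))
  totals <- pmax(100, round(stats::rnorm(n_emb, design$cells_per_embryo_mean,
                                         design$cells_per_embryo_sd)))
  alpha <- design$dirichlet_concentration * design$base_proportions
  props <- rdirichlet(n_emb, alpha)
  counts <- props * totals
  shrink <- 1 - design$effect_sizes
  counts[genotype == "mut", ] <-
    sweep(counts[genotype == "mut", , drop = FALSE], 2L, shrink, "*")
  counts <- round(counts)
  dimnames(counts) <- list(embryo_id, names(design$base_proportions))
  composition_table(counts,
                    embryo_meta = tibble::tibble(embryo_id = embryo_id,
                                                 genotype = genotype,
                                                 background = "B6"))
}

#' Design for a Gaussian-mixture embedding cohort
#'
#' A synthetic stand-in for an aligned low-dimensional embedding of one
#' developmental trajectory: cells fall into `n_components` Gaussian blobs
#' (sub-states) whose mixture weights may differ between wild-type and mutant
#' embryos, so that one component can be enriched or depleted in mutants.
#'
#' @param component_means Matrix (components x d, d >= 2) of blob centres.
#' @param component_cov_scale Isotropic standard deviation of each blob.
#' @param component_weights_wt,component_weights_mut Mixture weights per
#'   genotype (each sums to 1).
#' @param enriched_component Index of the component whose weight differs
#'   between genotypes, or `NULL` for exchangeable designs (bookkeeping only).
#' @param seed Integer seed.
#'
#' @return A list of class `embedding_design`.
#' @export
embedding_design <- function(component_means,
                             component_cov_scale = 0.5,
                             component_weights_wt = NULL,
                             component_weights_mut = NULL,
                             enriched_component = NULL,
                             seed = 1L) {
  component_means <- as.matrix(component_means)
  if (ncol(component_means) < 2) {
    stop("component_means must have at least 2 columns")
  }
  k <- nrow(component_means)
  if (is.null(component_weights_wt)) component_weights_wt <- rep(1 / k, k)
  if (is.null(component_weights_mut)) component_weights_mut <- component_weights_wt
  for (w in list(component_weights_wt, component_weights_mut)) {
    if (length(w) != k || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("weight vectors must be length ", k, ", non-negative, summing to 1")
    }
  }
  if (component_cov_scale <= 0) stop("component_cov_scale must be positive")
  structure(list(n_components = k, component_means = component_means,
                 component_cov_scale = component_cov_scale,
                 component_weights_wt = component_weights_wt,
                 component_weights_mut = component_weights_mut,
                 enriched_component = enriched_component,
                 seed = as.integer(seed)),
            class = "embedding_design")
}

#' Simulate a multi-embryo cohort in embedding space
#'
#' @param design An [embedding_design()].
#' @param n_embryos_per_genotype Replicate embryos per genotype.
#' @param cells_per_embryo Cells sampled per embryo (must be at least 10 times
#'   the number of mixture components).
#'
#' @return A tibble with columns `cell_id`, `embryo_id`, `genotype`,
#'   `component`, and coordinates `dim1..dimd`.
#' @export
simulate_embedding_cohort <- function(design, n_embryos_per_genotype = 4,
                                      cells_per_embryo = 500) {
  stopifnot(inherits(design, "embedding_design"))
  if (cells_per_embryo < 10 * design$n_components) {
    stop("cells_per_embryo must be at least 10 x n_components (",
         10 * design$n_components, ")")
  }
  set.seed(design$seed)
  d <- ncol(design$component_means)
  out <- list()
  for (g in c("wt", "mut")) {
    w <- if (g == "wt") design$component_weights_wt else design$component_weights_mut
    for (e in seq_len(n_embryos_per_genotype)) {
      comp <- sample.int(design$n_components, cells_per_embryo,
                         replace = TRUE, prob = w)
      coords <- design$component_means[comp, , drop = FALSE] +
        matrix(stats::rnorm(cells_per_embryo * d,
                            sd = design$component_cov_scale),
               cells_per_embryo, d)
      colnames(coords) <- paste0("dim", seq_len(d))
      out[[paste0(g, e)]] <- dplyr::bind_cols(
        tibble::tibble(embryo_id = paste0(g, ".", e), genotype = g,
                       component = comp),
        tibble::as_tibble(coords))
    }
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::mutate(res,
                       cell_id = sprintf("cell%05d", seq_len(nrow(res))),
                       .before = 1)
  res
}

#' Add synthetic expression counts linked to a per-cell covariate
#'
#' Overlays a sparse gamma-Poisson (negative binomial) count matrix on a cell
#' table: every gene has a lognormal baseline mean scaled by a per-cell
#' library-size factor spanning at least two-fold, and genes listed in
#' `linked_genes` have their log-mean shifted by `slope * covariate`.
#'
#' @param data Per-cell tibble (e.g. from [simulate_embedding_cohort()])
#'   containing the covariate column.
#' @param n_genes Total genes to simulate.
#' @param linked_genes Named numeric vector of slopes, names becoming gene
#'   ids; must not exceed `n_genes` entries.
#' @param covariate Name of the per-cell covariate column.
#' @param dispersion Gamma-Poisson dispersion (variance = mu + dispersion *
#'   mu^2).
#' @param base_mean_log,base_mean_sdlog Lognormal parameters of baseline gene
#'   means.
#' @param seed Integer seed.
#'
#' @return A `cell_dataset` whose `cells` slot carries `data` plus a
#'   `size_factor` column; linked genes keep their given names, background
#'   genes are `gene1..gene<n>`.
#' @export
simulate_expression <- function(data, n_genes = 500,
                                linked_genes = numeric(0),
                                covariate = "lochness",
                                dispersion = 0.5,
                                base_mean_log = log(0.3),
                                base_mean_sdlog = 1,
                                seed = 1L) {
  if (!covariate %in% names(data)) {
    stop("data must contain the per-cell covariate column `", covariate, "`")
  }
  if (n_genes < length(linked_genes)) {
    stop("n_genes must be at least the number of linked genes")
  }
  set.seed(seed)
  n_cells <- nrow(data)
  x <- data[[covariate]]
  n_bg <- n_genes - length(linked_genes)
  gene_ids <- c(names(linked_genes), paste0("gene", seq_len(n_bg)))
  if (is.null(names(linked_genes)) && length(linked_genes)) {
    gene_ids <- c(paste0("linked", seq_along(linked_genes)),
                  paste0("gene", seq_len(n_bg)))
  }
  slopes <- c(unname(linked_genes), rep(0, n_bg))
  base_mu <- exp(stats::rnorm(n_genes, base_mean_log, base_mean_sdlog))
  # library sizes spanning >= 2-fold
  size_factor <- 2^stats::runif(n_cells, -0.75, 0.75)
  counts <- matrix(0L, n_genes, n_cells)
  for (g in seq_len(n_genes)) {
    mu <- size_factor * base_mu[g] * exp(slopes[g] * x)
    counts[g, ] <- stats::rnbinom(n_cells, mu = mu, size = 1 / dispersion)
  }
  rownames(counts) <- gene_ids
  cells <- dplyr::mutate(tibble::as_tibble(data), size_factor = size_factor)
  if (!"cell_id" %in% names(cells)) {
    cells$cell_id <- sprintf("cell%05d", seq_len(n_cells))
  }
  cell_dataset(counts, cells,
               genes = tibble::tibble(gene_id = gene_ids,
                                      gene_name = gene_ids,
                                      slope = slopes))
}

#' Design for a staged reference timecourse
#'
#' A synthetic stand-in for a staged wild-type reference atlas: cells at each
#' embryonic day sit around a centroid displaced along the first embedding
#' axis by `drift_per_day` per day, with isotropic Gaussian noise.
#'
#' @param timepoints Strictly increasing embryonic days (default E9.5-E13.5).
#' @param cells_per_timepoint Cells per stage.
#' @param drift_per_day Centroid displacement per day along `dim1`.
#' @param noise_sd Isotropic standard deviation around the centroid.
#' @param n_dims Embedding dimensionality.
#' @param seed Integer seed.
#'
#' @return A list of class `timecourse_design`.
#' @export
timecourse_design <- function(timepoints = seq(9.5, 13.5, by = 1),
                              cells_per_timepoint = 500,
                              drift_per_day = 1, noise_sd = 0.5,
                              n_dims = 2, seed = 1L) {
  if (length(timepoints) < 2) stop("at least 2 timepoints are required")
  if (any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(timepoints = timepoints,
                 cells_per_timepoint = cells_per_timepoint,
                 drift_per_day = drift_per_day, noise_sd = noise_sd,
                 n_dims = n_dims, seed = as.integer(seed)),
            class = "timecourse_design")
}

#' Simulate a staged reference atlas
#'
#' @param design A [timecourse_design()].
#' @return A tibble of class `reference_atlas` with columns `cell_id`, `time`
#'   and `dim1..dimd`.
#' @export
simulate_reference_timecourse <- function(design) {
  stopifnot(inherits(design, "timecourse_design"))
  set.seed(design$seed)
  t0 <- design$timepoints[1]
  n <- design$cells_per_timepoint
  d <- design$n_dims
  rows <- lapply(design$timepoints, function(t) {
    coords <- matrix(stats::rnorm(n * d, sd = design$noise_sd), n, d)
    coords[, 1] <- coords[, 1] + design$drift_per_day * (t - t0)
    colnames(coords) <- paste0("dim", seq_len(d))
    dplyr::bind_cols(tibble::tibble(time = t), tibble::as_tibble(coords))
  })
  atlas <- dplyr::bind_rows(rows)
  atlas <- dplyr::mutate(atlas,
                         cell_id = sprintf("ref%05d", seq_len(nrow(atlas))),
                         .before = 1)
  class(atlas) <- c("reference_atlas", class(atlas))
  atlas
}

#' Centroid of a reference stage
#'
#' Convenience accessor: the expected embedding location of a given
#' developmental time in a simulated timecourse design.
#'
#' @param design A [timecourse_design()].
#' @param time A time value (need not be one of the design's timepoints).
#' @return Numeric vector of length `n_dims`.
#' @export
stage_centroid <- function(design, time) {
  stopifnot(inherits(design, "timecourse_design"))
  out <- numeric(design$n_dims)
  out[1] <- design$drift_per_day * (time - design$timepoints[1])
  out
}
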