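#' Embryo-by-cell-type composition table
#'
#' @param counts Non-negative matrix, embryos in rows, cell types in columns,
#'   with dimnames.
#' @param embryo_meta Tibble with `embryo_id` (matching rownames), `genotype`
#'   and `background`.
#' @param size_factors Optional per-embryo size factors; computed from row
#'   totals via [compute_size_factors()] when `NULL`.
#'
#' @return An object of class `composition_table`.
#' @export
composition_table <- function(counts, embryo_meta, size_factors = NULL) {
  counts <- as.matrix(counts)
  embryo_meta <- tibble::as_tibble(embryo_meta)
  stopifnot(nrow(counts) == nrow(embryo_meta))
  if (is.null(rownames(counts))) rownames(counts) <- embryo_meta$embryo_id
  if (!identical(rownames(counts), as.character(embryo_meta$embryo_id))) {
    stop("rownames(counts) must match embryo_meta$embryo_id")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!"background" %in% names(embryo_meta)) embryo_meta$background <- "B6"
  n_total <- rowSums(counts)
  if (is.null(size_factors)) size_factors <- compute_size_factors(n_total)
  structure(list(counts = counts, embryo_meta = embryo_meta,
                 size_factors = size_factors, n_total = n_total),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("<composition_table> ", nrow(x$counts), " embryos x ", ncol(x$counts),
      " cell types\n", sep = "")
  cat("  genotypes: ",
      paste(names(table(x$embryo_meta$genotype)),
            table(x$embryo_meta$genotype), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn composition_table Long-format view: one row per embryo and
#'   cell type, with metadata, counts and proportions.
#' @param x A `composition_table`.
#' @param ... Unused.
#' @method tidy composition_table
#' @export
tidy.composition_table <- function(x, ...) {
  long <- tibble::as_tibble(as.table(x$counts), .name_repair = "minimal")
  names(long) <- c("embryo_id", "cell_type", "count")
  long$count <- as.numeric(long$count)
  long <- dplyr::left_join(long, x$embryo_meta, by = "embryo_id")
  totals <- tibble::tibble(embryo_id = rownames(x$counts),
                           n_total = unname(x$n_total),
                           size_factor = unname(x$size_factors))
  long <- dplyr::left_join(long, totals, by = "embryo_id")
  dplyr::mutate(long, proportion = .data$count / .data$n_total)
}

#' Cross-tabulate cells into a composition table
#'
#' @param cells Per-cell data frame (or the `cells` slot of a
#'   `cell_dataset`) with `embryo_id`, an annotation column, and optionally
#'   `genotype` / `background`.
#' @param annotation Name of the annotation column (e.g. `"sub_trajectory"`).
#' @return A `composition_table`. Unannotated cells (`NA`) are excluded with
#'   a message.
#' @export
build_count_matrix <- function(cells, annotation = "sub_trajectory") {
  if (inherits(cells, "cell_dataset")) cells <- cells$cells
  if (!annotation %in% names(cells)) {
    stop("annotation column `", annotation, "` not found")
  }
  ann <- cells[[annotation]]
  if (all(is.na(ann))) stop("annotation column `", annotation, "` is empty")
  drop <- is.na(ann)
  if (any(drop)) {
    message(sum(drop), " unannotated cells excluded from the count matrix")
    cells <- cells[!drop, , drop = FALSE]
    ann <- ann[!drop]
  }
  counts <- table(factor(cells$embryo_id), factor(ann))
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  meta_cols <- intersect(c("embryo_id", "genotype", "background"),
                         names(cells))
  meta <- dplyr::distinct(cells[, meta_cols, drop = FALSE])
  if (anyDuplicated(meta$embryo_id)) {
    stop("embryo metadata (genotype/background) is not constant per embryo")
  }
  meta <- meta[match(rownames(counts), meta$embryo_id), , drop = FALSE]
  if (!"genotype" %in% names(meta)) meta$genotype <- NA_character_
  composition_table(counts, meta)
}

# Beta-binomial log-likelihood for a logit-linear mean with shared
# overdispersion rho; theta = (1 - rho) / rho so alpha = mu * theta,
# beta = (1 - mu) * theta. Falls back to the binomial limit for tiny rho.
bb_loglik <- function(b0, b1, rho, k, n, g) {
  mu <- stats::plogis(b0 + b1 * g)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  if (rho < 1e-8) {
    return(sum(stats::dbinom(k, n, mu, log = TRUE)))
  }
  theta <- (1 - rho) / rho
  a <- mu * theta
  b <- (1 - mu) * theta
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Beta-binomial regression of one cell type on genotype
#'
#' Maximum-likelihood fit of a beta-binomial model for replicate embryo
#' counts `k` out of totals `n`, with a logit-linear mean
#' `logit(mu) = b0 + b1 * genotype` and a single overdispersion parameter
#' `rho` shared across embryos. The optimiser restarts from the binomial
#' logistic solution combined with `rho` in {0.001, 0.01, 0.1}; the genotype
#' effect is tested with a Wald test from the observed information, with a
#' likelihood-ratio fallback when the Hessian is near-singular.
#'
#' @param k Successes (cells of the focal type) per embryo.
#' @param n Totals per embryo; `n >= k >= 0`.
#' @param genotype Binary indicator (0/1, logical, or two-level factor with
#'   the reference level first).
#'
#' @return An object of class `beta_binom_fit` with elements
#'   `coef_intercept`, `coef_genotype`, `rho`, `loglik`, `se_genotype`,
#'   `p_value`, `converged`, `test` ("wald" or "lrt").
#' @export
fit_beta_binomial <- function(k, n, genotype) {
  if (any(k > n)) stop("k must not exceed n")
  if (any(k < 0) || any(n <= 0)) stop("counts must satisfy n >= k >= 0")
  g <- if (is.factor(genotype)) as.integer(genotype) - 1L else as.integer(genotype)
  if (!all(g %in% c(0L, 1L))) stop("genotype must be binary")
  if (sum(g == 0) < 2 || sum(g == 1) < 2) {
    stop("at least 2 embryos per genotype group are required")
  }
  k <- as.numeric(k); n <- as.numeric(n)

  bin <- suppressWarnings(
    stats::glm(cbind(k, n - k) ~ g, family = stats::binomial()))
  start_b <- unname(coef(bin))
  start_b[!is.finite(start_b)] <- 0
  start_b <- pmin(pmax(start_b, -10), 10)

  negll <- function(par) {
    -bb_loglik(par[1], par[2], stats::plogis(par[3]), k, n, g)
  }
  lower <- c(-15, -15, stats::qlogis(1e-6))
  upper <- c(15, 15, stats::qlogis(0.95))
  ctrl <- list(iter.max = 500, eval.max = 1000, rel.tol = 1e-12,
               x.tol = 1e-12)
  best <- NULL
  for (rho0 in c(0.001, 0.01, 0.1)) {
    fit <- tryCatch(
      stats::nlminb(c(start_b, stats::qlogis(rho0)), negll,
                    lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  if (!is.null(best)) {
    # polish: restart once from the winning point
    polish <- tryCatch(
      stats::nlminb(best$par, negll, lower = lower, upper = upper,
                    control = ctrl),
      error = function(e) NULL)
    if (!is.null(polish) && polish$objective <= best$objective) {
      best <- polish
    }
  }
  if (is.null(best)) {
    return(structure(list(coef_intercept = NA_real_, coef_genotype = NA_real_,
                          rho = NA_real_, loglik = NA_real_,
                          se_genotype = NA_real_, p_value = NA_real_,
                          converged = FALSE, test = NA_character_,
                          n_embryos = length(k)),
                     class = "beta_binom_fit"))
  }
  # the optimum can sit on the rho -> 0 boundary, where the model collapses
  # to binomial logistic regression; take that limit when it dominates
  ll_bin <- as.numeric(stats::logLik(bin))
  if (is.finite(ll_bin) && ll_bin >= -best$objective) {
    sm <- summary(bin)$coefficients
    return(structure(list(coef_intercept = unname(coef(bin)[1]),
                          coef_genotype = unname(coef(bin)[2]),
                          rho = 0, loglik = ll_bin,
                          se_genotype = sm["g", 2],
                          p_value = sm["g", 4],
                          converged = TRUE, test = "wald",
                          n_embryos = length(k)),
                     class = "beta_binom_fit"))
  }
  par <- best$par
  ll <- -best$objective
  se <- NA_real_; p <- NA_real_; test <- "wald"
  H <- tryCatch(stats::optimHess(par, negll), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && is.finite(V[2, 2]) && V[2, 2] > 0) {
      se <- sqrt(V[2, 2])
      p <- 2 * stats::pnorm(-abs(par[2] / se))
    }
  }
  if (!is.finite(p)) {
    # likelihood-ratio fallback: profile out the genotype effect
    negll0 <- function(q) -bb_loglik(q[1], 0, stats::plogis(q[2]), k, n, g)
    fit0 <- stats::nlminb(c(par[1], par[3]), negll0,
                          lower = lower[c(1, 3)], upper = upper[c(1, 3)])
    p <- stats::pchisq(2 * (ll + fit0$objective), df = 1, lower.tail = FALSE)
    test <- "lrt"
  }
  structure(list(coef_intercept = par[1], coef_genotype = par[2],
                 rho = stats::plogis(par[3]), loglik = ll,
                 se_genotype = se, p_value = p,
                 converged = best$convergence == 0, test = test,
                 n_embryos = length(k)),
            class = "beta_binom_fit")
}

#' @export
print.beta_binom_fit <- function(x, ...) {
  cat("<beta_binom_fit> genotype effect ", signif(x$coef_genotype, 4),
      " (logit scale), rho ", signif(x$rho, 3), ", p ",
      format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_beta_binomial One row per model term.
#' @param x A `beta_binom_fit`.
#' @param ... Unused.
#' @method tidy beta_binom_fit
#' @export
tidy.beta_binom_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "genotype"),
                 estimate = c(x$coef_intercept, x$coef_genotype),
                 std.error = c(NA_real_, x$se_genotype),
                 p.value = c(NA_real_, x$p_value))
}

#' @describeIn fit_beta_binomial One-row model summary.
#' @method glance beta_binom_fit
#' @export
glance.beta_binom_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho, logLik = x$loglik, nobs = x$n_embryos,
                 converged = x$converged, test = x$test)
}

#' Log2 ratio of cell-type proportions
#'
#' `log2(((k_mut + pc)/(n_mut + pc)) / ((k_ref + pc)/(n_ref + pc)))` with a
#' pseudocount guarding zeros. Vectorised.
#'
#' @param k_mut,n_mut Merged mutant cell count for the type and total.
#' @param k_ref,n_ref Merged pooled-reference count and total.
#' @param pseudocount Added to every numerator and denominator.
#' @return Numeric log2 ratios.
#' @export
log2_proportion_ratio <- function(k_mut, n_mut, k_ref, n_ref,
                                  pseudocount = 0.5) {
  if (any(n_mut <= 0) || any(n_ref <= 0)) stop("totals must be positive")
  pc <- pseudocount
  log2(((k_mut + pc) / (n_mut + pc)) / ((k_ref + pc) / (n_ref + pc)))
}

#' Clip log2 ratios for display
#' @param x Log2 ratios.
#' @param clip Symmetric bound; values beyond `±clip` are set to `±clip`.
#' @return Clipped values.
#' @export
clip_log2_ratio <- function(x, clip = 2) pmin(pmax(x, -clip), clip)

#' Test every cell type for composition changes
#'
#' For each mutant genotype within its background strain, tests each cell
#' type's proportion against the pooled reference (all other embryos of the
#' same background) by beta-binomial regression. Counts are first normalized
#' by embryo size factors and rounded; types whose normalized mean count per
#' embryo falls below `config$min_mean_cells` are reported untested.
#' Significance is at the uncorrected `config$alpha` (nominal).
#'
#' @param table A `composition_table`.
#' @param config A [pipeline_config()].
#' @param wt_label Genotype label regarded as wild type (never tested as the
#'   focal genotype, but part of every pooled reference).
#' @param normalize If `FALSE`, raw counts are used instead of size-factor
#'   normalized counts.
#'
#' @return A tibble of class `composition_result`: one row per (background,
#'   genotype, cell type) with `log2_ratio`, `log2_ratio_display`, `p_value`,
#'   `n_mut_cells`, `n_ref_cells`, `tested`, `significant`.
#' @export
test_composition_all <- function(table, config = pipeline_config(),
                                 wt_label = "wt", normalize = TRUE) {
  stopifnot(inherits(table, "composition_table"))
  counts <- table$counts
  if (normalize) {
    counts <- sweep(counts, 1L, table$size_factors, "/")
  }
  # the mean-count filter sees the normalized values; the regression needs
  # integers, so rounding happens after the filter
  tested_type <- colMeans(counts) >= config$min_mean_cells
  counts <- round(counts)
  n_total <- rowSums(counts)
  meta <- table$embryo_meta
  rows <- list()
  for (bg in unique(meta$background)) {
    in_bg <- meta$background == bg
    genos <- unique(meta$genotype[in_bg])
    focal <- setdiff(genos, wt_label)
    if (length(genos) < 2) {
      warning("background ", bg, " has a single genotype; skipped")
      next
    }
    for (g in focal) {
      is_mut <- in_bg & meta$genotype == g
      is_ref <- in_bg & meta$genotype != g
      for (ct in colnames(counts)) {
        k <- counts[in_bg, ct]
        n <- n_total[in_bg]
        ind <- as.integer(meta$genotype[in_bg] == g)
        k_mut <- sum(counts[is_mut, ct]); N_mut <- sum(n_total[is_mut])
        k_ref <- sum(counts[is_ref, ct]); N_ref <- sum(n_total[is_ref])
        lr <- log2_proportion_ratio(k_mut, N_mut, k_ref, N_ref)
        p <- NA_real_
        if (tested_type[[ct]]) {
          fit <- tryCatch(fit_beta_binomial(k, n, ind),
                          error = function(e) NULL)
          if (!is.null(fit)) p <- fit$p_value
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          background = bg, genotype = g, cell_type = ct,
          log2_ratio = lr,
          log2_ratio_display = clip_log2_ratio(lr, config$log2_display_clip),
          p_value = p, n_mut_cells = k_mut, n_ref_cells = k_ref,
          tested = tested_type[[ct]] && !is.na(p),
          significant = tested_type[[ct]] && !is.na(p) && p < config$alpha)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("composition_result", class(out))
  attr(out, "alpha") <- config$alpha
  out
}

#' Power simulation for composition testing
#'
#' Simulates paired wild-type/mutant cohorts from a Dirichlet model around
#' `base_proportions` and measures, for every combination of effect size,
#' replicate number and focal cell type, the fraction of simulations in which
#' the beta-binomial test detects the shift at level `alpha`. The effect is
#' applied to one focal type at a time and that type is the one tested.
#'
#' @param base_proportions Baseline proportion vector (named; sums to 1).
#' @param effect_sizes Effect sizes to scan (0.1 = 10% count reduction).
#' @param n_replicates Replicate embryos per genotype to scan.
#' @param cell_types Names (or indices) of focal types; defaults to all.
#' @param config A [pipeline_config()]; supplies `alpha`, `n_power_sims` and
#'   the seed.
#' @param cells_per_embryo_mean,cells_per_embryo_sd Per-embryo cell recovery.
#' @param dirichlet_concentration Replicate-to-replicate tightness.
#'
#' @return A tibble of class `power_grid`: one row per (cell type, abundance,
#'   effect size, replicates) with the estimated `power`.
#' @export
simulate_power <- function(base_proportions,
                           effect_sizes = c(0.01, 0.1, 0.25),
                           n_replicates = c(4, 8, 16),
                           cell_types = NULL,
                           config = pipeline_config(),
                           cells_per_embryo_mean = 15000,
                           cells_per_embryo_sd = 3000,
                           dirichlet_concentration = 8000) {
  if (is.null(names(base_proportions))) {
    names(base_proportions) <- paste0("type", seq_along(base_proportions))
  }
  if (is.null(cell_types)) cell_types <- names(base_proportions)
  if (is.numeric(cell_types)) cell_types <- names(base_proportions)[cell_types]
  base_seed <- stage_seed(config, "power")
  grid <- expand.grid(cell_type = cell_types, effect_size = effect_sizes,
                      n_replicates = n_replicates,
                      stringsAsFactors = FALSE)
  grid$abundance <- base_proportions[grid$cell_type]
  power <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ct <- grid$cell_type[i]
    eff <- stats::setNames(grid$effect_size[i], ct)
    hits <- logical(config$n_power_sims)
    for (s in seq_len(config$n_power_sims)) {
      des <- cohort_design(
        base_proportions = base_proportions,
        dirichlet_concentration = dirichlet_concentration,
        n_wt_embryos = grid$n_replicates[i],
        n_mut_embryos = grid$n_replicates[i],
        cells_per_embryo_mean = cells_per_embryo_mean,
        cells_per_embryo_sd = cells_per_embryo_sd,
        effect_sizes = eff,
        seed = (base_seed + 7919L * i + s) %% .Machine$integer.max)
      tab <- simulate_composition_cohort(des)
      counts <- round(sweep(tab$counts, 1L, tab$size_factors, "/"))
      n <- rowSums(counts)
      ind <- as.integer(tab$embryo_meta$genotype == "mut")
      fit <- tryCatch(fit_beta_binomial(counts[, ct], n, ind),
                      error = function(e) NULL)
      hits[s] <- !is.null(fit) && is.finite(fit$p_value) &&
        fit$p_value < config$alpha
    }
    power[i] <- mean(hits)
  }
  out <- tibble::as_tibble(grid)
  out$power <- power
  out$alpha <- config$alpha
  out$n_sims <- config$n_power_sims
  class(out) <- c("power_grid", class(out))
  out
}
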