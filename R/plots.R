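#' @importFrom ggplot2 ggplot aes geom_density geom_tile geom_line geom_point
#'   geom_hline scale_fill_gradient2 facet_wrap labs theme_minimal
NULL

#' Plot observed lochNESS against its permutation null
#'
#' Density of the observed per-cell scores overlaid on the pooled permuted
#' scores; an exchangeable cohort shows two coincident bell shapes centred at
#' zero.
#'
#' @param object A `lochness_result` (ideally after [lochness_null()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lochness_result
#' @export
autoplot.lochness_result <- function(object, ...) {
  df <- tibble::tibble(score = object$scores, which = "observed")
  if (!is.null(object$perm_scores)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      score = as.vector(object$perm_scores), which = "permuted null"))
  }
  ggplot(df, aes(x = .data$score, colour = .data$which)) +
    geom_density() +
    labs(x = "lochNESS", y = "density", colour = NULL) +
    theme_minimal()
}

#' Heatmap of embryo similarity scores
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object; white corresponds to the exchangeable expectation
#'   of 1.
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$embryo_j, y = .data$embryo_i,
                   fill = .data$similarity)) +
    geom_tile() +
    scale_fill_gradient2(midpoint = 1) +
    labs(x = "target embryo", y = "scored embryo", fill = "similarity") +
    theme_minimal()
}

#' Power curves over the simulation grid
#'
#' One line per focal cell type (labelled by abundance), power against the
#' number of replicates, faceted by effect size, with the nominal level shown
#' as a dashed line.
#'
#' @param object A `power_grid` from [simulate_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_grid
#' @export
autoplot.power_grid <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      abundance_lab = paste0(.data$cell_type, " (",
                                             signif(100 * .data$abundance, 2),
                                             "%)"))
  ggplot(df, aes(x = .data$n_replicates, y = .data$power,
                 colour = .data$abundance_lab)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = unique(df$alpha), linetype = "dashed") +
    facet_wrap(~effect_size, labeller = ggplot2::label_both) +
    labs(x = "replicates per genotype", y = "power", colour = "cell type") +
    theme_minimal()
}

#' Heatmap of composition test results
#'
#' Display-clipped log2 proportion ratios per genotype and cell type; only
#' nominally significant entries are coloured.
#'
#' @param object A `composition_result` from [test_composition_all()].
#' @param significant_only Grey out non-significant entries (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composition_result
#' @export
autoplot.composition_result <- function(object, significant_only = TRUE,
                                        ...) {
  df <- tibble::as_tibble(object)
  if (significant_only) {
    df$log2_ratio_display[!df$significant] <- NA_real_
  }
  ggplot(df, aes(x = .data$cell_type, y = .data$genotype,
                 fill = .data$log2_ratio_display)) +
    geom_tile() +
    scale_fill_gradient2(low = "red", high = "blue", na.value = "grey90") +
    labs(x = "cell type", y = "genotype", fill = "log2 ratio") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
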