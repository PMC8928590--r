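#' Plot a chromosome-arm distribution profile
#'
#' Bar chart of event counts over relative arm-position bins, one panel per
#' SV type. Distal enrichment shows up as raised bins near 0 and 1.
#'
#' @param profile Tibble from [bin_arm_distribution()].
#' @return A ggplot object.
#' @export
plot_arm_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = (bin_start + bin_end) / 2, y = count)) +
    ggplot2::geom_col(width = min(profile$bin_end - profile$bin_start),
                      fill = "grey30") +
    ggplot2::facet_wrap(~svtype, scales = "free_y") +
    ggplot2::labs(x = "Relative position on chromosome arm",
                  y = "Event count") +
    ggplot2::theme_minimal()
}

#' Plot permutation null distributions against observed values
#'
#' Histograms of the simulated null metric values per repeat class with the
#' observed value as a vertical line; the enrichment p is the fraction of
#' the null to the right of that line.
#'
#' @param object A `perm_enrichment` object.
#' @param metric Which metric to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_enrichment <- function(object, metric = "length_pct", ...) {
  stopifnot(metric %in% names(object$null))
  nv <- object$null[[metric]]
  df <- as_tibble(nv) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "repeat_class",
                        values_to = "null_value")
  obs <- object$results |>
    filter(metric == !!metric) |>
    select(repeat_class, observed)
  ggplot2::ggplot(df, ggplot2::aes(x = null_value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = observed),
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~repeat_class, scales = "free") +
    ggplot2::labs(x = metric, y = "Simulations") +
    ggplot2::theme_minimal()
}

#' Plot a Venn sharing summary as a bar chart
#'
#' Event percentages per sharing category, annotated with raw counts.
#'
#' @param venn Tibble from [venn_summary()].
#' @return A ggplot object.
#' @export
plot_venn_summary <- function(venn) {
  venn <- venn |>
    mutate(venn_category = factor(venn_category,
                                  levels = venn_categories()))
  ggplot2::ggplot(venn, ggplot2::aes(x = venn_category, y = pct_events)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = n_events), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = "Sharing category", y = "% of events") +
    ggplot2::theme_minimal()
}

#' Plot repeat-enrichment fold decay from target to flanks
#'
#' Folds (observed / genome baseline) for the target set and its flank
#' sets; local co-location shows as folds decaying toward 1 with flank
#' distance.
#'
#' @param folds Tibble from [enrichment_folds()].
#' @param metric Metric to display.
#' @return A ggplot object.
#' @export
plot_fold_decay <- function(folds, metric = "length_pct") {
  df <- folds |>
    filter(metric == !!metric) |>
    mutate(set = factor(set, levels = unique(folds$set)))
  ggplot2::ggplot(df, ggplot2::aes(x = set, y = fold,
                                   group = repeat_class,
                                   colour = repeat_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = sprintf("Fold vs genome (%s)", metric),
                  colour = "Repeat class") +
    ggplot2::theme_minimal()
}
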