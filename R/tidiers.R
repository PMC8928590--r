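#' Tidy a permutation enrichment result
#'
#' One row per repeat class x metric with observed value, genome baseline,
#' fold, and empirical enrichment/depletion p-values, plus a formatted p
#' (`"< 1/n_iter"` when no null value exceeded the observation).
#'
#' @param x A `perm_enrichment` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.perm_enrichment <- function(x, ...) {
  x$results |>
    mutate(p_enrich_label = format_empirical_p(p_enrich, x$n_iter))
}

#' @rdname tidy.perm_enrichment
#' @export
glance.perm_enrichment <- function(x, ...) {
  tibble(
    n_iter = x$n_iter,
    n_classes = length(unique(x$results$repeat_class)),
    n_metrics = length(unique(x$results$metric)),
    n_significant = sum(x$results$p_enrich < 0.05),
    target_n = x$target_n,
    target_mean_len = x$target_mean_len,
    target_sd_len = x$target_sd_len,
    seed = x$seed
  )
}

#' Tidy a terminal enrichment test
#'
#' @param x A `terminal_test` object.
#' @param ... Unused.
#' @return Per-chromosome window table with densities.
#' @export
tidy.terminal_test <- function(x, ...) {
  x$per_chromosome
}

#' @rdname tidy.terminal_test
#' @export
glance.terminal_test <- function(x, ...) {
  tibble(
    p_value = x$p_value,
    p_unpaired = x$p_unpaired,
    n_chromosomes = nrow(x$per_chromosome),
    n_events = x$n_events,
    mean_density_end = mean(x$per_chromosome$density_end),
    mean_density_interior = mean(x$per_chromosome$density_interior),
    terminal_frac = x$terminal_frac,
    window = x$window
  )
}
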