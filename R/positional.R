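#' Relative chromosome-arm positions of SV calls
#'
#' Adds a `rel_pos` column: the event midpoint divided by the chromosome
#' length, in `[0, 1)`. Cattle autosomes are acrocentric, so a whole
#' chromosome is treated as a single arm. BND records use their single
#' breakend position as midpoint.
#'
#' @param calls Call tibble (`chrom`, `start`, `end`, `svtype`).
#' @param genome Genome tibble; a call on a chromosome absent from it is an
#'   error.
#' @return `calls` with `rel_pos` added.
#' @export
relative_positions <- function(calls, genome) {
  validate_genome(genome)
  unknown <- setdiff(unique(calls$chrom), genome$chrom)
  if (length(unknown) > 0) {
    abort(paste0("Calls on chromosomes absent from the genome: ",
                 paste(unknown, collapse = ", ")))
  }
  len <- setNames(genome$length, genome$chrom)
  mid <- ifelse(calls$svtype == "BND", calls$start,
                floor((calls$start + calls$end) / 2))
  mutate(calls, rel_pos = unname(mid / len[calls$chrom]))
}

#' Bin relative positions into an arm profile
#'
#' Half-open bins `[k * w, (k + 1) * w)` over `[0, 1]`; counts are conserved
#' (a relative position of exactly 1 cannot occur for a midpoint).
#'
#' @param calls Call tibble with `rel_pos` (see [relative_positions()]);
#'   a bare numeric vector of fractions is also accepted.
#' @param bin_width Bin width as a fraction of the arm (default 0.05, i.e.
#'   20 bins).
#' @return Tibble: `bin_start`, `bin_end`, `svtype`, `count` (all bins
#'   present for every svtype, zero-filled).
#' @export
bin_arm_distribution <- function(calls, bin_width = 0.05) {
  if (is.numeric(calls)) {
    calls <- tibble(rel_pos = calls, svtype = "all")
  }
  n_bins <- ceiling(1 / bin_width)
  edges <- seq(0, by = bin_width, length.out = n_bins + 1)
  types <- unique(calls$svtype)
  if (length(types) == 0) types <- "all"
  grid <- tidyr::expand_grid(svtype = types, bin = seq_len(n_bins))
  hits <- calls |>
    mutate(bin = pmin(floor(rel_pos / bin_width) + 1, n_bins)) |>
    count(svtype, bin)
  grid |>
    left_join(hits, by = c("svtype", "bin")) |>
    mutate(count = coalesce(n, 0L),
           bin_start = edges[bin], bin_end = edges[bin + 1]) |>
    select(bin_start, bin_end, svtype, count)
}

#' Terminal (subtelomeric) enrichment test
#'
#' Tests whether events concentrate near chromosome ends. Per chromosome,
#' the terminal `terminal_frac` at each end is excluded; the two *end
#' windows* are the next `window` bp inward on each side; the *interior* is
#' the remainder. Event density (events/Mb) in the pooled end windows is
#' compared with interior density across chromosomes using a paired
#' two-sided Wilcoxon signed-rank test (the primary statistic); a pooled
#' unpaired rank-sum test over per-window densities is reported as a
#' secondary statistic. Chromosomes shorter than `2 * (terminal + window)`
#' are skipped with a warning. If every paired difference is zero the
#' paired p-value is 1 by convention.
#'
#' @param calls Call tibble; midpoints are used (BND: breakend position).
#' @param genome Genome tibble.
#' @param terminal_frac Excluded terminal fraction per end.
#' @param window End-window width in bp.
#' @param use_density Compare events/Mb (default) rather than raw counts.
#' @return Object of class `terminal_test`: `$per_chromosome` tibble,
#'   `$p_value` (paired), `$p_unpaired`, and the parameters. Supports
#'   [tidy()] and [glance()].
#' @export
terminal_enrichment_test <- function(calls, genome, terminal_frac = 0.05,
                                     window = 5e6, use_density = TRUE) {
  validate_genome(genome)
  len <- setNames(genome$length, genome$chrom)
  mid <- ifelse(calls$svtype == "BND", calls$start,
                floor((calls$start + calls$end) / 2))
  chrom <- calls$chrom

  usable <- genome$length >= 2 * (terminal_frac * genome$length + window)
  if (any(!usable)) {
    warn(sprintf(
      "%d chromosome(s) shorter than 2 * (terminal + window) skipped: %s",
      sum(!usable), paste(genome$chrom[!usable], collapse = ", ")))
  }
  g <- genome[usable, , drop = FALSE]
  if (nrow(g) < 2) {
    abort("Need at least 2 usable chromosomes for the terminal test.")
  }

  per <- map(seq_len(nrow(g)), function(i) {
    cn <- g$chrom[i]; L <- g$length[i]
    t0 <- terminal_frac * L
    m <- mid[chrom == cn]
    in_left <- m >= t0 & m < t0 + window
    in_right <- m >= L - t0 - window & m < L - t0
    in_term <- m < t0 | m >= L - t0
    n_end <- sum(in_left) + sum(in_right)
    n_int <- sum(!in_left & !in_right & !in_term)
    end_mb <- 2 * window / 1e6
    int_mb <- (L - 2 * t0 - 2 * window) / 1e6
    tibble(chrom = cn, n_end = n_end, n_interior = n_int,
           end_mb = end_mb, interior_mb = int_mb,
           density_end = n_end / end_mb,
           density_interior = n_int / int_mb)
  }) |> bind_rows()

  if (use_density) {
    x <- per$density_end; y <- per$density_interior
  } else {
    x <- per$n_end; y <- per$n_interior
  }
  d <- x - y
  p_paired <- if (all(d == 0)) 1 else {
    suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value)
  }
  p_unpaired <- if (all(x == 0) && all(y == 0)) 1 else {
    suppressWarnings(wilcox.test(x, y, paired = FALSE, exact = FALSE)$p.value)
  }

  structure(list(
    per_chromosome = per,
    p_value = p_paired,
    p_unpaired = p_unpaired,
    terminal_frac = terminal_frac, window = window,
    use_density = use_density,
    n_events = sum(per$n_end) + sum(per$n_interior)
  ), class = "terminal_test")
}

#' @export
print.terminal_test <- function(x, ...) {
  cat(sprintf(
    "Terminal enrichment test: end windows of %.1f Mb after excluding the terminal %.0f%%\n",
    x$window / 1e6, 100 * x$terminal_frac))
  cat(sprintf("Paired Wilcoxon signed-rank p = %.4g (unpaired rank-sum p = %.4g)\n",
              x$p_value, x$p_unpaired))
  cat(sprintf("Chromosomes: %d; mean end density %.3f /Mb vs interior %.3f /Mb\n",
              nrow(x$per_chromosome),
              mean(x$per_chromosome$density_end),
              mean(x$per_chromosome$density_interior)))
  invisible(x)
}

#' Terminal test per SV type
#'
#' Runs [terminal_enrichment_test()] for all events pooled and separately
#' per svtype.
#' @inheritParams terminal_enrichment_test
#' @param types SV types to test individually.
#' @return Tibble: `svtype`, `p_value`, `p_unpaired`, `n_events`.
#' @export
terminal_test_by_type <- function(calls, genome, terminal_frac = 0.05,
                                  window = 5e6,
                                  types = c("DEL", "DUP")) {
  run <- function(sub, label) {
    tt <- terminal_enrichment_test(sub, genome, terminal_frac, window)
    tibble(svtype = label, p_value = tt$p_value,
           p_unpaired = tt$p_unpaired, n_events = tt$n_events)
  }
  out <- list(run(calls, "all"))
  for (tp in types) {
    sub <- calls[calls$svtype == tp, , drop = FALSE]
    if (nrow(sub) > 0) out <- c(out, list(run(sub, tp)))
  }
  bind_rows(out)
}
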