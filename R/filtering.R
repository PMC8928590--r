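#' Filtering policy for SV calls
#'
#' The two quality filters applied to raw LUMPY-style calls:
#'
#' * **Length**: DEL and DUP events are kept iff
#'   `min_len <= length <= max_len` (bounds inclusive; CNVs are defined on
#'   50 bp to 5 Mb). INV and BND records pass through untouched.
#' * **Support**: a call is kept iff one read signal clears three quarters of
#'   the sample's fold coverage while the other signal clears its secondary
#'   floor: `(PE > coverage_fraction * coverage AND SR > secondary_sr_min)`
#'   or `(SR > coverage_fraction * coverage AND PE > secondary_pe_min)`.
#'   Comparisons are strict and the coverage threshold is real-valued
#'   (no rounding of `0.75 * coverage`).
#'
#' @param min_len,max_len Inclusive DEL/DUP length bounds in bp.
#' @param coverage_fraction Fraction of fold coverage the primary signal must
#'   exceed; in (0, 1].
#' @param secondary_sr_min SR floor when PE is the primary signal (kept call
#'   needs `SR > secondary_sr_min`).
#' @param secondary_pe_min PE floor when SR is the primary signal.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(min_len = 50, max_len = 5e6,
                          coverage_fraction = 0.75,
                          secondary_sr_min = 1, secondary_pe_min = 3) {
  if (!(min_len < max_len)) abort("min_len must be < max_len")
  if (!(coverage_fraction > 0 && coverage_fraction <= 1)) {
    abort("coverage_fraction must be in (0, 1]")
  }
  structure(list(min_len = min_len, max_len = max_len,
                 coverage_fraction = coverage_fraction,
                 secondary_sr_min = secondary_sr_min,
                 secondary_pe_min = secondary_pe_min),
            class = "filter_policy")
}

#' Length-filter SV calls
#'
#' @param calls Call tibble.
#' @param policy A [filter_policy()].
#' @return The calls that survive the length filter.
#' @examples
#' calls <- tibble::tibble(svtype = c("DEL", "DEL", "INV"),
#'                         chrom = "chr1", start = 0,
#'                         end = c(49, 50, 10), length = c(49, 50, 10))
#' filter_by_length(calls) # the 49 bp DEL is removed, INV passes through
#' @export
filter_by_length <- function(calls, policy = filter_policy()) {
  cnv <- calls$svtype %in% c("DEL", "DUP")
  keep <- !cnv | (calls$length >= policy$min_len &
                    calls$length <= policy$max_len)
  calls[keep, , drop = FALSE]
}

#' Support-filter SV calls
#'
#' @param calls Call tibble with `pe`, `sr`, `sample_id`.
#' @param coverage Per-sample fold coverage: a named numeric vector or a data
#'   frame with columns `sample_id`, `coverage`.
#' @param policy A [filter_policy()].
#' @return The calls that survive the support filter (applied to all SV
#'   types).
#' @export
filter_by_support <- function(calls, coverage, policy = filter_policy()) {
  if (is.data.frame(coverage)) {
    coverage <- setNames(coverage$coverage, coverage$sample_id)
  }
  missing <- setdiff(unique(calls$sample_id), names(coverage))
  if (length(missing) > 0) {
    abort(paste0("No coverage given for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  thr <- policy$coverage_fraction * coverage[calls$sample_id]
  keep <- (calls$pe > thr & calls$sr > policy$secondary_sr_min) |
    (calls$sr > thr & calls$pe > policy$secondary_pe_min)
  calls[keep, , drop = FALSE]
}

#' Read a per-sample coverage table
#'
#' Tab-separated `sample<TAB>fold`.
#' @param path File path.
#' @return Tibble with `sample_id`, `coverage`.
#' @export
read_coverage_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("sample_id", "coverage"),
                  col_types = "cd", progress = FALSE)
}

#' Tally SV calls by group
#'
#' Per-group (and overall) statistics in the shape of a per-group SV summary
#' table: counts of BND/DEL/DUP/INV records, summed event lengths in kb for
#' DEL/DUP/INV, and the fraction of the genome covered by the *merged*
#' footprint of each type's calls (union, not sum of lengths).
#'
#' @param calls Call tibble with `group`.
#' @param genome Genome tibble used as the coverage denominator (autosomes,
#'   by convention).
#' @return Tidy tibble: one row per group x svtype (plus `svtype = "Total"`
#'   and `group = "Total"` margins) with `n`, `length_kb`, `genome_covered`.
#' @export
tally_by_group <- function(calls, genome) {
  validate_genome(genome)
  types <- c("BND", "DEL", "DUP", "INV")
  groups <- unique(calls$group)
  denom <- genome_size(genome)

  tally_one <- function(sub, group_label) {
    rows <- map(types, function(tp) {
      x <- sub[sub$svtype == tp, , drop = FALSE]
      cov_bp <- if (nrow(x) == 0 || tp == "BND") 0 else {
        m <- merge_regions(x[, c("chrom", "start", "end")])
        sum(m$end - m$start)
      }
      tibble(group = group_label, svtype = tp, n = nrow(x),
             length_kb = if (tp == "BND") NA_real_ else
               round(sum(x$length, na.rm = TRUE) / 1000, 2),
             genome_covered = cov_bp / denom)
    })
    all_cnv <- sub[sub$svtype %in% c("DEL", "DUP", "INV"), , drop = FALSE]
    cov_all <- if (nrow(all_cnv) == 0) 0 else {
      m <- merge_regions(all_cnv[, c("chrom", "start", "end")])
      sum(m$end - m$start)
    }
    bind_rows(rows, tibble(
      group = group_label, svtype = "Total", n = nrow(sub),
      length_kb = round(sum(sub$length, na.rm = TRUE) / 1000, 2),
      genome_covered = cov_all / denom))
  }

  out <- map(groups, function(g) {
    tally_one(calls[calls$group == g, , drop = FALSE], g)
  })
  bind_rows(bind_rows(out), tally_one(calls, "Total"))
}
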