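#' Merge genomic regions
#'
#' Collapses overlapping (and, for `gap = 0`, book-ended) regions on the same
#' chromosome into maximal runs. Regions separated by at most `gap` bp are
#' merged. The union measure (total covered bp) is invariant under merging
#' when `gap = 0`.
#'
#' @param regions Region table (`chrom`, `start`, `end`; 0-based half-open).
#' @param gap Maximum separation in bp for two regions to be merged. `gap = 0`
#'   merges overlapping and directly adjacent regions.
#' @return A tibble of sorted, pairwise non-overlapping regions.
#' @examples
#' r <- tibble::tibble(chrom = "chr1", start = c(10, 20), end = c(20, 30))
#' merge_regions(r) # one region [10, 30)
#' @export
merge_regions <- function(regions, gap = 0) {
  validate_regions(regions)
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  gr <- GenomicRanges::reduce(as_granges(regions), min.gapwidth = gap + 1)
  out <- as_region_tbl(gr)
  arrange(out, match(chrom, unique(regions$chrom)), start)
}

#' Unique non-redundant fragments of a pairwise SegDup table
#'
#' Pools both fragments of every pair and deduplicates on exact coordinates.
#' The result is *not* merged: overlapping but non-identical fragments stay
#' distinct, matching the "unique nonredundant fragment regions" convention of
#' SDquest-style summaries.
#'
#' @param pairs A SegDup pair table (see [generate_segdup_pairs()] /
#'   [read_segdup_pairs()]): columns `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`.
#' @return A region tibble of distinct fragments.
#' @export
nonredundant_fragments <- function(pairs) {
  frags <- bind_rows(
    tibble(chrom = pairs$chrom_a, start = pairs$start_a, end = pairs$end_a),
    tibble(chrom = pairs$chrom_b, start = pairs$start_b, end = pairs$end_b)
  )
  distinct(frags, chrom, start, end)
}

#' Fixed-width flanking regions
#'
#' For each region, constructs an upstream and a downstream flank of `size`
#' bp, clipped at chromosome bounds. Under the default policy the merged
#' footprint of *all* input regions is subtracted from the flanks, so flanks
#' never overlap any input region (an inter-region flank between two close
#' regions is truncated accordingly).
#'
#' @param regions Region table.
#' @param size Flank width in bp (> 0).
#' @param genome Genome table ([genome_def()]); needed for clipping.
#' @param subtract_inputs If `TRUE` (default), subtract the merged input
#'   footprint from the flanks.
#' @return Region tibble of flank pieces (merged, non-overlapping).
#' @export
flank_regions <- function(regions, size, genome, subtract_inputs = TRUE) {
  validate_regions(regions, genome)
  stopifnot(size > 0)
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  len <- setNames(genome$length, genome$chrom)
  left <- tibble(chrom = regions$chrom,
                 start = pmax(0, regions$start - size),
                 end = regions$start)
  right <- tibble(chrom = regions$chrom,
                  start = regions$end,
                  end = pmin(len[regions$chrom], regions$end + size))
  fl <- bind_rows(left, right)
  fl <- fl[fl$start < fl$end, ]
  if (nrow(fl) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fl <- merge_regions(fl)
  if (subtract_inputs) {
    gr <- GenomicRanges::setdiff(as_granges(fl), as_granges(merge_regions(regions)))
    fl <- as_region_tbl(gr)
  }
  arrange(fl, match(chrom, genome$chrom), start)
}

#' Per-chromosome coverage summary of a region set
#'
#' Counts regions, sums their merged footprint, and expresses the footprint
#' as a percentage of each chromosome. Chromosomes without regions get zero
#' rows, so denominators stay explicit.
#'
#' @param regions Region table.
#' @param genome Genome table.
#' @return Tibble with `chrom`, `n_regions`, `covered_bp`, `pct_covered`
#'   (2 decimals).
#' @export
per_chromosome_summary <- function(regions, genome) {
  validate_regions(regions, genome)
  merged <- merge_regions(regions)
  counts <- regions |> count(chrom, name = "n_regions")
  cov <- merged |>
    mutate(width = end - start) |>
    group_by(chrom) |>
    summarise(covered_bp = sum(width), .groups = "drop")
  genome |>
    left_join(counts, by = "chrom") |>
    left_join(cov, by = "chrom") |>
    mutate(
      n_regions = coalesce(n_regions, 0L),
      covered_bp = coalesce(covered_bp, 0),
      pct_covered = round(100 * covered_bp / length, 2)
    ) |>
    select(chrom, n_regions, covered_bp, pct_covered)
}

#' Summarise a pairwise SegDup fragment table
#'
#' Headline statistics of a pairwise segmental-duplication table: pair count,
#' percentage of pairs above each sequence-identity threshold (strict `>`),
#' percentage in reversed orientation, percentage interchromosomal, and the
#' number of unique non-redundant fragment regions. Percentages are
#' `100 * count / n_pairs`, reported to 2 decimals.
#'
#' @param pairs SegDup pair table with `identity`, `same_orientation` and
#'   fragment coordinates.
#' @param identity_thresholds Identity cut-offs (fractions).
#' @return One-row tibble.
#' @examples
#' p <- tibble::tibble(
#'   chrom_a = "chr1", start_a = 0, end_a = 100,
#'   chrom_b = c("chr1", "chr2"), start_b = c(500, 0), end_b = c(600, 100),
#'   identity = c(0.85, 0.95), same_orientation = c(TRUE, FALSE)
#' )
#' summarize_segdup_pairs(p)
#' @export
summarize_segdup_pairs <- function(pairs, identity_thresholds = c(0.8, 0.9)) {
  n <- nrow(pairs)
  pct <- function(k) round(100 * k / n, 2)
  out <- tibble(
    n_pairs = n,
    pct_reversed = pct(sum(!pairs$same_orientation)),
    pct_interchromosomal = pct(sum(pairs$chrom_a != pairs$chrom_b)),
    n_unique_fragments = nrow(nonredundant_fragments(pairs))
  )
  for (t in identity_thresholds) {
    out[[sprintf("pct_identity_gt_%d", round(100 * t))]] <-
      pct(sum(pairs$identity > t))
  }
  out
}

#' Read / write SegDup pair tables
#'
#' Tab-separated with columns chromA, startA, endA, chromB, startB, endB,
#' identity, orientation (`+` same, `-` reversed).
#'
#' @param path File path.
#' @param pairs Pair table.
#' @return A pair tibble (read) or `path` invisibly (write).
#' @export
read_segdup_pairs <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
                  "identity", "orientation"),
    col_types = "cddcdddc",
    progress = FALSE
  )
  x |>
    mutate(same_orientation = .data$orientation == "+",
           interchromosomal = chrom_a != chrom_b) |>
    select(-"orientation")
}

#' @rdname read_segdup_pairs
#' @export
write_segdup_pairs <- function(pairs, path) {
  out <- pairs |>
    mutate(orientation = ifelse(same_orientation, "+", "-")) |>
    select("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
           "identity", "orientation")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a region table as BED
#'
#' BED3 plus any extra columns present (e.g. repeat class).
#' @param regions Region table.
#' @param path File path.
#' @param extra_cols Extra columns to carry after the first three.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, extra_cols = setdiff(names(regions), c("chrom", "start", "end"))) {
  out <- regions[, c("chrom", "start", "end", extra_cols), drop = FALSE]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
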