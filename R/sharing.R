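canonical_groups <- function() {
  c("Sample1-sperms", "Sample2-sperms", "Sample1-trio")
}

# map a set of group labels to a Venn category name
venn_category_of <- function(groups) {
  g <- sort(unique(groups))
  key <- paste(g, collapse = "|")
  lut <- c(
    "Sample1-sperms" = "s1",
    "Sample2-sperms" = "s2",
    "Sample1-trio" = "trio",
    "Sample1-sperms|Sample2-sperms" = "s1_s2",
    "Sample1-sperms|Sample1-trio" = "s1_trio",
    "Sample1-trio|Sample2-sperms" = "s2_trio",
    "Sample1-sperms|Sample1-trio|Sample2-sperms" = "all"
  )
  unname(lut[key]) %||% NA_character_
}

# union-find for reciprocal-overlap clustering
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Cluster same-type CNV calls across samples
#'
#' Single-linkage clustering of DEL/DUP calls into cross-sample events. Two
#' calls are linked when they share the same SV type and chromosome and
#' overlap under the chosen rule: `"any"` (default, >= 1 bp) or
#' `"reciprocal"` (both calls covered by the overlap to at least
#' `min_reciprocal`). Deterministic for any input order (calls are sorted
#' internally).
#'
#' @param calls Filtered DEL/DUP call tibble (`sample_id`, `group`,
#'   `svtype`, `chrom`, `start`, `end`).
#' @param overlap_rule `"any"` or `"reciprocal"`.
#' @param min_reciprocal Reciprocal-overlap fraction for the
#'   `"reciprocal"` rule.
#' @return Tibble of event clusters: `event_id`, `svtype`, `chrom`,
#'   `start`/`end` (member span), `n_members`, `n_samples`,
#'   `groups_present`, `venn_category`, `is_singleton`, `length_union`,
#'   `length_sum`, and a `members` list-column of member call rows.
#' @export
cluster_events <- function(calls, overlap_rule = c("any", "reciprocal"),
                           min_reciprocal = 0.5) {
  overlap_rule <- match.arg(overlap_rule)
  calls <- calls[calls$svtype %in% c("DEL", "DUP"), , drop = FALSE]
  calls <- arrange(calls, svtype, chrom, start, end, sample_id)
  n <- nrow(calls)
  if (n == 0) {
    return(tibble(event_id = character(), svtype = character(),
                  chrom = character(), start = numeric(), end = numeric(),
                  n_members = integer(), n_samples = integer(),
                  groups_present = character(), venn_category = character(),
                  is_singleton = logical(), length_union = numeric(),
                  length_sum = numeric(), members = list()))
  }

  if (overlap_rule == "any") {
    # sorted single-linkage: a new cluster starts when a call clears the
    # running max end of the open run
    cl <- integer(n)
    key <- paste(calls$svtype, calls$chrom)
    run_max <- -Inf; cur_key <- ""; k <- 0L
    for (i in seq_len(n)) {
      if (key[i] != cur_key || calls$start[i] >= run_max) {
        k <- k + 1L
        cur_key <- key[i]
        run_max <- calls$end[i]
      } else {
        run_max <- max(run_max, calls$end[i])
      }
      cl[i] <- k
    }
  } else {
    gr <- as_granges(calls)
    hits <- GenomicRanges::findOverlaps(gr, gr)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- qi < si & calls$svtype[qi] == calls$svtype[si]
    qi <- qi[keep]; si <- si[keep]
    ov <- pmin(calls$end[qi], calls$end[si]) - pmax(calls$start[qi], calls$start[si])
    rec <- ov / pmax(calls$end[qi] - calls$start[qi],
                     calls$end[si] - calls$start[si]) >= min_reciprocal &
      ov / pmin(calls$end[qi] - calls$start[qi],
                calls$end[si] - calls$start[si]) >= min_reciprocal
    parent <- seq_len(n)
    for (j in which(rec)) {
      a <- uf_find(parent, qi[j]); b <- uf_find(parent, si[j])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    cl <- match(roots, unique(roots))
  }

  calls$.cluster <- cl
  split_idx <- split(seq_len(n), cl)
  rows <- map(seq_along(split_idx), function(k) {
    idx <- split_idx[[k]]
    sub <- calls[idx, , drop = FALSE]
    tibble(
      event_id = sprintf("cnv%05d", k),
      svtype = sub$svtype[1],
      chrom = sub$chrom[1],
      start = min(sub$start), end = max(sub$end),
      n_members = nrow(sub),
      n_samples = length(unique(sub$sample_id)),
      groups_present = paste(sort(unique(sub$group)), collapse = ","),
      venn_category = venn_category_of(sub$group),
      is_singleton = nrow(sub) == 1,
      length_union = union_bp(sub$start, sub$end),
      length_sum = sum(sub$end - sub$start),
      members = list(select(sub, -".cluster"))
    )
  })
  bind_rows(rows)
}

#' Remove singleton events
#'
#' Drops clusters with exactly one member call. A DEL/DUP observed in two or
#' more sperm cells of the same bull occurred more than once and is kept.
#'
#' @param clusters Cluster tibble from [cluster_events()].
#' @return The non-singleton clusters.
#' @export
remove_singletons <- function(clusters) {
  clusters[clusters$n_members >= 2, , drop = FALSE]
}

#' Venn sharing summary over the three groups
#'
#' Event and length percentages per Venn category. Lengths are reported
#' under both conventions: the union footprint of member calls
#' (`length_union`) and the sum of member lengths (`length_sum`); event and
#' length percentages use `100 * x / total`, rounded to 2 decimals.
#'
#' @param clusters Cluster tibble (typically after [remove_singletons()]).
#' @return Tibble: one row per category present, with `n_groups`,
#'   `n_events`, `pct_events`, `length_union_kb`, `pct_length_union`,
#'   `length_sum_kb`, `pct_length_sum`.
#' @export
venn_summary <- function(clusters) {
  total <- nrow(clusters)
  tot_union <- sum(clusters$length_union)
  tot_sum <- sum(clusters$length_sum)
  clusters |>
    group_by(venn_category) |>
    summarise(
      n_events = n(),
      length_union_kb = sum(length_union) / 1000,
      length_sum_kb = sum(length_sum) / 1000,
      .groups = "drop"
    ) |>
    mutate(
      n_groups = vapply(venn_category, function(cat) {
        if (is.na(cat)) NA_integer_
        else length(category_groups(cat))
      }, integer(1)),
      pct_events = round(100 * n_events / total, 2),
      pct_length_union = round(100 * 1000 * length_union_kb / tot_union, 2),
      pct_length_sum = round(100 * 1000 * length_sum_kb / tot_sum, 2)
    ) |>
    arrange(match(venn_category, venn_categories())) |>
    select(venn_category, n_groups, n_events, pct_events,
           length_union_kb, pct_length_union, length_sum_kb, pct_length_sum)
}

#' Read a gene annotation (GFF3/GTF) into a feature table
#'
#' Keeps transcript/exon/CDS/UTR/codon features and extracts a gene
#' identifier from the usual attribute fields.
#'
#' @param path GFF3 or GTF file.
#' @param feature_types Feature types to keep (GFF3 `type` column values).
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `feature_type`, `gene_id`.
#' @export
read_gene_annotation <- function(path,
                                 feature_types = c(
                                   "gene", "transcript", "mRNA", "exon",
                                   "CDS", "three_prime_UTR",
                                   "five_prime_UTR", "start_codon",
                                   "stop_codon")) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  keep <- as.character(gr$type) %in% feature_types
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  gene <- if ("gene_id" %in% names(md)) as.character(md$gene_id)
    else if ("Parent" %in% names(md)) as.character(md$Parent)
    else if ("ID" %in% names(md)) as.character(md$ID)
    else NA_character_
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = BiocGenerics::end(gr),
    feature_type = as.character(gr$type),
    gene_id = gene
  )
}

#' Intersect regions with gene features
#'
#' Overlap (>= 1 bp) of each region with annotated gene features: which
#' genes a region hits and through which feature kinds. A region inside an
#' intron hits the transcript but none of its exons.
#'
#' @param regions Region table; a `region_id` column is added if missing.
#' @param features Feature tibble from [read_gene_annotation()] (or the same
#'   columns built directly).
#' @return Tibble: `region_id`, `gene_id`, `feature_type` (one row per
#'   region x feature overlap).
#' @export
annotate_features <- function(regions, features) {
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("region%05d", seq_len(nrow(regions)))
  }
  if (nrow(regions) == 0 || nrow(features) == 0) {
    return(tibble(region_id = character(), gene_id = character(),
                  feature_type = character()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(regions),
                                      as_granges(features))
  tibble(
    region_id = regions$region_id[S4Vectors::queryHits(hits)],
    gene_id = features$gene_id[S4Vectors::subjectHits(hits)],
    feature_type = features$feature_type[S4Vectors::subjectHits(hits)]
  ) |> distinct()
}

#' Fisher / Benjamini-Hochberg term enrichment
#'
#' Generic annotation-term enrichment of a target gene set against a
#' universe: per term, a 2x2 table (in/out of target x with/without term), a
#' two-sided Fisher exact test, and BH adjustment across all tested terms.
#' The term map is any user-supplied term-to-gene table (GO, KEGG, QTL
#' traits, ...), so no live database is needed.
#'
#' @param target Character vector of target gene IDs; must be a subset of
#'   `universe`.
#' @param universe Character vector of all gene IDs considered.
#' @param term_map Data frame with columns `term` and `gene_id`.
#' @param alpha Significance threshold on the adjusted p.
#' @return Tibble: `term`, `n_target`, `n_universe`, `odds_ratio`,
#'   `p_value`, `p_adj`, `significant`, sorted by `p_value`.
#' @export
fisher_enrichment <- function(target, universe, term_map, alpha = 0.05) {
  universe <- unique(universe)
  target <- unique(target)
  if (length(universe) == 0) abort("Empty universe.")
  extra <- setdiff(target, universe)
  if (length(extra) > 0) {
    abort(paste0("Target genes missing from the universe: ",
                 paste(head(extra, 5), collapse = ", "),
                 if (length(extra) > 5) ", ..."))
  }
  tm <- term_map |>
    filter(gene_id %in% universe) |>
    distinct(term, gene_id)
  terms <- unique(tm$term)
  rows <- map(terms, function(t) {
    tg <- tm$gene_id[tm$term == t]
    a <- length(intersect(tg, target))
    b <- length(target) - a
    c_ <- length(tg) - a
    d <- length(universe) - length(target) - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2))
    tibble(term = t, n_target = a, n_universe = length(tg),
           odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  bind_rows(rows) |>
    mutate(p_adj = p.adjust(p_value, method = "BH"),
           significant = p_adj < alpha) |>
    arrange(p_value)
}
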