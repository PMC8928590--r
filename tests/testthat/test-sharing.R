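mk_call <- function(sample_id, group, svtype, chrom, start, end) {
  tibble::tibble(sample_id = sample_id, group = group, svtype = svtype,
                 chrom = chrom, start = start, end = end,
                 length = end - start)
}

test_that("clustering links same-type overlapping calls across samples", {
  two <- dplyr::bind_rows(
    mk_call("a", "Sample1-sperms", "DEL", "chr1", 100, 200),
    mk_call("b", "Sample2-sperms", "DEL", "chr1", 100, 200))
  cl <- cluster_events(two)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 2)
  expect_false(cl$is_singleton)
  expect_equal(cl$venn_category, "s1_s2")

  # DEL and DUP at identical coordinates stay separate
  mixed <- dplyr::bind_rows(
    mk_call("a", "Sample1-sperms", "DEL", "chr1", 100, 200),
    mk_call("b", "Sample1-sperms", "DUP", "chr1", 100, 200))
  expect_equal(nrow(cluster_events(mixed)), 2)

  # book-ended calls do not overlap (half-open) and are not linked
  adj <- dplyr::bind_rows(
    mk_call("a", "Sample1-sperms", "DEL", "chr1", 100, 200),
    mk_call("b", "Sample1-sperms", "DEL", "chr1", 200, 300))
  expect_equal(nrow(cluster_events(adj)), 2)

  # transitive chain joins into one cluster (single linkage)
  chain <- dplyr::bind_rows(
    mk_call("a", "Sample1-sperms", "DEL", "chr1", 100, 200),
    mk_call("b", "Sample1-sperms", "DEL", "chr1", 150, 400),
    mk_call("c", "Sample1-trio", "DEL", "chr1", 350, 500))
  ch <- cluster_events(chain)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$n_members, 3)
  expect_equal(ch$length_union, 400)
  expect_equal(ch$length_sum, 100 + 250 + 150)

  # order invariance
  shuffled <- chain[c(3, 1, 2), ]
  expect_equal(cluster_events(shuffled)$length_union, 400)

  # reciprocal rule separates a small call inside a large one
  nested <- dplyr::bind_rows(
    mk_call("a", "Sample1-sperms", "DEL", "chr1", 0, 10000),
    mk_call("b", "Sample1-sperms", "DEL", "chr1", 4000, 4100))
  expect_equal(nrow(cluster_events(nested, "any")), 1)
  expect_equal(nrow(cluster_events(nested, "reciprocal")), 2)
})

test_that("singleton removal keeps clusters with at least two member calls", {
  ones <- dplyr::bind_rows(
    mk_call("a", "Sample1-sperms", "DEL", "chr1", 100, 200),
    mk_call("a", "Sample1-sperms", "DUP", "chr2", 100, 200))
  cl <- cluster_events(ones)
  expect_equal(nrow(remove_singletons(cl)), 0)

  # two sperm cells of one bull: occurred twice, kept
  twice <- dplyr::bind_rows(
    mk_call("a", "Sample1-sperms", "DEL", "chr1", 100, 200),
    mk_call("b", "Sample1-sperms", "DEL", "chr1", 100, 200))
  expect_equal(nrow(remove_singletons(cluster_events(twice))), 1)

  sim <- simulate_study(small_sim_config())
  cl2 <- cluster_events(sim$calls[sim$calls$svtype %in% c("DEL", "DUP"), ])
  kept <- remove_singletons(cl2)
  expect_identical(kept, cl2[cl2$n_members >= 2, ])
})

test_that("venn summaries report exact percentages under both length conventions", {
  one_cat <- dplyr::bind_rows(
    mk_call("a", "Sample1-sperms", "DEL", "chr1", 100, 200),
    mk_call("b", "Sample1-sperms", "DEL", "chr1", 100, 200),
    mk_call("a", "Sample1-sperms", "DEL", "chr2", 500, 900),
    mk_call("b", "Sample1-sperms", "DEL", "chr2", 500, 900))
  v <- venn_summary(remove_singletons(cluster_events(one_cat)))
  expect_equal(nrow(v), 1)
  expect_equal(v$pct_events, 100)
  expect_equal(v$pct_length_union, 100)

  sim <- simulate_study(small_sim_config(support_pass_fraction = 1))
  cl <- cluster_events(sim$calls[sim$calls$svtype %in% c("DEL", "DUP"), ])
  kept <- remove_singletons(cl)
  v2 <- venn_summary(kept)
  expect_equal(sum(v2$n_events), nrow(kept))
  expect_equal(sum(v2$pct_events), 100, tolerance = 0.05)
  # categories recover the planted profile at jitter = 0
  prof <- table(sim$events$venn_category[!sim$events$is_singleton])
  for (cat in names(prof)) {
    expect_equal(v2$n_events[v2$venn_category == cat], unname(prof[[cat]]))
  }
})

test_that("gene-feature annotation reports per-kind overlaps", {
  feats <- tibble::tibble(
    chrom = "chr1",
    start = c(1000, 1000, 9000),
    end = c(10000, 1100, 10000),
    feature_type = c("transcript", "exon", "exon"),
    gene_id = "geneA")
  # region in the intron: transcript hit, no exon hit
  intron <- tibble::tibble(chrom = "chr1", start = 5000, end = 5100)
  hits <- annotate_features(intron, feats)
  expect_equal(sort(unique(hits$feature_type)), "transcript")
  # region spanning the gene hits every feature kind
  span <- tibble::tibble(chrom = "chr1", start = 0, end = 20000)
  hits2 <- annotate_features(span, feats)
  expect_setequal(unique(hits2$feature_type), c("transcript", "exon"))

  # random fixture vs per-feature intersection oracle
  g <- toy_genome()
  regions <- random_fixture(50, g, max_len = 2e4, seed = 2)
  feats2 <- random_fixture(80, g, max_len = 5e3, seed = 3) |>
    dplyr::mutate(feature_type = sample(c("exon", "CDS"), 80, replace = TRUE),
                  gene_id = paste0("g", sample.int(20, 80, replace = TRUE)))
  got <- annotate_features(regions, feats2)
  expected <- 0L
  seen <- character()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(feats2))) {
      if (regions$chrom[i] == feats2$chrom[j] &&
          regions$start[i] < feats2$end[j] &&
          feats2$start[j] < regions$end[i]) {
        key <- paste(i, feats2$gene_id[j], feats2$feature_type[j])
        if (!key %in% seen) { seen <- c(seen, key); expected <- expected + 1L }
      }
    }
  }
  expect_equal(nrow(got), expected)
})

test_that("fisher enrichment matches closed-form cases and enforces preconditions", {
  # symmetric table: odds ratio 1, p = 1
  uni <- paste0("g", 1:20)
  target <- paste0("g", 1:10)
  tm <- tibble::tibble(term = "T1",
                       gene_id = paste0("g", c(1:5, 11:15)))
  r <- fisher_enrichment(target, uni, tm)
  expect_equal(r$p_value, 1)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-6)

  # BH fixed point: m hypotheses all at p = 0.05 stay at 0.05
  expect_equal(p.adjust(rep(0.05, 7), method = "BH"), rep(0.05, 7))
  # BH adjusted p never below raw p and monotone in rank
  set.seed(1)
  praw <- runif(20)
  padj <- p.adjust(praw, "BH")
  expect_true(all(padj >= praw))
  o <- order(praw)
  expect_true(all(diff(padj[o]) >= -1e-12))

  # extreme term: all of target, none of background
  tm2 <- tibble::tibble(term = "T2", gene_id = target)
  r2 <- fisher_enrichment(target, uni, tm2)
  expect_equal(r2$p_value, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-9)

  expect_error(fisher_enrichment("gX", uni, tm), "missing from the universe")
  expect_error(fisher_enrichment(character(), character(), tm), "Empty universe")
})
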