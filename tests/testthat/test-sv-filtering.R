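test_that("VCF parsing converts coordinates and tolerates edge cases", {
  dir <- withr::local_tempdir()

  empty <- write_fixture_vcf(character(), file.path(dir, "empty.vcf"))
  expect_equal(nrow(parse_sv_vcf(empty, "s1")), 0)

  one <- write_fixture_vcf(
    "chr1\t101\tv1\tN\t<DEL>\t.\t.\tSVTYPE=DEL;END=200;SVLEN=-100;PE=5;SR=3",
    file.path(dir, "one.vcf"))
  x <- parse_sv_vcf(one, "s1", "Sample1-sperms")
  expect_equal(x$start, 100)
  expect_equal(x$end, 200)
  expect_equal(x$length, 100)

  # missing END on a non-BND record: dropped with a warning, not fatal
  two <- write_fixture_vcf(c(
    "chr1\t101\tv1\tN\t<DEL>\t.\t.\tSVTYPE=DEL;END=200;PE=5;SR=3",
    "chr1\t301\tv2\tN\t<DUP>\t.\t.\tSVTYPE=DUP;PE=5;SR=3"
  ), file.path(dir, "two.vcf"))
  expect_warning(y <- parse_sv_vcf(two, "s1"), "missing END")
  expect_equal(nrow(y), 1)

  # no SVTYPE header is fatal, naming the path
  bad <- file.path(dir, "bad.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), bad)
  expect_error(parse_sv_vcf(bad, "s1"), "SVTYPE")
  expect_error(parse_sv_vcf(file.path(dir, "nope.vcf"), "s1"), "not found")
})

test_that("per-type parse counts equal an independent line count", {
  dir <- withr::local_tempdir()
  set.seed(4)
  types <- sample(c("DEL", "DUP", "INV"), 20, replace = TRUE)
  pos <- sort(sample.int(1e6, 20)) * 10
  recs <- sprintf("chr1\t%d\tv%d\tN\t<%s>\t.\t.\tSVTYPE=%s;END=%d;PE=5;SR=3",
                  pos, seq_along(types), types, types, pos + 500)
  p <- write_fixture_vcf(recs, file.path(dir, "mix.vcf"))
  parsed <- parse_sv_vcf(p, "s1")
  for (tp in c("DEL", "DUP", "INV")) {
    expect_equal(sum(parsed$svtype == tp),
                 sum(grepl(paste0("SVTYPE=", tp), recs)))
  }
})

make_calls <- function(svtype, length, pe = 10, sr = 10,
                       sample_id = "s1") {
  tibble::tibble(
    sample_id = sample_id, group = "Sample1-sperms", svtype = svtype,
    chrom = "chr1", start = 1000, end = 1000 + ifelse(is.na(length), 1, length),
    length = length, pe = pe, sr = sr
  )
}

test_that("length filter keeps the inclusive 50 bp - 5 Mb CNV range and spares INV/BND", {
  calls <- dplyr::bind_rows(
    make_calls("DEL", 49), make_calls("DEL", 50), make_calls("DEL", 5e6),
    make_calls("DUP", 5e6 + 1), make_calls("INV", 10),
    make_calls("BND", NA_real_)
  )
  kept <- filter_by_length(calls)
  expect_equal(nrow(kept), 4)
  expect_true(all(kept$length[kept$svtype == "DEL"] %in% c(50, 5e6)))
  expect_true("INV" %in% kept$svtype)  # untouched despite 10 bp
  expect_true("BND" %in% kept$svtype)
})

test_that("support filter implements the either-signal coverage rule strictly", {
  cov <- c(s1 = 4)
  keep1 <- filter_by_support(make_calls("DEL", 100, pe = 4, sr = 2), cov)
  expect_equal(nrow(keep1), 1)  # 4 > 3 and 2 > 1
  keep2 <- filter_by_support(make_calls("DEL", 100, pe = 4, sr = 1), cov)
  expect_equal(nrow(keep2), 0)  # secondary SR condition fails
  # SR-primary branch: SR > 3 with PE > 3
  keep3 <- filter_by_support(make_calls("DEL", 100, pe = 4, sr = 4), cov)
  expect_equal(nrow(keep3), 1)
  # threshold is real-valued: coverage 4.4 -> 3.3; PE = 4 > 3.3 passes
  keep4 <- filter_by_support(make_calls("DEL", 100, pe = 4, sr = 2),
                             c(s1 = 4.4))
  expect_equal(nrow(keep4), 1)
  # SR-primary needs PE strictly > 3: PE = 3 fails both branches
  keep5 <- filter_by_support(make_calls("DEL", 100, pe = 3, sr = 9),
                             c(s1 = 4.4))
  expect_equal(nrow(keep5), 0)
  keep6 <- filter_by_support(make_calls("DEL", 100, pe = 4, sr = 9),
                             c(s1 = 4.4))
  expect_equal(nrow(keep6), 1)

  expect_error(filter_by_support(make_calls("DEL", 100), c(other = 4)),
               "s1")
})

test_that("filters agree with a per-record brute-force re-check and compose", {
  set.seed(9)
  n <- 500
  calls <- tibble::tibble(
    sample_id = sample(c("a", "b"), n, replace = TRUE),
    group = "Sample1-sperms",
    svtype = sample(c("DEL", "DUP", "INV", "BND"), n, replace = TRUE),
    chrom = "chr1",
    start = sample.int(1e7, n),
    length = round(exp(runif(n, log(10), log(1e7)))),
    pe = sample(0:8, n, replace = TRUE),
    sr = sample(0:8, n, replace = TRUE)
  ) |>
    dplyr::mutate(end = start + ifelse(svtype == "BND", 1, length),
                  length = ifelse(svtype == "BND", NA_real_, length))
  cov <- c(a = 4, b = 6.5)
  pol <- filter_policy()

  out <- filter_by_support(filter_by_length(calls, pol), cov, pol)

  expected <- logical(n)
  for (i in seq_len(n)) {
    len_ok <- if (calls$svtype[i] %in% c("DEL", "DUP")) {
      calls$length[i] >= 50 && calls$length[i] <= 5e6
    } else TRUE
    thr <- 0.75 * cov[[calls$sample_id[i]]]
    sup_ok <- (calls$pe[i] > thr && calls$sr[i] > 1) ||
      (calls$sr[i] > thr && calls$pe[i] > 3)
    expected[i] <- len_ok && sup_ok
  }
  expect_equal(nrow(out), sum(expected))
  expect_equal(out$start, calls$start[expected])

  # idempotence and order invariance of composition
  expect_identical(filter_by_length(out, pol), out)
  expect_identical(filter_by_support(out, cov, pol), out)
  other_order <- filter_by_length(filter_by_support(calls, cov, pol), pol)
  expect_identical(out, other_order)
  # no fabrication
  expect_true(all(out$start %in% calls$start))
})

test_that("group tallies separate counts, summed kb, and union coverage", {
  g <- genome_def("chr1", 1e6)
  expect_equal(sum(tally_by_group(
    tibble::tibble(sample_id = character(), group = character(),
                   svtype = character(), chrom = character(),
                   start = numeric(), end = numeric(),
                   length = numeric()), g)$n), 0)

  # two fully overlapping 1 kb DELs: summed kb 2.0, union footprint 1 kb
  calls <- tibble::tibble(
    sample_id = c("a", "b"), group = "Sample1-sperms", svtype = "DEL",
    chrom = "chr1", start = 1000, end = 2000, length = 1000
  )
  t1 <- tally_by_group(calls, g)
  del <- t1[t1$group == "Sample1-sperms" & t1$svtype == "DEL", ]
  expect_equal(del$length_kb, 2.0)
  expect_equal(del$genome_covered, 1000 / 1e6)

  # 50-call fixture vs independent per-record accumulation
  set.seed(2)
  g2 <- toy_genome()
  fix <- random_fixture(50, g2, max_len = 2e4, seed = 3) |>
    dplyr::mutate(sample_id = "a",
                  group = sample(c("Sample1-sperms", "Sample2-sperms"), 50,
                                 replace = TRUE),
                  svtype = sample(c("DEL", "DUP", "INV"), 50, replace = TRUE),
                  length = end - start)
  t2 <- tally_by_group(fix, g2)
  for (grp in unique(fix$group)) {
    for (tp in c("DEL", "DUP", "INV")) {
      sub <- fix[fix$group == grp & fix$svtype == tp, ]
      row <- t2[t2$group == grp & t2$svtype == tp, ]
      expect_equal(row$n, nrow(sub))
      expect_equal(row$length_kb, round(sum(sub$length) / 1000, 2))
      m <- oracle_merge(sub[, c("chrom", "start", "end")])
      expect_equal(row$genome_covered, sum(m$end - m$start) / sum(g2$length))
    }
  }
  # group totals sum to the overall total
  tot <- t2[t2$group == "Total" & t2$svtype == "Total", ]
  expect_equal(tot$n, nrow(fix))
})
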