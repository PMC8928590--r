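test_that("genome generation honours the configured range and is deterministic", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_range = c(1e6, 1e6))
  g <- generate_genome(cfg)
  expect_equal(nrow(g), 1)
  expect_equal(g$length, 1e6)

  cfg2 <- sim_config(n_chromosomes = 29, chrom_length_range = c(40e6, 160e6),
                     seed = 7)
  g1 <- generate_genome(cfg2)
  g2 <- generate_genome(cfg2)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 29)
  expect_true(all(g1$length >= 40e6 & g1$length <= 160e6))
  expect_false(anyDuplicated(g1$chrom) > 0)

  # independent re-draw with the same generator routine and seed
  redraw <- withr::with_seed(spermcnv:::derive_seed(7L, "genome"),
                             round(runif(29, 40e6, 160e6)))
  expect_equal(sum(g1$length), sum(redraw))

  expect_error(sim_config(chrom_length_range = c(2e6, 1e6)), "min exceeds max")
})

test_that("repeat annotation realises requested densities with non-overlapping classes", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_range = c(25e6, 25e6),
                    repeat_class_densities = c(Satellite = 0.05, LINE = 0.10),
                    seed = 3)
  g <- generate_genome(cfg)
  reps <- generate_repeats(g, cfg)

  sat <- reps[reps$repeat_class == "Satellite", ]
  frac <- sum(sat$end - sat$start) / sum(g$length)
  expect_gte(frac, 0.045)
  expect_lte(frac, 0.055)

  # within-class features are non-overlapping
  for (cls in unique(reps$repeat_class)) {
    x <- reps[reps$repeat_class == cls, ]
    x <- x[order(match(x$chrom, g$chrom), x$start), ]
    same <- x$chrom[-1] == x$chrom[-nrow(x)]
    expect_true(all(x$start[-1][same] >= x$end[-nrow(x)][same]))
  }

  # determinism and the empty case
  expect_identical(reps, generate_repeats(g, cfg))
  cfg0 <- sim_config(repeat_class_densities = c(LINE = 0))
  expect_equal(nrow(generate_repeats(g, cfg0)), 0)
  expect_error(sim_config(repeat_class_densities = c(LINE = 0.7, SINE = 0.5)),
               "sum")
})

test_that("segdup pair generation matches configured identity and orientation structure", {
  cfg <- sim_config(n_chromosomes = 3, chrom_length_range = c(1e7, 2e7),
                    segdup_pair_count = 0)
  g <- generate_genome(cfg)
  expect_equal(nrow(generate_segdup_pairs(g, cfg)), 0)

  cfg1 <- sim_config(n_chromosomes = 3, chrom_length_range = c(1e7, 2e7),
                     segdup_pair_count = 500, segdup_identity_mean = 0.9,
                     segdup_identity_sd = 0, seed = 11)
  p <- generate_segdup_pairs(g, cfg1)
  expect_equal(nrow(p), 500)
  expect_true(all(p$identity == 0.9))

  # interchromosomal flag agrees with a brute recount of the emitted table
  expect_equal(mean(p$interchromosomal), mean(p$chrom_a != p$chrom_b))
  expect_true(all(p$start_a >= 0 & p$end_a <= 2e7 + 1e7))
  expect_identical(p, generate_segdup_pairs(g, cfg1))
})

test_that("planted call sets reproduce the requested sharing profile and truth", {
  cfg <- small_sim_config()
  sim <- simulate_study(cfg)

  shared <- sim$events[!sim$events$is_singleton, ]
  got <- table(shared$venn_category)
  expect_equal(got[["all"]], 3)
  expect_equal(got[["s1_s2"]], 5)
  expect_equal(got[["s1"]], 4)
  expect_equal(got[["trio"]], 2)

  # truth-table consistency: every non-BND call maps to exactly one event
  non_bnd <- sim$calls[sim$calls$svtype != "BND", ]
  expect_true(all(non_bnd$event_id %in% sim$events$event_id))
  expect_equal(sort(unique(non_bnd$event_id)), sort(sim$events$event_id))

  # shared events always have >= 2 member calls
  counts <- table(non_bnd$event_id)
  expect_true(all(counts[shared$event_id] >= 2))

  # determinism
  sim2 <- simulate_study(cfg)
  expect_identical(sim$calls, sim2$calls)
  expect_identical(sim$events, sim2$events)
})

test_that("distal placement respects the configured bias", {
  base <- list(n_chromosomes = 6, chrom_length_range = c(2e7, 4e7),
               repeat_class_densities = c(LINE = 0.05),
               satellite_colocation_prob = 0, cnv_counts_per_sample = 40,
               sharing_profile = c(s1 = 0), n_sperm_sample1 = 3,
               n_sperm_sample2 = 3, inv_per_sample = 0, bnd_per_sample = 0,
               cnv_length_range = c(50, 1e4), seed = 5)

  # distal_bias = 1: every planted midpoint inside the terminal band
  cfg1 <- do.call(sim_config, c(base, list(distal_bias = 1)))
  g <- generate_genome(cfg1)
  sim1 <- generate_callsets(g, generate_repeats(g, cfg1), cfg1)
  len <- setNames(g$length, g$chrom)
  mid <- (sim1$events$start + sim1$events$end) / 2
  rel <- mid / len[sim1$events$chrom]
  w <- cfg1$distal_width_frac
  expect_true(all(rel < w | rel > 1 - w))
  expect_true(all(sim1$events$placed_distal))

  # distal_bias = 0: midpoints uniform; terminal-10% mass ~ 0.10
  cfg0 <- do.call(sim_config,
                  utils::modifyList(c(base, list(distal_bias = 0)),
                                    list(cnv_counts_per_sample = 150)))
  sim0 <- generate_callsets(g, generate_repeats(g, cfg0), cfg0)
  mid0 <- (sim0$events$start + sim0$events$end) / 2
  rel0 <- mid0 / len[sim0$events$chrom]
  frac10 <- mean(rel0 < 0.05 | rel0 > 0.95)
  n <- length(rel0)
  expect_lt(abs(frac10 - 0.10), 4 * sqrt(0.1 * 0.9 / n))
  expect_false(any(sim0$events$placed_distal))
})

test_that("satellite co-location places midpoints inside satellite repeats", {
  cfg <- sim_config(n_chromosomes = 3, chrom_length_range = c(2e7, 3e7),
                    repeat_class_densities = c(Satellite = 0.03),
                    satellite_colocation_prob = 1, distal_bias = 0,
                    cnv_counts_per_sample = 30,
                    sharing_profile = c(s1 = 0),
                    n_sperm_sample1 = 2, n_sperm_sample2 = 2,
                    inv_per_sample = 0, bnd_per_sample = 0,
                    cnv_length_range = c(50, 5e3), seed = 8)
  g <- generate_genome(cfg)
  reps <- generate_repeats(g, cfg)
  sim <- generate_callsets(g, reps, cfg)
  expect_true(all(sim$events$placed_satellite))
  sat <- reps[reps$repeat_class == "Satellite", ]
  mid <- floor((sim$events$start + sim$events$end) / 2)
  inside <- vapply(seq_len(nrow(sim$events)), function(i) {
    any(sat$chrom == sim$events$chrom[i] &
          sat$start <= mid[i] & sat$end > mid[i])
  }, logical(1))
  # midpoints sit in satellites except where the interval was clamped at a
  # chromosome end
  expect_gte(mean(inside), 0.95)
})

test_that("unplaceable events fail loudly instead of being truncated", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_range = c(1e6, 1e6),
                    repeat_class_densities = c(LINE = 0.01),
                    cnv_length_range = c(2e6, 2e6),
                    sharing_profile = c(s1 = 1), cnv_counts_per_sample = 0,
                    inv_per_sample = 0, bnd_per_sample = 0,
                    n_sperm_sample1 = 2, n_sperm_sample2 = 2)
  g <- generate_genome(cfg)
  expect_error(generate_callsets(g, generate_repeats(g, cfg), cfg),
               "Cannot place")
})

test_that("call sets round-trip through LUMPY-dialect VCFs", {
  sim <- simulate_study(small_sim_config())
  dir <- withr::local_tempdir()
  paths <- write_callset_vcfs(sim$calls, sim$genome, dir)
  sid <- names(paths)[1]
  parsed <- parse_sv_vcf(paths[[sid]], sid, "Sample1-sperms")
  orig <- sim$calls[sim$calls$sample_id == sid, ]
  orig <- orig[order(match(orig$chrom, sim$genome$chrom), orig$start), ]
  expect_equal(nrow(parsed), nrow(orig))
  expect_equal(parsed$start, orig$start)
  expect_equal(parsed$end, orig$end)
  expect_equal(parsed$svtype, orig$svtype)
  expect_equal(parsed$pe, orig$pe)
  expect_equal(parsed$sr, orig$sr)
  # BND mates are paired by ID
  bnd <- parsed[parsed$svtype == "BND", ]
  expect_true(all(bnd$mate_id %in% bnd$bnd_id))
})
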