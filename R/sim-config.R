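#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the package targets: a 29-autosome cattle-like genome, two
#' bulls' deep-sequenced sperm panels (8 and 6 cells at ~4x coverage) plus one
#' diploid trio proband at 40x, a sharing profile of 433 non-singleton
#' DEL/DUP events across the three groups, and planted distal and
#' satellite-co-location structure.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param chrom_length_range Length range in bp, `c(min, max)`.
#' @param repeat_class_densities Named fractions of the genome per repeat
#'   class; must sum to <= 1.
#' @param repeat_mean_lengths Named mean feature length (bp) per class;
#'   classes missing here fall back to 1000 bp.
#' @param segdup_pair_count Number of pairwise SegDup fragments to simulate.
#' @param segdup_identity_mean,segdup_identity_sd Sequence-identity
#'   distribution of pairs (normal, truncated to (0, 1]).
#' @param segdup_frag_mean_len Mean fragment length in bp (log-normal).
#' @param segdup_reversed_prob Probability a pair is in reversed orientation.
#' @param cnv_counts_per_sample Planted singleton DEL/DUP calls per sample.
#' @param cnv_length_range DEL/DUP length range in bp; lengths are drawn
#'   log-uniformly so both bounds are exercised.
#' @param length_outlier_fraction Fraction of singleton calls whose length is
#'   drawn outside/at the CNV length bounds (49 bp, 50 bp, 5 Mb, 5 Mb + 1,
#'   and a wide log-uniform), to exercise the length filter.
#' @param distal_bias Probability a planted CNV midpoint is placed in the
#'   distal band of a chromosome end.
#' @param distal_width_frac Width of the distal band as a fraction of the
#'   chromosome, per end. Default 0.15: the band covers the terminal strip
#'   plus the subtelomeric windows scored by [terminal_enrichment_test()].
#' @param satellite_colocation_prob Probability a planted CNV midpoint is
#'   placed inside a Satellite repeat (takes precedence over `distal_bias`).
#' @param sharing_profile Named event counts per Venn category over the three
#'   groups; names among `s1`, `s2`, `trio`, `s1_s2`, `s1_trio`, `s2_trio`,
#'   `all`. The default reproduces the 433-event demo profile.
#' @param n_sperm_sample1,n_sperm_sample2 Deep-sequenced sperm cells per bull.
#' @param sperm_coverage Fold genome coverage of each sperm cell.
#' @param trio_coverage Fold coverage of the three diploid trio members
#'   (proband, sire, dam); recycled to length 3.
#' @param per_sample_coverage Optional named vector overriding per-sample
#'   coverage.
#' @param support_pass_fraction Fraction of emitted calls drawn to pass the
#'   support-read filter at the sample's coverage.
#' @param inv_per_sample,bnd_per_sample Planted INV events and BND breakend
#'   pairs per sample.
#' @param jitter Max absolute shift (bp) applied independently to each
#'   member call of a shared event; 0 means identical coordinates.
#' @param seed Integer master seed.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, chrom_length_range = c(5e6, 5e6))
#' @export
sim_config <- function(n_chromosomes = 29,
                       chrom_length_range = c(40e6, 160e6),
                       repeat_class_densities = c(
                         LINE = 0.10, SINE = 0.05, LTR = 0.03,
                         DNA = 0.02, Satellite = 0.02),
                       repeat_mean_lengths = c(
                         LINE = 3000, SINE = 300, LTR = 500,
                         DNA = 600, Satellite = 2000),
                       segdup_pair_count = 1000,
                       segdup_identity_mean = 0.80,
                       segdup_identity_sd = 0.10,
                       segdup_frag_mean_len = 5000,
                       segdup_reversed_prob = 0.5,
                       cnv_counts_per_sample = 20,
                       cnv_length_range = c(50, 5e6),
                       length_outlier_fraction = 0.05,
                       distal_bias = 0.3,
                       distal_width_frac = 0.15,
                       satellite_colocation_prob = 0.3,
                       sharing_profile = c(
                         all = 18, s1_trio = 45, s1_s2 = 158, s2_trio = 18,
                         s1 = 123, s2 = 56, trio = 15),
                       n_sperm_sample1 = 8,
                       n_sperm_sample2 = 6,
                       sperm_coverage = 4,
                       trio_coverage = c(40, 10, 20),
                       per_sample_coverage = NULL,
                       support_pass_fraction = 0.9,
                       inv_per_sample = 5,
                       bnd_per_sample = 5,
                       jitter = 0,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = n_chromosomes,
    chrom_length_range = as.numeric(chrom_length_range),
    repeat_class_densities = repeat_class_densities,
    repeat_mean_lengths = repeat_mean_lengths,
    segdup_pair_count = segdup_pair_count,
    segdup_identity_mean = segdup_identity_mean,
    segdup_identity_sd = segdup_identity_sd,
    segdup_frag_mean_len = segdup_frag_mean_len,
    segdup_reversed_prob = segdup_reversed_prob,
    cnv_counts_per_sample = cnv_counts_per_sample,
    cnv_length_range = as.numeric(cnv_length_range),
    length_outlier_fraction = length_outlier_fraction,
    distal_bias = distal_bias,
    distal_width_frac = distal_width_frac,
    satellite_colocation_prob = satellite_colocation_prob,
    sharing_profile = sharing_profile,
    n_sperm_sample1 = n_sperm_sample1,
    n_sperm_sample2 = n_sperm_sample2,
    sperm_coverage = sperm_coverage,
    trio_coverage = trio_coverage,
    per_sample_coverage = per_sample_coverage,
    support_pass_fraction = support_pass_fraction,
    inv_per_sample = inv_per_sample,
    bnd_per_sample = bnd_per_sample,
    jitter = jitter,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

venn_categories <- function() {
  c("s1", "s2", "trio", "s1_s2", "s1_trio", "s2_trio", "all")
}

validate_sim_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)

  chk(cfg$n_chromosomes >= 1, "n_chromosomes must be >= 1")
  chk(length(cfg$chrom_length_range) == 2 && all(cfg$chrom_length_range > 0),
      "chrom_length_range must be two positive lengths")
  chk(cfg$chrom_length_range[1] <= cfg$chrom_length_range[2],
      "chrom_length_range: min exceeds max")
  d <- cfg$repeat_class_densities
  chk(all(d >= 0 & d <= 1), "repeat densities must be in [0, 1]")
  chk(sum(d) <= 1, "repeat densities must sum to <= 1")
  probs <- c(distal_bias = cfg$distal_bias,
             satellite_colocation_prob = cfg$satellite_colocation_prob,
             support_pass_fraction = cfg$support_pass_fraction,
             segdup_reversed_prob = cfg$segdup_reversed_prob,
             length_outlier_fraction = cfg$length_outlier_fraction)
  for (nm in names(probs)) {
    chk(probs[[nm]] >= 0 && probs[[nm]] <= 1,
        sprintf("%s must be in [0, 1]", nm))
  }
  chk(cfg$distal_width_frac > 0 && cfg$distal_width_frac <= 0.5,
      "distal_width_frac must be in (0, 0.5]")
  counts <- c(cfg$segdup_pair_count, cfg$cnv_counts_per_sample,
              cfg$inv_per_sample, cfg$bnd_per_sample,
              cfg$n_sperm_sample1, cfg$n_sperm_sample2)
  chk(all(counts >= 0), "all counts must be >= 0")
  chk(all(names(cfg$sharing_profile) %in% venn_categories()),
      paste0("sharing_profile names must be among: ",
             paste(venn_categories(), collapse = ", ")))
  chk(all(cfg$sharing_profile >= 0), "sharing_profile counts must be >= 0")
  chk(length(cfg$cnv_length_range) == 2 &&
        cfg$cnv_length_range[1] >= 1 &&
        cfg$cnv_length_range[1] <= cfg$cnv_length_range[2],
      "cnv_length_range must be an increasing pair of lengths >= 1")
  chk(cfg$jitter >= 0, "jitter must be >= 0")
  if (length(errs) > 0) {
    abort(paste0("Invalid simulation config:\n",
                 paste0("- ", errs, collapse = "\n")))
  }
  invisible(cfg)
}

# canonical group labels and sample rosters; the trio group is the three
# diploid family members (proband, sire, dam)
sim_samples <- function(cfg) {
  s1 <- sprintf("S1_sperm_%02d", seq_len(cfg$n_sperm_sample1))
  s2 <- sprintf("S2_sperm_%02d", seq_len(cfg$n_sperm_sample2))
  trio <- c("S1_trio_proband", "S1_trio_sire", "S1_trio_dam")
  tc <- rep_len(as.numeric(cfg$trio_coverage), 3)
  tbl <- tibble(
    sample_id = c(s1, s2, trio),
    group = c(rep("Sample1-sperms", length(s1)),
              rep("Sample2-sperms", length(s2)),
              rep("Sample1-trio", 3)),
    coverage = c(rep(cfg$sperm_coverage, length(s1)),
                 rep(cfg$sperm_coverage, length(s2)),
                 tc)
  )
  if (!is.null(cfg$per_sample_coverage)) {
    ov <- cfg$per_sample_coverage
    hit <- tbl$sample_id %in% names(ov)
    tbl$coverage[hit] <- as.numeric(ov[tbl$sample_id[hit]])
  }
  tbl
}
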