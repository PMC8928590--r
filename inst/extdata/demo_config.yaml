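# Demo study configuration: a cattle-like 29-autosome genome, two bulls'
# deep-sequenced sperm panels (8 + 6 cells at 4x) plus the diploid family
# trio (40x / 10x / 20x), and the 433-event three-group sharing profile.
# CNV lengths are log-uniform on 50 bp - 50 kb, matching the observed mean
# shared-event length (~4 kb); all emitted calls pass the support filter, so
# the demo emulates the post-QC call set.
seed: 1
sim:
  n_chromosomes: 29
  chrom_length_range: [40000000, 160000000]
  repeat_class_densities: {LINE: 0.10, SINE: 0.05, LTR: 0.03, DNA: 0.02, Satellite: 0.02}
  repeat_mean_lengths: {LINE: 3000, SINE: 300, LTR: 500, DNA: 600, Satellite: 2000}
  segdup_pair_count: 2000
  cnv_counts_per_sample: 20
  cnv_length_range: [50, 50000]
  sharing_profile: {all: 18, s1_trio: 45, s1_s2: 158, s2_trio: 18, s1: 123, s2: 56, trio: 15}
  n_sperm_sample1: 8
  n_sperm_sample2: 6
  sperm_coverage: 4
  trio_coverage: [40, 10, 20]
  support_pass_fraction: 1.0
  distal_bias: 0.3
  satellite_colocation_prob: 0.3
enrichment:
  n_iter: 1000
  flank_sizes: [5000, 20000]
positional:
  terminal_frac: 0.05
  window: 5000000
sharing:
  overlap_rule: any
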