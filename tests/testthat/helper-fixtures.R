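# small shared fixtures built in code

toy_genome <- function() {
  genome_def(c("chr1", "chr2", "chr3"), c(3e7, 2e7, 1e7))
}

small_sim_config <- function(...) {
  sim_config(
    n_chromosomes = 4, chrom_length_range = c(2e7, 4e7),
    segdup_pair_count = 200, cnv_counts_per_sample = 5,
    cnv_length_range = c(50, 2e5),
    sharing_profile = c(all = 3, s1_s2 = 5, s1 = 4, trio = 2),
    n_sperm_sample1 = 3, n_sperm_sample2 = 3,
    inv_per_sample = 2, bnd_per_sample = 2,
    seed = 42, ...
  )
}

# hand-written VCF text fixture
write_fixture_vcf <- function(records, path,
                              contigs = c(chr1 = 3e7, chr2 = 2e7)) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"t\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"t\">",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(hdr, records), path)
  path
}
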