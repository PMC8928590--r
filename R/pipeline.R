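pipeline_defaults <- function() {
  list(
    seed = 1L,
    sim = as.list(unclass(sim_config())),
    filter = list(min_len = 50, max_len = 5e6, coverage_fraction = 0.75,
                  secondary_sr_min = 1, secondary_pe_min = 3),
    enrichment = list(n_iter = 1000, flank_sizes = c(5000, 20000),
                      classes = NULL),
    positional = list(terminal_frac = 0.05, window = 5e6),
    sharing = list(overlap_rule = "any", min_reciprocal = 0.5),
    annotation = list(gff = NULL, term_map = NULL)
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Every omitted key falls back
#' to its default (the defaults are echoed back in the result); unknown keys
#' are errors, and all errors are reported at once.
#'
#' @param config Path to a YAML file, or a list.
#' @return A normalised config list of class `spermcnv_config`.
#' @examples
#' cfg <- validate_config(list(seed = 7, enrichment = list(n_iter = 100)))
#' cfg$enrichment$n_iter
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- pipeline_defaults()
  errs <- character()

  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top) > 0) {
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(unknown_top, collapse = ", ")))
  }
  merged <- defaults
  for (sect in intersect(names(config), names(defaults))) {
    if (sect == "seed") { merged$seed <- config$seed; next }
    unknown <- setdiff(names(config[[sect]]), names(defaults[[sect]]))
    if (length(unknown) > 0) {
      errs <- c(errs, paste0("unknown key(s) in `", sect, "`: ",
                             paste(unknown, collapse = ", ")))
    }
    for (k in intersect(names(config[[sect]]), names(defaults[[sect]]))) {
      merged[[sect]][[k]] <- config[[sect]][[k]]
    }
  }
  # YAML parses vectors/maps as lists: flatten the numeric-vector fields
  for (k in c("chrom_length_range", "repeat_class_densities",
              "repeat_mean_lengths", "cnv_length_range", "sharing_profile",
              "trio_coverage")) {
    if (is.list(merged$sim[[k]])) merged$sim[[k]] <- unlist(merged$sim[[k]])
  }
  if (is.list(merged$enrichment$flank_sizes)) {
    merged$enrichment$flank_sizes <- unlist(merged$enrichment$flank_sizes)
  }

  cf <- merged$filter$coverage_fraction
  if (!(is.numeric(cf) && cf > 0 && cf <= 1)) {
    errs <- c(errs, "filter.coverage_fraction out of (0, 1]")
  }
  if (!(merged$filter$min_len < merged$filter$max_len)) {
    errs <- c(errs, "filter.min_len must be < filter.max_len")
  }
  if (!(merged$enrichment$n_iter >= 1)) {
    errs <- c(errs, "enrichment.n_iter must be >= 1")
  }
  tf <- merged$positional$terminal_frac
  if (!(is.numeric(tf) && tf >= 0 && tf < 0.5)) {
    errs <- c(errs, "positional.terminal_frac out of [0, 0.5)")
  }
  psc <- merged$sim$per_sample_coverage
  if (!is.null(psc)) {
    psc <- unlist(psc)
    dup <- names(psc)[duplicated(names(psc))]
    if (length(dup) > 0) {
      errs <- c(errs, paste0("duplicate sample IDs in sim.per_sample_coverage: ",
                             paste(unique(dup), collapse = ", ")))
    }
    merged$sim$per_sample_coverage <- psc
  }
  sim_try <- tryCatch({
    merged$sim$seed <- merged$seed
    do.call(sim_config, merged$sim)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(sim_try)) errs <- c(errs, sim_try)

  for (p in c("gff", "term_map")) {
    f <- merged$annotation[[p]]
    if (!is.null(f) && !file.exists(f)) {
      errs <- c(errs, paste0("annotation.", p, " file not found: ", f))
    }
  }

  if (length(errs) > 0) {
    abort(paste0("Invalid configuration:\n",
                 paste0("- ", errs, collapse = "\n")))
  }
  structure(merged, class = "spermcnv_config")
}

write_stage_tsv <- function(x, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, name)
  tmp <- paste0(path, ".tmp")
  drop <- vapply(x, is.list, logical(1)) # list-columns are not serialisable
  readr::write_tsv(x[, !drop, drop = FALSE], tmp, progress = FALSE)
  file.rename(tmp, path)
  path
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes, in dependency order: simulate (genome, repeats, SegDup pairs,
#' per-sample VCF call sets), filter (length + support, per-group tally),
#' segdup-summarize, repeat enrichment (CNV regions and flanks), positional
#' analysis, sharing (cluster, singleton removal, Venn), and -- when an
#' annotation is configured -- gene/term enrichment. Each stage's tables are
#' written atomically under `out_dir/<stage>/`, and a JSON run manifest
#' (config snapshot, seed, package version, per-stage row counts, file
#' checksums) is written last. Fully deterministic for a fixed seed.
#'
#' @param config A config accepted by [validate_config()].
#' @param out_dir Output directory.
#' @param keep_tables Return the in-memory tables too (default `TRUE`).
#' @return Invisibly, a list with the stage tables and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("spermcnv_run_"),
                         keep_tables = TRUE) {
  cfg <- if (inherits(config, "spermcnv_config")) config
         else validate_config(config)
  t0 <- Sys.time()
  stage_files <- character()
  counts <- list()
  log_stage <- function(name) {
    inform(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  }

  # -- simulate
  log_stage("simulate")
  sim_cfg <- do.call(sim_config, { s <- cfg$sim; s$seed <- cfg$seed; s })
  sim <- simulate_study(sim_cfg)
  sim_dir <- file.path(out_dir, "simulate")
  if (!dir.exists(sim_dir)) dir.create(sim_dir, recursive = TRUE)
  write_chrom_sizes(sim$genome, file.path(sim_dir, "genome.chrom.sizes"))
  write_bed(sim$repeats, file.path(sim_dir, "repeats.bed"))
  write_segdup_pairs(sim$segdup_pairs, file.path(sim_dir, "segdup_pairs.tsv"))
  vcf_paths <- write_callset_vcfs(sim$calls, sim$genome,
                                  file.path(sim_dir, "vcf"))
  stage_files["truth_events"] <- write_stage_tsv(sim$events, sim_dir,
                                                 "truth_events.tsv")
  stage_files["samples"] <- write_stage_tsv(sim$samples, sim_dir,
                                            "samples.tsv")
  counts$simulate <- list(calls = nrow(sim$calls), events = nrow(sim$events),
                          samples = nrow(sim$samples))

  # -- filter (re-parse the emitted VCFs: exercises the format round trip)
  log_stage("filter")
  parsed <- imap(vcf_paths, function(p, sid) {
    parse_sv_vcf(p, sid, sim$samples$group[sim$samples$sample_id == sid])
  }) |> bind_rows()
  policy <- do.call(filter_policy, cfg$filter)
  filtered <- parsed |>
    filter_by_length(policy) |>
    filter_by_support(sim$samples, policy)
  tally <- tally_by_group(filtered, sim$genome)
  filt_dir <- file.path(out_dir, "filter")
  stage_files["filtered_calls"] <- write_stage_tsv(filtered, filt_dir,
                                                   "filtered_calls.tsv")
  stage_files["tally"] <- write_stage_tsv(tally, filt_dir, "tally.tsv")
  counts$filter <- list(parsed = nrow(parsed), kept = nrow(filtered))

  # -- segdup summarize
  log_stage("segdup-summarize")
  sd_sum <- summarize_segdup_pairs(sim$segdup_pairs)
  frags <- nonredundant_fragments(sim$segdup_pairs)
  sd_regions <- merge_regions(frags)
  sd_chrom <- per_chromosome_summary(sd_regions, sim$genome)
  sd_dir <- file.path(out_dir, "segdup")
  stage_files["segdup_summary"] <- write_stage_tsv(sd_sum, sd_dir,
                                                   "pair_summary.tsv")
  stage_files["segdup_regions"] <- write_stage_tsv(sd_regions, sd_dir,
                                                   "merged_regions.tsv")
  stage_files["segdup_per_chrom"] <- write_stage_tsv(sd_chrom, sd_dir,
                                                     "per_chromosome.tsv")
  counts$segdup <- list(pairs = nrow(sim$segdup_pairs),
                        fragments = nrow(frags),
                        merged_regions = nrow(sd_regions))

  # -- repeat enrichment on the merged CNV footprint
  log_stage("enrich")
  cnv <- filtered[filtered$svtype %in% c("DEL", "DUP"), , drop = FALSE]
  cnv_regions <- merge_regions(cnv[, c("chrom", "start", "end")])
  enr_dir <- file.path(out_dir, "enrich")
  if (nrow(cnv_regions) > 0) {
    perm <- permutation_test(cnv_regions, sim$repeats, sim$genome,
                             n_iter = cfg$enrichment$n_iter,
                             seed = derive_seed(cfg$seed, "enrich"),
                             classes = cfg$enrichment$classes)
    folds <- enrichment_folds(cnv_regions, sim$repeats, sim$genome,
                              flank_sizes = cfg$enrichment$flank_sizes)
    stage_files["enrichment"] <- write_stage_tsv(tidy(perm), enr_dir,
                                                 "enrichment.tsv")
    stage_files["flank_folds"] <- write_stage_tsv(folds, enr_dir,
                                                  "flank_folds.tsv")
  } else {
    perm <- NULL; folds <- NULL
    warn("No CNV regions after filtering; enrichment stage skipped.")
  }
  counts$enrich <- list(cnv_regions = nrow(cnv_regions),
                        n_iter = cfg$enrichment$n_iter)

  # -- positional
  log_stage("arms")
  pos <- relative_positions(cnv, sim$genome)
  profile <- bin_arm_distribution(pos)
  tt <- terminal_test_by_type(cnv, sim$genome,
                              terminal_frac = cfg$positional$terminal_frac,
                              window = cfg$positional$window)
  pos_dir <- file.path(out_dir, "arms")
  stage_files["arm_profile"] <- write_stage_tsv(profile, pos_dir,
                                                "arm_profile.tsv")
  stage_files["terminal_test"] <- write_stage_tsv(tt, pos_dir,
                                                  "terminal_test.tsv")
  counts$arms <- list(events = nrow(pos))

  # -- sharing
  log_stage("share")
  clusters <- cluster_events(cnv, overlap_rule = cfg$sharing$overlap_rule,
                             min_reciprocal = cfg$sharing$min_reciprocal)
  shared <- remove_singletons(clusters)
  venn <- venn_summary(shared)
  share_dir <- file.path(out_dir, "share")
  stage_files["clusters"] <- write_stage_tsv(clusters, share_dir,
                                             "clusters.tsv")
  stage_files["venn"] <- write_stage_tsv(venn, share_dir, "venn.tsv")
  counts$share <- list(clusters = nrow(clusters),
                       non_singletons = nrow(shared))

  # -- annotation (optional)
  annot <- NULL
  if (!is.null(cfg$annotation$gff)) {
    log_stage("annotate")
    features <- read_gene_annotation(cfg$annotation$gff)
    annot <- annotate_features(shared[, c("chrom", "start", "end")], features)
    stage_files["annotation"] <- write_stage_tsv(annot,
                                                 file.path(out_dir, "annotate"),
                                                 "gene_overlaps.tsv")
    if (!is.null(cfg$annotation$term_map)) {
      tm <- readr::read_tsv(cfg$annotation$term_map,
                            col_types = readr::cols(), progress = FALSE)
      enr <- fisher_enrichment(unique(annot$gene_id),
                               unique(features$gene_id), tm)
      stage_files["term_enrichment"] <- write_stage_tsv(
        enr, file.path(out_dir, "annotate"), "term_enrichment.tsv")
    }
    counts$annotate <- list(gene_overlaps = nrow(annot))
  }

  # -- manifest (written last)
  manifest <- list(
    tool = "spermcnv",
    version = as.character(packageVersion("spermcnv")),
    seed = cfg$seed,
    config = unclass(cfg),
    stage_counts = counts,
    files = as.list(vapply(stage_files, function(p) {
      unname(tools::md5sum(p))
    }, character(1))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  file.rename(tmp, manifest_path)

  out <- list(out_dir = out_dir, manifest = manifest)
  if (keep_tables) {
    out <- c(out, list(
      sim = sim, filtered = filtered, tally = tally,
      segdup_summary = sd_sum, segdup_regions = sd_regions,
      enrichment = perm, flank_folds = folds,
      arm_profile = profile, terminal = tt,
      clusters = clusters, venn = venn, annotation = annot
    ))
  }
  invisible(out)
}
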