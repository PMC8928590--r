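#' Generate a toy genome
#'
#' Chromosome lengths are drawn uniformly from the configured range;
#' deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return A genome tibble ([genome_def()]).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  rng <- config$chrom_length_range
  n <- config$n_chromosomes
  lens <- with_seed(derive_seed(config$seed, "genome"), {
    round(runif(n, rng[1], rng[2]))
  })
  genome_def(paste0("chr", seq_len(n)), lens)
}

#' Generate a repeat annotation
#'
#' Places, for each configured repeat class, non-overlapping features along
#' the genome whose total length realises the requested genome fraction
#' almost exactly (feature lengths are log-normal around the class mean and
#' rescaled to the target total; gaps between features are
#' exponential-spaced). Different classes are placed independently and may
#' overlap each other, as in real annotations.
#'
#' @param genome Genome tibble.
#' @param config A [sim_config()].
#' @return Tibble with `chrom`, `start`, `end`, `repeat_class`, `family`,
#'   sorted by position.
#' @export
generate_repeats <- function(genome, config) {
  validate_genome(genome)
  validate_sim_config(config)
  dens <- config$repeat_class_densities
  dens <- dens[dens > 0]
  if (length(dens) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  repeat_class = character(), family = character()))
  }
  G <- genome_size(genome)
  off <- genome_offsets(genome)
  chrom_ends <- off + genome$length

  out <- with_seed(derive_seed(config$seed, "repeats"), {
    rows <- list()
    for (cls in names(dens)) {
      target_bp <- round(dens[[cls]] * G)
      mean_len <- config$repeat_mean_lengths[[cls]] %||% 1000
      n <- max(1L, round(target_bp / mean_len))
      lens <- stats::rlnorm(n, meanlog = log(mean_len) - 0.125, sdlog = 0.5)
      lens <- pmax(1, round(lens * target_bp / sum(lens)))
      # absorb rounding drift into the last feature
      drift <- target_bp - sum(lens)
      lens[n] <- max(1, lens[n] + drift)
      gaps <- stats::rexp(n + 1)
      gaps <- gaps / sum(gaps) * (G - sum(lens))
      starts_lin <- floor(cumsum(gaps[seq_len(n)]) + cumsum(c(0, lens[-n])))
      rows[[cls]] <- tibble(start_lin = starts_lin,
                            end_lin = starts_lin + lens,
                            repeat_class = cls,
                            family = paste0(cls, "-fam",
                                            sample.int(5, n, replace = TRUE)))
    }
    bind_rows(rows)
  })
  split_linear(out, genome, off, chrom_ends)
}

# split linear-coordinate features at chromosome boundaries
split_linear <- function(feat, genome, off = genome_offsets(genome),
                         chrom_ends = off + genome$length) {
  idx_s <- findInterval(feat$start_lin, off)
  idx_e <- findInterval(feat$end_lin - 1, off)
  same <- idx_s == idx_e
  easy <- feat[same, ]
  easy_idx <- idx_s[same]
  res <- tibble(
    chrom = genome$chrom[easy_idx],
    start = unname(easy$start_lin - off[easy_idx]),
    end = unname(easy$end_lin - off[easy_idx]),
    repeat_class = easy$repeat_class,
    family = easy$family
  )
  if (any(!same)) {
    hard <- feat[!same, ]
    pieces <- pmap(list(hard$start_lin, hard$end_lin, hard$repeat_class,
                        hard$family),
                   function(s, e, cls, fam) {
      ks <- findInterval(s, off):findInterval(e - 1, off)
      tibble(
        chrom = genome$chrom[ks],
        start = unname(pmax(s, off[ks]) - off[ks]),
        end = unname(pmin(e, chrom_ends[ks]) - off[ks]),
        repeat_class = cls, family = fam
      )
    })
    res <- bind_rows(res, bind_rows(pieces))
  }
  res |>
    filter(end > start) |>
    arrange(match(chrom, genome$chrom), start)
}

#' Generate a pairwise SegDup fragment table
#'
#' Fragment coordinates are uniform over the genome (chromosome chosen with
#' probability proportional to its length); identities are normal, truncated
#' to (0, 1]; orientation is Bernoulli.
#'
#' @param genome Genome tibble.
#' @param config A [sim_config()].
#' @return Pair tibble: `chrom_a/start_a/end_a`, `chrom_b/start_b/end_b`,
#'   `identity`, `same_orientation`, `interchromosomal`.
#' @export
generate_segdup_pairs <- function(genome, config) {
  validate_genome(genome)
  validate_sim_config(config)
  n <- config$segdup_pair_count
  if (n == 0) {
    return(tibble(chrom_a = character(), start_a = numeric(), end_a = numeric(),
                  chrom_b = character(), start_b = numeric(), end_b = numeric(),
                  identity = numeric(), same_orientation = logical(),
                  interchromosomal = logical()))
  }
  with_seed(derive_seed(config$seed, "segdup"), {
    lens <- round(stats::rlnorm(2 * n, log(config$segdup_frag_mean_len), 0.6))
    lens <- pmin(pmax(lens, 200), min(genome$length))
    ci <- sample.int(nrow(genome), 2 * n, replace = TRUE, prob = genome$length)
    L <- genome$length[ci]
    starts <- floor(runif(2 * n) * (L - lens + 1))
    ident <- rnorm(n, config$segdup_identity_mean, config$segdup_identity_sd)
    if (config$segdup_identity_sd > 0) {
      for (k in 1:100) {
        bad <- ident <= 0 | ident > 1
        if (!any(bad)) break
        ident[bad] <- rnorm(sum(bad), config$segdup_identity_mean,
                            config$segdup_identity_sd)
      }
    }
    ident <- pmin(pmax(ident, .Machine$double.eps), 1)
    a <- seq_len(n); b <- n + seq_len(n)
    tibble(
      chrom_a = genome$chrom[ci[a]], start_a = starts[a],
      end_a = starts[a] + lens[a],
      chrom_b = genome$chrom[ci[b]], start_b = starts[b],
      end_b = starts[b] + lens[b],
      identity = ident,
      same_orientation = runif(n) >= config$segdup_reversed_prob
    ) |>
      mutate(interchromosomal = chrom_a != chrom_b)
  })
}

# ---- CNV call-set generation ------------------------------------------------

category_groups <- function(cat) {
  switch(cat,
    s1 = "Sample1-sperms",
    s2 = "Sample2-sperms",
    trio = "Sample1-trio",
    s1_s2 = c("Sample1-sperms", "Sample2-sperms"),
    s1_trio = c("Sample1-sperms", "Sample1-trio"),
    s2_trio = c("Sample2-sperms", "Sample1-trio"),
    all = c("Sample1-sperms", "Sample2-sperms", "Sample1-trio"),
    abort(paste0("Unknown Venn category: ", cat))
  )
}

# sample() without the length-1 surprise
resample <- function(x, n) x[sample.int(length(x), n)]

# union footprint (bp) of member intervals, base R (single chromosome)
union_bp <- function(start, end) {
  o <- order(start)
  s <- start[o]; e <- end[o]
  cme <- cummax(e)
  n <- length(s)
  new_run <- c(TRUE, s[-1] > cme[-n])
  run_end <- cme[c(which(new_run)[-1] - 1, n)]
  sum(run_end - s[new_run])
}

# midpoint placement for one event
place_midpoint <- function(genome, off, sat_lin, sat_cum, cfg) {
  if (length(sat_cum) > 0 && runif(1) < cfg$satellite_colocation_prob) {
    u <- runif(1) * sat_cum[length(sat_cum)]
    j <- findInterval(u, c(0, sat_cum[-length(sat_cum)]))
    pos_lin <- sat_lin[j, 1] + (u - c(0, sat_cum)[j])
    ci <- findInterval(pos_lin, off)
    return(list(chrom_i = ci, mid = floor(pos_lin - off[ci]),
                distal = FALSE, satellite = TRUE))
  }
  ci <- sample.int(nrow(genome), 1, prob = genome$length)
  L <- genome$length[ci]
  if (runif(1) < cfg$distal_bias) {
    w <- cfg$distal_width_frac * L
    mid <- if (runif(1) < 0.5) runif(1, 0, w) else runif(1, L - w, L)
    return(list(chrom_i = ci, mid = floor(mid), distal = TRUE,
                satellite = FALSE))
  }
  list(chrom_i = ci, mid = floor(runif(1, 0, L)), distal = FALSE,
       satellite = FALSE)
}

# fit an interval of length len with midpoint ~ mid inside [0, L); NULL if len > L
fit_interval <- function(mid, len, L) {
  if (len > L) return(NULL)
  start <- round(mid - len / 2)
  start <- min(max(start, 0), L - len)
  c(start, start + len)
}

# vectorised PE/SR support draw; pass calls satisfy the support rule at the
# sample's coverage, fail calls violate both branches regardless of coverage
draw_support <- function(pass, coverage) {
  n <- length(pass)
  thr <- floor(0.75 * coverage)
  pe <- integer(n); sr <- integer(n)
  branch_a <- runif(n) < 0.5
  pa <- pass & branch_a
  pb <- pass & !branch_a
  pe[pa] <- thr[pa] + 1L + rpois(sum(pa), 2)
  sr[pa] <- 2L + rpois(sum(pa), 1)
  sr[pb] <- thr[pb] + 1L + rpois(sum(pb), 2)
  pe[pb] <- 4L + rpois(sum(pb), 1)
  nf <- sum(!pass)
  pe[!pass] <- sample(0:3, nf, replace = TRUE)
  sr[!pass] <- sample(0:1, nf, replace = TRUE)
  list(pe = pe, sr = sr)
}

#' Generate multi-sample SV call sets with planted truth
#'
#' Emits one call table covering all samples (two bulls' sperm panels plus
#' the trio proband) together with a per-event truth table. Planted
#' structure:
#'
#' * shared DEL/DUP events following the configured Venn `sharing_profile`
#'   (every shared event is carried by >= 2 calls, so it survives singleton
#'   removal);
#' * per-sample singleton DEL/DUP calls, a configurable fraction of which
#'   carry boundary or out-of-range lengths to exercise the length filter;
#' * per-sample INV events and BND breakend mate pairs;
#' * midpoints placed in the distal chromosome band or inside Satellite
#'   repeats with the configured probabilities (satellite placement takes
#'   precedence; realised flags are recorded);
#' * PE/SR support drawn so that `support_pass_fraction` of calls passes the
#'   support filter at the sample's coverage, with the planted flag recorded.
#'
#' @param genome Genome tibble.
#' @param repeats Repeat annotation from [generate_repeats()] (Satellite
#'   features drive co-location placement; may be empty).
#' @param config A [sim_config()].
#' @return A list with `calls` (per-call tibble including `pe`, `sr`,
#'   `pass_support`, `pass_length`), `events` (per-event truth with Venn
#'   category, placement flags, and both the union and summed length
#'   conventions), and `samples` (sample/group/coverage roster).
#' @export
generate_callsets <- function(genome, repeats, config) {
  validate_genome(genome)
  validate_sim_config(config)
  samples <- sim_samples(config)
  off <- genome_offsets(genome)
  cov_of <- setNames(samples$coverage, samples$sample_id)
  grp_of <- setNames(samples$group, samples$sample_id)

  sat <- repeats[repeats$repeat_class == "Satellite", , drop = FALSE]
  sat_lin <- if (nrow(sat) > 0) to_linear(sat, genome) else
    matrix(numeric(), ncol = 2)
  sat_cum <- if (nrow(sat) > 0) cumsum(sat_lin[, 2] - sat_lin[, 1]) else
    numeric()

  prof <- config$sharing_profile
  prof <- prof[prof > 0]

  with_seed(derive_seed(config$seed, "callsets"), {
    ev_rows <- list(); call_rows <- list()
    eid <- 0L
    # linear footprints of already-placed DEL/DUP events: distinct planted
    # events of the same type never overlap, so planted truth categories are
    # exactly recoverable by overlap clustering at jitter = 0
    placed_s <- list(DEL = numeric(), DUP = numeric())
    placed_e <- list(DEL = numeric(), DUP = numeric())

    rlen <- function() {
      r <- log(config$cnv_length_range)
      round(exp(runif(1, r[1], r[2])))
    }

    make_event <- function(category, is_singleton, carriers, svtype, len) {
      eid <<- eid + 1L
      id <- sprintf("ev%05d", eid)
      track <- svtype %in% c("DEL", "DUP")
      placed <- NULL
      for (try in 1:1000) {
        p <- place_midpoint(genome, off, sat_lin, sat_cum, config)
        iv <- fit_interval(p$mid, len, genome$length[p$chrom_i])
        if (is.null(iv)) next
        if (track) {
          s_lin <- iv[1] + off[p$chrom_i]; e_lin <- iv[2] + off[p$chrom_i]
          if (any(placed_s[[svtype]] < e_lin & placed_e[[svtype]] > s_lin)) next
        }
        placed <- list(p = p, iv = iv)
        break
      }
      if (is.null(placed)) {
        abort(sprintf(
          "Cannot place an event of length %g bp without exceeding chromosome bounds or overlapping an existing same-type event.",
          len))
      }
      if (track) {
        placed_s[[svtype]] <<- c(placed_s[[svtype]],
                                 placed$iv[1] + off[placed$p$chrom_i])
        placed_e[[svtype]] <<- c(placed_e[[svtype]],
                                 placed$iv[2] + off[placed$p$chrom_i])
      }
      chrom <- genome$chrom[placed$p$chrom_i]
      L <- genome$length[placed$p$chrom_i]
      s0 <- placed$iv[1]
      m <- length(carriers)
      if (config$jitter > 0) {
        sh <- round(runif(m, -config$jitter, config$jitter))
        ms <- pmin(pmax(s0 + sh, 0), L - len)
      } else {
        ms <- rep(s0, m)
      }
      pass <- runif(m) < config$support_pass_fraction
      sup <- draw_support(pass, cov_of[carriers])
      call_rows[[id]] <<- list(
        event_id = rep(id, m), sample_id = carriers,
        group = unname(grp_of[carriers]), svtype = rep(svtype, m),
        chrom = rep(chrom, m), start = ms, end = ms + len,
        length = rep(as.numeric(len), m), pe = sup$pe, sr = sup$sr,
        pass_support = pass
      )
      ev_rows[[id]] <<- list(
        event_id = id,
        venn_category = category,
        is_singleton = is_singleton,
        svtype = svtype, chrom = chrom, start = s0, end = s0 + len,
        length = as.numeric(len),
        placed_distal = placed$p$distal,
        placed_satellite = placed$p$satellite,
        n_carriers = m,
        groups_present = paste(sort(unique(grp_of[carriers])), collapse = ","),
        length_union = union_bp(ms, ms + len),
        length_sum = as.numeric(m * len)
      )
      invisible(id)
    }

    # shared (non-singleton) events per Venn category
    for (cat in names(prof)) {
      groups <- category_groups(cat)
      for (k in seq_len(prof[[cat]])) {
        carriers <- character()
        for (g in groups) {
          pool <- samples$sample_id[samples$group == g]
          # single-group events need >= 2 carriers to survive singleton removal
          n_carry <- if (length(groups) == 1) resample(2:min(4, length(pool)), 1)
            else resample(1:min(3, length(pool)), 1)
          carriers <- c(carriers, resample(pool, n_carry))
        }
        make_event(cat, FALSE, carriers, resample(c("DEL", "DUP"), 1), rlen())
      }
    }

    # per-sample singletons, some with boundary / out-of-range lengths
    for (sid in samples$sample_id) {
      for (k in seq_len(config$cnv_counts_per_sample)) {
        len <- if (runif(1) < config$length_outlier_fraction) {
          wide_max <- min(5e7, 2 * config$cnv_length_range[2],
                          max(genome$length) / 4)
          switch(sample.int(5, 1),
                 config$cnv_length_range[1] - 1,
                 config$cnv_length_range[1],
                 config$cnv_length_range[2],
                 config$cnv_length_range[2] + 1,
                 round(exp(runif(1, log(10), log(max(wide_max, 11))))))
        } else rlen()
        len <- min(max(1, len), max(genome$length))
        make_event(NA_character_, TRUE, sid, resample(c("DEL", "DUP"), 1), len)
      }
    }

    # per-sample INV events
    for (sid in samples$sample_id) {
      for (k in seq_len(config$inv_per_sample)) {
        len <- round(exp(runif(1, log(1000), log(1e6))))
        make_event(NA_character_, TRUE, sid, "INV", len)
      }
    }

    calls <- bind_rows(lapply(call_rows, as_tibble))
    events <- bind_rows(lapply(ev_rows, as_tibble))

    # per-sample BND breakend mate pairs
    bnd <- list()
    for (sid in samples$sample_id) {
      nb <- config$bnd_per_sample
      if (nb == 0) next
      ci <- sample.int(nrow(genome), 2 * nb, replace = TRUE,
                       prob = genome$length)
      pos <- floor(runif(2 * nb) * (genome$length[ci] - 1))
      pass <- rep(runif(nb) < config$support_pass_fraction, each = 2)
      sup <- draw_support(pass, rep(cov_of[sid], 2 * nb))
      ids <- sprintf("ev%05d", eid + rep(seq_len(nb), each = 2))
      eid <- eid + nb
      bnd[[sid]] <- tibble(
        event_id = ids, sample_id = sid, group = unname(grp_of[sid]),
        svtype = "BND", chrom = genome$chrom[ci], start = pos, end = pos + 1,
        length = NA_real_, pe = sup$pe, sr = sup$sr, pass_support = pass,
        bnd_id = paste0(ids, "_", rep(1:2, nb)),
        mate_id = paste0(ids, "_", rep(2:1, nb))
      )
    }
    if (length(bnd) > 0) {
      calls <- bind_rows(
        calls |> mutate(bnd_id = NA_character_, mate_id = NA_character_),
        bind_rows(bnd)
      )
    }

    calls <- calls |>
      mutate(pass_length = !(svtype %in% c("DEL", "DUP")) |
               (length >= config$cnv_length_range[1] &
                  length <= config$cnv_length_range[2]))

    list(calls = calls, events = events, samples = samples)
  })
}

#' Generate every simulation product in one call
#'
#' Convenience wrapper running [generate_genome()], [generate_repeats()],
#' [generate_segdup_pairs()] and [generate_callsets()] with one config.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `repeats`, `segdup_pairs`, `calls`, `events`,
#'   `samples`, and the `config` used.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- generate_genome(config)
  repeats <- generate_repeats(genome, config)
  pairs <- generate_segdup_pairs(genome, config)
  cs <- generate_callsets(genome, repeats, config)
  list(genome = genome, repeats = repeats, segdup_pairs = pairs,
       calls = cs$calls, events = cs$events, samples = cs$samples,
       config = config)
}
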