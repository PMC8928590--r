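# ---- fast repeat-overlap index ---------------------------------------------
# Repeats are projected onto a linear ("unrolled") genome once; overlap
# length against any merged target set then costs O(log n) per target piece
# via cumulative-coverage lookups. Within a class, features are unioned
# before indexing (a no-op for RepeatMasker-style tables, whose classes are
# internally non-overlapping); all bp and count metrics refer to these
# disjoint features, identically for observed and permuted targets.

repeat_index <- function(repeats, genome) {
  validate_genome(genome)
  G <- genome_size(genome)
  classes <- sort(unique(repeats$repeat_class))
  idx <- list()
  for (cls in classes) {
    x <- repeats[repeats$repeat_class == cls, , drop = FALSE]
    lin <- to_linear(x, genome)
    m <- merge_linear(lin[, 1], lin[, 2])
    rs <- m[, 1]; re <- m[, 2]
    idx[[cls]] <- list(
      starts = rs, ends = re, cum = cumsum(c(0, re - rs)),
      n_features = length(rs), total_bp = sum(re - rs)
    )
  }
  structure(list(classes = idx, genome_bp = G, genome = genome),
            class = "repeat_index")
}

# repeat bp of one class inside [0, x) of the linear genome
cum_cov <- function(cl, x) {
  j <- findInterval(x, cl$starts)
  out <- numeric(length(x))
  hit <- j > 0
  jh <- j[hit]
  out[hit] <- cl$cum[jh] + pmin(pmax(x[hit] - cl$starts[jh], 0),
                                cl$ends[jh] - cl$starts[jh])
  out
}

# merge sorted-by-nothing linear intervals; returns 2-col matrix
merge_linear <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  n <- length(s)
  if (n == 0) return(cbind(numeric(), numeric()))
  cme <- cummax(e)
  new_run <- c(TRUE, s[-1] > cme[-n])
  cbind(s[new_run], cme[c(which(new_run)[-1] - 1, n)])
}

# class metrics against merged linear target pieces (matrix [s, e))
class_content <- function(cl, m) {
  length_bp <- sum(cum_cov(cl, m[, 2]) - cum_cov(cl, m[, 1]))
  lo <- findInterval(m[, 1] + 0.5, cl$ends)   # features ending <= piece start
  hi <- findInterval(m[, 2] - 0.5, cl$starts) # features starting < piece end
  prev <- 0; count <- 0
  for (i in seq_len(nrow(m))) {
    count <- count + max(0, hi[i] - max(lo[i], prev))
    prev <- max(prev, hi[i])
  }
  c(length_bp = length_bp, count = count)
}

#' Repeat content of a region set
#'
#' For each repeat class, computes against the merged footprint of `target`:
#' `length_bp` (repeat bp intersected with the footprint; a partially
#' overlapping repeat contributes only its overlapped bp), `count` (repeat
#' features overlapping the footprint, each counted once), `avg_length`
#' (`length_bp / count`), `length_pct` (`100 * length_bp / footprint bp`)
#' and `count_per_mb` (`count / (footprint bp / 1e6)`).
#'
#' Within a class, overlapping annotation features are unioned before any
#' accounting (standard RepeatMasker tables are already disjoint per class,
#' so this is normally a no-op).
#'
#' @param target Region table.
#' @param repeats Repeat annotation (`chrom`, `start`, `end`,
#'   `repeat_class`).
#' @param genome Genome tibble.
#' @param index Optional pre-built index from `repeat_index()` (used by the
#'   permutation test to avoid rebuilding it every iteration).
#' @return Tibble with one row per class, plus the footprint size in the
#'   `target_bp` column.
#' @export
repeat_content <- function(target, repeats, genome, index = NULL) {
  if (is.null(index)) index <- repeat_index(repeats, genome)
  validate_regions(target, genome)
  classes <- names(index$classes)
  if (nrow(target) == 0) {
    warn("Empty target region set; all repeat-content metrics are 0.")
    return(tibble(repeat_class = classes, length_bp = 0, count = 0,
                  avg_length = 0, length_pct = 0, count_per_mb = 0,
                  target_bp = 0))
  }
  lin <- to_linear(target, genome)
  m <- merge_linear(lin[, 1], lin[, 2])
  target_bp <- sum(m[, 2] - m[, 1])
  rows <- map(classes, function(cls) {
    cc <- class_content(index$classes[[cls]], m)
    tibble(repeat_class = cls,
           length_bp = unname(cc[["length_bp"]]),
           count = unname(cc[["count"]]))
  })
  bind_rows(rows) |>
    mutate(
      avg_length = ifelse(count > 0, length_bp / count, 0),
      length_pct = 100 * length_bp / target_bp,
      count_per_mb = count / (target_bp / 1e6),
      target_bp = target_bp
    )
}

# genome-wide baseline rows (target = whole genome)
genome_baseline <- function(index) {
  G <- index$genome_bp
  map(names(index$classes), function(cls) {
    cl <- index$classes[[cls]]
    tibble(repeat_class = cls,
           avg_length = if (cl$n_features > 0) cl$total_bp / cl$n_features else 0,
           length_pct = 100 * cl$total_bp / G,
           count_per_mb = cl$n_features / (G / 1e6))
  }) |> bind_rows()
}

#' Draw a random region set matched on length distribution
#'
#' `n` regions with lengths from a normal distribution (truncated below at
#' 50 bp), chromosomes chosen with probability proportional to length, and
#' starts uniform such that each region fits its chromosome. Regions may
#' overlap one another. An `exclude` set is avoided by rejection sampling
#' (at most 1000 retries per region).
#'
#' @param genome Genome tibble.
#' @param n Number of regions (>= 1).
#' @param mean_len,sd_len Length distribution parameters in bp.
#' @param exclude Optional region table to avoid.
#' @return Region tibble.
#' @export
random_region_set <- function(genome, n, mean_len, sd_len = 0,
                              exclude = NULL) {
  validate_genome(genome)
  stopifnot(n >= 1, mean_len > 0)
  lens <- pmax(50, round(rnorm(n, mean_len, sd_len)))
  lens <- pmin(lens, max(genome$length))
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  L <- genome$length[ci]
  refit <- lens > L
  for (k in 1:1000) {
    if (!any(refit)) break
    ci[refit] <- sample.int(nrow(genome), sum(refit), replace = TRUE,
                            prob = genome$length)
    L <- genome$length[ci]
    refit <- lens > L
  }
  if (any(refit)) {
    abort("Cannot place random regions: lengths exceed every chromosome.")
  }
  starts <- floor(runif(n) * (L - lens + 1))
  out <- tibble(chrom = genome$chrom[ci], start = starts, end = starts + lens)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    ex <- as_granges(merge_regions(exclude))
    for (k in 1:1000) {
      bad <- IRanges::overlapsAny(as_granges(out), ex)
      if (!any(bad)) break
      nb <- sum(bad)
      ci2 <- sample.int(nrow(genome), nb, replace = TRUE,
                        prob = genome$length)
      L2 <- genome$length[ci2]
      ok <- lens[bad] <= L2
      if (!all(ok)) next
      st2 <- floor(runif(nb) * (L2 - lens[bad] + 1))
      out$chrom[bad] <- genome$chrom[ci2]
      out$start[bad] <- st2
      out$end[bad] <- st2 + lens[bad]
    }
    if (any(IRanges::overlapsAny(as_granges(out), ex))) {
      abort("Cannot place random regions avoiding the exclude set after 1000 retries.")
    }
  }
  out
}

#' Random-region permutation test for repeat enrichment
#'
#' For each repeat class and metric, compares the observed value on `target`
#' with a null distribution obtained by redrawing `n_iter` random region
#' sets matched to the target's region count and length mean/SD
#' ([random_region_set()]), recomputing the metric each time. The
#' enrichment p-value is the frequency of null values strictly greater than
#' the observed one divided by `n_iter` (so the minimum attainable p is 0,
#' reported as `< 1/n_iter`); a depletion p using strictly-less is reported
#' alongside. Folds are observed / genome-wide baseline.
#'
#' @param target Region table (e.g. CNV regions, SegDups, or their flanks).
#' @param repeats Repeat annotation.
#' @param genome Genome tibble.
#' @param n_iter Number of simulated region sets.
#' @param seed Integer seed; iteration `i` uses a derived sub-seed, so runs
#'   are reproducible and order-independent.
#' @param metrics Metrics to test.
#' @param classes Repeat classes to test (default: all present).
#' @param length_mode `"normal"` draws lengths from a truncated normal with
#'   the target's mean/SD; `"resample"` permutes the observed lengths
#'   (sensitivity mode).
#' @param small_sample_correction If `TRUE`, p-values use `(k + 1) /
#'   (n_iter + 1)`; off by default.
#' @return An object of class `perm_enrichment`: `$results` tibble
#'   (`repeat_class`, `metric`, `observed`, `baseline`, `fold`, `p_enrich`,
#'   `p_deplete`), `$null` (list of metric matrices, `n_iter` x classes),
#'   and the matched length parameters. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
permutation_test <- function(target, repeats, genome, n_iter = 1000,
                             seed = 1L,
                             metrics = c("avg_length", "length_pct",
                                         "count_per_mb"),
                             classes = NULL,
                             length_mode = c("normal", "resample"),
                             small_sample_correction = FALSE) {
  stopifnot(n_iter >= 1)
  length_mode <- match.arg(length_mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  index <- repeat_index(repeats, genome)
  if (!is.null(classes)) {
    miss <- setdiff(classes, names(index$classes))
    if (length(miss) > 0) {
      abort(paste0("Repeat class(es) absent from annotation: ",
                   paste(miss, collapse = ", ")))
    }
    index$classes <- index$classes[classes]
  }
  cls_names <- names(index$classes)
  obs <- repeat_content(target, repeats, genome, index = index)

  tlens <- target$end - target$start
  n <- nrow(target)
  mean_len <- mean(tlens); sd_len <- if (n > 1) sd(tlens) else 0

  null_vals <- map(metrics, ~ matrix(
    NA_real_, nrow = n_iter, ncol = length(cls_names),
    dimnames = list(NULL, cls_names)))
  names(null_vals) <- metrics

  off <- genome_offsets(index$genome)
  glen <- index$genome$length
  gprob <- glen / sum(glen)

  for (i in seq_len(n_iter)) {
    with_seed(derive_seed(seed, "perm", i), {
      lens <- if (length_mode == "resample") {
        tlens[sample.int(n, n)]
      } else {
        pmin(pmax(50, round(rnorm(n, mean_len, sd_len))), max(glen))
      }
      ci <- sample.int(length(glen), n, replace = TRUE, prob = gprob)
      L <- glen[ci]
      refit <- lens > L
      for (k in 1:1000) {
        if (!any(refit)) break
        ci[refit] <- sample.int(length(glen), sum(refit), replace = TRUE,
                                prob = gprob)
        L <- glen[ci]
        refit <- lens > L
      }
      starts <- floor(runif(n) * (L - lens + 1)) + off[ci]
      m <- merge_linear(starts, starts + lens)
      tbp <- sum(m[, 2] - m[, 1])
      for (cls in cls_names) {
        cc <- class_content(index$classes[[cls]], m)
        vals <- c(
          avg_length = if (cc["count"] > 0) cc[["length_bp"]] / cc[["count"]] else 0,
          length_pct = 100 * cc[["length_bp"]] / tbp,
          count_per_mb = cc[["count"]] / (tbp / 1e6)
        )
        for (mt in metrics) null_vals[[mt]][i, cls] <- vals[[mt]]
      }
    })
  }

  base <- genome_baseline(index)
  res <- list()
  for (mt in metrics) {
    ob <- setNames(obs[[mt]], obs$repeat_class)[cls_names]
    bl <- setNames(base[[mt]], base$repeat_class)[cls_names]
    k_gt <- colSums(null_vals[[mt]] > rep(ob, each = n_iter))
    k_lt <- colSums(null_vals[[mt]] < rep(ob, each = n_iter))
    if (small_sample_correction) {
      p_en <- (k_gt + 1) / (n_iter + 1); p_de <- (k_lt + 1) / (n_iter + 1)
    } else {
      p_en <- k_gt / n_iter; p_de <- k_lt / n_iter
    }
    res[[mt]] <- tibble(
      repeat_class = cls_names, metric = mt,
      observed = unname(ob), baseline = unname(bl),
      fold = unname(ifelse(bl > 0, ob / bl, NA_real_)),
      p_enrich = unname(p_en), p_deplete = unname(p_de)
    )
  }

  structure(list(
    results = bind_rows(res),
    null = null_vals,
    n_iter = n_iter, seed = seed,
    target_n = n, target_mean_len = mean_len, target_sd_len = sd_len,
    length_mode = length_mode,
    small_sample_correction = small_sample_correction
  ), class = "perm_enrichment")
}

#' @export
print.perm_enrichment <- function(x, ...) {
  cat(sprintf(
    "Random-region permutation enrichment test (%d iterations, seed %d)\n",
    x$n_iter, x$seed))
  cat(sprintf("Target: %d regions, mean length %.0f bp (SD %.0f)\n",
              x$target_n, x$target_mean_len, x$target_sd_len))
  print(x$results, n = Inf)
  invisible(x)
}

#' Format an empirical permutation p-value
#'
#' A p of 0 from `k / n_iter` is reported as an upper bound, e.g.
#' `"< 0.001"` at 1000 iterations.
#' @param p Empirical p-value(s).
#' @param n_iter Number of iterations used.
#' @return Character vector.
#' @export
format_empirical_p <- function(p, n_iter) {
  ifelse(p == 0, paste0("< ", format(1 / n_iter, scientific = FALSE)),
         format(p, digits = 3, scientific = FALSE))
}

#' Repeat enrichment folds for a target and its flanks
#'
#' Convenience wrapper computing observed/baseline folds for the target
#' region set and fixed-width flank sets (default 5 kb and 20 kb), the decay
#' pattern used to argue that repeat co-location is local to the regions
#' themselves.
#'
#' @param target Region table.
#' @param repeats Repeat annotation.
#' @param genome Genome tibble.
#' @param flank_sizes Flank widths in bp.
#' @return Tibble: `set` (`"target"`, `"flank_5kb"`, ...), `repeat_class`,
#'   `metric`, `observed`, `baseline`, `fold`.
#' @export
enrichment_folds <- function(target, repeats, genome,
                             flank_sizes = c(5000, 20000)) {
  index <- repeat_index(repeats, genome)
  base <- genome_baseline(index) |>
    tidyr::pivot_longer(c(avg_length, length_pct, count_per_mb),
                        names_to = "metric", values_to = "baseline")
  sets <- c(list(target = target),
            setNames(map(flank_sizes,
                         ~ flank_regions(target, .x, genome)),
                     paste0("flank_", flank_sizes / 1000, "kb")))
  imap(sets, function(rg, nm) {
    repeat_content(rg, repeats, genome, index = index) |>
      tidyr::pivot_longer(c(avg_length, length_pct, count_per_mb),
                          names_to = "metric", values_to = "observed") |>
      mutate(set = nm) |>
      select(set, repeat_class, metric, observed)
  }) |>
    bind_rows() |>
    left_join(base, by = c("repeat_class", "metric")) |>
    mutate(fold = ifelse(baseline > 0, observed / baseline, NA_real_))
}
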