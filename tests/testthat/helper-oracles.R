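# Brute-force oracles, written independently of the package internals:
# naive pairwise/per-record computations used to cross-check the interval
# algebra and the exact tests.

# O(n^2) brute-force merge: build the full pairwise "within gap" linkage
# graph, take its transitive closure by label propagation, and emit the
# hull (min start, max end) of every connected component
oracle_merge <- function(regions, gap = 0) {
  n <- nrow(regions)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  lab <- seq_len(n)
  linked <- function(i, j) {
    regions$chrom[i] == regions$chrom[j] &&
      regions$start[i] <= regions$end[j] + gap &&
      regions$start[j] <= regions$end[i] + gap
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (lab[i] != lab[j] && linked(i, j)) {
          new <- min(lab[i], lab[j])
          lab[lab == lab[i] | lab == lab[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(lab), function(l) {
    idx <- which(lab == l)
    data.frame(chrom = regions$chrom[idx[1]],
               start = min(regions$start[idx]),
               end = max(regions$end[idx]))
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  tibble::as_tibble(out)
}

# subtract a set of intervals from one interval (same chromosome, bp-wise)
oracle_subtract_one <- function(s, e, subs, sube) {
  pieces <- list(c(s, e))
  for (k in seq_along(subs)) {
    nxt <- list()
    for (p in pieces) {
      if (sube[k] <= p[1] || subs[k] >= p[2]) {
        nxt <- c(nxt, list(p))
      } else {
        if (subs[k] > p[1]) nxt <- c(nxt, list(c(p[1], subs[k])))
        if (sube[k] < p[2]) nxt <- c(nxt, list(c(sube[k], p[2])))
      }
    }
    pieces <- nxt
  }
  pieces
}

# per-region construct-then-subtract flank oracle
oracle_flanks <- function(regions, size, genome, subtract = TRUE) {
  len <- stats::setNames(genome$length, genome$chrom)
  fl <- list()
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    l1 <- max(0, regions$start[i] - size); l2 <- regions$start[i]
    r1 <- regions$end[i]; r2 <- min(len[[ch]], regions$end[i] + size)
    if (l1 < l2) fl <- c(fl, list(data.frame(chrom = ch, start = l1, end = l2)))
    if (r1 < r2) fl <- c(fl, list(data.frame(chrom = ch, start = r1, end = r2)))
  }
  if (length(fl) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  fl <- do.call(rbind, fl)
  merged_fl <- oracle_merge(fl)
  if (!subtract) return(merged_fl)
  inputs <- oracle_merge(regions[, c("chrom", "start", "end")])
  out <- list()
  for (i in seq_len(nrow(merged_fl))) {
    ch <- merged_fl$chrom[i]
    sub <- inputs[inputs$chrom == ch, , drop = FALSE]
    pieces <- oracle_subtract_one(merged_fl$start[i], merged_fl$end[i],
                                  sub$start, sub$end)
    for (p in pieces) {
      out <- c(out, list(data.frame(chrom = ch, start = p[1], end = p[2])))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  tibble::as_tibble(out)
}

# per-feature intersection oracle for repeat content of one class:
# bp of overlap with the merged target footprint, and features touched
oracle_class_content <- function(target, class_feats) {
  m <- oracle_merge(target[, c("chrom", "start", "end")])
  bp <- 0; touched <- 0
  for (j in seq_len(nrow(class_feats))) {
    same <- m$chrom == class_feats$chrom[j]
    if (!any(same)) next
    ov <- pmin(m$end[same], class_feats$end[j]) -
      pmax(m$start[same], class_feats$start[j])
    ov <- ov[ov > 0]
    if (length(ov) > 0) { bp <- bp + sum(ov); touched <- touched + 1 }
  }
  list(length_bp = bp, count = touched,
       target_bp = sum(m$end - m$start))
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration
# for the 2x2 table (a, b; c, d): sum P(tables) <= P(observed) * (1 + eps)
oracle_fisher_p <- function(a, b, c, d) {
  k <- a + b          # target size
  white <- a + c      # genes with the term
  n <- a + b + c + d
  lo <- max(0, k - (n - white)); hi <- min(k, white)
  probs <- stats::dhyper(lo:hi, white, n - white, k)
  p_obs <- stats::dhyper(a, white, n - white, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random region fixture on a small genome
random_fixture <- function(n, genome, max_len = 5e4, seed = 1) {
  withr::with_seed(seed, {
    ci <- sample.int(nrow(genome), n, replace = TRUE)
    L <- genome$length[ci]
    lens <- pmax(1, round(stats::runif(n, 1, max_len)))
    lens <- pmin(lens, L)
    s <- floor(stats::runif(n) * (L - lens + 1))
    tibble::tibble(chrom = genome$chrom[ci], start = s, end = s + lens)
  })
}

expect_same_regions <- function(x, y) {
  xs <- dplyr::arrange(tibble::as_tibble(x[, c("chrom", "start", "end")]),
                       chrom, start, end)
  ys <- dplyr::arrange(tibble::as_tibble(y[, c("chrom", "start", "end")]),
                       chrom, start, end)
  expect_equal(as.data.frame(xs), as.data.frame(ys), ignore_attr = TRUE)
}
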