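#' Define a genome as an ordered chromosome-size table
#'
#' The genome table fixes the coordinate space for every other function in the
#' package: all intervals are 0-based half-open `[start, end)` and must fall
#' inside `[0, length)` of a listed chromosome. Conversion to the 1-based
#' conventions of VCF and GRanges happens only at format boundaries.
#'
#' @param chrom Character vector of unique chromosome names, in order.
#' @param length Numeric vector of chromosome lengths in bp (> 0).
#' @return A tibble with columns `chrom`, `length`.
#' @examples
#' genome_def(c("chr1", "chr2"), c(1e6, 2e6))
#' @export
genome_def <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    abort("`chrom` and `length` must have the same length.")
  }
  if (anyDuplicated(chrom)) {
    abort(paste0("Duplicated chromosome names: ",
                 paste(unique(chrom[duplicated(chrom)]), collapse = ", ")))
  }
  if (any(!is.finite(length) | length <= 0)) {
    abort("All chromosome lengths must be finite and > 0.")
  }
  tibble(chrom = chrom, length = length)
}

validate_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome))) {
    abort("`genome` must be a data frame with columns `chrom` and `length` (see genome_def()).")
  }
  invisible(genome)
}

genome_size <- function(genome) sum(genome$length)

#' Read / write a chrom.sizes table
#'
#' Two-column tab-separated `name<TAB>length`, the dialect used by UCSC tools.
#'
#' @param path File path.
#' @param genome A genome table from [genome_def()].
#' @return `read_chrom_sizes()` returns a genome tibble; `write_chrom_sizes()`
#'   returns `path` invisibly.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = readr::cols(chrom = "c", length = "d"),
                       progress = FALSE)
  genome_def(x$chrom, x$length)
}

#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(genome, path) {
  validate_genome(genome)
  readr::write_tsv(genome, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# ---- region table <-> GRanges conversion (0-based half-open <-> 1-based closed)

validate_regions <- function(regions, genome = NULL) {
  if (!is.data.frame(regions) ||
      !all(c("chrom", "start", "end") %in% names(regions))) {
    abort("A region table needs columns `chrom`, `start`, `end`.")
  }
  if (nrow(regions) > 0) {
    bad <- regions$start < 0 | regions$start >= regions$end
    if (any(bad)) {
      abort(sprintf("%d region(s) violate 0 <= start < end.", sum(bad)))
    }
    if (!is.null(genome)) {
      validate_genome(genome)
      unknown <- setdiff(unique(regions$chrom), genome$chrom)
      if (length(unknown) > 0) {
        abort(paste0("Regions on chromosomes absent from the genome: ",
                     paste(unknown, collapse = ", ")))
      }
      len <- setNames(genome$length, genome$chrom)
      over <- regions$end > len[regions$chrom]
      if (any(over)) {
        abort(sprintf("%d region(s) extend past their chromosome end.", sum(over)))
      }
    }
  }
  invisible(regions)
}

as_granges <- function(regions, genome = NULL) {
  seqinfo <- NULL
  if (!is.null(genome)) {
    seqinfo <- GenomeInfoDb::Seqinfo(seqnames = genome$chrom,
                                     seqlengths = genome$length)
  }
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end),
    seqinfo = seqinfo
  )
}

as_region_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = BiocGenerics::end(gr)
  )
}

# Linear ("unrolled") genome coordinates: chromosomes concatenated in order.
genome_offsets <- function(genome) {
  setNames(cumsum(c(0, head(genome$length, -1))), genome$chrom)
}

to_linear <- function(regions, genome) {
  off <- genome_offsets(genome)
  cbind(regions$start + off[regions$chrom], regions$end + off[regions$chrom])
}

# ---- deterministic sub-seed derivation -------------------------------------
# One master seed per run; sub-streams keyed by a label so adding samples or
# stages does not shift earlier draws. Kept below 2^31.
derive_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(as.character(label)) * (seq_along(utf8ToInt(as.character(label))) %% 97 + 1))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + as.numeric(index) * 7919) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
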