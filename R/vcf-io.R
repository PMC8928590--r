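#' Write per-sample LUMPY-dialect SV VCFs
#'
#' One VCF v4.2 per sample with INFO keys `SVTYPE`, `END`, `SVLEN`, `PE`,
#' `SR` (and `MATEID` for BND mates). Internal 0-based half-open coordinates
#' become 1-based `POS`/`END` on output.
#'
#' @param calls Call tibble (as produced by [generate_callsets()]).
#' @param genome Genome tibble (for `##contig` header lines).
#' @param dir Output directory; files are named `<sample_id>.vcf`.
#' @return Named character vector of file paths, invisibly.
#' @export
write_callset_vcfs <- function(calls, genome, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (sid in unique(calls$sample_id)) {
    path <- file.path(dir, paste0(sid, ".vcf"))
    write_sv_vcf(calls[calls$sample_id == sid, ], genome, path)
    paths[sid] <- path
  }
  invisible(paths)
}

#' @rdname write_callset_vcfs
#' @param path Output file for a single sample's calls.
#' @export
write_sv_vcf <- function(calls, genome, path) {
  validate_genome(genome)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=spermcnv-sim",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Number of paired-end reads supporting the variant\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Number of split reads supporting the variant\">",
    "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"ID of mate breakend\">",
    sprintf("##contig=<ID=%s,length=%d>", genome$chrom, as.integer(genome$length)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(calls) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  calls <- calls |> arrange(match(chrom, genome$chrom), start)
  is_bnd <- calls$svtype == "BND"
  id <- if ("bnd_id" %in% names(calls)) {
    ifelse(is_bnd & !is.na(calls$bnd_id), calls$bnd_id, calls$event_id)
  } else calls$event_id
  svlen <- ifelse(calls$svtype == "DEL", -calls$length, calls$length)
  info <- ifelse(
    is_bnd,
    sprintf("SVTYPE=BND;MATEID=%s;PE=%d;SR=%d",
            if ("mate_id" %in% names(calls)) calls$mate_id else ".",
            as.integer(calls$pe), as.integer(calls$sr)),
    sprintf("SVTYPE=%s;END=%d;SVLEN=%d;PE=%d;SR=%d",
            calls$svtype, as.integer(calls$end), as.integer(svlen),
            as.integer(calls$pe), as.integer(calls$sr))
  )
  alt <- ifelse(is_bnd,
                sprintf("N[%s:%d[", calls$chrom, as.integer(calls$start + 2)),
                paste0("<", calls$svtype, ">"))
  body <- sprintf("%s\t%d\t%s\tN\t%s\t.\t.\t%s",
                  calls$chrom, as.integer(calls$start + 1), id, alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse a LUMPY-dialect SV VCF
#'
#' Reads a VCF v4.2 with `SVTYPE` (and `END`, `PE`, `SR`) INFO keys, as
#' written by LUMPY/smoove, and returns calls in the package's internal
#' convention: 0-based half-open intervals (`start = POS - 1`, `end = END`).
#' DEL/DUP/INV records missing `END` are dropped individually with a
#' warning; BND records keep their single breakend position (`end = start +
#' 1`, undefined length) and carry `MATEID` when present.
#'
#' @param path VCF file.
#' @param sample_id Sample label to stamp on every record.
#' @param group Group label (e.g. `"Sample1-sperms"`).
#' @return Call tibble: `sample_id`, `group`, `svtype`, `chrom`, `start`,
#'   `end`, `length`, `pe`, `sr`, `bnd_id`, `mate_id`.
#' @export
parse_sv_vcf <- function(path, sample_id, group = NA_character_) {
  if (!file.exists(path)) {
    abort(paste0("VCF not found: ", path))
  }
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) {
                    abort(paste0("Cannot read VCF ", path, ": ",
                                 conditionMessage(e)))
                  })
  meta <- vcf@meta
  if (!any(grepl("##INFO=<ID=SVTYPE", meta, fixed = TRUE))) {
    abort(paste0("VCF ", path, " has no SVTYPE INFO header; not an SV VCF."))
  }
  fx <- vcf@fix
  if (is.null(fx) || nrow(fx) == 0) {
    return(tibble(sample_id = character(), group = character(),
                  svtype = character(), chrom = character(),
                  start = numeric(), end = numeric(), length = numeric(),
                  pe = numeric(), sr = numeric(),
                  bnd_id = character(), mate_id = character()))
  }
  get_info <- function(key) {
    suppressWarnings(vcfR::extract.info(vcf, element = key))
  }
  svtype <- unname(get_info("SVTYPE"))
  endv <- unname(suppressWarnings(as.numeric(get_info("END"))))
  pe <- unname(suppressWarnings(as.numeric(get_info("PE"))))
  sr <- unname(suppressWarnings(as.numeric(get_info("SR"))))
  mate <- unname(get_info("MATEID"))
  out <- tibble(
    sample_id = sample_id, group = group,
    svtype = svtype,
    chrom = fx[, "CHROM"],
    start = as.numeric(fx[, "POS"]) - 1,
    end = endv,
    pe = ifelse(is.na(pe), 0, pe),
    sr = ifelse(is.na(sr), 0, sr),
    bnd_id = ifelse(svtype == "BND", fx[, "ID"], NA_character_),
    mate_id = ifelse(svtype == "BND", mate, NA_character_)
  )
  is_bnd <- out$svtype == "BND"
  out$end[is_bnd] <- out$start[is_bnd] + 1
  drop <- !is_bnd & is.na(out$end)
  if (any(drop)) {
    warn(sprintf("%s: dropped %d non-BND record(s) with missing END.",
                 path, sum(drop)))
    out <- out[!drop, ]
    is_bnd <- out$svtype == "BND"
  }
  out$length <- ifelse(is_bnd, NA_real_, out$end - out$start)
  select(out, sample_id, group, svtype, chrom, start, end, length, pe, sr,
         bnd_id, mate_id)
}
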