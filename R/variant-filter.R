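#' Read variant calls from a VCF file
#'
#' Parses VCF v4.x via vcfR and returns one call per (site, alternative
#' allele): multi-allelic records are split. Read depth is taken from the
#' first sample's FORMAT DP when present, otherwise from INFO DP, otherwise 0.
#' Missing QUAL is treated as 0.
#'
#' @param path VCF file path (plain text or bgzipped)
#' @return data.frame with columns chrom, pos, id, ref, alt, qual, depth,
#'   genotype (NA when no sample column), is_snv
#' @export
read_vcf <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop(sprintf("failed to parse VCF %s: %s", path, conditionMessage(e)))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), qual = numeric(),
                      depth = integer(), genotype = character(),
                      is_snv = logical(), stringsAsFactors = FALSE))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop(sprintf("malformed VCF %s: non-numeric POS at record %d", path, which(is.na(pos))[1L]))
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0

  depth <- rep.int(0L, n)
  info_dp <- suppressWarnings(as.integer(vcfR::extract.info(v, element = "DP")))
  depth[!is.na(info_dp)] <- info_dp[!is.na(info_dp)]
  gt <- rep(NA_character_, n)
  if (ncol(v@gt) >= 2L) {
    fmt_dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1L]))
    depth[!is.na(fmt_dp)] <- fmt_dp[!is.na(fmt_dp)]
    gt <- unname(vcfR::extract.gt(v, element = "GT")[, 1L])
  }

  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  reps <- pmax(lengths(alt_list), 1L)
  idx <- rep(seq_len(n), reps)
  alt <- unlist(lapply(alt_list, function(a) if (length(a) == 0L) NA_character_ else a))
  ref <- fix[idx, "REF"]
  out <- data.frame(
    chrom = fix[idx, "CHROM"],
    pos = pos[idx],
    id = ifelse(is.na(fix[idx, "ID"]) | fix[idx, "ID"] == ".", NA_character_, fix[idx, "ID"]),
    ref = ref,
    alt = alt,
    qual = qual[idx],
    depth = depth[idx],
    genotype = gt[idx],
    stringsAsFactors = FALSE
  )
  out$is_snv <- !is.na(out$alt) & nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% DNA_BASES & out$alt %in% DNA_BASES
  rownames(out) <- NULL
  out
}

#' Depth / quality / type / in-peak variant filters
#'
#' A call passes when depth >= `min_depth`, site quality >= `min_qual`, both
#' alleles are single bases, and the position lies inside the consensus peak
#' set. Each failing call is attributed to the first rule it fails, in the
#' order depth, quality, type, peak; the attribution order affects only the
#' report breakdown, never the pass set.
#'
#' @param calls data.frame from [read_vcf()]
#' @param peaks consensus peak set (or any interval data.frame); NULL skips
#'   the in-peak rule
#' @param min_depth minimum read depth (calls with fewer reads fail)
#' @param min_qual minimum phred-scaled site quality
#' @return list with `passing` (data.frame subset) and `report`
#'   (class `filter_report`: disposition counts partitioning the input)
#' @export
apply_filters <- function(calls, peaks, min_depth = 10, min_qual = 20) {
  disposition <- rep("pass", nrow(calls))
  in_peak <- if (is.null(peaks)) rep(TRUE, nrow(calls)) else {
    peaks_contain(peaks, calls$chrom, calls$pos)
  }
  disposition[!in_peak] <- "fail_outside_peak"
  disposition[!calls$is_snv] <- "fail_not_snv"
  disposition[calls$qual < min_qual] <- "fail_qual"
  disposition[calls$depth < min_depth] <- "fail_depth"
  levels <- c("pass", "fail_depth", "fail_qual", "fail_not_snv", "fail_outside_peak")
  counts <- table(factor(disposition, levels = levels))
  report <- structure(
    list(counts = as.list(as.integer(counts)), total = nrow(calls),
         min_depth = min_depth, min_qual = min_qual),
    class = "filter_report"
  )
  names(report$counts) <- levels
  list(passing = calls[disposition == "pass", , drop = FALSE],
       report = report,
       disposition = disposition)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Variant filter report (%d calls; depth >= %g, qual >= %g):\n",
              x$total, x$min_depth, x$min_qual))
  for (nm in names(x$counts)) cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  frac <- if (x$total > 0) x$counts$pass / x$total else NA_real_
  cat(sprintf("  pass fraction      %.3f\n", frac))
  invisible(x)
}

#' Write filtered calls as TSV
#' @param calls data.frame of variant calls
#' @param path output path
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
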