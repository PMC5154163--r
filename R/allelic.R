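#' Read a per-site base-count pileup table
#'
#' Tab-separated with header columns `chrom`, `pos` (1-based) and per-base
#' read counts `A`, `C`, `G`, `T`.
#'
#' @param path file path
#' @return data.frame of per-site counts
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", DNA_BASES)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("pileup %s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  df
}

#' Allele read counts at a variant site
#'
#' Counts reads supporting the reference base, the alternative base, and any
#' other base. The source is either a pileup count table ([read_pileup()]) or
#' an indexed BAM file (counted via Rsamtools with a minimum base quality).
#'
#' @param source pileup data.frame, pileup TSV path, or path to an indexed BAM
#' @param chrom,pos site (1-based)
#' @param ref,alt single-base alleles
#' @param min_base_quality minimum base quality for BAM counting
#' @return list with `n_ref`, `n_alt`, `n_other` and `vaf`
#'   (= n_alt / (n_ref + n_alt); NA when no informative reads)
#' @export
count_alleles <- function(source, chrom, pos, ref, alt, min_base_quality = 20L) {
  if (is.character(source) && length(source) == 1L && grepl("\\.bam$", source)) {
    counts <- bam_base_counts(source, chrom, pos, min_base_quality)
  } else {
    df <- if (is.character(source)) read_pileup(source) else source
    row <- df[df$chrom == chrom & df$pos == pos, , drop = FALSE]
    if (nrow(row) == 0L) stop(sprintf("site %s:%d absent from pileup source", chrom, pos))
    counts <- unlist(row[1L, DNA_BASES])
  }
  counts <- stats::setNames(as.integer(counts), DNA_BASES)
  n_ref <- counts[[toupper(ref)]]
  n_alt <- counts[[toupper(alt)]]
  n_other <- sum(counts) - n_ref - n_alt
  vaf <- if (n_ref + n_alt > 0L) n_alt / (n_ref + n_alt) else NA_real_
  list(n_ref = n_ref, n_alt = n_alt, n_other = n_other, vaf = vaf)
}

bam_base_counts <- function(bam, chrom, pos, min_base_quality) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM pileup counting requires the Rsamtools package")
  }
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos)))
  pp <- Rsamtools::PileupParam(
    min_base_quality = as.integer(min_base_quality),
    min_mapq = 0L, min_nucleotide_depth = 1L,
    distinguish_strands = FALSE, include_deletions = FALSE,
    include_insertions = FALSE, max_depth = 100000L)
  res <- Rsamtools::pileup(bam, scanBamParam = param, pileupParam = pp)
  res <- res[res$pos == pos, , drop = FALSE]
  counts <- stats::setNames(integer(4), DNA_BASES)
  if (nrow(res) > 0L) {
    agg <- tapply(res$count, as.character(res$nucleotide), sum)
    hit <- intersect(names(agg), DNA_BASES)
    counts[hit] <- as.integer(agg[hit])
  }
  counts
}

#' Chi-square test of allele enrichment
#'
#' One-degree-of-freedom goodness-of-fit of the (reference, alternative) read
#' counts against expected proportions (default 50:50, the heterozygous
#' null). Sites with fewer informative reads than `min_reads` are flagged and
#' not tested (p = NA). Counts supporting neither allele are excluded.
#'
#' @param n_ref,n_alt informative read counts
#' @param expected length-2 positive proportions (ref, alt) summing to 1
#' @param min_reads minimum informative coverage to run the test
#' @param yates apply Yates continuity correction
#' @return list with `n_ref`, `n_alt`, `vaf`, `chi2`, `p`,
#'   `sufficient_coverage`
#' @export
allele_enrichment_test <- function(n_ref, n_alt, expected = c(0.5, 0.5),
                                   min_reads = 10L, yates = FALSE) {
  if (any(expected <= 0) || abs(sum(expected) - 1) > 1e-9) {
    stop("expected proportions must be positive and sum to 1")
  }
  n <- n_ref + n_alt
  if (n == 0L) stop("no informative reads: both allele counts are zero")
  vaf <- n_alt / n
  sufficient <- n >= min_reads
  obs <- c(n_ref, n_alt)
  exp <- expected * n
  dev <- abs(obs - exp)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / exp)
  p <- if (sufficient) stats::pchisq(chi2, df = 1L, lower.tail = FALSE) else NA_real_
  list(n_ref = n_ref, n_alt = n_alt, vaf = vaf, chi2 = chi2, p = p,
       sufficient_coverage = sufficient)
}

#' Allele-specific binding tests for a set of variant sites
#'
#' @param sites data.frame with chrom, pos, ref, alt
#' @param source pileup source (see [count_alleles()])
#' @param expected,min_reads,yates see [allele_enrichment_test()]
#' @return data.frame of per-site counts, VAF, chi-square statistic and p
#' @export
allelic_binding_table <- function(sites, source, expected = c(0.5, 0.5),
                                  min_reads = 10L, yates = FALSE) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    cts <- count_alleles(source, sites$chrom[i], sites$pos[i],
                         sites$ref[i], sites$alt[i])
    if (cts$n_ref + cts$n_alt == 0L) {
      return(data.frame(chrom = sites$chrom[i], pos = sites$pos[i],
                        ref = sites$ref[i], alt = sites$alt[i],
                        n_ref = cts$n_ref, n_alt = cts$n_alt, n_other = cts$n_other,
                        vaf = NA_real_, chi2 = NA_real_, p = NA_real_,
                        sufficient_coverage = FALSE, stringsAsFactors = FALSE))
    }
    tst <- allele_enrichment_test(cts$n_ref, cts$n_alt, expected, min_reads, yates)
    data.frame(chrom = sites$chrom[i], pos = sites$pos[i],
               ref = sites$ref[i], alt = sites$alt[i],
               n_ref = cts$n_ref, n_alt = cts$n_alt, n_other = cts$n_other,
               vaf = tst$vaf, chi2 = tst$chi2, p = tst$p,
               sufficient_coverage = tst$sufficient_coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
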