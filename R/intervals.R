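#' Read a BED6 / narrowPeak peak file
#'
#' Coordinates are kept in the BED convention: 0-based half-open. Track,
#' browser and comment lines are ignored; input need not be sorted.
#'
#' @param path file path
#' @return data.frame with columns chrom, start, end (and name, score, strand
#'   when present), sorted by chrom then start
#' @export
read_peaks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\\s+")
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop(sprintf("peak file %s: fewer than 3 fields at line %d",
                 path, idx[which(ncols < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("peak file %s: non-numeric coordinate at line %d", path, idx[bad[1L]]))
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop(sprintf("peak file %s: start >= end (or negative) at line %d", path, idx[bad[1L]]))
  }
  out <- data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
  if (all(ncols >= 4L)) out$name <- vapply(fields, `[[`, character(1), 4L)
  if (all(ncols >= 5L)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
  if (all(ncols >= 6L)) out$strand <- vapply(fields, `[[`, character(1), 6L)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED
#'
#' For [consensus_peaks()] objects the per-interval support count is written
#' in the score column.
#' @param x data.frame of intervals (chrom/start/end, optional name/score/strand)
#'   or a `consensus_peaks` object
#' @param path output path
#' @export
write_peaks <- function(x, path) {
  if (inherits(x, "consensus_peaks")) {
    df <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                     name = sprintf("consensus_%d", seq_len(nrow(x))),
                     score = x$support, strand = ".",
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                     name = x$name %||% sprintf("peak_%d", seq_len(nrow(x))),
                     score = x$score %||% 0,
                     strand = x$strand %||% ".",
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' k-of-n consensus binding sites
#'
#' A genomic position belongs to the consensus when it is covered by peaks
#' from at least `k` of the `n` input datasets (each dataset counts at most
#' once per base; overlapping peaks within one dataset are merged first).
#' Maximal runs of qualifying positions are emitted as intervals; the support
#' of an interval is the minimum dataset coverage across its positions, so
#' runs are split where coverage crosses `k` but not at every coverage change.
#'
#' @param peak_sets list of interval data.frames (one per dataset)
#' @param k minimum number of supporting datasets
#' @return a `consensus_peaks` data.frame (chrom, start, end, support) with
#'   attributes `k` and `n`
#' @export
consensus_peaks <- function(peak_sets, k) {
  n <- length(peak_sets)
  if (n < 1L) stop("at least one peak set is required")
  if (k < 1L || k > n) stop(sprintf("k must be between 1 and n = %d datasets", n))
  chroms <- sort(unique(unlist(lapply(peak_sets, function(p) p$chrom))))
  out <- list()
  for (ch in chroms) {
    covs <- lapply(peak_sets, function(p) {
      p <- p[p$chrom == ch, , drop = FALSE]
      if (nrow(p) == 0L) return(NULL)
      ## BED half-open -> IRanges closed 1-based
      IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end))
    })
    covs <- covs[!vapply(covs, is.null, logical(1))]
    if (length(covs) < k) next
    maxend <- max(vapply(covs, function(r) max(IRanges::end(r)), numeric(1)))
    depth <- Reduce(`+`, lapply(covs, function(r) IRanges::coverage(r, width = maxend)))
    runs <- IRanges::slice(depth, lower = k, rangesOnly = FALSE)
    if (length(runs) == 0L) next
    out[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(runs) - 1L,
      end = IRanges::end(runs),
      support = as.integer(IRanges::viewMins(runs)),
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               support = integer(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "k") <- as.integer(k)
  attr(res, "n") <- as.integer(n)
  class(res) <- c("consensus_peaks", "data.frame")
  res
}

#' @export
print.consensus_peaks <- function(x, ...) {
  st <- peak_stats(x)
  cat(sprintf("Consensus peak set: %d intervals (k = %d of n = %d), mean width %s bp\n",
              st$count, attr(x, "k"), attr(x, "n"),
              if (is.na(st$mean_width)) "NA" else sprintf("%.1f", st$mean_width)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Interval-set summary statistics
#' @param x interval data.frame (consensus_peaks or plain chrom/start/end)
#' @return list with `count` and `mean_width` (NA when empty)
#' @export
peak_stats <- function(x) {
  count <- nrow(x)
  list(count = count,
       mean_width = if (count == 0L) NA_real_ else mean(x$end - x$start))
}

#' Point-in-peak query
#'
#' Tests whether 1-based genomic positions fall inside the interval set
#' (binary search per chromosome).
#'
#' @param x interval data.frame (0-based half-open)
#' @param chrom,pos vectors of chromosome names and 1-based positions
#' @return logical vector
#' @export
peaks_contain <- function(x, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  pos0 <- as.integer(pos) - 1L
  res <- logical(length(pos))
  for (ch in unique(chrom)) {
    sub <- x[x$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (nrow(sub) == 0L) next
    ## merge so binary search on starts is valid even for overlapping input
    merged <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1L, end = sub$end))
    starts <- IRanges::start(merged) - 1L
    ends <- IRanges::end(merged)
    idx <- findInterval(pos0[sel], starts)
    hit <- idx >= 1L
    hit[hit] <- pos0[sel][hit] < ends[idx[hit]]
    res[sel] <- hit
  }
  res
}
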