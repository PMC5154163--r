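#' Reference/alternative allele contexts around a variant
#'
#' Extracts the 2w-1 bases of reference sequence centered on a SNV and builds
#' the pair of in-silico sequences carrying the reference and the alternative
#' allele; every motif window that covers the variant is contained in this
#' context, so the best anchored hit over the context equals the best hit in
#' the genome.
#'
#' @param chrom,pos variant location (`pos` 1-based)
#' @param ref,alt single-base alleles
#' @param genome a named [Biostrings::DNAStringSet] (or named character vector
#'   of contig sequences)
#' @param w motif width
#' @return list with `chrom`, `pos`, `ref`, `alt`, `ctx_ref`, `ctx_alt`,
#'   `anchor` (1-based offset of the variant within the contexts, always `w`)
#'   and `ref_mismatch` (TRUE when the genome base differs from `ref`)
#' @export
build_contexts <- function(chrom, pos, ref, alt, genome, w) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L) stop("build_contexts requires single-base alleles")
  if (ref == alt) stop("ref and alt alleles must differ")
  contig <- genome_sequence(genome, chrom)
  L <- nchar(contig)
  if (pos < 1L || pos > L) stop(sprintf("position %s:%d outside contig bounds", chrom, pos))
  if (pos - (w - 1L) < 1L || pos + (w - 1L) > L) {
    stop(sprintf("variant %s:%d has fewer than w-1 = %d flanking bases", chrom, pos, w - 1L))
  }
  ctx <- toupper(substr(contig, pos - (w - 1L), pos + (w - 1L)))
  anchor <- w
  genome_base <- substr(ctx, anchor, anchor)
  mismatch <- genome_base != ref
  ctx_ref <- ctx
  substr(ctx_ref, anchor, anchor) <- ref
  ctx_alt <- ctx
  substr(ctx_alt, anchor, anchor) <- alt
  list(chrom = chrom, pos = pos, ref = ref, alt = alt,
       ctx_ref = ctx_ref, ctx_alt = ctx_alt, anchor = anchor,
       ref_mismatch = mismatch)
}

genome_sequence <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop(sprintf("contig '%s' not in genome", chrom))
    return(as.character(genome[[chrom]]))
  }
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop(sprintf("contig '%s' not in genome", chrom))
    return(genome[[chrom]])
  }
  stop("genome must be a named DNAStringSet or named character vector")
}

#' p-value-ratio statistic for one variant against one matrix
#'
#' The reference and alternative contexts are each independently scanned for
#' their best anchored motif hit (window and strand may differ between
#' alleles); each best score is converted to an exact tail p-value, and the
#' statistic is \eqn{\log_{10}(p_{ref}/p_{alt})}. Positive values mean the
#' alternative allele is the stronger predicted binder.
#'
#' @param lom a [log_odds()] matrix
#' @param d the matrix's [score_distribution()]
#' @param ctx_ref,ctx_alt allele context sequences
#' @param anchor 1-based variant offset within the contexts
#' @return list with `p_ref`, `p_alt`, `log_ratio` and `direction`
#'   ("increase" when p_alt < p_ref, otherwise "decrease")
#' @export
ratio_statistic <- function(lom, d, ctx_ref, ctx_alt, anchor) {
  hit_ref <- best_hit(lom, ctx_ref, anchor)
  hit_alt <- best_hit(lom, ctx_alt, anchor)
  p_ref <- score_pvalue(d, hit_ref$score)
  p_alt <- score_pvalue(d, hit_alt$score)
  list(
    p_ref = p_ref,
    p_alt = p_alt,
    log_ratio = log10(p_ref / p_alt),
    direction = if (p_alt < p_ref) "increase" else "decrease"
  )
}

#' Null distribution of the p-value-ratio statistic
#'
#' The null draws a 2w-1 context i.i.d. from the background model, places the
#' substitution at the center (anchor) position, draws the alternative base
#' uniformly from the three non-reference bases, and records the log10
#' p-value ratio. `mode = "exact"` enumerates all \eqn{4^{2w-1} \times 3}
#' (context, alternative) pairs with their background probabilities;
#' `mode = "monte_carlo"` samples them reproducibly from `seed`.
#'
#' @param lom a [log_odds()] matrix
#' @param d its [score_distribution()]
#' @param mode "exact" or "monte_carlo"
#' @param n_samples Monte-Carlo sample count (>= 1000)
#' @param seed integer seed for Monte-Carlo mode
#' @param max_enumeration cap on the exact enumeration size
#' @return an object of class `ratio_null`
#' @export
build_ratio_null <- function(lom, d, mode = c("monte_carlo", "exact"),
                             n_samples = 10000L, seed = 1L,
                             max_enumeration = 2^20) {
  stopifnot(inherits(lom, "log_odds_matrix"), inherits(d, "score_distribution"))
  mode <- match.arg(mode)
  w <- lom$width
  L <- 2L * w - 1L
  anchor <- w
  if (mode == "exact") {
    total <- 4^L * 3
    if (total > max_enumeration) {
      stop(sprintf(
        "exact null would enumerate %.0f cases (cap %.0f); use mode = 'monte_carlo'",
        total, max_enumeration))
    }
    codes <- enumerate_codes(L)
    logw <- matrix(log(lom$bg)[codes], nrow = nrow(codes))
    ctx_weight <- exp(rowSums(logw))
    p_ref <- score_pvalue(d, best_hit_batch_int(lom, codes, anchor) * lom$granularity)
    vals <- numeric(0)
    wts <- numeric(0)
    for (shift in 1:3) {
      alt_codes <- codes
      alt_codes[, anchor] <- ((codes[, anchor] - 1L + shift) %% 4L) + 1L
      p_alt <- score_pvalue(d, best_hit_batch_int(lom, alt_codes, anchor) * lom$granularity)
      vals <- c(vals, log10(p_ref / p_alt))
      wts <- c(wts, ctx_weight / 3)
    }
    ## aggregate duplicate ratio values
    key <- round(vals, 12)
    agg <- rowsum(wts, group = key)
    out <- list(values = as.numeric(rownames(agg)), weights = as.numeric(agg[, 1L]),
                mode = "exact", n_samples = length(vals), seed = NA_integer_)
  } else {
    if (n_samples < 1000L) stop("monte_carlo mode requires n_samples >= 1000")
    sampled <- with_subseed(seed, 0L, {
      codes <- matrix(
        sample.int(4L, n_samples * L, replace = TRUE, prob = lom$bg),
        nrow = n_samples)
      shift <- sample.int(3L, n_samples, replace = TRUE)
      list(codes = codes, shift = shift)
    })
    codes <- sampled$codes
    alt_codes <- codes
    alt_codes[, anchor] <- ((codes[, anchor] - 1L + sampled$shift) %% 4L) + 1L
    p_ref <- score_pvalue(d, best_hit_batch_int(lom, codes, anchor) * lom$granularity)
    p_alt <- score_pvalue(d, best_hit_batch_int(lom, alt_codes, anchor) * lom$granularity)
    out <- list(values = log10(p_ref / p_alt), weights = NULL,
                mode = "monte_carlo", n_samples = n_samples, seed = as.integer(seed))
  }
  out$matrix_id <- lom$matrix_id
  out$abs_sorted <- sort(abs(out$values))
  structure(out, class = "ratio_null")
}

#' @export
print.ratio_null <- function(x, ...) {
  cat(sprintf("p-value-ratio null for '%s': %s, %d %s\n",
              x$matrix_id, x$mode, x$n_samples,
              if (x$mode == "exact") "enumerated cases" else "samples"))
  invisible(x)
}

enumerate_codes <- function(L) {
  n <- 4^L
  codes <- matrix(0L, nrow = n, ncol = L)
  for (j in seq_len(L)) {
    codes[, j] <- rep(rep(1:4, each = 4^(L - j)), length.out = n)
  }
  codes
}

#' Two-sided null p-value of an observed log ratio
#'
#' \eqn{P(|T_{null}| \ge |t|)}. In Monte-Carlo mode an add-one correction
#' \eqn{(k+1)/(n+1)} keeps the p-value away from zero.
#'
#' @param null a [build_ratio_null()] object
#' @param observed_log_ratio observed log10 p-value ratio(s)
#' @return probabilities in (0, 1]
#' @export
null_pvalue <- function(null, observed_log_ratio) {
  stopifnot(inherits(null, "ratio_null"))
  tol <- 1e-9
  vapply(observed_log_ratio, function(t) {
    a <- abs(t)
    if (null$mode == "exact") {
      idx <- abs(null$values) >= a - tol
      max(sum(null$weights[idx]), 0)
    } else {
      k <- length(null$abs_sorted) - findInterval(a - tol, null$abs_sorted)
      (k + 1) / (null$n_samples + 1)
    }
  }, numeric(1))
}

#' Assess the motif impact of one variant against a panel of matrices
#'
#' Runs [ratio_statistic()] and [null_pvalue()] for each matrix. A matrix
#' calls the variant when its null p-value is below `alpha`; the adjusted
#' p-value is a Bonferroni correction over the matrices tested, and
#' `databases_supporting` lists the source tag of every matrix that
#' independently calls the variant.
#'
#' @param ctx a [build_contexts()] result
#' @param matrices list of [log_odds()] matrices
#' @param dists list of matching [score_distribution()]s
#' @param nulls list of matching [build_ratio_null()]s
#' @param alpha significance cutoff on the null p-value (default 0.05)
#' @return data.frame, one row per matrix, with columns chrom, pos, ref, alt,
#'   matrix_id, source, p_ref, p_alt, log_ratio, null_p, adjusted_p,
#'   direction, significant, databases_supporting
#' @export
assess_variant <- function(ctx, matrices, dists, nulls, alpha = 0.05) {
  stopifnot(length(matrices) >= 1L,
            length(dists) == length(matrices),
            length(nulls) == length(matrices))
  m <- length(matrices)
  rows <- lapply(seq_len(m), function(i) {
    st <- ratio_statistic(matrices[[i]], dists[[i]], ctx$ctx_ref, ctx$ctx_alt, ctx$anchor)
    np <- null_pvalue(nulls[[i]], st$log_ratio)
    data.frame(
      chrom = ctx$chrom, pos = ctx$pos, ref = ctx$ref, alt = ctx$alt,
      matrix_id = matrices[[i]]$matrix_id, source = matrices[[i]]$source,
      p_ref = st$p_ref, p_alt = st$p_alt, log_ratio = st$log_ratio,
      null_p = np, adjusted_p = min(1, np * m), direction = st$direction,
      significant = np < alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$databases_supporting <- paste(sort(unique(out$source[out$significant])), collapse = ",")
  out
}

#' Rank regSNV calls
#'
#' Ascending adjusted p-value; ties broken by decreasing |log ratio|, then by
#' genomic coordinate. The output is a permutation of the input rows.
#'
#' @param results data.frame as produced by [assess_variant()] rows
#' @return the reordered data.frame
#' @export
rank_regsnvs <- function(results) {
  if (nrow(results) == 0L) return(results)
  ord <- order(results$adjusted_p, -abs(results$log_ratio),
               results$chrom, results$pos)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
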