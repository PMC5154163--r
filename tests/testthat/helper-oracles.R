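# Independent brute-force oracles used to validate the dynamic-programming
# and aggregation code paths. These deliberately use plain enumeration and
# loops, never the package's DP/batch internals.

# all 4^L base-code sequences as an n x L integer matrix
enum_all_codes <- function(L) {
  n <- 4^L
  m <- matrix(0L, n, L)
  for (j in seq_len(L)) m[, j] <- rep(rep(1:4, each = 4^(L - j)), length.out = n)
  m
}

# exact distribution of total column scores of random w-mers, by enumeration;
# `scores` is a 4 x w matrix (continuous or integer), bg a length-4 prob vector
oracle_score_dist <- function(scores, bg) {
  w <- ncol(scores)
  codes <- enum_all_codes(w)
  tot <- numeric(nrow(codes))
  prob <- numeric(nrow(codes))
  for (i in seq_len(nrow(codes))) {
    s <- 0; p <- 1
    for (j in seq_len(w)) {
      s <- s + scores[codes[i, j], j]
      p <- p * bg[codes[i, j]]
    }
    tot[i] <- s
    prob[i] <- p
  }
  agg <- rowsum(prob, group = round(tot, 9))
  list(support = as.numeric(rownames(agg)), mass = as.numeric(agg[, 1]))
}

oracle_tail <- function(dist, s, tol = 1e-9) {
  sum(dist$mass[dist$support >= s - tol])
}

# best score over all strands/windows covering `anchor`, explicit loops
oracle_best_score <- function(scores, codes_row, anchor) {
  w <- ncol(scores)
  L <- length(codes_row)
  rc <- scores[4:1, w:1, drop = FALSE]
  best <- -Inf
  for (o in max(1, anchor - w + 1):min(L - w + 1, anchor)) {
    win <- codes_row[o:(o + w - 1)]
    if (anyNA(win)) next
    sf <- 0; sr <- 0
    for (j in seq_len(w)) {
      sf <- sf + scores[win[j], j]
      sr <- sr + rc[win[j], j]
    }
    best <- max(best, sf, sr)
  }
  best
}

# exact null of the log10 p-value ratio by full enumeration of contexts and
# alternative bases (weights from bg), independent of build_ratio_null
oracle_ratio_null <- function(lom, bg) {
  w <- lom$width
  L <- 2 * w - 1
  anchor <- w
  g <- lom$granularity
  sc <- lom$int_scores
  dist <- oracle_score_dist(sc, bg)
  tail_of <- function(s) oracle_tail(dist, s, tol = 0.5)  # integer grid
  codes <- enum_all_codes(L)
  vals <- numeric(0); wts <- numeric(0)
  for (i in seq_len(nrow(codes))) {
    row <- codes[i, ]
    pw <- prod(bg[row])
    p_ref <- tail_of(oracle_best_score(sc, row, anchor))
    for (b in setdiff(1:4, row[anchor])) {
      alt <- row
      alt[anchor] <- b
      p_alt <- tail_of(oracle_best_score(sc, alt, anchor))
      vals <- c(vals, log10(p_ref / p_alt))
      wts <- c(wts, pw / 3)
    }
  }
  list(values = vals, weights = wts)
}

oracle_null_pvalue <- function(null, obs, tol = 1e-9) {
  sum(null$weights[abs(null$values) >= abs(obs) - tol])
}

# per-base k-of-n consensus oracle on a small genome
oracle_consensus_mask <- function(peak_sets, k, genome_len) {
  depth <- integer(genome_len)  # depth[i] = datasets covering 0-based base i-1
  for (p in peak_sets) {
    cov <- logical(genome_len)
    for (r in seq_len(nrow(p))) {
      cov[(p$start[r] + 1):min(p$end[r], genome_len)] <- TRUE
    }
    depth <- depth + cov
  }
  depth >= k
}

consensus_to_mask <- function(cps, genome_len) {
  mask <- logical(genome_len)
  for (r in seq_len(nrow(cps))) {
    mask[(cps$start[r] + 1):min(cps$end[r], genome_len)] <- TRUE
  }
  mask
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  combs <- utils::combn(n + m, n)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - n * (n + 1) / 2
  }
  u_all <- apply(combs, 2, function(idx) {
    r <- rank(vals)
    sum(r[idx]) - n * (n + 1) / 2
  })
  u_obs <- u_of(seq_len(n))
  center <- n * m / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# hand step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

# rank-based AUROC (mid-ranks for ties); larger score = more positive-like
oracle_auroc <- function(score_pos, score_neg) {
  r <- rank(c(score_pos, score_neg))
  n1 <- length(score_pos); n2 <- length(score_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# random position matrix for property tests
random_matrix <- function(w, total = 20L, source = "JASPAR") {
  counts <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(w)) counts[, j] <- as.numeric(stats::rmultinom(1, total, rep(0.25, 4)))
  position_matrix(counts, matrix_id = sprintf("rand_w%d", w), source = source)
}

random_peak_set <- function(genome_len, n_peaks) {
  start <- sample.int(genome_len - 2L, n_peaks, replace = TRUE) - 1L
  width <- sample.int(max(2L, genome_len %/% 10L), n_peaks, replace = TRUE)
  data.frame(chrom = "chrR", start = start,
             end = pmin(start + width, genome_len), stringsAsFactors = FALSE)
}

random_background <- function() {
  p <- stats::runif(4, 0.5, 2)
  p <- p / sum(p)
  names(p) <- c("A", "C", "G", "T")
  p
}
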