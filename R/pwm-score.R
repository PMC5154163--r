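#' Log-odds scoring matrix from a position matrix
#'
#' Per-position, per-base log2-odds scores against a background nucleotide
#' model:
#' \deqn{s(j,b) = \log_2 \frac{(c_{jb} + \lambda\,q_b)/(\sum_b c_{jb} + \lambda)}{q_b}}
#' where \eqn{\lambda} is the pseudocount (distributed proportionally to the
#' background) and \eqn{q_b} the background probability of base b. Scores are
#' additionally rounded to the discretization granularity used for the exact
#' score-distribution dynamic programming; that rounding is the sole source of
#' approximation in downstream p-values.
#'
#' @param m a [position_matrix()]
#' @param bg named background probabilities over A, C, G, T
#' @param pseudocount positive total pseudocount
#' @param granularity score discretization step, in bits
#' @return an object of class `log_odds_matrix` with elements `scores`
#'   (continuous), `int_scores` (integer multiples of `granularity`), `width`,
#'   `granularity`, `bg`, `matrix_id`, `source`
#' @export
log_odds <- function(m, bg = uniform_background(), pseudocount = 0.8,
                     granularity = 1e-3) {
  stopifnot(inherits(m, "position_matrix"))
  bg <- check_background(bg)
  if (!is.numeric(pseudocount) || pseudocount < 0) stop("pseudocount must be >= 0")
  if (granularity <= 0) stop("granularity must be positive")
  colsums <- colSums(m$counts)
  if (pseudocount == 0 && any(colsums == 0)) {
    stop("zero column sum requires a positive pseudocount")
  }
  probs <- sweep(m$counts + outer(bg, rep(pseudocount, m$width)),
                 2, colsums + pseudocount, "/")
  scores <- log2(sweep(probs, 1, bg, "/"))
  structure(
    list(
      scores = scores,
      int_scores = round(scores / granularity),
      width = m$width,
      granularity = granularity,
      bg = bg,
      matrix_id = m$matrix_id,
      source = m$source
    ),
    class = "log_odds_matrix"
  )
}

#' @export
print.log_odds_matrix <- function(x, ...) {
  cat(sprintf("Log-odds matrix '%s' (%s), width %d, granularity %g bits\n",
              x$matrix_id, x$source, x$width, x$granularity))
  print(round(x$scores, 3))
  invisible(x)
}

## reverse-complement view of the scoring matrix: scoring the minus strand of
## a window equals scoring the window with base-complemented, column-reversed
## scores
rc_int_scores <- function(lom) {
  lom$int_scores[4:1, lom$width:1, drop = FALSE]
}

#' Exact distribution of PWM scores under the background model
#'
#' Computes, by position-wise convolution over the discretized score grid, the
#' exact probability distribution of the total log-odds score of a random
#' w-mer drawn i.i.d. from the background model. This is the null used to turn
#' motif-match scores into p-values.
#'
#' @param lom a [log_odds()] matrix
#' @param bg background model; defaults to the one the matrix was built with
#' @return an object of class `score_distribution` with `support` (scores, in
#'   bits, integer multiples of the granularity), `mass`, `tail`
#'   (\eqn{P(S \ge support_i)}) and `granularity`
#' @export
score_distribution <- function(lom, bg = lom$bg) {
  stopifnot(inherits(lom, "log_odds_matrix"))
  bg <- check_background(bg)
  w <- lom$width
  k <- lom$int_scores  # 4 x w integer matrix
  lo <- sum(apply(k, 2, min))
  hi <- sum(apply(k, 2, max))
  ## dp[i] = P(sum of first j columns == lo_j + i - 1)
  dp <- 1
  off <- 0L  # current minimum achievable integer score
  for (j in seq_len(w)) {
    kj <- k[, j]
    kmin <- min(kj); kmax <- max(kj)
    new <- numeric(length(dp) + (kmax - kmin))
    for (b in 1:4) {
      sh <- kj[b] - kmin
      idx <- seq_along(dp) + sh
      new[idx] <- new[idx] + dp * bg[b]
    }
    dp <- new
    off <- off + kmin
  }
  int_support <- seq.int(lo, hi)
  keep <- dp > 0
  int_support <- int_support[keep]
  mass <- dp[keep]
  structure(
    list(
      support = int_support * lom$granularity,
      int_support = int_support,
      mass = mass,
      tail = rev(cumsum(rev(mass))),
      granularity = lom$granularity
    ),
    class = "score_distribution"
  )
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "Exact PWM score distribution: %d support points in [%.3f, %.3f] bits (g = %g)\n",
    length(x$support), min(x$support), max(x$support), x$granularity))
  cat(sprintf("total mass %.12f\n", sum(x$mass)))
  invisible(x)
}

#' Upper-tail p-value of a PWM score
#'
#' \eqn{P(S \ge s)} under the exact background score distribution, with `s`
#' rounded to the distribution's granularity. Vectorized over `s`.
#'
#' @param d a [score_distribution()]
#' @param s numeric score(s), in bits
#' @return probabilities, non-increasing in `s`
#' @export
score_pvalue <- function(d, s) {
  stopifnot(inherits(d, "score_distribution"))
  k <- round(s / d$granularity)
  ## number of support points strictly below k
  below <- findInterval(k - 0.5, d$int_support)
  n <- length(d$int_support)
  p <- numeric(length(k))
  inb <- below < n
  p[inb] <- d$tail[below[inb] + 1L]
  p[!inb] <- 0
  p
}

#' Best motif hit covering an anchored position
#'
#' Scores every w-window of `seq` (both strands) that covers the anchor
#' position and returns the maximum. Windows containing non-ACGT characters
#' are skipped; if every window is skipped an error is raised. Ties are broken
#' deterministically: lowest window offset first, then '+' strand.
#'
#' @param lom a [log_odds()] matrix
#' @param seq nucleotide string
#' @param anchor 1-based position in `seq` every scored window must cover
#' @return list with `score` (bits), `strand` ("+" or "-") and `offset`
#'   (1-based start of the winning window)
#' @export
best_hit <- function(lom, seq, anchor) {
  stopifnot(inherits(lom, "log_odds_matrix"))
  codes <- seq_to_codes(seq)
  L <- length(codes)
  w <- lom$width
  if (L < w) stop("sequence shorter than motif width")
  if (anchor < 1L || anchor > L) stop("anchor outside sequence")
  offs <- seq.int(max(1L, anchor - w + 1L), min(L - w + 1L, anchor))
  if (length(offs) == 0L) stop("no window of the motif width covers the anchor")
  fwd <- lom$int_scores
  rev <- rc_int_scores(lom)
  best <- NULL
  for (o in offs) {
    win <- codes[o:(o + w - 1L)]
    if (anyNA(win)) next
    for (strand in c("+", "-")) {
      mat <- if (strand == "+") fwd else rev
      sc <- sum(mat[cbind(win, seq_len(w))])
      if (is.null(best) || sc > best$int) {
        best <- list(int = sc, strand = strand, offset = o)
      }
    }
  }
  if (is.null(best)) stop("all candidate windows contain non-ACGT characters")
  list(score = best$int * lom$granularity, strand = best$strand, offset = best$offset)
}

## Vectorized best-hit score over many equal-length contexts.
## `codes` is an n x L integer matrix; every window covering column `anchor`
## is scored on both strands; returns integer best scores (granularity units).
## Rows containing NA in all covering windows get NA.
best_hit_batch_int <- function(lom, codes, anchor) {
  w <- lom$width
  L <- ncol(codes)
  n <- nrow(codes)
  offs <- seq.int(max(1L, anchor - w + 1L), min(L - w + 1L, anchor))
  fwd <- lom$int_scores
  rev <- rc_int_scores(lom)
  best <- rep.int(NA_integer_, n)
  for (o in offs) {
    win <- codes[, o:(o + w - 1L), drop = FALSE]
    scf <- integer(n)
    scr <- integer(n)
    for (j in seq_len(w)) {
      b <- win[, j]
      scf <- scf + fwd[cbind(b, j)]
      scr <- scr + rev[cbind(b, j)]
    }
    sc <- pmax(scf, scr)
    better <- !is.na(sc) & (is.na(best) | sc > best)
    best[better] <- sc[better]
  }
  best
}
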