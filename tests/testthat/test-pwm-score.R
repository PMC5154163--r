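toy_lom <- function(scores, granularity = 1e-3, bg = uniform_background()) {
  scores <- as.matrix(scores)
  rownames(scores) <- c("A", "C", "G", "T")
  structure(
    list(scores = scores, int_scores = round(scores / granularity),
         width = ncol(scores), granularity = granularity, bg = bg,
         matrix_id = "toy", source = "JASPAR"),
    class = "log_odds_matrix")
}

test_that("log-odds formula matches hand evaluation", {
  # uniform column is uninformative
  m <- position_matrix(matrix(1, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL)))
  lom <- log_odds(m, pseudocount = 0.8)
  expect_equal(unname(lom$scores), matrix(0, 4, 3))

  # pseudocount -> 0 limit of a fully specific column: log2(1/0.25) = 2 bits
  m2 <- position_matrix(matrix(c(4, 0, 0, 0), 4, 1,
                               dimnames = list(c("A", "C", "G", "T"), NULL)))
  lom2 <- log_odds(m2, pseudocount = 1e-9)
  expect_equal(unname(lom2$scores["A", 1]), 2, tolerance = 1e-6)

  # fixed counts (3,1,0,0), uniform bg, pseudocount 1: independent evaluation
  m3 <- position_matrix(matrix(c(3, 1, 0, 0), 4, 1,
                               dimnames = list(c("A", "C", "G", "T"), NULL)))
  lom3 <- log_odds(m3, pseudocount = 1)
  pc <- 1; bg <- 0.25; colsum <- 4
  hand <- log2((c(3, 1, 0, 0) + pc * bg) / (colsum + pc) / bg)
  expect_equal(unname(lom3$scores[, 1]), hand, tolerance = 1e-12)

  expect_error(log_odds(position_matrix(matrix(0, 4, 1,
    dimnames = list(c("A", "C", "G", "T"), NULL))), pseudocount = 0),
    "pseudocount")
})

test_that("single-column score distribution enumerates directly", {
  lom <- toy_lom(matrix(c(1, 0, 0, 0), 4, 1))
  d <- score_distribution(lom)
  expect_equal(d$support, c(0, 1))
  expect_equal(d$mass, c(0.75, 0.25))
  expect_equal(score_pvalue(d, 1), 0.25)
  expect_equal(score_pvalue(d, 0), 1)
})

test_that("DP distribution equals brute-force enumeration on rounded scores", {
  set.seed(21)
  for (rep in 1:8) {
    w <- sample(1:6, 1)
    bg <- if (rep %% 2 == 0) random_background() else uniform_background()
    lom <- log_odds(random_matrix(w), bg = bg, granularity = 1e-3)
    d <- score_distribution(lom)
    expect_lt(abs(sum(d$mass) - 1), 1e-9)
    oracle <- oracle_score_dist(lom$int_scores, bg)
    expect_equal(d$int_support, oracle$support)
    expect_equal(d$mass, oracle$mass, tolerance = 1e-12)
  }
})

test_that("binning error against continuous-score enumeration is at most w*g/2", {
  set.seed(22)
  g <- 1e-3
  for (rep in 1:4) {
    w <- sample(2:5, 1)
    bg <- random_background()
    lom <- log_odds(random_matrix(w), bg = bg, granularity = g)
    d <- score_distribution(lom)
    oracle <- oracle_score_dist(lom$scores, bg)
    slack <- w * g / 2 + 1e-9
    for (s in c(oracle$support, runif(10, min(oracle$support), max(oracle$support)))) {
      p <- score_pvalue(d, s)
      expect_lte(p, oracle_tail(oracle, s - slack) + 1e-12)
      expect_gte(p, oracle_tail(oracle, s + slack) - 1e-12)
    }
  }
})

test_that("score_pvalue is a non-increasing step function with correct limits", {
  set.seed(23)
  lom <- log_odds(random_matrix(4))
  d <- score_distribution(lom)
  expect_equal(score_pvalue(d, min(d$support) - 5), 1)
  expect_equal(score_pvalue(d, -Inf), 1)
  expect_equal(score_pvalue(d, max(d$support) + 5), 0)
  expect_equal(score_pvalue(d, Inf), 0)
  s <- sort(runif(50, min(d$support) - 1, max(d$support) + 1))
  p <- score_pvalue(d, s)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("w=2 toy p-values equal tail sums from 16-mer enumeration", {
  set.seed(24)
  lom <- log_odds(random_matrix(2))
  d <- score_distribution(lom)
  oracle <- oracle_score_dist(lom$int_scores, uniform_background())
  for (k in oracle$support) {
    expect_equal(score_pvalue(d, k * lom$granularity),
                 oracle_tail(oracle, k, tol = 0.5), tolerance = 1e-12)
  }
})

test_that("uniform matrix scores every sequence 0 with p-value 1", {
  m <- position_matrix(matrix(5, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL)))
  lom <- log_odds(m)
  d <- score_distribution(lom)
  expect_equal(d$support, 0)
  for (seq in c("ACGT", "TTTTT", "GGCCAAT")) {
    hit <- best_hit(lom, seq, 2)
    expect_equal(hit$score, 0)
    expect_equal(score_pvalue(d, hit$score), 1)
  }
})

test_that("best_hit finds the consensus match with deterministic tie-breaks", {
  m <- ere_motif()
  lom <- log_odds(m)
  cons <- paste(c("G", "G", "T", "C", "A", "A", "A", "A", "T", "G", "A", "C", "C"),
                collapse = "")
  hit <- best_hit(lom, cons, 7)
  expect_equal(hit$score, sum(apply(lom$int_scores, 2, max)) * lom$granularity)
  # the ERE is a perfect palindrome: the '-' strand ties and '+' wins the tie
  expect_equal(hit$strand, "+")
  expect_equal(hit$offset, 1L)
  # palindromic motif scores the reverse complement sequence identically
  rc <- paste(rev(c("C", "C", "A", "G", "T", "T", "T", "T", "A", "C", "T", "G", "G")),
              collapse = "")
  expect_equal(best_hit(lom, rc, 7)$score, hit$score)
})

test_that("best_hit equals exhaustive evaluation of all covering windows", {
  set.seed(25)
  for (rep in 1:5) {
    w <- sample(2:5, 1)
    lom <- log_odds(random_matrix(w), bg = random_background())
    L <- w + 2L
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    anchor <- ceiling(L / 2)
    hit <- best_hit(lom, seq, anchor)
    oracle <- oracle_best_score(lom$int_scores,
                                match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")),
                                anchor) * lom$granularity
    expect_equal(hit$score, oracle, tolerance = 1e-12)
  }
})

test_that("best_hit is invariant under reverse-complementing matrix and sequence", {
  set.seed(26)
  for (rep in 1:5) {
    w <- sample(2:6, 1)
    m <- random_matrix(w)
    lom <- log_odds(m)
    rc_counts <- m$counts[4:1, w:1, drop = FALSE]
    rownames(rc_counts) <- c("A", "C", "G", "T")
    lom_rc <- log_odds(position_matrix(rc_counts))
    L <- 2 * w + 1L
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    anchor <- w + 1L
    rc_seq <- paste(rev(chartr("ACGT", "TGCA", strsplit(seq, "")[[1]])), collapse = "")
    expect_equal(best_hit(lom, seq, anchor)$score,
                 best_hit(lom_rc, rc_seq, L - anchor + 1L)$score,
                 tolerance = 1e-12)
  }
})

test_that("windows with ambiguous bases are skipped; all-ambiguous errors", {
  lom <- log_odds(random_matrix(3))
  # anchor at 5; windows covering it: offsets 3,4,5; N at position 3 kills offset 3
  hit <- best_hit(lom, "ACNTAGA", 5)
  expect_true(hit$offset >= 4L)
  expect_error(best_hit(lom, "ANNNA", 3), "non-ACGT")
  expect_error(best_hit(lom, "AC", 1), "shorter")
})
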