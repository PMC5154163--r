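test_that("build_contexts constructs allele sequences differing only at the anchor", {
  genome <- c(chr1 = "AACGTTAGGA")
  ctx <- build_contexts("chr1", 4, "G", "T", genome, w = 3)
  expect_equal(nchar(ctx$ctx_ref), 5L)  # 2w - 1
  expect_equal(ctx$anchor, 3L)
  expect_equal(substr(ctx$ctx_ref, 3, 3), "G")
  expect_equal(substr(ctx$ctx_alt, 3, 3), "T")
  ref_chars <- strsplit(ctx$ctx_ref, "")[[1]]
  alt_chars <- strsplit(ctx$ctx_alt, "")[[1]]
  expect_equal(which(ref_chars != alt_chars), 3L)
  expect_false(ctx$ref_mismatch)
})

test_that("build_contexts flags boundary and reference-mismatch conditions", {
  genome <- c(chr1 = "AACGTT")
  expect_error(build_contexts("chr1", 1, "A", "G", genome, w = 3), "flanking")
  expect_error(build_contexts("chr1", 6, "T", "G", genome, w = 3), "flanking")
  expect_error(build_contexts("chr2", 3, "C", "G", genome, w = 2), "contig")
  # VCF ref disagreeing with the FASTA is flagged, not silently rescored
  ctx <- build_contexts("chr1", 3, "T", "G", genome, w = 3)
  expect_true(ctx$ref_mismatch)
  expect_equal(substr(ctx$ctx_ref, ctx$anchor, ctx$anchor), "T")
  expect_error(build_contexts("chr1", 3, "C", "C", genome, w = 3), "differ")
})

test_that("ratio statistic detects a motif-completing substitution", {
  lom <- log_odds(ere_motif())
  d <- score_distribution(lom)
  w <- 13
  flank <- strrep("T", w - 1)
  weak <- "GTTCAAAATGACC"   # consensus broken at column 2
  genome <- c(chrT = paste0(flank, weak, flank))
  ctx <- build_contexts("chrT", w - 1 + 2, "T", "G", genome, w = w)
  st <- ratio_statistic(lom, d, ctx$ctx_ref, ctx$ctx_alt, ctx$anchor)
  expect_lt(st$p_alt, st$p_ref)
  expect_equal(st$direction, "increase")
  expect_gt(st$log_ratio, 0)
})

test_that("ratio p-values equal brute-force tail sums for a w=4 toy matrix", {
  set.seed(31)
  lom <- log_odds(random_matrix(4), bg = random_background())
  d <- score_distribution(lom)
  oracle <- oracle_score_dist(lom$int_scores, lom$bg)
  for (rep in 1:5) {
    seqs <- sample(c("A", "C", "G", "T"), 7, replace = TRUE)
    alt <- sample(setdiff(c("A", "C", "G", "T"), seqs[4]), 1)
    ctx_ref <- paste(seqs, collapse = "")
    seqs[4] <- alt
    ctx_alt <- paste(seqs, collapse = "")
    st <- ratio_statistic(lom, d, ctx_ref, ctx_alt, 4)
    codes_ref <- match(strsplit(ctx_ref, "")[[1]], c("A", "C", "G", "T"))
    codes_alt <- match(strsplit(ctx_alt, "")[[1]], c("A", "C", "G", "T"))
    expect_equal(st$p_ref,
                 oracle_tail(oracle, oracle_best_score(lom$int_scores, codes_ref, 4), 0.5),
                 tolerance = 1e-12)
    expect_equal(st$p_alt,
                 oracle_tail(oracle, oracle_best_score(lom$int_scores, codes_alt, 4), 0.5),
                 tolerance = 1e-12)
  }
})

test_that("swapping ref and alt negates the log ratio and flips direction", {
  set.seed(32)
  lom <- log_odds(random_matrix(3))
  d <- score_distribution(lom)
  null <- build_ratio_null(lom, d, mode = "exact")
  for (rep in 1:5) {
    seqs <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
    alt <- sample(setdiff(c("A", "C", "G", "T"), seqs[3]), 1)
    ctx_ref <- paste(seqs, collapse = "")
    seqs2 <- seqs; seqs2[3] <- alt
    ctx_alt <- paste(seqs2, collapse = "")
    st <- ratio_statistic(lom, d, ctx_ref, ctx_alt, 3)
    sw <- ratio_statistic(lom, d, ctx_alt, ctx_ref, 3)
    expect_equal(sw$log_ratio, -st$log_ratio, tolerance = 1e-12)
    if (st$log_ratio != 0) expect_true(st$direction != sw$direction)
    expect_equal(null_pvalue(null, st$log_ratio), null_pvalue(null, sw$log_ratio))
  }
})

test_that("uniform matrix yields a point-mass ratio null and no calls", {
  m <- position_matrix(matrix(5, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL)))
  lom <- log_odds(m)
  d <- score_distribution(lom)
  null <- build_ratio_null(lom, d, mode = "exact")
  expect_equal(null$values, 0)
  expect_equal(sum(null$weights), 1, tolerance = 1e-9)
  expect_equal(null_pvalue(null, 0), 1)
})

test_that("exact ratio null matches full enumeration for w = 2", {
  set.seed(33)
  for (bg in list(uniform_background(), random_background())) {
    lom <- log_odds(random_matrix(2), bg = bg)
    d <- score_distribution(lom)
    null <- build_ratio_null(lom, d, mode = "exact")
    oracle <- oracle_ratio_null(lom, bg)
    expect_equal(sum(null$weights), 1, tolerance = 1e-9)
    probes <- c(0, unique(round(oracle$values, 6)), max(abs(oracle$values)) + 1)
    for (t in probes) {
      expect_equal(null_pvalue(null, t), oracle_null_pvalue(oracle, t),
                   tolerance = 1e-9)
    }
  }
})

test_that("exact mode refuses enumerations over the cap, Monte Carlo needs n >= 1000", {
  lom <- log_odds(random_matrix(8))
  d <- score_distribution(lom)
  expect_error(build_ratio_null(lom, d, mode = "exact"), "monte_carlo")
  expect_error(build_ratio_null(lom, d, mode = "monte_carlo", n_samples = 10),
               ">= 1000")
})

test_that("Monte-Carlo null is seed-reproducible and consistent with the exact null", {
  set.seed(34)
  lom <- log_odds(random_matrix(3), bg = random_background())
  d <- score_distribution(lom)
  mc1 <- build_ratio_null(lom, d, mode = "monte_carlo", n_samples = 20000, seed = 9)
  mc2 <- build_ratio_null(lom, d, mode = "monte_carlo", n_samples = 20000, seed = 9)
  expect_identical(mc1$values, mc2$values)

  exact <- build_ratio_null(lom, d, mode = "exact")
  for (t in quantile(abs(exact$values), c(0.5, 0.9, 0.99))) {
    p_true <- null_pvalue(exact, t)
    p_mc <- null_pvalue(mc1, t)
    se <- sqrt(p_true * (1 - p_true) / mc1$n_samples)
    expect_lt(abs(p_mc - p_true), 3 * se + 2 / mc1$n_samples)
  }
})

test_that("null_pvalue has the add-one floor and degenerate-observation behaviour", {
  set.seed(35)
  lom <- log_odds(random_matrix(3))
  d <- score_distribution(lom)
  mc <- build_ratio_null(lom, d, mode = "monte_carlo", n_samples = 1000, seed = 2)
  expect_equal(null_pvalue(mc, 0), 1)
  expect_equal(null_pvalue(mc, max(abs(mc$values)) + 10), 1 / 1001)
  expect_true(all(null_pvalue(mc, c(-2, -1, 0, 1, 2)) > 0))
})

test_that("assess_variant applies Bonferroni and records supporting databases", {
  lom_j <- log_odds(ere_motif("ERE_J", "JASPAR"))
  lom_t <- log_odds(ere_motif("ERE_T", "TRANSFAC"))
  d <- score_distribution(lom_j)
  null <- build_ratio_null(lom_j, d, mode = "monte_carlo", n_samples = 5000, seed = 4)
  w <- 13
  genome <- c(chrT = paste0(strrep("T", w - 1), "GTTCAAAATGACC", strrep("T", w - 1)))
  ctx <- build_contexts("chrT", w + 1, "T", "G", genome, w = w)

  one <- assess_variant(ctx, list(lom_j), list(d), list(null))
  expect_equal(one$adjusted_p, one$null_p)

  # identical matrices under both database tags: identical p, both tags listed
  two <- assess_variant(ctx, list(lom_j, lom_t), list(d, d), list(null, null))
  expect_equal(two$null_p[1], two$null_p[2])
  expect_equal(two$adjusted_p, pmin(1, two$null_p * 2))
  expect_true(all(two$significant))
  expect_equal(unique(two$databases_supporting), "JASPAR,TRANSFAC")
  expect_equal(two$direction, c("increase", "increase"))

  # shuffled-context control at a motif-free locus is not called
  genome2 <- c(chrT = paste0(strrep("T", w - 1), "TATTCTGATAAGC", strrep("T", w - 1)))
  ctx2 <- build_contexts("chrT", w + 1, "A", "G", genome2, w = w)
  ctrl <- assess_variant(ctx2, list(lom_j), list(d), list(null))
  expect_false(ctrl$significant)
})

test_that("rank_regsnvs orders by adjusted p with |log-ratio| tie-break", {
  df <- data.frame(
    chrom = "chr1", pos = c(30, 10, 20), ref = "A", alt = "G",
    matrix_id = "m", source = "JASPAR",
    p_ref = 0.5, p_alt = 0.1,
    log_ratio = c(1.0, 2.0, 0.5),
    null_p = c(1e-3, 1e-3, 1e-5),
    adjusted_p = c(1e-3, 1e-3, 1e-5),
    direction = "increase", significant = TRUE,
    stringsAsFactors = FALSE)
  ranked <- rank_regsnvs(df)
  expect_equal(ranked$pos, c(20, 10, 30))  # smallest p first, then larger |ratio|
  expect_setequal(paste(ranked$pos, ranked$log_ratio),
                  paste(df$pos, df$log_ratio))  # permutation
})
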