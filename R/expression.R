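#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. The exact null distribution
#' is used when n + m <= 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity correction is applied (the behaviour
#' of [stats::wilcox.test()], which backs this function).
#'
#' @param x,y numeric vectors (both non-empty)
#' @return list with `U` (the statistic for `x`) and `p`
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 12L) && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value, exact = use_exact)
}

#' Read an expression matrix (genes x samples) from TSV
#'
#' First column holds gene symbols (must be unique); remaining columns are
#' samples of log2 TPM values.
#' @param path file path
#' @return numeric matrix with gene rownames
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes)) stop(sprintf("expression matrix %s: duplicated gene symbols", path))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- genes
  storage.mode(m) <- "double"
  m
}

#' Read sample metadata (sample, er_status) from TSV
#' @param path file path
#' @return data.frame with at least columns sample and er_status ("pos"/"neg")
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "er_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("metadata %s: missing column(s) %s", path,
                                 paste(miss, collapse = ", ")))
  df
}

#' Read a regSNV x sample genotype-carrier table from TSV
#'
#' First column `regsnv_id`; remaining columns one per sample with values
#' "WT", "carrier" or "missing".
#' @param path file path
#' @return character matrix with regsnv_id rownames and sample colnames
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Carrier-vs-WT expression association for regSNV target genes
#'
#' For each (regSNV, target gene) pair, compares the target's log2 TPM
#' between variant carriers and wild-type samples among ER-positive tumors
#' with the Mann-Whitney U test; samples with missing genotype are dropped.
#' The log2 fold change is the difference of group means of log2 TPM
#' (carrier - WT). p-values are Benjamini-Hochberg adjusted across all
#' testable pairs.
#'
#' @param pairs data.frame with columns regsnv_id and target_gene
#' @param expr genes x samples matrix ([read_expression()])
#' @param metadata sample metadata ([read_sample_metadata()])
#' @param genotypes regSNV x sample carrier matrix ([read_genotypes()])
#' @param er_filter restrict to this ER status (default "pos"; NULL keeps all)
#' @param min_group minimum samples per group for a testable pair
#' @return data.frame with regsnv_id, target_gene, n_carrier, n_wt, log2_fc,
#'   u_stat, p, adjusted_p, testable
#' @export
associate_expression <- function(pairs, expr, metadata, genotypes,
                                 er_filter = "pos", min_group = 2L) {
  samples <- colnames(expr)
  meta <- metadata[match(samples, metadata$sample), , drop = FALSE]
  if (anyNA(meta$sample)) stop("metadata does not cover every expression sample")
  keep_sample <- if (is.null(er_filter)) rep(TRUE, length(samples)) else
    meta$er_status == er_filter
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    rid <- pairs$regsnv_id[i]
    gene <- pairs$target_gene[i]
    base <- data.frame(regsnv_id = rid, target_gene = gene,
                       n_carrier = NA_integer_, n_wt = NA_integer_,
                       log2_fc = NA_real_, u_stat = NA_real_, p = NA_real_,
                       testable = FALSE, stringsAsFactors = FALSE)
    if (!gene %in% rownames(expr) || !rid %in% rownames(genotypes)) return(base)
    gt <- genotypes[rid, samples]
    carrier <- keep_sample & gt == "carrier"
    wt <- keep_sample & gt == "WT"
    base$n_carrier <- sum(carrier)
    base$n_wt <- sum(wt)
    if (base$n_carrier < min_group || base$n_wt < min_group) return(base)
    xc <- expr[gene, carrier]
    xw <- expr[gene, wt]
    mw <- mann_whitney(xc, xw)
    base$log2_fc <- mean(xc) - mean(xw)
    base$u_stat <- mw$U
    base$p <- mw$p
    base$testable <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  out$adjusted_p[out$testable] <- bh_adjust(out$p[out$testable])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in \[0, 1\]
#' @return adjusted p-values (mapped back to the input order)
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Enrichment of regSNVs near differentially regulated genes
#'
#' 2x2 chi-square test of independence between being a regSNV (vs any other
#' filtered SNV) and having the nearest gene within `max_dist` of a
#' differentially-expressed gene.
#'
#' @param all_snvs data.frame with chrom, pos and a logical column or id set
#'   identifying regSNVs via `regsnv_ids` (matched against an `id` column
#'   built as chrom:pos)
#' @param regsnv_ids character vector of chrom:pos ids flagged as regSNVs
#' @param de_genes character vector of differentially regulated gene symbols
#' @param genes gene models ([read_genes()])
#' @param max_dist proximity cutoff in bp (strict `<`)
#' @return list with `chi2`, `p`, `table` (2x2 contingency)
#' @export
de_proximity_enrichment <- function(all_snvs, regsnv_ids, de_genes, genes,
                                    max_dist = 5000L) {
  id <- paste0(all_snvs$chrom, ":", all_snvs$pos)
  is_reg <- id %in% regsnv_ids
  near_de <- vapply(seq_len(nrow(all_snvs)), function(i) {
    nn <- nearest_genes(all_snvs$chrom[i], all_snvs$pos[i], genes)
    (!is.na(nn$gene_5p) && nn$gene_5p %in% de_genes && nn$dist_5p < max_dist) ||
      (!is.na(nn$gene_3p) && nn$gene_3p %in% de_genes && nn$dist_3p < max_dist)
  }, logical(1))
  tab <- table(regSNV = factor(is_reg, levels = c(TRUE, FALSE)),
               near_DE = factor(near_de, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop("chi-square test undefined: a contingency margin is zero")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = ht$p.value, table = tab)
}
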