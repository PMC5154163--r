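# a small two-gene model used across the annotation tests:
# coding gene BODY1 on [1000, 3000) with exons [1000,1200) and [2800,3000),
# ncRNA gene NC1 on [5000, 5500)
toy_genes <- function() {
  df <- data.frame(
    symbol = c("BODY1", "NC1"),
    chrom = "chr1",
    strand = c("+", "+"),
    start = c(1000L, 5000L),
    end = c(3000L, 5500L),
    biotype = c("coding", "ncRNA"),
    stringsAsFactors = FALSE)
  df$exons <- list(cbind(start = c(1000L, 2800L), end = c(1200L, 3000L)),
                   cbind(start = 5000L, end = 5500L))
  df
}

test_that("BED12 block arithmetic reconstructs exon structure", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 1000, 3000, "BODY1", 0, "+", 1000, 3000, "0",
                     2, "200,200,", "0,1800,"), collapse = "\t"), p)
  g <- read_genes(p)
  expect_equal(g$symbol, "BODY1")
  expect_equal(g$biotype, "coding")
  expect_equal(g$exons[[1]], cbind(start = c(1000L, 2800L), end = c(1200L, 3000L)))

  # thickStart == thickEnd marks a non-coding transcript
  writeLines(paste(c("chr1", 5000, 5500, "NC1", 0, "+", 5000, 5000, "0",
                     1, "500,", "0,"), collapse = "\t"), p)
  expect_equal(read_genes(p)$biotype, "ncRNA")

  writeLines(paste(c("chr1", 1000, 3000, "X", 0, "+", 1000, 3000, "0",
                     2, "200,", "0,1800,"), collapse = "\t"), p)
  expect_error(read_genes(p), "blockCount")
})

test_that("GFF3 and BED12 encodings of the same gene yield identical models", {
  pb <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 1000, 3000, "BODY1", 0, "+", 1000, 3000, "0",
                     2, "200,200,", "0,1800,"), collapse = "\t"), pb)
  pg <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t3000\t.\t+\t.\tID=BODY1;Name=BODY1",
    "chr1\ttest\texon\t1001\t1200\t.\t+\t.\tParent=BODY1",
    "chr1\ttest\texon\t2801\t3000\t.\t+\t.\tParent=BODY1"), pg)
  gb <- read_genes(pb)
  gg <- read_genes(pg)
  expect_equal(gg$symbol, gb$symbol)
  expect_equal(gg$start, gb$start)
  expect_equal(gg$end, gb$end)
  expect_equal(unname(gg$exons[[1]]), unname(gb$exons[[1]]))

  # single-exon GFF3 gene
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t101\t300\t.\t-\t.\tID=G2;biotype=lncRNA",
               "chr1\ttest\texon\t101\t300\t.\t-\t.\tParent=G2"), pg)
  g2 <- read_genes(pg)
  expect_equal(nrow(g2$exons[[1]]), 1L)
  expect_equal(g2$biotype, "ncRNA")
})

test_that("genomic-context classification follows the precedence rules", {
  g <- toy_genes()
  # inside exon 1 of the coding gene
  expect_equal(classify_position("chr1", 1100, g), "exonic")
  # centrally between two exons of the gene body
  expect_equal(classify_position("chr1", 2000, g), "intronic")
  # inside the ncRNA body
  expect_equal(classify_position("chr1", 5200, g), "ncRNA")
  # within 1 kb upstream of the TSS (strand +, TSS at 0-based 1000)
  expect_equal(classify_position("chr1", 500, g), "promoter")
  # beyond the promoter but within 5 kb upstream
  expect_equal(classify_position("chr1", 50, g, promoter_window = 100), "upstream")
  # 10 kb away from every gene with (1 kb, 5 kb) windows
  expect_equal(classify_position("chr1", 15500, g), "intergenic")
  expect_equal(classify_position("chr2", 1100, g), "intergenic")
})

test_that("promoter classification is strand-aware", {
  g <- toy_genes()
  g$strand <- c("-", "+")
  # for a '-' gene the TSS is the right end; just right of it is the promoter
  expect_equal(classify_position("chr1", 3500, g), "promoter")
  expect_equal(classify_position("chr1", 500, g,
                                 promoter_window = 1000, upstream_window = 5000),
               "upstream")
})

test_that("nearest genes use gene-body distance with lexicographic tie-break", {
  genes <- data.frame(
    symbol = c("BGENE", "AGENE"), chrom = "chr1", strand = "+",
    start = c(0L, 500L), end = c(100L, 600L), biotype = "coding",
    stringsAsFactors = FALSE)
  genes$exons <- list(cbind(start = 0L, end = 100L), cbind(start = 500L, end = 600L))

  # inside a gene: that gene on both sides at distance 0
  nn <- nearest_genes("chr1", 50, genes)
  expect_equal(nn, list(gene_5p = "BGENE", dist_5p = 0L,
                        gene_3p = "BGENE", dist_3p = 0L))

  # equidistant flanks: 200 on each side
  nn <- nearest_genes("chr1", 301, genes)
  expect_equal(nn$dist_5p, 200L)
  expect_equal(nn$dist_3p, 200L)
  expect_equal(nn$gene_5p, "BGENE")
  expect_equal(nn$gene_3p, "AGENE")

  # single-gene side missing
  nn <- nearest_genes("chr1", 700, genes)
  expect_equal(nn$gene_5p, "AGENE")
  expect_true(is.na(nn$gene_3p))

  # equidistant genes on the same side tie-break lexicographically
  genes2 <- genes
  genes2$start <- c(0L, 0L); genes2$end <- c(100L, 100L)
  nn <- nearest_genes("chr1", 301, genes2)
  expect_equal(nn$gene_5p, "AGENE")
})

test_that("nearest-gene distances agree with a brute-force all-pairs scan", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    start <- sort(sample(seq(0, 5000, by = 10), n))
    genes <- data.frame(
      symbol = sprintf("G%02d", sample(n)), chrom = "chr1", strand = "+",
      start = start, end = start + sample(50:200, n, replace = TRUE),
      biotype = "coding", stringsAsFactors = FALSE)
    genes$exons <- lapply(seq_len(n), function(i) {
      cbind(start = genes$start[i], end = genes$end[i])
    })
    for (pos in sample(1:6000, 20)) {
      nn <- nearest_genes("chr1", pos, genes)
      pos0 <- pos - 1
      inside <- genes$start <= pos0 & pos0 < genes$end
      if (any(inside)) {
        expect_equal(nn$dist_5p, 0L)
        expect_equal(nn$dist_3p, 0L)
      } else {
        left <- genes$end <= pos0
        if (any(left)) expect_equal(nn$dist_5p, min(pos0 - genes$end[left]))
        right <- genes$start > pos0
        if (any(right)) expect_equal(nn$dist_3p, min(genes$start[right] - pos0))
      }
    }
  }
})

test_that("classification is total over random positions", {
  set.seed(62)
  g <- toy_genes()
  cats <- classify_position(rep("chr1", 100), sample(1:20000, 100), g)
  expect_true(all(cats %in% c("exonic", "ncRNA", "intronic", "promoter",
                              "upstream", "intergenic")))
})

test_that("the E2 proximity filter gates on direction and strict distance", {
  records <- data.frame(
    chrom = "chr1", pos = c(1, 2, 3, 4),
    direction = c("increase", "increase", "decrease", "increase"),
    gene_5p = c("E2GENE", "E2GENE", "E2GENE", "OTHER"),
    dist_5p = c(4999L, 5000L, 0L, 100L),
    gene_3p = NA_character_, dist_3p = NA_integer_,
    stringsAsFactors = FALSE)
  kept <- e2_proximity_filter(records, "E2GENE", max_dist = 5000)
  expect_equal(kept$pos, 1)   # 4999 < 5000 kept; 5000 dropped; decrease dropped
  expect_equal(nrow(e2_proximity_filter(records, character(0))), 0L)
})
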