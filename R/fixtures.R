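#' Synthetic estrogen-response-element-like motif
#'
#' A width-13 palindromic motif modeled on the canonical ERE half-site
#' arrangement (GGTCA nnn TGACC): ten highly specific columns (dominant base
#' count 85 of 100) flanking a three-base uninformative spacer.
#'
#' @param matrix_id identifier
#' @param source "JASPAR" or "TRANSFAC" tag
#' @return a [position_matrix()]
#' @export
ere_motif <- function(matrix_id = "ERE_SYN", source = "JASPAR") {
  consensus <- c("G", "G", "T", "C", "A", NA, NA, NA, "T", "G", "A", "C", "C")
  counts <- matrix(25, nrow = 4, ncol = length(consensus),
                   dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(consensus)) {
    if (!is.na(consensus[j])) {
      counts[, j] <- 5
      counts[consensus[j], j] <- 85
    }
  }
  position_matrix(counts, matrix_id = matrix_id, source = source)
}

#' Fixture configuration
#'
#' Defines the conditions of the synthetic study: a single-contig background
#' genome hosting planted ERE instances; nine ChIP-seq peak datasets with
#' jitter and dropout over the true sites, combined at k = 6 (the study
#' design of nine datasets and six-of-n consensus); variants straddling the
#' 10-read / Q20 thresholds; allele pileups biased 70:30 toward the
#' stronger-binding allele; and an expression cohort of 200 ER+ tumors with
#' 30 carriers, a 2 log2-TPM planted shift and unit noise.
#'
#' @param seed integer; every output is reproducible from it
#' @param genome_length contig length in bp (one planted site per 8 kb slot)
#' @param n_peak_datasets,consensus_k peak replicate count and consensus k
#' @param peak_halfwidth half-width of true peaks around the motif (gives the
#'   ~385 bp mean peak length of real ER consensus sites)
#' @param peak_jitter_sd,peak_dropout per-dataset peak boundary jitter (bp)
#'   and per-site dataset dropout probability (inclusion is floored at
#'   `consensus_k` datasets so every true site survives the consensus)
#' @param n_planted_increase,n_planted_decrease planted weak-to-strong and
#'   strong-to-weak motif SNVs
#' @param n_neutral_snvs background SNVs inside peaks but away from motifs
#' @param n_fail_depth,n_fail_qual,n_not_snv,n_outside_peak planted
#'   filter-failure records
#' @param read_depth_mean mean depth of passing calls
#' @param allele_bias pileup probability of the stronger-binding allele
#' @param pileup_depth reads per pileup site
#' @param n_samples,er_pos_fraction,n_carriers,effect_size,noise_sd
#'   expression-cohort design (ER+ count = n_samples * er_pos_fraction)
#' @param n_true_assoc number of increase-site target genes given the
#'   expression shift
#' @param gene_fraction fraction of planted sites given a nearby (< 5 kb)
#'   target gene
#' @return a list of class `fixture_config`
#' @export
fixture_config <- function(seed,
                           genome_length = 320000L,
                           n_peak_datasets = 9L,
                           consensus_k = 6L,
                           peak_halfwidth = 186L,
                           peak_jitter_sd = 20,
                           peak_dropout = 0.15,
                           n_planted_increase = 25L,
                           n_planted_decrease = 15L,
                           n_neutral_snvs = 60L,
                           n_fail_depth = 3L,
                           n_fail_qual = 2L,
                           n_not_snv = 1L,
                           n_outside_peak = 4L,
                           read_depth_mean = 30,
                           allele_bias = 0.7,
                           pileup_depth = 30L,
                           n_samples = 250L,
                           er_pos_fraction = 0.8,
                           n_carriers = 30L,
                           effect_size = 2,
                           noise_sd = 1,
                           n_true_assoc = 12L,
                           gene_fraction = 0.8) {
  cfg <- as.list(environment())
  n_sites <- cfg$n_planted_increase + cfg$n_planted_decrease
  slot <- 8000L
  if (n_sites * slot > cfg$genome_length) {
    stop(sprintf("genome of %d bp cannot host %d planted sites (8 kb per site)",
                 cfg$genome_length, n_sites))
  }
  if (cfg$n_neutral_snvs > 4L * n_sites) {
    stop("too many neutral SNVs for the available in-peak positions")
  }
  if (cfg$consensus_k > cfg$n_peak_datasets) stop("consensus_k exceeds n_peak_datasets")
  if (cfg$n_true_assoc > cfg$n_planted_increase) stop("n_true_assoc exceeds planted increase sites")
  cfg$n_sites <- n_sites
  cfg$slot <- slot
  structure(cfg, class = "fixture_config")
}

#' Generate a complete synthetic study with known truth
#'
#' Writes every input the pipeline consumes (FASTA genome, JASPAR and
#' TRANSFAC motif files, per-dataset narrowPeak files, VCF, pileup TSV,
#' expression/metadata/genotype TSVs, BED12 gene models, E2 gene list) plus
#' truth tables labelling each SNV (planted_increase / planted_decrease /
#' neutral, expected filter disposition) and each expression association
#' (true_effect / null). All randomness derives from `cfg$seed` through
#' per-component sub-streams, so outputs are byte-reproducible and adding a
#' component never perturbs the others.
#'
#' @param cfg a [fixture_config()]
#' @param dir output directory (created if needed)
#' @return list with `paths` (named file paths), `truth` (`snvs` and
#'   `associations` data.frames) and `config`
#' @export
make_fixture <- function(cfg, dir) {
  stopifnot(inherits(cfg, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- "chrSYN"
  w <- 13L
  motif <- ere_motif("ERE_JASPAR_SYN", "JASPAR")
  consensus_codes <- apply(motif$counts, 2, which.max)
  weakest_codes <- apply(motif$counts, 2, which.min)
  j0 <- 2L  # high-information column carrying the planted substitution

  ## --- genome with embedded motif instances ------------------------------
  genome_codes <- with_subseed(cfg$seed, 1L, {
    sample.int(4L, cfg$genome_length, replace = TRUE)
  })
  site <- data.frame(
    idx = seq_len(cfg$n_sites),
    slot_start = (seq_len(cfg$n_sites) - 1L) * cfg$slot,
    label = rep(c("planted_increase", "planted_decrease"),
                c(cfg$n_planted_increase, cfg$n_planted_decrease)),
    stringsAsFactors = FALSE
  )
  site <- site[with_subseed(cfg$seed, 2L, sample.int(nrow(site))), ]  # shuffle labels over slots
  site <- site[order(site$slot_start), ]
  site$motif_start <- site$slot_start + 1000L  # 0-based
  for (i in seq_len(nrow(site))) {
    emb <- consensus_codes
    if (site$label[i] == "planted_increase") emb[j0] <- weakest_codes[j0]
    genome_codes[(site$motif_start[i] + 1L):(site$motif_start[i] + w)] <- emb
  }
  site$snv_pos <- site$motif_start + j0  # 1-based position of planted SNV
  site$ref <- ifelse(site$label == "planted_increase",
                     DNA_BASES[weakest_codes[j0]], DNA_BASES[consensus_codes[j0]])
  site$alt <- ifelse(site$label == "planted_increase",
                     DNA_BASES[consensus_codes[j0]], DNA_BASES[weakest_codes[j0]])

  ## --- gene models and E2 list -------------------------------------------
  genes <- with_subseed(cfg$seed, 3L, {
    has_gene <- stats::runif(nrow(site)) < cfg$gene_fraction
    dist <- sample(500:1500, nrow(site), replace = TRUE)
    g <- data.frame(
      site = site$idx,
      symbol = sprintf("GENE%03d", seq_len(nrow(site))),
      start = site$motif_start + w + dist,
      stringsAsFactors = FALSE
    )[has_gene, , drop = FALSE]
    g$end <- g$start + 800L
    g
  })
  site$gene <- genes$symbol[match(site$idx, genes$site)]
  e2_genes <- with_subseed(cfg$seed, 4L, {
    inc <- site$gene[site$label == "planted_increase" & !is.na(site$gene)]
    dec <- site$gene[site$label == "planted_decrease" & !is.na(site$gene)]
    c(inc[stats::runif(length(inc)) < 0.8], dec[stats::runif(length(dec)) < 0.3])
  })

  ## --- variant records ----------------------------------------------------
  n_extra_slots <- 4L
  extra_off <- -50L - 30L * (seq_len(n_extra_slots) - 1L)  # offsets from motif_start, in-peak
  pool <- expand.grid(site = seq_len(nrow(site)), slot = seq_len(n_extra_slots))
  pool <- pool[order(pool$slot, pool$site), ]
  pool$pos <- site$motif_start[pool$site] + extra_off[pool$slot] + 1L  # 1-based
  need <- cfg$n_neutral_snvs + cfg$n_fail_depth + cfg$n_fail_qual + cfg$n_not_snv
  stopifnot(nrow(pool) >= need)
  pool <- pool[seq_len(need), ]
  pool$role <- rep(c("neutral", "fail_depth", "fail_qual", "fail_not_snv"),
                   c(cfg$n_neutral_snvs, cfg$n_fail_depth, cfg$n_fail_qual, cfg$n_not_snv))
  outside_pos <- site$slot_start[seq_len(cfg$n_outside_peak)] + 6000L + 40L * seq_len(cfg$n_outside_peak)

  vcf <- with_subseed(cfg$seed, 5L, {
    other_base <- function(p) {
      vapply(p, function(pp) {
        DNA_BASES[sample(setdiff(1:4, genome_codes[pp]), 1L)]
      }, character(1))
    }
    planted <- data.frame(
      pos = site$snv_pos, ref = site$ref, alt = site$alt,
      label = site$label, disposition = "pass", stringsAsFactors = FALSE)
    extras <- data.frame(
      pos = pool$pos,
      ref = DNA_BASES[genome_codes[pool$pos]],
      alt = other_base(pool$pos),
      label = rep("neutral", nrow(pool)),
      disposition = ifelse(pool$role == "neutral", "pass", as.character(pool$role)),
      stringsAsFactors = FALSE)
    not_snv <- extras$disposition == "fail_not_snv"
    extras$ref[not_snv] <- paste0(
      DNA_BASES[genome_codes[extras$pos[not_snv]]],
      DNA_BASES[genome_codes[extras$pos[not_snv] + 1L]])
    outside <- data.frame(
      pos = outside_pos,
      ref = DNA_BASES[genome_codes[outside_pos]],
      alt = other_base(outside_pos),
      label = rep("neutral", length(outside_pos)),
      disposition = rep("fail_outside_peak", length(outside_pos)),
      stringsAsFactors = FALSE)
    v <- rbind(planted, extras, outside)
    v$depth <- 10L + stats::rpois(nrow(v), cfg$read_depth_mean - 10)
    v$qual <- round(stats::runif(nrow(v), 50, 200), 1)
    v$depth[v$disposition == "fail_depth"] <- sample(1:9, sum(v$disposition == "fail_depth"), replace = TRUE)
    v$qual[v$disposition == "fail_qual"] <- round(stats::runif(sum(v$disposition == "fail_qual"), 1, 19.5), 1)
    v[order(v$pos), ]
  })
  vcf$chrom <- chrom
  vcf$id <- sprintf("snv%04d", seq_len(nrow(vcf)))

  ## --- peak datasets ------------------------------------------------------
  peak_sets <- with_subseed(cfg$seed, 6L, {
    incl <- matrix(FALSE, nrow(site), cfg$n_peak_datasets)
    for (i in seq_len(nrow(site))) {
      n_in <- max(cfg$consensus_k,
                  stats::rbinom(1L, cfg$n_peak_datasets, 1 - cfg$peak_dropout))
      incl[i, sample.int(cfg$n_peak_datasets, n_in)] <- TRUE
    }
    lapply(seq_len(cfg$n_peak_datasets), function(d) {
      rows <- which(incl[, d])
      start <- site$motif_start[rows] - cfg$peak_halfwidth +
        round(stats::rnorm(length(rows), 0, cfg$peak_jitter_sd))
      end <- site$motif_start[rows] + w + cfg$peak_halfwidth +
        round(stats::rnorm(length(rows), 0, cfg$peak_jitter_sd))
      data.frame(chrom = chrom, start = pmax(0L, as.integer(start)),
                 end = as.integer(end), stringsAsFactors = FALSE)
    })
  })

  ## --- allele pileups at planted and neutral sites ------------------------
  pile <- with_subseed(cfg$seed, 7L, {
    snvs <- vcf[vcf$disposition == "pass" & nchar(vcf$ref) == 1L, , drop = FALSE]
    p_alt <- ifelse(snvs$label == "planted_increase", cfg$allele_bias,
                    ifelse(snvs$label == "planted_decrease", 1 - cfg$allele_bias, 0.5))
    n_alt <- stats::rbinom(nrow(snvs), cfg$pileup_depth, p_alt)
    counts <- matrix(0L, nrow(snvs), 4L, dimnames = list(NULL, DNA_BASES))
    for (i in seq_len(nrow(snvs))) {
      counts[i, snvs$alt[i]] <- n_alt[i]
      counts[i, snvs$ref[i]] <- cfg$pileup_depth - n_alt[i]
    }
    cbind(data.frame(chrom = snvs$chrom, pos = snvs$pos, stringsAsFactors = FALSE),
          as.data.frame(counts))
  })

  ## --- expression cohort --------------------------------------------------
  assoc_sites <- site[!is.na(site$gene), , drop = FALSE]
  true_idx <- which(assoc_sites$label == "planted_increase")[seq_len(min(cfg$n_true_assoc, sum(assoc_sites$label == "planted_increase")))]
  pairs <- data.frame(
    regsnv_id = paste0(chrom, ":", assoc_sites$snv_pos),
    target_gene = assoc_sites$gene,
    truth = ifelse(seq_len(nrow(assoc_sites)) %in% true_idx, "true_effect", "null"),
    stringsAsFactors = FALSE
  )
  cohort <- make_cohort(
    pairs = pairs[, c("regsnv_id", "target_gene")],
    true_pairs = pairs$regsnv_id[pairs$truth == "true_effect"],
    n_samples = cfg$n_samples, er_pos_fraction = cfg$er_pos_fraction,
    n_carriers = cfg$n_carriers, effect_size = cfg$effect_size,
    noise_sd = cfg$noise_sd, seed = cfg$seed + 8L
  )

  ## --- write everything ---------------------------------------------------
  paths <- list()
  genome_seq <- codes_to_seq(genome_codes)
  dna <- Biostrings::DNAStringSet(stats::setNames(genome_seq, chrom))
  paths$genome <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(dna, paths$genome)

  paths$motif_jaspar <- file.path(dir, "motif_jaspar.txt")
  write_jaspar(motif, paths$motif_jaspar)
  paths$motif_transfac <- file.path(dir, "motif_transfac.txt")
  write_transfac(ere_motif("ERE_TRANSFAC_SYN", "TRANSFAC"), paths$motif_transfac)

  paths$peaks <- vapply(seq_along(peak_sets), function(d) {
    p <- file.path(dir, sprintf("peaks_%02d.narrowPeak", d))
    df <- peak_sets[[d]]
    utils::write.table(
      data.frame(df$chrom, df$start, df$end,
                 sprintf("peak_%02d_%d", d, seq_len(nrow(df))),
                 0L, ".", 5, 4, 3, (df$end - df$start) %/% 2L),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    p
  }, character(1))

  paths$vcf <- file.path(dir, "variants.vcf")
  write_fixture_vcf(vcf, chrom, cfg$genome_length, paths$vcf)

  paths$pileup <- file.path(dir, "pileup.tsv")
  utils::write.table(pile, paths$pileup, sep = "\t", quote = FALSE, row.names = FALSE)

  paths$genes <- file.path(dir, "genes.bed")
  gene_bed <- data.frame(
    chrom = chrom, start = genes$start, end = genes$end, name = genes$symbol,
    score = 0L, strand = "+", thickStart = genes$start, thickEnd = genes$end,
    rgb = "0,0,0", blockCount = 2L,
    blockSizes = sprintf("%d,%d,", 200L, 200L),
    blockStarts = sprintf("%d,%d,", 0L, genes$end - genes$start - 200L),
    stringsAsFactors = FALSE
  )
  utils::write.table(gene_bed, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  paths$e2_genes <- file.path(dir, "e2_genes.txt")
  writeLines(sort(unique(e2_genes)), paths$e2_genes)

  paths$expression <- file.path(dir, "expression.tsv")
  utils::write.table(
    data.frame(gene = rownames(cohort$expr), cohort$expr, check.names = FALSE),
    paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$metadata <- file.path(dir, "metadata.tsv")
  utils::write.table(cohort$metadata, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$genotypes <- file.path(dir, "genotypes.tsv")
  utils::write.table(
    data.frame(regsnv_id = rownames(cohort$genotypes), cohort$genotypes,
               check.names = FALSE),
    paths$genotypes, sep = "\t", quote = FALSE, row.names = FALSE)

  truth_snvs <- data.frame(
    chrom = vcf$chrom, pos = vcf$pos, id = vcf$id, ref = vcf$ref, alt = vcf$alt,
    label = vcf$label, expected_disposition = vcf$disposition,
    stringsAsFactors = FALSE
  )
  paths$truth_snvs <- file.path(dir, "truth_snvs.tsv")
  utils::write.table(truth_snvs, paths$truth_snvs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth_associations <- file.path(dir, "truth_associations.tsv")
  utils::write.table(pairs, paths$truth_associations, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(paths = paths,
       truth = list(snvs = truth_snvs, associations = pairs),
       config = cfg)
}

#' Simulate one genotype-expression cohort with planted associations
#'
#' Expression is log2 TPM, gene baselines drawn once per gene, unit-variance
#' noise per sample; ER+ carriers of a "true" regSNV have their target gene
#' shifted by `effect_size`. Exactly `n_carriers` of the ER+ samples carry
#' each regSNV.
#'
#' @param pairs data.frame with regsnv_id and target_gene
#' @param true_pairs regsnv_ids whose targets receive the planted shift
#' @param n_samples,er_pos_fraction,n_carriers,effect_size,noise_sd design
#' @param seed integer
#' @return list with `expr` (genes x samples), `metadata`, `genotypes`
#' @export
make_cohort <- function(pairs, true_pairs, n_samples = 250L,
                        er_pos_fraction = 0.8, n_carriers = 30L,
                        effect_size = 2, noise_sd = 1, seed = 1L) {
  with_subseed(seed, 0L, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    n_pos <- round(n_samples * er_pos_fraction)
    er <- rep(c("pos", "neg"), c(n_pos, n_samples - n_pos))
    genes <- unique(pairs$target_gene)
    baseline <- stats::runif(length(genes), 4, 12)
    expr <- matrix(stats::rnorm(length(genes) * n_samples, 0, noise_sd),
                   nrow = length(genes), dimnames = list(genes, samples)) + baseline
    gt <- matrix("WT", nrow(pairs), n_samples,
                 dimnames = list(pairs$regsnv_id, samples))
    pos_idx <- which(er == "pos")
    neg_idx <- which(er == "neg")
    for (i in seq_len(nrow(pairs))) {
      carriers <- sample(pos_idx, n_carriers)
      gt[i, carriers] <- "carrier"
      if (length(neg_idx) > 0L) {
        neg_car <- neg_idx[stats::runif(length(neg_idx)) < n_carriers / length(pos_idx)]
        gt[i, neg_car] <- "carrier"
      }
      if (pairs$regsnv_id[i] %in% true_pairs) {
        expr[pairs$target_gene[i], carriers] <-
          expr[pairs$target_gene[i], carriers] + effect_size
      }
    }
    list(expr = expr,
         metadata = data.frame(sample = samples, er_status = er,
                               stringsAsFactors = FALSE),
         genotypes = gt)
  })
}

write_fixture_vcf <- function(v, chrom, contig_len, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, contig_len),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SAMPLE1"), collapse = "\t")
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%.1f\t.\tDP=%d\tGT:DP\t0/1:%d",
                  v$chrom, v$pos, v$id, v$ref, v$alt, v$qual, v$depth, v$depth)
  writeLines(c(header, body), path)
}
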