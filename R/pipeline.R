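#' Pipeline configuration
#'
#' Collects every input path and tunable of the regSNV workflow. Defaults
#' follow the study design: six-of-n consensus, depth >= 10 reads, site
#' quality >= Q20, 0.05 null-p cutoff, 5 kb estrogen-regulated-gene
#' proximity, 1 kb promoter / 5 kb upstream windows.
#'
#' @param genome FASTA path
#' @param peak_files character vector of BED6/narrowPeak paths
#' @param vcf variant call path
#' @param jaspar,transfac motif file paths (either may be NULL)
#' @param genes BED12/GFF3 gene-model path (optional)
#' @param e2_genes estrogen-regulated gene-symbol list path (optional)
#' @param pileup per-site allele count TSV (optional)
#' @param expression,metadata,genotypes expression-cohort TSV paths (optional)
#' @param k consensus support threshold
#' @param min_depth,min_qual variant filters
#' @param background background base probabilities
#' @param pseudocount,granularity log-odds construction parameters
#' @param null_mode,null_samples,seed ratio-null construction
#' @param alpha regSNV significance cutoff on the null p-value
#' @param max_dist E2-gene proximity cutoff (bp, strict)
#' @param promoter_window,upstream_window annotation windows (bp)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(genome, peak_files, vcf,
                            jaspar = NULL, transfac = NULL,
                            genes = NULL, e2_genes = NULL, pileup = NULL,
                            expression = NULL, metadata = NULL, genotypes = NULL,
                            k = 6L, min_depth = 10, min_qual = 20,
                            background = uniform_background(),
                            pseudocount = 0.8, granularity = 1e-3,
                            null_mode = "monte_carlo", null_samples = 10000L,
                            seed = 1L, alpha = 0.05, max_dist = 5000L,
                            promoter_window = 1000L, upstream_window = 5000L) {
  cfg <- as.list(environment())
  if (length(cfg$peak_files) < 1L) stop("config error: no peak files")
  if (cfg$k > length(cfg$peak_files)) {
    stop(sprintf("config error: k = %d exceeds the %d peak datasets",
                 cfg$k, length(cfg$peak_files)))
  }
  if (is.null(cfg$jaspar) && is.null(cfg$transfac)) {
    stop("config error: at least one motif file (jaspar/transfac) is required")
  }
  for (f in c(cfg$genome, cfg$peak_files, cfg$vcf, cfg$jaspar, cfg$transfac,
              cfg$genes, cfg$e2_genes, cfg$pileup, cfg$expression,
              cfg$metadata, cfg$genotypes)) {
    if (!file.exists(f)) stop(sprintf("config error: input not readable: %s", f))
  }
  if (cfg$alpha <= 0 || cfg$min_depth < 0 || cfg$min_qual < 0 || cfg$max_dist <= 0) {
    stop("config error: thresholds must be positive")
  }
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(unclass(cfg))), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full regSNV detection workflow
#'
#' Stages, in order: consensus peak construction, variant filtering, motif
#' impact scoring against every matrix, regSNV ranking, gene annotation, the
#' estrogen-regulated-gene proximity filter, allele-specific binding tests,
#' and carrier-vs-WT expression association. Each output file carries a
#' header line recording the configuration hash and seed; a rerun with the
#' same configuration and inputs is byte-identical.
#'
#' @param cfg a [pipeline_config()]
#' @param out_dir output directory
#' @return (invisibly) list with the in-memory results of every stage and
#'   `paths` of the written files
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  stamp <- sprintf("# regsnv config_hash=%s seed=%d", hash, as.integer(cfg$seed))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  stage <- "consensus"
  res <- tryCatch({
    peak_sets <- lapply(cfg$peak_files, read_peaks)
    cps <- consensus_peaks(peak_sets, cfg$k)
    st <- peak_stats(cps)
    note("consensus: %d datasets, k=%d -> %d intervals, mean width %.1f bp",
         length(peak_sets), cfg$k, st$count, st$mean_width)

    stage <- "filter"
    calls <- read_vcf(cfg$vcf)
    flt <- apply_filters(calls, cps, cfg$min_depth, cfg$min_qual)
    note("filter: %d calls -> %d pass (depth %d, qual %d, not_snv %d, outside %d)",
         flt$report$total, flt$report$counts$pass, flt$report$counts$fail_depth,
         flt$report$counts$fail_qual, flt$report$counts$fail_not_snv,
         flt$report$counts$fail_outside_peak)

    stage <- "score"
    mats <- list()
    if (!is.null(cfg$jaspar)) mats <- c(mats, list(parse_jaspar(cfg$jaspar)))
    if (!is.null(cfg$transfac)) mats <- c(mats, list(parse_transfac(cfg$transfac)))
    loms <- lapply(mats, log_odds, bg = cfg$background,
                   pseudocount = cfg$pseudocount, granularity = cfg$granularity)
    dists <- lapply(loms, score_distribution)
    nulls <- lapply(seq_along(loms), function(i) {
      build_ratio_null(loms[[i]], dists[[i]], mode = cfg$null_mode,
                       n_samples = cfg$null_samples, seed = cfg$seed + i)
    })
    genome <- Biostrings::readDNAStringSet(cfg$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    assessed <- lapply(seq_len(nrow(flt$passing)), function(i) {
      v <- flt$passing[i, ]
      ctx <- build_contexts(v$chrom, v$pos, v$ref, v$alt, genome,
                            w = max(vapply(loms, `[[`, integer(1), "width")))
      out <- assess_variant(ctx, loms, dists, nulls, alpha = cfg$alpha)
      out$id <- v$id
      out
    })
    assessed <- if (length(assessed)) do.call(rbind, assessed) else
      stop("no variants passed filtering")
    ranked <- rank_regsnvs(assessed)
    regsnvs <- ranked[ranked$significant, , drop = FALSE]
    note("score: %d variants x %d matrices -> %d regSNV calls (%d increase, %d decrease)",
         nrow(flt$passing), length(loms), nrow(regsnvs),
         sum(regsnvs$direction == "increase"), sum(regsnvs$direction == "decrease"))

    stage <- "annotate"
    annotated <- e2_kept <- NULL
    if (!is.null(cfg$genes)) {
      genes <- read_genes(cfg$genes)
      annotated <- annotate_regsnvs(regsnvs, genes,
                                    cfg$promoter_window, cfg$upstream_window)
      note("annotate: categories %s",
           paste(names(table(annotated$category)), table(annotated$category),
                 sep = "=", collapse = " "))
      if (!is.null(cfg$e2_genes)) {
        e2 <- read_gene_list(cfg$e2_genes)
        e2_kept <- e2_proximity_filter(annotated, e2, cfg$max_dist)
        note("e2_filter: %d increase-direction calls within %d bp of an E2 gene",
             nrow(e2_kept), cfg$max_dist)
      }
    }

    stage <- "allelic"
    allelic <- NULL
    if (!is.null(cfg$pileup)) {
      sites <- unique(regsnvs[, c("chrom", "pos", "ref", "alt")])
      pile <- read_pileup(cfg$pileup)
      sites <- sites[paste0(sites$chrom, ":", sites$pos) %in%
                       paste0(pile$chrom, ":", pile$pos), , drop = FALSE]
      allelic <- allelic_binding_table(sites, pile)
      note("allelic: %d sites tested, %d with sufficient coverage",
           nrow(allelic), sum(allelic$sufficient_coverage))
    }

    stage <- "associate"
    assoc <- NULL
    if (!is.null(cfg$expression) && !is.null(cfg$metadata) &&
        !is.null(cfg$genotypes) && !is.null(annotated)) {
      expr <- read_expression(cfg$expression)
      meta <- read_sample_metadata(cfg$metadata)
      gts <- read_genotypes(cfg$genotypes)
      targets <- unique(do.call(rbind, lapply(c("gene_5p", "gene_3p"), function(side) {
        data.frame(regsnv_id = paste0(annotated$chrom, ":", annotated$pos),
                   target_gene = annotated[[side]], stringsAsFactors = FALSE)
      })))
      targets <- targets[!is.na(targets$target_gene), , drop = FALSE]
      assoc <- associate_expression(targets, expr, meta, gts)
      note("associate: %d (regSNV, gene) pairs, %d testable, %d at BH q<0.05",
           nrow(assoc), sum(assoc$testable),
           sum(assoc$adjusted_p < 0.05, na.rm = TRUE))
    }

    list(consensus = cps, filter = flt, assessed = ranked, regsnvs = regsnvs,
         annotated = annotated, e2_kept = e2_kept, allelic = allelic,
         association = assoc)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  paths <- list()
  emit <- function(name, df, file) {
    p <- file.path(out_dir, file)
    con <- file(p, "w")
    writeLines(stamp, con)
    if (!is.null(df)) {
      df <- as.data.frame(df)
      df[] <- lapply(df, function(col) {
        if (is.numeric(col) && !is.integer(col)) signif(col, 10) else col
      })
      utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    close(con)
    paths[[name]] <<- p
  }
  ## consensus goes out as BED with the support count in the score column
  cons_bed <- file.path(out_dir, "consensus.bed")
  writeLines(stamp, cons_bed)
  cbed <- data.frame(res$consensus$chrom, res$consensus$start, res$consensus$end,
                     sprintf("consensus_%d", seq_len(nrow(res$consensus))),
                     res$consensus$support, ".")
  suppressWarnings(
    utils::write.table(cbed, cons_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE))
  paths$consensus <- cons_bed
  emit("filter_report",
       data.frame(disposition = names(res$filter$report$counts),
                  count = unlist(res$filter$report$counts)),
       "filter_report.tsv")
  emit("regsnvs", res$assessed, "regsnvs.tsv")
  if (!is.null(res$annotated)) emit("annotation", res$annotated, "annotation.tsv")
  if (!is.null(res$e2_kept)) emit("e2_filtered", res$e2_kept, "e2_filtered.tsv")
  if (!is.null(res$allelic)) emit("allelic", res$allelic, "allelic.tsv")
  if (!is.null(res$association)) emit("association", res$association, "association.tsv")
  logp <- file.path(out_dir, "run_log.txt")
  writeLines(c(stamp, log_lines), logp)
  paths$log <- logp

  res$paths <- paths
  res$log <- log_lines
  invisible(res)
}
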