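#' Read gene models from BED12 or GFF3
#'
#' BED12: block fields give the exon structure; a gene with `thickStart ==
#' thickEnd` (no CDS) is treated as non-coding RNA, otherwise coding. GFF3 is
#' read via rtracklayer; `gene` features (with an optional
#' `biotype`/`gene_biotype` attribute) define gene bodies and their `exon`
#' children the exon structure.
#'
#' @param path file path; format chosen by extension (`.bed` vs
#'   `.gff`/`.gff3`) unless `format` is given
#' @param format "bed12", "gff3" or NULL (auto)
#' @return data.frame with columns symbol, chrom, strand, start, end (0-based
#'   half-open), biotype ("coding"/"ncRNA") and a list-column `exons` of
#'   two-column (start, end) matrices
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed12"
  }
  format <- match.arg(format, c("bed12", "gff3"))
  if (format == "bed12") read_genes_bed12(path) else read_genes_gff3(path)
}

read_genes_bed12 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\\s+")[[1L]]
    if (length(f) < 12L) stop(sprintf("gene BED12 %s: fewer than 12 fields at line %d", path, i))
    start <- as.integer(f[2L]); end <- as.integer(f[3L])
    thick_start <- as.integer(f[7L]); thick_end <- as.integer(f[8L])
    nblocks <- as.integer(f[10L])
    sizes <- as.integer(strsplit(f[11L], ",")[[1L]])
    offsets <- as.integer(strsplit(f[12L], ",")[[1L]])
    if (length(sizes) != nblocks || length(offsets) != nblocks) {
      stop(sprintf("gene BED12 %s line %d: blockCount disagrees with block lists", path, i))
    }
    ex_start <- start + offsets
    ex_end <- ex_start + sizes
    if (any(ex_end > end) || any(ex_start < start)) {
      stop(sprintf("gene BED12 %s line %d: exon blocks outside gene body", path, i))
    }
    list(symbol = f[4L], chrom = f[1L], strand = f[6L], start = start, end = end,
         biotype = if (thick_start == thick_end) "ncRNA" else "coding",
         exons = cbind(start = ex_start, end = ex_end))
  })
  genes_df(rows)
}

read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  genes <- md[md$type == "gene", , drop = FALSE]
  exons <- md[md$type == "exon", , drop = FALSE]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    sym <- g$Name %||% g$ID
    if (is.na(sym)) sym <- g$ID
    parent_ids <- c(g$ID, sym)
    ex <- exons[vapply(exons$Parent, function(p) any(unlist(p) %in% parent_ids), logical(1)), ,
                drop = FALSE]
    biotype <- g$biotype %||% g$gene_biotype %||% "coding"
    if (is.na(biotype)) biotype <- "coding"
    biotype <- if (grepl("nc|lnc|lincRNA|antisense", biotype, ignore.case = TRUE)) "ncRNA" else "coding"
    ex_mat <- if (nrow(ex) > 0L) {
      cbind(start = ex$start - 1L, end = ex$end)   # GFF 1-based closed -> half-open
    } else {
      cbind(start = g$start - 1L, end = g$end)
    }
    ex_mat <- ex_mat[order(ex_mat[, 1L]), , drop = FALSE]
    list(symbol = as.character(sym), chrom = as.character(g$seqnames),
         strand = as.character(g$strand), start = g$start - 1L, end = g$end,
         biotype = biotype, exons = ex_mat)
  })
  genes_df(rows)
}

genes_df <- function(rows) {
  out <- data.frame(
    symbol = vapply(rows, `[[`, character(1), "symbol"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    biotype = vapply(rows, `[[`, character(1), "biotype"),
    stringsAsFactors = FALSE
  )
  out$exons <- lapply(rows, `[[`, "exons")
  out
}

#' Genomic-context category of a position
#'
#' Categories, in precedence order: `exonic` (inside a coding gene's exon),
#' `ncRNA` (inside a non-coding gene body), `intronic` (inside a coding gene
#' body but not an exon), `promoter` (within `promoter_window` bp upstream of
#' a TSS, strand-aware), `upstream` (beyond the promoter but within
#' `upstream_window` bp of the TSS), else `intergenic`.
#'
#' @param chrom,pos position (1-based); vectors are supported
#' @param genes data.frame from [read_genes()]
#' @param promoter_window,upstream_window distances upstream of the TSS, bp
#' @return character vector of categories
#' @export
classify_position <- function(chrom, pos, genes,
                              promoter_window = 1000L, upstream_window = 5000L) {
  mapply(function(ch, p) {
    pos0 <- p - 1L
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) return("intergenic")
    inside <- pos0 >= g$start & pos0 < g$end
    if (any(inside & g$biotype == "coding")) {
      for (i in which(inside & g$biotype == "coding")) {
        ex <- g$exons[[i]]
        if (any(pos0 >= ex[, "start"] & pos0 < ex[, "end"])) return("exonic")
      }
    }
    if (any(inside & g$biotype == "ncRNA")) return("ncRNA")
    if (any(inside)) return("intronic")
    ## strand-aware distance upstream of the TSS
    tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
    updist <- ifelse(g$strand == "-", pos0 - tss, tss - pos0)
    up <- updist > 0
    if (any(up & updist <= promoter_window)) return("promoter")
    if (any(up & updist <= upstream_window)) return("upstream")
    "intergenic"
  }, chrom, pos, USE.NAMES = FALSE)
}

#' Nearest genes on each genomic side
#'
#' Gene-body distances: 0 when the position falls inside a gene (that gene is
#' then reported on both sides); otherwise `pos0 - end` for genes to the left
#' (5' in genome coordinates) and `start - pos0` for genes to the right. Ties
#' are broken by symbol lexicographic order.
#'
#' @param chrom,pos position (1-based, scalars)
#' @param genes data.frame from [read_genes()]
#' @return list with `gene_5p`, `dist_5p`, `gene_3p`, `dist_3p` (NA when a
#'   side has no gene)
#' @export
nearest_genes <- function(chrom, pos, genes) {
  pos0 <- pos - 1L
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  empty <- list(gene_5p = NA_character_, dist_5p = NA_integer_,
                gene_3p = NA_character_, dist_3p = NA_integer_)
  if (nrow(g) == 0L) return(empty)
  inside <- which(pos0 >= g$start & pos0 < g$end)
  if (length(inside) > 0L) {
    sym <- sort(g$symbol[inside])[1L]
    return(list(gene_5p = sym, dist_5p = 0L, gene_3p = sym, dist_3p = 0L))
  }
  out <- empty
  left <- which(g$end <= pos0)
  if (length(left) > 0L) {
    d <- pos0 - g$end[left]
    best <- left[order(d, g$symbol[left])][1L]
    out$gene_5p <- g$symbol[best]
    out$dist_5p <- pos0 - g$end[best]
  }
  right <- which(g$start > pos0)
  if (length(right) > 0L) {
    d <- g$start[right] - pos0
    best <- right[order(d, g$symbol[right])][1L]
    out$gene_3p <- g$symbol[best]
    out$dist_3p <- g$start[best] - pos0
  }
  out
}

#' Annotate ranked regSNV calls with genomic context and flanking genes
#'
#' @param results data.frame with chrom/pos columns (one row per call)
#' @param genes data.frame from [read_genes()]
#' @param promoter_window,upstream_window see [classify_position()]
#' @return `results` with added columns category, gene_5p, dist_5p, gene_3p,
#'   dist_3p
#' @export
annotate_regsnvs <- function(results, genes,
                             promoter_window = 1000L, upstream_window = 5000L) {
  if (nrow(results) == 0L) {
    results$category <- character(0)
    results$gene_5p <- character(0); results$dist_5p <- integer(0)
    results$gene_3p <- character(0); results$dist_3p <- integer(0)
    return(results)
  }
  results$category <- classify_position(results$chrom, results$pos, genes,
                                        promoter_window, upstream_window)
  nn <- lapply(seq_len(nrow(results)), function(i) {
    nearest_genes(results$chrom[i], results$pos[i], genes)
  })
  results$gene_5p <- vapply(nn, `[[`, character(1), "gene_5p")
  results$dist_5p <- vapply(nn, `[[`, integer(1), "dist_5p")
  results$gene_3p <- vapply(nn, `[[`, character(1), "gene_3p")
  results$dist_3p <- vapply(nn, `[[`, integer(1), "dist_3p")
  results
}

#' Estrogen-regulated-gene proximity filter
#'
#' Keeps calls predicted to increase binding whose nearest gene on either
#' side is in the supplied estrogen-regulated gene list at a distance
#' strictly below `max_dist`.
#'
#' @param records annotated results from [annotate_regsnvs()]
#' @param e2_genes character vector of estrogen-regulated gene symbols
#' @param max_dist maximum distance in bp (strict `<`)
#' @param direction_required direction a call must have to be kept
#' @return the filtered data.frame
#' @export
e2_proximity_filter <- function(records, e2_genes, max_dist = 5000L,
                                direction_required = "increase") {
  if (nrow(records) == 0L) return(records)
  near_e2 <- (!is.na(records$gene_5p) & records$gene_5p %in% e2_genes &
                records$dist_5p < max_dist) |
             (!is.na(records$gene_3p) & records$gene_3p %in% e2_genes &
                records$dist_3p < max_dist)
  keep <- records$direction == direction_required & near_e2
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a one-symbol-per-line gene list
#' @param path file path
#' @return character vector of symbols
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
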