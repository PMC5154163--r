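#' Position matrix constructor
#'
#' A transcription-factor binding motif represented as per-position base
#' counts (or frequencies). Counts are stored as a 4 x w matrix with rows
#' A, C, G, T.
#'
#' @param counts numeric 4 x w matrix, rownames A/C/G/T, non-negative
#' @param matrix_id character identifier
#' @param source one of "JASPAR", "TRANSFAC"
#' @return an object of class `position_matrix`
#' @export
position_matrix <- function(counts, matrix_id = "motif", source = c("JASPAR", "TRANSFAC")) {
  source <- match.arg(source)
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  if (!setequal(rownames(counts), DNA_BASES)) stop("count rows must be named A, C, G, T")
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (ncol(counts) < 1L) stop("motif width must be >= 1")
  if (any(counts < 0) || any(!is.finite(counts))) stop("counts must be finite and non-negative")
  structure(
    list(matrix_id = matrix_id, source = source, counts = counts, width = ncol(counts)),
    class = "position_matrix"
  )
}

#' @export
print.position_matrix <- function(x, ...) {
  cat(sprintf("Position matrix '%s' (%s), width %d\n", x$matrix_id, x$source, x$width))
  print(x$counts)
  invisible(x)
}

#' Parse a JASPAR position frequency matrix
#'
#' Accepts both the bracketed dialect (`A [ 4 0 ]`) and the bare dialect
#' (`A 4 0`). A header line starting with `>` supplies the matrix id.
#'
#' @param text character vector of lines, a single string with newlines, or a
#'   file path (when `is_file = TRUE` or the single string names an existing file)
#' @param is_file force interpretation of `text` as a path
#' @return a [position_matrix()]
#' @export
parse_jaspar <- function(text, is_file = NA) {
  lines <- as_lines(text, is_file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("JASPAR parse error: empty input")
  id <- "motif"
  if (startsWith(trimws(lines[1L]), ">")) {
    id <- sub("^>\\s*", "", trimws(lines[1L]))
    id <- strsplit(id, "\\s+")[[1L]][1L]
    lines <- lines[-1L]
  }
  if (length(lines) != 4L) {
    stop(sprintf("JASPAR parse error: expected 4 base rows, got %d", length(lines)))
  }
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- gsub("[][]", " ", lines[i])
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    base <- toupper(toks[1L])
    if (!base %in% DNA_BASES) {
      stop(sprintf("JASPAR parse error at row %d: row label '%s' is not A/C/G/T", i, toks[1L]))
    }
    vals <- suppressWarnings(as.numeric(toks[-1L]))
    if (length(vals) == 0L || anyNA(vals)) {
      stop(sprintf("JASPAR parse error at row %d: non-numeric count", i))
    }
    if (any(vals < 0)) stop(sprintf("JASPAR parse error at row %d: negative count", i))
    rows[[base]] <- vals
  }
  if (length(rows) != 4L) stop("JASPAR parse error: duplicated or missing base row")
  w <- unique(lengths(rows))
  if (length(w) != 1L) stop("JASPAR parse error: rows have differing lengths")
  counts <- do.call(rbind, rows[DNA_BASES])
  rownames(counts) <- DNA_BASES
  position_matrix(counts, matrix_id = id, source = "JASPAR")
}

#' Parse a TRANSFAC matrix block
#'
#' Expects an optional `ID` line, a `P0` (or `PO`) column-header line naming
#' the base order, numbered per-position rows (`01  4 0 0 0  A`) and a `//`
#' terminator.
#'
#' @inheritParams parse_jaspar
#' @return a [position_matrix()]
#' @export
parse_transfac <- function(text, is_file = NA) {
  lines <- as_lines(text, is_file)
  id <- "motif"
  idl <- grep("^ID\\s+", lines, value = TRUE)
  if (length(idl) >= 1L) id <- strsplit(trimws(sub("^ID\\s+", "", idl[1L])), "\\s+")[[1L]][1L]
  p0 <- grep("^P0|^PO", lines)
  if (length(p0) == 0L) stop("TRANSFAC parse error: missing P0 header line")
  p0 <- p0[1L]
  hdr <- strsplit(trimws(lines[p0]), "\\s+")[[1L]][-1L]
  hdr <- toupper(hdr)
  if (!setequal(hdr, DNA_BASES)) {
    stop("TRANSFAC parse error: P0 header must name columns A, C, G, T")
  }
  term <- grep("^//", lines)
  term <- term[term > p0]
  if (length(term) == 0L) stop("TRANSFAC parse error: missing '//' terminator")
  body <- lines[(p0 + 1L):(term[1L] - 1L)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("TRANSFAC parse error: no matrix rows between P0 and '//'")
  counts <- matrix(0, nrow = 4L, ncol = length(body), dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(body)) {
    toks <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    rownum <- suppressWarnings(as.integer(toks[1L]))
    if (is.na(rownum)) {
      stop(sprintf("TRANSFAC parse error at matrix row %d: row number expected", i))
    }
    if (rownum != i) {
      stop(sprintf("TRANSFAC parse error: non-contiguous row numbers (row %d labelled %02d)", i, rownum))
    }
    vals <- suppressWarnings(as.numeric(toks[2:5]))
    if (anyNA(vals)) stop(sprintf("TRANSFAC parse error at matrix row %d: non-numeric count", i))
    if (any(vals < 0)) stop(sprintf("TRANSFAC parse error at matrix row %d: negative count", i))
    counts[hdr, i] <- vals
  }
  position_matrix(counts, matrix_id = id, source = "TRANSFAC")
}

#' Write a position matrix in JASPAR PFM layout
#' @param m a [position_matrix()]
#' @param path output file; when NULL the lines are returned invisibly
#' @export
write_jaspar <- function(m, path = NULL) {
  stopifnot(inherits(m, "position_matrix"))
  lines <- c(
    paste0(">", m$matrix_id),
    vapply(DNA_BASES, function(b) {
      paste0(b, " [ ", paste(format_count(m$counts[b, ]), collapse = " "), " ]")
    }, character(1))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a position matrix as a TRANSFAC block
#' @inheritParams write_jaspar
#' @export
write_transfac <- function(m, path = NULL) {
  stopifnot(inherits(m, "position_matrix"))
  body <- vapply(seq_len(m$width), function(j) {
    col <- m$counts[, j]
    cons <- DNA_BASES[which.max(col)]
    paste0(sprintf("%02d", j), "  ", paste(format_count(col), collapse = " "), "  ", cons)
  }, character(1))
  lines <- c(paste("ID", m$matrix_id), "P0      A C G T", body, "//")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

format_count <- function(x) {
  ifelse(x == round(x), format(as.integer(round(x))), format(x))
}

as_lines <- function(text, is_file = NA) {
  if (length(text) == 1L) {
    looks_like_file <- if (is.na(is_file)) !grepl("\n", text) && file.exists(text) else is_file
    if (looks_like_file) return(readLines(text, warn = FALSE))
    return(strsplit(text, "\n", fixed = TRUE)[[1L]])
  }
  text
}
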