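DNA_BASES <- c("A", "C", "G", "T")

#' Convert a nucleotide string to integer codes
#'
#' A=1, C=2, G=3, T=4; any other character becomes NA. Case-insensitive.
#' @param seq single character string
#' @return integer vector of length nchar(seq)
#' @keywords internal
seq_to_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(chars, DNA_BASES)
}

codes_to_seq <- function(codes) {
  paste(ifelse(is.na(codes), "N", DNA_BASES[codes]), collapse = "")
}

## complement of codes: A<->T (1<->4), C<->G (2<->3)
complement_codes <- function(codes) 5L - codes

reverse_complement <- function(seq) {
  codes_to_seq(rev(complement_codes(seq_to_codes(seq))))
}

#' Run an expression under a derived RNG sub-stream
#'
#' Saves and restores the caller's RNG state so that independently generated
#' fixture components never perturb one another.
#' @keywords internal
with_subseed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## validated background model: named probabilities over A,C,G,T
check_background <- function(bg) {
  if (is.null(names(bg))) names(bg) <- DNA_BASES
  if (!setequal(names(bg), DNA_BASES)) {
    stop("background model must name probabilities for A, C, G, T")
  }
  bg <- bg[DNA_BASES]
  if (any(bg <= 0)) stop("background probabilities must be positive")
  if (abs(sum(bg) - 1) > 1e-9) stop("background probabilities must sum to 1")
  bg
}

#' Uniform background nucleotide model
#' @return named numeric vector of probabilities over A, C, G, T
#' @export
uniform_background <- function() {
  c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
}
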