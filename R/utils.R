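#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Complements A/C/G/T (N maps to N) and reverses. Vectorised over its input.
#'
#' @param x character vector of DNA strings over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch]
    if (anyNA(comp)) stop("revcomp: non-DNA character in sequence")
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Derive a reproducible sub-seed from a master seed and a stream tag
#'
#' Keeps independent RNG streams per operation (and per sample) so that adding
#' draws to one stream does not perturb another. The derived seed stays within
#' 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the stream (e.g. "counts", "reads:s01").
#' @return an integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 104729L
  as.integer((abs(seed) + 7919 * h) %% (.Machine$integer.max - 1L)) + 1L
}

# strict scalar checks used across parsers
.chk_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stop(nm, " must be TRUE or FALSE")
  x
}
.chk_num <- function(x, nm, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(nm, " must be a number in [", lo, ", ", hi, "]")
  x
}
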