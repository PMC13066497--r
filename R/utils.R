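# Small shared helpers: sequence utilities, deterministic per-anchor seeding,
# and the percent formatting used in run summaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @examples
#' revComp("ACGTT")
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b single strings of equal length.
#' @return integer number of differing positions.
#' @examples
#' hammingDist("ACGT", "ACGA")
#' @export
hammingDist <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hammingDist: sequences have different lengths (",
         nchar(a), " vs ", nchar(b), ")")
  }
  sum(charToRaw(a) != charToRaw(b))
}

#' Deterministic per-anchor random seed
#'
#' Derives a 31-bit seed from an anchor sequence and a master seed by a
#' polynomial rolling hash, so per-anchor random streams do not depend on the
#' order in which anchors are processed.
#'
#' @param anchor anchor sequence (single string).
#' @param master master seed (integer).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
anchorSeed <- function(anchor, master = 0L) {
  stopifnot(is.character(anchor), length(anchor) == 1L)
  h <- 0
  for (code in utf8ToInt(anchor)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((h + (as.numeric(master) %% 2147483647) * 7919) %% 2147483647)
}

# uniform random DNA string of length n, from the current RNG stream
randomDNA <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# all k-mer substrings of a single sequence (character vector, possibly empty)
kmersOf <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Percentage of a count ratio, rounded as reported
#'
#' Percentages are rounded to two decimals; below 1% trailing zeros are
#' dropped in the formatted form (so 0.398% prints as "0.4").
#'
#' @param num,den integer numerator and denominator.
#' @return `percentOf()`: numeric percentage rounded to two decimals;
#'   `formatPercent()`: the corresponding display string.
#' @examples
#' percentOf(408, 10567)    # 3.86
#' formatPercent(134, 33650) # "0.4"
#' @export
percentOf <- function(num, den) {
  if (den == 0) return(0)
  round(100 * num / den, 2)
}

#' @rdname percentOf
#' @export
formatPercent <- function(num, den) {
  p <- percentOf(num, den)
  s <- formatC(p, format = "f", digits = 2)
  if (p < 1) s <- sub("\\.?0+$", "", s)
  if (s == "") s <- "0"
  s
}
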