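# Artifact screening: anchors matching sequencing adapters/vectors are
# flagged before any downstream interpretation. Anchors are exactly k nt, so
# exact k-mer membership (closed under reverse complement) replaces read
# alignment; a mismatch-tolerant scan is available for parity with aligner
# sensitivity.

#' Build an exact k-mer contaminant index
#'
#' Indexes every k-mer substring of every record of a contaminant FASTA
#' (adapters, vectors) together with its reverse complement.
#'
#' @param contaminants path to a FASTA file, a `DNAStringSet`, or a character
#'   vector of sequences.
#' @param k k-mer length (the anchor length; default 27).
#' @return a [ContaminantIndex-class].
#' @export
buildContaminantIndex <- function(contaminants, k = 27L) {
  if (is.character(contaminants) && length(contaminants) == 1L &&
      file.exists(contaminants)) {
    contaminants <- Biostrings::readDNAStringSet(contaminants)
  }
  seqs <- as.character(contaminants)
  if (!length(seqs)) {
    warning("empty contaminant input: nothing will be flagged")
    return(new("ContaminantIndex", kmers = character(0), k = as.integer(k)))
  }
  kmers <- unlist(lapply(seqs, kmersOf, k = k), use.names = FALSE)
  kmers <- unique(c(kmers, revComp(kmers)))
  new("ContaminantIndex", kmers = sort(kmers), k = as.integer(k))
}

#' Screen anchors against a contaminant index
#'
#' TRUE marks an artifact. Exact membership by default; with
#' `max_mismatch > 0` an anchor is flagged when any indexed k-mer is within
#' that Hamming distance (brute-force scan).
#'
#' @param anchors character vector of anchor sequences (length k).
#' @param index a [ContaminantIndex-class].
#' @param max_mismatch maximum Hamming distance still flagged (default 0,
#'   exact matching).
#' @return logical vector, one flag per anchor.
#' @export
screenAnchors <- function(anchors, index, max_mismatch = 0L) {
  stopifnot(is(index, "ContaminantIndex"))
  if (!length(index@kmers)) return(rep(FALSE, length(anchors)))
  if (any(nchar(anchors) != index@k)) {
    stop("anchors must have length k = ", index@k)
  }
  if (max_mismatch == 0L) {
    return(anchors %in% index@kmers)
  }
  vapply(anchors, function(a) {
    raw_a <- charToRaw(a)
    for (km in index@kmers) {
      if (sum(raw_a != charToRaw(km)) <= max_mismatch) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}
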