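# Central S4 classes. An AnchorTable is the per-anchor sample x target count
# matrix every downstream stage consumes; AnchorTableSet is the collection
# built from a whole dataset, backed by a long-format count table.

#' AnchorTable: per-anchor sample-by-target counts
#'
#' Holds, for one anchor sequence, the matrix of read counts with samples as
#' rows and target sequences as columns. Row/column names are required.
#' `totalTargets` records the number of distinct targets observed before any
#' truncation to the most frequent targets.
#'
#' @slot anchor anchor sequence (single string).
#' @slot counts numeric matrix, samples x targets, non-negative, with dimnames.
#' @slot totalTargets integer, distinct targets before truncation.
#' @export
setClass("AnchorTable",
  slots = c(anchor = "character", counts = "matrix", totalTargets = "integer")
)

setValidity("AnchorTable", function(object) {
  msg <- character(0)
  if (length(object@anchor) != 1L || !nzchar(object@anchor))
    msg <- c(msg, "anchor must be a single non-empty string")
  cts <- object@counts
  if (!is.numeric(cts)) msg <- c(msg, "counts must be numeric")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msg <- c(msg, "counts must have sample row names and target column names")
  if (!is.null(colnames(cts)) && anyDuplicated(colnames(cts)))
    msg <- c(msg, "duplicate target columns")
  if (length(object@totalTargets) != 1L || object@totalTargets < ncol(cts))
    msg <- c(msg, "totalTargets must be a single integer >= ncol(counts)")
  if (length(msg)) msg else TRUE
})

#' Construct an AnchorTable
#'
#' @param anchor anchor sequence.
#' @param counts samples x targets count matrix with dimnames.
#' @param totalTargets distinct targets before truncation (default
#'   `ncol(counts)`).
#' @return an [AnchorTable-class] object.
#' @export
AnchorTable <- function(anchor, counts, totalTargets = ncol(counts)) {
  counts <- as.matrix(counts)
  new("AnchorTable", anchor = anchor, counts = counts,
      totalTargets = as.integer(totalTargets))
}

#' @describeIn AnchorTable anchor sequence accessor.
#' @param x an AnchorTable.
#' @export
setGeneric("anchorSequence", function(x) standardGeneric("anchorSequence"))

#' @export
setMethod("anchorSequence", "AnchorTable", function(x) x@anchor)

#' @describeIn AnchorTable count matrix accessor.
#' @export
setGeneric("anchorCounts", function(x) standardGeneric("anchorCounts"))

#' @export
setMethod("anchorCounts", "AnchorTable", function(x) x@counts)

#' Derived statistics of an AnchorTable
#'
#' `sampleTotals()` gives per-sample totals n_j, `targetTotals()` per-target
#' totals N_t, `totalCount()` the grand total M, and `rankedTargets()` the
#' targets ordered by decreasing total count with lexicographic tie-breaking.
#'
#' @param x an [AnchorTable-class].
#' @return numeric vector / scalar / character vector respectively.
#' @export
sampleTotals <- function(x) rowSums(anchorCounts(x))

#' @rdname sampleTotals
#' @export
targetTotals <- function(x) colSums(anchorCounts(x))

#' @rdname sampleTotals
#' @export
totalCount <- function(x) sum(anchorCounts(x))

#' @rdname sampleTotals
#' @export
rankedTargets <- function(x) {
  tot <- targetTotals(x)
  names(tot)[order(-tot, names(tot))]
}

setMethod("show", "AnchorTable", function(object) {
  cat("AnchorTable for anchor", object@anchor, "\n")
  cat("  ", nrow(object@counts), "samples x", ncol(object@counts),
      "targets (", object@totalTargets, "before truncation ), M =",
      sum(object@counts), "\n")
})

#' AnchorTableSet: all anchor tables of a dataset
#'
#' Backed by a long-format table with columns `anchor`, `sample_id`, `target`,
#' `count`. Individual [AnchorTable-class] objects are materialized on demand
#' with [anchorTable()].
#'
#' @slot pairs data.table of (anchor, sample_id, target, count).
#' @slot samples character vector of all sample names (a sample with zero
#'   counts for some anchor still appears as a zero row in its table).
#' @slot config extraction configuration used to build the set.
#' @export
setClass("AnchorTableSet",
  slots = c(pairs = "data.frame", samples = "character", config = "list")
)

setValidity("AnchorTableSet", function(object) {
  need <- c("anchor", "sample_id", "target", "count")
  if (!all(need %in% names(object@pairs)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  if (nrow(object@pairs) && any(object@pairs$count < 0))
    return("counts must be non-negative")
  if (!all(unique(object@pairs$sample_id) %in% object@samples))
    return("pairs contain samples missing from the samples slot")
  TRUE
})

#' @describeIn AnchorTableSet anchors present in the set.
#' @param x an AnchorTableSet.
#' @export
setGeneric("anchorNames", function(x) standardGeneric("anchorNames"))

#' @export
setMethod("anchorNames", "AnchorTableSet", function(x) {
  sort(unique(x@pairs$anchor))
})

#' @describeIn AnchorTableSet sample names.
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @export
setMethod("sampleNames", "AnchorTableSet", function(x) x@samples)

setMethod("length", "AnchorTableSet", function(x) {
  length(unique(x@pairs$anchor))
})

setMethod("show", "AnchorTableSet", function(object) {
  cat("AnchorTableSet:", length(object), "anchors,",
      length(object@samples), "samples, total pairs =",
      sum(object@pairs$count), "\n")
})

#' AnchorTestResults: per-anchor significance results
#'
#' @slot results data.frame with one row per tested anchor: `anchor`,
#'   `p_value`, `q_value`, `effect_size` (NA when not emitted),
#'   `n_unique_targets`, `mean_hamming_to_top`, `M`, `significant`.
#' @slot embeddings named list (by anchor) of the optimized embeddings:
#'   `c` (per-sample, in -1/+1), `f` (per-target, in 0/1), `mu_train`,
#'   `S_train`, test totals `m_j`.
#' @slot config test configuration used.
#' @export
setClass("AnchorTestResults",
  slots = c(results = "data.frame", embeddings = "list", config = "list")
)

setMethod("show", "AnchorTestResults", function(object) {
  n <- nrow(object@results)
  cat("AnchorTestResults:", n, "anchors tested,",
      sum(object@results$significant), "significant at FDR",
      object@config$fdr_threshold, "\n")
})

#' @describeIn AnchorTestResults result table accessor.
#' @param x an AnchorTestResults.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @export
setMethod("resultTable", "AnchorTestResults", function(x) x@results)

#' @describeIn AnchorTestResults anchors significant at the configured FDR.
#' @export
setGeneric("significantAnchors", function(x) standardGeneric("significantAnchors"))

#' @export
setMethod("significantAnchors", "AnchorTestResults", function(x) {
  x@results$anchor[x@results$significant]
})

#' ContaminantIndex: exact k-mer membership index for artifact screening
#'
#' Contains every k-mer of the indexed sequences and their reverse
#' complements (closed under reverse complement).
#'
#' @slot kmers sorted character vector of k-mers.
#' @slot k k-mer length.
#' @export
setClass("ContaminantIndex", slots = c(kmers = "character", k = "integer"))

setValidity("ContaminantIndex", function(object) {
  if (length(object@kmers) == 0L) return(TRUE)
  if (any(nchar(object@kmers) != object@k))
    return("all k-mers must have length k")
  rc <- revComp(object@kmers)
  if (!all(rc %in% object@kmers))
    return("index is not closed under reverse complement")
  TRUE
})

setMethod("show", "ContaminantIndex", function(object) {
  cat("ContaminantIndex:", length(object@kmers), "k-mers (k =", object@k, ")\n")
})

setMethod("length", "ContaminantIndex", function(x) length(x@kmers))

#' AlignmentBlocks: placement of a concatenated anchor+target on the reference
#'
#' `status` is one of `"contiguous"`, `"spliced"`, `"unaligned"`. For spliced
#' placements there are two blocks on the same chromosome and strand, and
#' `junction` holds `(donor_end, acceptor_start)`: the 1-based coordinates of
#' the last base of the upstream block and the first base of the downstream
#' block (so the skipped interval is `[donor_end + 1, acceptor_start - 1]`).
#'
#' @slot status alignment status.
#' @slot blocks GRanges of 0 (unaligned), 1 (contiguous) or 2 (spliced) blocks.
#' @slot junction integer(2) `(donor_end, acceptor_start)`, NA when not spliced.
#' @slot multiplicity number of equally good placements found.
#' @export
setClass("AlignmentBlocks",
  slots = c(status = "character", blocks = "GRanges",
            junction = "integer", multiplicity = "integer")
)

setValidity("AlignmentBlocks", function(object) {
  if (!object@status %in% c("contiguous", "spliced", "unaligned"))
    return("status must be contiguous, spliced or unaligned")
  nb <- length(object@blocks)
  if (object@status == "unaligned" && nb != 0L)
    return("unaligned placements must have no blocks")
  if (object@status == "contiguous" && nb != 1L)
    return("contiguous placements must have exactly one block")
  if (object@status == "spliced") {
    if (nb < 2L) return("spliced placements must have two blocks")
    if (length(unique(as.character(seqnames(object@blocks)))) != 1L ||
        length(unique(as.character(strand(object@blocks)))) != 1L)
      return("spliced blocks must share chromosome and strand")
    if (length(object@junction) != 2L || any(is.na(object@junction)))
      return("spliced placements need a (donor_end, acceptor_start) junction")
  }
  TRUE
})

#' @describeIn AlignmentBlocks alignment status accessor.
#' @param x an AlignmentBlocks.
#' @export
setGeneric("alignmentStatus", function(x) standardGeneric("alignmentStatus"))

#' @export
setMethod("alignmentStatus", "AlignmentBlocks", function(x) x@status)

#' @describeIn AlignmentBlocks blocks accessor (GRanges).
#' @export
setGeneric("alignmentBlocks", function(x) standardGeneric("alignmentBlocks"))

#' @export
setMethod("alignmentBlocks", "AlignmentBlocks", function(x) x@blocks)

#' @describeIn AlignmentBlocks junction accessor, `(donor_end, acceptor_start)`.
#' @export
setGeneric("alignmentJunction", function(x) standardGeneric("alignmentJunction"))

#' @export
setMethod("alignmentJunction", "AlignmentBlocks", function(x) x@junction)

setMethod("show", "AlignmentBlocks", function(object) {
  cat("AlignmentBlocks:", object@status)
  if (object@status != "unaligned") {
    b <- object@blocks
    cat(" ", paste(sprintf("%s:%d-%d(%s)", as.character(seqnames(b)),
                           start(b), end(b), as.character(strand(b))),
                   collapse = " | "))
    if (object@status == "spliced")
      cat("  junction", object@junction[1], "->", object@junction[2])
  }
  cat("\n")
})

#' GroundTruth: planted event registry for a synthetic dataset
#'
#' @slot config the [simConfig()] used.
#' @slot genome DNAStringSet of the synthetic genome.
#' @slot exons GRanges of exon records with a `gene` metadata column.
#' @slot haplotypes data.frame of planted haplotype substitutions.
#' @slot contaminants DNAStringSet of foreign (non-genomic) sequences.
#' @slot events data.frame, one row per planted event, including the two
#'   discriminating 54-nt sequences (`seq1`, `seq2`) and the shared anchor.
#' @slot realized data.frame of realized per-sample isoform read counts
#'   (filled by [writeDataset()] / [simulateSample()]).
#' @export
setClass("GroundTruth",
  slots = c(config = "list", genome = "DNAStringSet", exons = "GRanges",
            haplotypes = "data.frame", contaminants = "DNAStringSet",
            events = "data.frame", realized = "data.frame")
)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@events), "planted events,",
      sum(width(object@genome)), "bp genome,",
      length(object@contaminants), "foreign sequences\n")
  if (nrow(object@events))
    print(table(object@events$kind))
})

#' @describeIn GroundTruth planted event table accessor.
#' @param x a GroundTruth.
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' @export
setMethod("truthEvents", "GroundTruth", function(x) x@events)

#' @describeIn GroundTruth synthetic genome accessor.
#' @export
setGeneric("truthGenome", function(x) standardGeneric("truthGenome"))

#' @export
setMethod("truthGenome", "GroundTruth", function(x) x@genome)

#' @describeIn GroundTruth exon annotation accessor.
#' @export
setGeneric("truthExons", function(x) standardGeneric("truthExons"))

#' @export
setMethod("truthExons", "GroundTruth", function(x) x@exons)
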