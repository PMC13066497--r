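# Extraction stage: decompose reads into (anchor, target) pairs, accumulate
# per-anchor sample x target counts, and apply abundance/composition filters.

#' Extraction configuration
#'
#' Defaults follow the published parameterization: 27-nt anchors and targets
#' with no gap, homopolymer filter at 8 bases, anchors kept when observed in
#' at least 50 reads overall, in at least 1 sample with at least 5 reads, with
#' strictly more than 1 distinct target, truncated to the 10 most frequent
#' targets. Pairs are tiled at a step equal to the full anchor+gap+target span
#' so that pairs from one read are disjoint.
#'
#' @param anchor_len anchor length in nt.
#' @param target_len target length in nt.
#' @param gap_len gap between anchor and target in nt.
#' @param poly_ACGT_len homopolymer run length at or above which an anchor or
#'   target is discarded.
#' @param anchor_count_threshold minimum total reads M per anchor.
#' @param anchor_samples_threshold minimum number of samples that must reach
#'   `anchor_sample_counts_threshold` reads.
#' @param anchor_sample_counts_threshold per-sample read count defining an
#'   "observed" sample.
#' @param anchor_unique_targets_threshold an anchor is kept only if its number
#'   of distinct targets is strictly greater than this.
#' @param n_most_freq_targets targets retained per anchor after ranking.
#' @param tiling_step offset step between successive pairs in a read; defaults
#'   to `anchor_len + gap_len + target_len`.
#' @return a validated list of class `extraction_config`.
#' @export
extractionConfig <- function(anchor_len = 27L, target_len = 27L, gap_len = 0L,
                             poly_ACGT_len = 8L,
                             anchor_count_threshold = 50L,
                             anchor_samples_threshold = 1L,
                             anchor_sample_counts_threshold = 5L,
                             anchor_unique_targets_threshold = 1L,
                             n_most_freq_targets = 10L,
                             tiling_step = NULL) {
  if (is.null(tiling_step)) tiling_step <- anchor_len + gap_len + target_len
  cfg <- list(
    anchor_len = as.integer(anchor_len), target_len = as.integer(target_len),
    gap_len = as.integer(gap_len), poly_ACGT_len = as.integer(poly_ACGT_len),
    anchor_count_threshold = as.integer(anchor_count_threshold),
    anchor_samples_threshold = as.integer(anchor_samples_threshold),
    anchor_sample_counts_threshold = as.integer(anchor_sample_counts_threshold),
    anchor_unique_targets_threshold = as.integer(anchor_unique_targets_threshold),
    n_most_freq_targets = as.integer(n_most_freq_targets),
    tiling_step = as.integer(tiling_step)
  )
  stopifnot(cfg$anchor_len > 0, cfg$target_len > 0, cfg$gap_len >= 0,
            cfg$poly_ACGT_len > 0, cfg$tiling_step >= 1)
  class(cfg) <- c("extraction_config", "list")
  cfg
}

pairSpan <- function(config) {
  config$anchor_len + config$gap_len + config$target_len
}

#' Enumerate (anchor, target) pairs of one read
#'
#' Pairs start at offsets 0, step, 2*step, ...; each spans
#' `anchor_len + gap_len + target_len` consecutive bases. Pairs whose anchor
#' or target contains `N` are skipped. Reads shorter than one span yield an
#' empty result.
#'
#' @param read_sequence a single read sequence over A/C/G/T/N.
#' @param config an [extractionConfig()].
#' @return data.frame with columns `offset` (0-based), `anchor`, `target`.
#' @examples
#' cfg <- extractionConfig()
#' iteratePairs(strrep("A", 108), cfg)  # two pairs, offsets 0 and 54
#' @export
iteratePairs <- function(read_sequence, config = extractionConfig()) {
  stopifnot(is.character(read_sequence), length(read_sequence) == 1L)
  span <- pairSpan(config)
  n <- nchar(read_sequence)
  if (n < span) {
    return(data.frame(offset = integer(0), anchor = character(0),
                      target = character(0)))
  }
  offs <- seq(0L, n - span, by = config$tiling_step)
  anchor <- substring(read_sequence, offs + 1L, offs + config$anchor_len)
  tstart <- offs + config$anchor_len + config$gap_len + 1L
  target <- substring(read_sequence, tstart, tstart + config$target_len - 1L)
  keep <- !grepl("N", anchor, fixed = TRUE) & !grepl("N", target, fixed = TRUE)
  data.frame(offset = offs[keep], anchor = anchor[keep], target = target[keep])
}

#' Homopolymer filter
#'
#' TRUE iff the sequence contains a run of `min_run` or more identical bases.
#'
#' @param sequence character vector of sequences.
#' @param min_run run length threshold (default 8).
#' @return logical vector.
#' @examples
#' hasHomopolymer(c(strrep("A", 8), "ACACACACAC"))
#' @export
hasHomopolymer <- function(sequence, min_run = 8L) {
  stopifnot(all(nzchar(sequence)))
  pat <- paste(sprintf("%s{%d,}", c("A", "C", "G", "T", "N"), min_run),
               collapse = "|")
  grepl(pat, sequence)
}

# vectorized pair extraction for a whole sample; returns a data.table of
# anchor/target pair occurrences that pass the N and homopolymer filters
extractPairs <- function(seqs, config) {
  span <- pairSpan(config)
  lens <- nchar(seqs)
  maxlen <- if (length(lens)) max(lens) else 0L
  if (maxlen < span) {
    return(data.table(anchor = character(0), target = character(0)))
  }
  out <- vector("list", length(seq(0L, maxlen - span, by = config$tiling_step)))
  i <- 0L
  for (off in seq(0L, maxlen - span, by = config$tiling_step)) {
    i <- i + 1L
    ok <- lens >= off + span
    if (!any(ok)) next
    s <- seqs[ok]
    anchor <- substr(s, off + 1L, off + config$anchor_len)
    tstart <- off + config$anchor_len + config$gap_len + 1L
    target <- substr(s, tstart, tstart + config$target_len - 1L)
    out[[i]] <- data.table(anchor = anchor, target = target)
  }
  dt <- rbindlist(out)
  if (!nrow(dt)) return(dt)
  keep <- !grepl("N", dt$anchor, fixed = TRUE) &
    !grepl("N", dt$target, fixed = TRUE) &
    !hasHomopolymer(dt$anchor, config$poly_ACGT_len) &
    !hasHomopolymer(dt$target, config$poly_ACGT_len)
  dt[keep]
}

readFastqSequences <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop("malformed FASTQ in '", path, "': ", conditionMessage(e))
    }
  )
  as.character(seqs)
}

#' Build per-anchor count tables from FASTQ samples
#'
#' Reads every sample's FASTQ (R1 only), extracts (anchor, target) pairs and
#' accumulates per-anchor sample x target counts. Pairs whose anchor or target
#' contains an `N` or a disallowed homopolymer run are discarded before
#' counting, so the sum of all counts equals the number of emitted pairs that
#' pass both filters.
#'
#' @param sample_sheet path to a space-delimited "name path" sample sheet, or
#'   a data.frame with columns `name` and `path`.
#' @param config an [extractionConfig()].
#' @return an [AnchorTableSet-class].
#' @export
buildAnchorTables <- function(sample_sheet, config = extractionConfig()) {
  if (is.character(sample_sheet)) {
    sheet <- parseSampleSheet(sample_sheet)
  } else {
    sheet <- as.data.frame(sample_sheet)
    stopifnot(all(c("name", "path") %in% names(sheet)))
  }
  per_sample <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    seqs <- readFastqSequences(sheet$path[i])
    dt <- extractPairs(seqs, config)
    if (nrow(dt)) {
      dt <- dt[, .(count = .N), by = .(anchor, target)]
      dt[, sample_id := sheet$name[i]]
    } else {
      dt <- data.table(anchor = character(0), target = character(0),
                       count = integer(0), sample_id = character(0))
    }
    per_sample[[i]] <- dt
  }
  pairs <- rbindlist(per_sample)
  setkeyv(pairs, c("anchor", "sample_id", "target"))
  new("AnchorTableSet", pairs = pairs, samples = sheet$name,
      config = unclass(config))
}

#' Dump a count set as a long-format TSV
#'
#' Writes one row per (anchor, sample, target) with its read count.
#'
#' @param set an [AnchorTableSet-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeAnchorCounts <- function(set, path) {
  df <- as.data.frame(set@pairs)[, c("anchor", "sample_id", "target", "count")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Materialize one anchor's table from a set
#'
#' @param set an [AnchorTableSet-class].
#' @param anchor anchor sequence.
#' @return an [AnchorTable-class] with one row per sample of the set (zero
#'   rows included) and targets ordered by decreasing total count.
#' @export
anchorTable <- function(set, anchor) {
  sub <- set@pairs[set@pairs$anchor == anchor, ]
  if (!nrow(sub)) stop("anchor not present in set: ", anchor)
  targets <- sort(unique(sub$target))
  m <- matrix(0, nrow = length(set@samples), ncol = length(targets),
              dimnames = list(set@samples, targets))
  m[cbind(match(sub$sample_id, set@samples), match(sub$target, targets))] <-
    sub$count
  tot <- colSums(m)
  m <- m[, order(-tot, colnames(m)), drop = FALSE]
  total_targets <- attr(set@pairs, "total_targets")
  tt <- ncol(m)
  if (!is.null(total_targets)) {
    hit <- match(anchor, total_targets$anchor)
    if (!is.na(hit)) tt <- total_targets$n_targets[hit]
  }
  AnchorTable(anchor, m, totalTargets = tt)
}

#' Apply anchor-level abundance and composition filters
#'
#' An anchor is kept iff its total count M is at least
#' `anchor_count_threshold`, the number of samples with at least
#' `anchor_sample_counts_threshold` reads is at least
#' `anchor_samples_threshold`, and its number of distinct targets is strictly
#' greater than `anchor_unique_targets_threshold`. Kept anchors are truncated
#' to the `n_most_freq_targets` most frequent targets (ties broken
#' lexicographically); totals are recomputed after truncation.
#'
#' @param x an [AnchorTable-class] or [AnchorTableSet-class].
#' @param config an [extractionConfig()].
#' @return for an AnchorTable, a list with `keep` (logical) and `table` (the
#'   truncated table, or NULL when dropped); for an AnchorTableSet, the
#'   filtered set.
#' @export
setGeneric("applyAnchorFilters",
           function(x, config = extractionConfig())
             standardGeneric("applyAnchorFilters"))

#' @rdname applyAnchorFilters
#' @export
setMethod("applyAnchorFilters", "AnchorTable", function(x, config) {
  n_j <- sampleTotals(x)
  M <- sum(n_j)
  keep <- M >= config$anchor_count_threshold &&
    sum(n_j >= config$anchor_sample_counts_threshold) >=
      config$anchor_samples_threshold &&
    ncol(anchorCounts(x)) > config$anchor_unique_targets_threshold
  if (!keep) return(list(keep = FALSE, table = NULL))
  ranked <- rankedTargets(x)
  kept_targets <- head(ranked, config$n_most_freq_targets)
  m <- anchorCounts(x)[, kept_targets, drop = FALSE]
  list(keep = TRUE,
       table = AnchorTable(anchorSequence(x), m,
                           totalTargets = x@totalTargets))
})

#' @rdname applyAnchorFilters
#' @export
setMethod("applyAnchorFilters", "AnchorTableSet", function(x, config) {
  pairs <- as.data.table(x@pairs)
  if (!nrow(pairs)) return(x)
  per_sample <- pairs[, .(n_j = sum(count)), by = .(anchor, sample_id)]
  stats <- per_sample[, .(
    M = sum(n_j),
    n_obs = sum(n_j >= config$anchor_sample_counts_threshold)
  ), by = anchor]
  n_targ <- pairs[, .(n_targets = length(unique(target))), by = anchor]
  stats <- merge(stats, n_targ, by = "anchor")
  kept <- stats[
    M >= config$anchor_count_threshold &
      n_obs >= config$anchor_samples_threshold &
      n_targets > config$anchor_unique_targets_threshold,
    anchor
  ]
  pairs <- pairs[anchor %chin% kept]
  # truncate to the most frequent targets per anchor, lexicographic ties
  ttot <- pairs[, .(tot = sum(count)), by = .(anchor, target)]
  setorder(ttot, anchor, -tot, target)
  ttot[, rnk := seq_len(.N), by = anchor]
  keep_targets <- ttot[rnk <= config$n_most_freq_targets, .(anchor, target)]
  pairs <- merge(pairs, keep_targets, by = c("anchor", "target"))
  # remember pre-truncation target counts for downstream reporting
  setkeyv(pairs, c("anchor", "sample_id", "target"))
  attr(pairs, "total_targets") <- n_targ[anchor %chin% kept][order(anchor)]
  new("AnchorTableSet", pairs = pairs, samples = x@samples,
      config = unclass(config))
})
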