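# Annotation stage: place concatenated anchor+target sequences on a reference
# genome (contiguous, spliced or unaligned), assign genes by exon
# intersection, and classify the mechanism behind each significant anchor.
#
# The built-in matcher is exact-match only: a contiguous exact placement is
# preferred; otherwise the best two-block exact split is sought (prefix at one
# locus, suffix downstream within the intron bounds), maximizing the prefix
# length with ties broken by a GT..AG intron motif, then by smaller gap.
# Mismatch-tolerant spliced alignment on real data is delegated to the SAM
# import path ([readSamAlignments()]).

#' Load a genome as a named character vector
#'
#' @param genome a `DNAStringSet`, a named character vector of chromosome
#'   sequences, or a path to a FASTA file.
#' @return named character vector (chromosome name -> sequence).
#' @export
loadGenome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome) && is.null(names(genome))) {
    out <- as.character(Biostrings::readDNAStringSet(genome))
  } else if (is.character(genome)) {
    out <- genome
  } else {
    stop("unsupported genome input")
  }
  if (is.null(names(out))) stop("genome sequences must be named")
  # FASTA headers may carry descriptions; keep the first word
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

# exact occurrences of `pattern` in each chromosome; data.frame(chrom, start)
.findExact <- function(pattern, genome) {
  res <- list()
  for (chrom in names(genome)) {
    m <- gregexpr(pattern, genome[[chrom]], fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      res[[length(res) + 1L]] <- data.frame(chrom = chrom,
                                            start = as.integer(m),
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(0), start = integer(0)))
  }
  do.call(rbind, res)
}

.unalignedBlocks <- function() {
  new("AlignmentBlocks", status = "unaligned", blocks = GRanges(),
      junction = c(NA_integer_, NA_integer_), multiplicity = 0L)
}

# largest prefix length in [lo, hi] with at least one exact hit (prefix hits
# are monotone: longer prefixes hit a subset of positions)
.maxPrefixLen <- function(q, genome, lo, hi) {
  if (nrow(.findExact(substr(q, 1L, lo), genome)) == 0L) return(0L)
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (nrow(.findExact(substr(q, 1L, mid), genome)) > 0L) lo <- mid
    else hi <- mid - 1L
  }
  lo
}

# best exact two-block split of oriented query q; NULL when none exists
.spliceSearch <- function(q, genome, min_intron, max_intron, min_block) {
  n <- nchar(q)
  # any valid split has one block of length >= 20 containing the query's
  # first or last 20-mer; reject quickly when neither occurs
  if (n >= 40L &&
      nrow(.findExact(substr(q, 1L, 20L), genome)) == 0L &&
      nrow(.findExact(substr(q, n - 19L, n), genome)) == 0L) {
    return(NULL)
  }
  hi <- n - min_block
  Lmax <- .maxPrefixLen(q, genome, min_block, hi)
  if (Lmax == 0L) return(NULL)
  for (L in seq(min(Lmax, hi), min_block)) {
    pref_hits <- .findExact(substr(q, 1L, L), genome)
    if (!nrow(pref_hits)) next
    suff <- substr(q, L + 1L, n)
    suff_hits <- .findExact(suff, genome)
    if (!nrow(suff_hits)) next
    cand <- merge(pref_hits, suff_hits, by = "chrom",
                  suffixes = c("_p", "_s"))
    if (!nrow(cand)) next
    cand$gap <- cand$start_s - (cand$start_p + L)
    cand <- cand[cand$gap >= min_intron & cand$gap <= max_intron, ,
                 drop = FALSE]
    if (!nrow(cand)) next
    # tie-breaks: GT..AG intron motif, then smaller gap, then position
    cand$motif <- vapply(seq_len(nrow(cand)), function(i) {
      g <- genome[[cand$chrom[i]]]
      donor <- substr(g, cand$start_p[i] + L, cand$start_p[i] + L + 1L)
      accept <- substr(g, cand$start_s[i] - 2L, cand$start_s[i] - 1L)
      donor == "GT" && accept == "AG"
    }, logical(1))
    cand <- cand[order(-cand$motif, cand$gap, cand$chrom, cand$start_p), ,
                 drop = FALSE]
    best <- cand[1, ]
    return(list(L = L, chrom = best$chrom, p = best$start_p, s = best$start_s,
                multiplicity = nrow(cand)))
  }
  NULL
}

#' Place a concatenated anchor+target sequence on the genome
#'
#' A contiguous exact match is preferred; otherwise the best two-block exact
#' split with an intron-sized gap is sought (see the file header for the
#' tie-break order); otherwise the sequence is unaligned. Both strands are
#' searched (the reverse-complemented query against the forward genome text);
#' blocks are always reported in genome coordinates.
#'
#' @param sequence query sequence (54 nt at default lengths).
#' @param genome genome as accepted by [loadGenome()].
#' @param min_intron,max_intron allowed gap between the two blocks of a
#'   spliced placement (defaults 21 and 1e6).
#' @param min_block minimum block length considered for a split.
#' @return an [AlignmentBlocks-class].
#' @export
alignSequence <- function(sequence, genome, min_intron = 21L,
                          max_intron = 1000000L, min_block = 6L) {
  genome <- loadGenome(genome)
  n <- nchar(sequence)
  oriented <- c("+" = sequence, "-" = revComp(sequence))
  # contiguous placements first
  for (ori in c("+", "-")) {
    hits <- .findExact(oriented[[ori]], genome)
    if (nrow(hits)) {
      hits <- hits[order(hits$chrom, hits$start), , drop = FALSE]
      gr <- GRanges(hits$chrom[1],
                    IRanges(hits$start[1], hits$start[1] + n - 1L),
                    strand = ori)
      return(new("AlignmentBlocks", status = "contiguous", blocks = gr,
                 junction = c(NA_integer_, NA_integer_),
                 multiplicity = as.integer(nrow(hits))))
    }
  }
  # spliced: maximize the oriented prefix length across strands, "+" wins ties
  best <- NULL
  best_ori <- NULL
  for (ori in c("+", "-")) {
    sp <- .spliceSearch(oriented[[ori]], genome, min_intron, max_intron,
                        min_block)
    if (!is.null(sp) && (is.null(best) || sp$L > best$L)) {
      best <- sp
      best_ori <- ori
    }
  }
  if (is.null(best)) return(.unalignedBlocks())
  gr <- GRanges(best$chrom,
                IRanges(c(best$p, best$s),
                        c(best$p + best$L - 1L, best$s + (n - best$L) - 1L)),
                strand = best_ori)
  new("AlignmentBlocks", status = "spliced", blocks = gr,
      junction = c(as.integer(best$p + best$L - 1L), as.integer(best$s)),
      multiplicity = as.integer(best$multiplicity))
}

#' Read exon records from a BED file
#'
#' Expects BED6 rows (chrom, start, end, name, score, strand; 0-based
#' half-open) with one row per exon and the gene id in the name field.
#'
#' @param path BED file path.
#' @return GRanges (1-based inclusive) with a `gene` metadata column.
#' @export
readExonBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  rows <- vector("list", sum(keep))
  ri <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      stop("malformed BED row at line ", i, ": expected >= 6 fields")
    }
    st <- suppressWarnings(as.integer(f[2]))
    en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en) || st < 0L || en <= st) {
      stop("malformed BED row at line ", i, ": bad coordinates")
    }
    ri <- ri + 1L
    rows[[ri]] <- data.frame(chrom = f[1], start = st, end = en,
                             gene = f[4], strand = f[6],
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[seq_len(ri)])
  if (is.null(df)) {
    gr <- GRanges()
    mcols(gr)$gene <- character(0)
    return(gr)
  }
  strand <- ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = strand)
  mcols(gr)$gene <- df$gene
  gr
}

#' Assign genes overlapping alignment blocks
#'
#' Genes whose exons overlap any block by at least 1 bp, half-open BED
#' semantics preserved through the 1-based conversion (a block ending exactly
#' where an exon starts does not overlap).
#'
#' @param blocks an [AlignmentBlocks-class] or GRanges.
#' @param exons exon GRanges with `gene` metadata (see [readExonBed()]).
#' @return character vector of gene ids (unique, sorted).
#' @export
assignGenes <- function(blocks, exons) {
  if (is(blocks, "AlignmentBlocks")) blocks <- alignmentBlocks(blocks)
  if (!length(blocks)) return(character(0))
  ov <- findOverlaps(blocks, exons, ignore.strand = TRUE)
  sort(unique(mcols(exons)$gene[subjectHits(ov)]))
}

#' Introns implied by consecutive exons of each gene
#'
#' @param exons exon GRanges with `gene` metadata.
#' @return data.frame with `gene`, `chrom`, `donor_end`, `acceptor_start`
#'   (1-based coordinates of the flanking exonic bases).
#' @export
annotatedIntrons <- function(exons) {
  out <- list()
  genes <- unique(mcols(exons)$gene)
  for (g in genes) {
    ex <- exons[mcols(exons)$gene == g]
    ex <- ex[order(start(ex))]
    if (length(ex) < 2L) next
    for (i in seq_len(length(ex) - 1L)) {
      if (start(ex)[i + 1L] > end(ex)[i] + 1L) {
        out[[length(out) + 1L]] <- data.frame(
          gene = g, chrom = as.character(seqnames(ex))[i],
          donor_end = end(ex)[i], acceptor_start = start(ex)[i + 1L],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), chrom = character(0),
                      donor_end = integer(0), acceptor_start = integer(0)))
  }
  do.call(rbind, out)
}

#' Annotated vs cryptic junction status of a spliced placement
#'
#' A junction is annotated iff its `(donor_end, acceptor_start)` equals an
#' intron implied by consecutive exons of some gene; otherwise cryptic.
#'
#' @param blocks a spliced [AlignmentBlocks-class].
#' @param exons exon GRanges with `gene` metadata.
#' @return `"annotated"` or `"cryptic"`.
#' @export
junctionStatus <- function(blocks, exons) {
  if (alignmentStatus(blocks) != "spliced") {
    stop("junctionStatus requires a spliced placement, got ",
         alignmentStatus(blocks))
  }
  j <- alignmentJunction(blocks)
  chrom <- as.character(seqnames(alignmentBlocks(blocks)))[1]
  introns <- annotatedIntrons(exons)
  hit <- introns$chrom == chrom & introns$donor_end == j[1] &
    introns$acceptor_start == j[2]
  if (any(hit)) "annotated" else "cryptic"
}

EVENT_CATEGORIES <- c("allelic_or_snv", "intron_retention",
                      "annotated_splice_variation", "cryptic_splice",
                      "homolog_pair", "unaligned_target", "both_unaligned")

#' Classify the mechanism behind a significant anchor
#'
#' Rule cascade over the top-2 targets' placements: both unaligned;
#' exactly one unaligned; both contiguous at the same locus with small target
#' Hamming distance (allelic/SNV); both contiguous at different genes
#' (homolog pair); one spliced with the contiguous mate reading into the
#' spliced-out interval (intron retention); otherwise splice variation,
#' cryptic when any junction is unannotated.
#'
#' @param aln1,aln2 [AlignmentBlocks-class] of the top-1 and top-2
#'   concatenated anchor+target sequences.
#' @param target1,target2 the target sequences themselves.
#' @param exons exon GRanges with `gene` metadata.
#' @param hamming_threshold targets at most this many substitutions apart at
#'   a shared locus are called allelic/SNV (default 5).
#' @return list with `category`, `genes` (character vector) and `evidence`.
#' @export
classifyEvent <- function(aln1, aln2, target1, target2, exons,
                          hamming_threshold = 5L) {
  st1 <- alignmentStatus(aln1)
  st2 <- alignmentStatus(aln2)
  if (st1 == "unaligned" && st2 == "unaligned") {
    return(list(category = "both_unaligned", genes = character(0),
                evidence = "both top-2 targets unaligned"))
  }
  if (st1 == "unaligned" || st2 == "unaligned") {
    aligned <- if (st1 == "unaligned") aln2 else aln1
    return(list(category = "unaligned_target",
                genes = assignGenes(aligned, exons),
                evidence = sprintf("target %d unaligned",
                                   if (st1 == "unaligned") 1L else 2L)))
  }
  g1 <- assignGenes(aln1, exons)
  g2 <- assignGenes(aln2, exons)
  genes <- sort(unique(c(g1, g2)))
  if (st1 == "contiguous" && st2 == "contiguous") {
    hd <- if (nchar(target1) == nchar(target2)) {
      hammingDist(target1, target2)
    } else {
      NA_integer_
    }
    if (length(intersect(g1, g2)) && !is.na(hd) && hd <= hamming_threshold) {
      return(list(category = "allelic_or_snv", genes = genes,
                  evidence = sprintf(
                    "both contiguous, shared gene, Hamming %d <= %d",
                    hd, hamming_threshold)))
    }
    return(list(category = "homolog_pair", genes = genes,
                evidence = sprintf(
                  "both contiguous at %s loci (target Hamming %s)",
                  if (length(intersect(g1, g2))) "shared" else "distinct",
                  ifelse(is.na(hd), "NA", hd))))
  }
  if (xor(st1 == "spliced", st2 == "spliced")) {
    sp <- if (st1 == "spliced") aln1 else aln2
    ct <- if (st1 == "spliced") aln2 else aln1
    j <- alignmentJunction(sp)
    if (j[2] - j[1] > 1L) {
      intron <- GRanges(as.character(seqnames(alignmentBlocks(sp)))[1],
                        IRanges(j[1] + 1L, j[2] - 1L))
      ov <- findOverlaps(alignmentBlocks(ct), intron, ignore.strand = TRUE)
      if (length(ov)) {
        return(list(category = "intron_retention", genes = genes,
                    evidence = "contiguous target reads into the spliced-out interval"))
      }
    }
    js <- junctionStatus(sp, exons)
    if (js == "cryptic") {
      return(list(category = "cryptic_splice", genes = genes,
                  evidence = "spliced target with unannotated junction"))
    }
    return(list(category = "annotated_splice_variation", genes = genes,
                evidence = "spliced target with annotated junction, mate contiguous elsewhere"))
  }
  # both spliced
  js1 <- junctionStatus(aln1, exons)
  js2 <- junctionStatus(aln2, exons)
  if (js1 == "cryptic" || js2 == "cryptic") {
    return(list(category = "cryptic_splice", genes = genes,
                evidence = sprintf("junction status: target1 %s, target2 %s",
                                   js1, js2)))
  }
  list(category = "annotated_splice_variation", genes = genes,
       evidence = "both junctions annotated")
}

#' Classify all significant anchors of a run
#'
#' For each requested anchor, aligns the concatenated anchor+target sequences
#' of its top-2 targets and applies [classifyEvent()].
#'
#' @param anchors character vector of anchors to classify.
#' @param set the filtered [AnchorTableSet-class] (provides target ranking).
#' @param genome genome as accepted by [loadGenome()].
#' @param exons exon GRanges with `gene` metadata.
#' @param min_intron,max_intron,hamming_threshold passed through.
#' @return data.frame with one row per anchor: `anchor`, `category`, `genes`
#'   (comma-separated), `evidence`, `target1`, `target2`, `status1`,
#'   `status2`.
#' @export
classifyEvents <- function(anchors, set, genome, exons, min_intron = 21L,
                           max_intron = 1000000L, hamming_threshold = 5L) {
  genome <- loadGenome(genome)
  rows <- vector("list", length(anchors))
  for (i in seq_along(anchors)) {
    a <- anchors[i]
    tab <- anchorTable(set, a)
    ranked <- rankedTargets(tab)
    t1 <- ranked[1]
    t2 <- ranked[2]
    aln1 <- alignSequence(paste0(a, t1), genome, min_intron, max_intron)
    aln2 <- alignSequence(paste0(a, t2), genome, min_intron, max_intron)
    cls <- classifyEvent(aln1, aln2, t1, t2, exons, hamming_threshold)
    rows[[i]] <- data.frame(
      anchor = a, category = cls$category,
      genes = paste(cls$genes, collapse = ","),
      evidence = cls$evidence,
      target1 = t1, target2 = t2,
      status1 = alignmentStatus(aln1), status2 = alignmentStatus(aln2),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Concatenated anchor+target sequences for export
#'
#' Record ids encode the anchor and target rank as `<anchor>|rank<k>` and can
#' be parsed back with [parseConcatId()]; the FASTA is usable as a query set
#' for an external spliced aligner or the built-in matcher.
#'
#' @param anchors anchors to export.
#' @param set filtered [AnchorTableSet-class].
#' @param n_targets up to this many targets per anchor (default 10).
#' @return named character vector of concatenated sequences.
#' @export
concatTopTargets <- function(anchors, set, n_targets = 10L) {
  out <- character(0)
  for (a in anchors) {
    ranked <- head(rankedTargets(anchorTable(set, a)), n_targets)
    seqs <- paste0(a, ranked)
    names(seqs) <- sprintf("%s|rank%d", a, seq_along(ranked))
    out <- c(out, seqs)
  }
  out
}

#' @rdname concatTopTargets
#' @param path output FASTA path.
#' @return `exportConcatFasta()` returns the path invisibly.
#' @export
exportConcatFasta <- function(anchors, set, path, n_targets = 10L) {
  seqs <- concatTopTargets(anchors, set, n_targets)
  x <- DNAStringSet(seqs)
  writeXStringSet(x, path)
  invisible(path)
}

#' Parse a concatenated-sequence record id
#'
#' @param id record id of the form `<anchor>|rank<k>`.
#' @return list with `anchor` and `rank`.
#' @export
parseConcatId <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !grepl("^rank[0-9]+$", parts[2])) {
    stop("not a concatenated-sequence id: ", id)
  }
  list(anchor = parts[1], rank = as.integer(sub("rank", "", parts[2])))
}

#' Per-sample target fractions of an anchor
#'
#' For each sample, the fraction of that anchor's reads carrying each
#' retained target. Samples with zero reads for the anchor are ND ("no reads
#' found") and returned as NA rows.
#'
#' @param table an [AnchorTable-class].
#' @return numeric matrix (samples x targets) of fractions; NA rows mark ND
#'   samples.
#' @export
targetFractions <- function(table) {
  m <- anchorCounts(table)
  if (sum(m) == 0) stop("anchor table has no reads")
  n_j <- rowSums(m)
  frac <- m / n_j
  frac[n_j == 0, ] <- NA_real_
  frac
}

#' Import spliced alignments from a SAM file
#'
#' Alternative to the built-in matcher for real data: parses each record's
#' placement (via Rsamtools) into [AlignmentBlocks-class] objects, with
#' CIGAR `N` gaps interpreted as junctions.
#'
#' @param path SAM (or BAM) file path.
#' @return named list of [AlignmentBlocks-class], keyed by query name;
#'   unmapped records map to unaligned placements.
#' @export
readSamAlignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("readSamAlignments requires the Rsamtools package")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar")
  ))[[1]]
  out <- list()
  for (i in seq_along(rec$qname)) {
    qn <- rec$qname[i]
    if (bitwAnd(rec$flag[i], 4L) != 0L || is.na(rec$pos[i])) {
      out[[qn]] <- .unalignedBlocks()
      next
    }
    ops <- regmatches(rec$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", rec$cigar[i]))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
    kinds <- sub("[0-9]+", "", ops)
    pos <- rec$pos[i]
    blocks <- list()
    cur_start <- pos
    cur_end <- pos - 1L
    for (k in seq_along(kinds)) {
      if (kinds[k] %in% c("M", "=", "X", "D")) {
        cur_end <- cur_end + lens[k]
      } else if (kinds[k] == "N") {
        blocks[[length(blocks) + 1L]] <- c(cur_start, cur_end)
        cur_start <- cur_end + lens[k] + 1L
        cur_end <- cur_start - 1L
      }
      # I, S, H, P consume no reference
    }
    blocks[[length(blocks) + 1L]] <- c(cur_start, cur_end)
    bm <- do.call(rbind, blocks)
    chrom <- as.character(rec$rname[i])
    strand <- as.character(rec$strand[i])
    gr <- GRanges(chrom, IRanges(bm[, 1], bm[, 2]), strand = strand)
    status <- if (nrow(bm) >= 2L) "spliced" else "contiguous"
    junction <- if (nrow(bm) >= 2L) {
      c(as.integer(bm[1, 2]), as.integer(bm[2, 1]))
    } else {
      c(NA_integer_, NA_integer_)
    }
    out[[qn]] <- new("AlignmentBlocks", status = status, blocks = gr,
                     junction = junction, multiplicity = 1L)
  }
  out
}
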