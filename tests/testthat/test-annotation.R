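# annotation: exact placement, gene assignment, junction status, event
# classification, concatenated export, target fractions, SAM import

# deterministic little genome with two single-exon genes and one spliced gene
makeToyReference <- function(seed = 101) {
  set.seed(seed)
  spacer <- function(n = 30) randomKmer(n)
  exon1 <- randomKmer(54)
  # intron base 6 fixed to T and exon2 starting with C keep the planted
  # junctions unambiguous for the prefix-maximal exact matcher
  intron <- paste0("GT", randomKmer(3), "T", randomKmer(22), "AG")
  exon2 <- paste0("C", randomKmer(53))
  geneA <- randomKmer(80)
  geneB <- randomKmer(80)
  genome <- paste0(spacer(), geneA, spacer(), exon1, intron, exon2,
                   spacer(), geneB, spacer())
  offA <- 31L
  offS <- offA + 80L + 30L
  offB <- offS + 138L + 30L
  exons <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(
      start = c(offA, offS, offS + 84L, offB),
      end = c(offA + 79L, offS + 53L, offS + 137L, offB + 79L)
    ),
    strand = "+"
  )
  S4Vectors::mcols(exons)$gene <- c("geneA", "spliced", "spliced", "geneB")
  list(genome = c(chr1 = genome), exons = exons,
       exon1 = exon1, intron = intron, exon2 = exon2,
       geneA = geneA, geneB = geneB,
       exon1_range = c(offS, offS + 53L),
       exon2_range = c(offS + 84L, offS + 137L))
}

test_that("verbatim genome substrings align contiguously at their origin", {
  ref <- makeToyReference()
  q <- substr(ref$genome[["chr1"]], 40, 93)
  aln <- alignSequence(q, ref$genome)
  expect_equal(alignmentStatus(aln), "contiguous")
  b <- alignmentBlocks(aln)
  expect_equal(GenomicRanges::start(b), 40L)
  expect_equal(GenomicRanges::end(b), 93L)
  expect_equal(as.character(GenomicRanges::strand(b)), "+")

  # reverse complement maps to the minus strand at the same coordinates
  aln_rc <- alignSequence(revComp(q), ref$genome)
  expect_equal(alignmentStatus(aln_rc), "contiguous")
  expect_equal(GenomicRanges::start(alignmentBlocks(aln_rc)), 40L)
  expect_equal(as.character(GenomicRanges::strand(alignmentBlocks(aln_rc))),
               "-")
})

test_that("a junction-spanning query is placed as two blocks at the annotated intron", {
  ref <- makeToyReference()
  q <- paste0(substr(ref$exon1, 28, 54), substr(ref$exon2, 1, 27))
  aln <- alignSequence(q, ref$genome)
  expect_equal(alignmentStatus(aln), "spliced")
  j <- alignmentJunction(aln)
  expect_equal(j[1], ref$exon1_range[2])   # donor at exon1 end
  expect_equal(j[2], ref$exon2_range[1])   # acceptor at exon2 start
  expect_equal(junctionStatus(aln, ref$exons), "annotated")
  # blocks sum to the query length
  expect_equal(sum(GenomicRanges::width(alignmentBlocks(aln))), 54L)
})

test_that("junctions not implied by consecutive exons are cryptic", {
  ref <- makeToyReference()
  # donor 5 bases inside the intron, acceptor at exon2 start; the skipped
  # piece (25 nt) still exceeds the minimum intron size
  q <- paste0(substr(ref$exon1, 33, 54), substr(ref$intron, 1, 5),
              substr(ref$exon2, 1, 27))
  aln <- alignSequence(q, ref$genome)
  expect_equal(alignmentStatus(aln), "spliced")
  expect_equal(alignmentJunction(aln)[1], ref$exon1_range[2] + 5L)
  expect_equal(junctionStatus(aln, ref$exons), "cryptic")

  ctg <- alignSequence(substr(ref$geneA, 1, 54), ref$genome)
  expect_error(junctionStatus(ctg, ref$exons), "spliced")
})

test_that("sequences absent from the genome are unaligned (brute-force checked)", {
  ref <- makeToyReference()
  set.seed(9)
  repeat {
    q <- randomKmer(54)
    gen <- ref$genome[["chr1"]]
    if (!grepl(substr(q, 1, 20), gen, fixed = TRUE) &&
        !grepl(substr(q, 35, 54), gen, fixed = TRUE) &&
        !grepl(substr(q, 1, 20), revComp(gen), fixed = TRUE) &&
        !grepl(substr(q, 35, 54), revComp(gen), fixed = TRUE)) break
  }
  expect_equal(alignmentStatus(alignSequence(q, ref$genome)), "unaligned")
})

test_that("contiguous placements agree with Biostrings matchPattern", {
  ref <- makeToyReference()
  gen <- ref$genome[["chr1"]]
  set.seed(23)
  for (i in 1:25) {
    start <- sample(nchar(gen) - 53, 1)
    q <- substr(gen, start, start + 53)
    aln <- alignSequence(q, ref$genome)
    oracle <- Biostrings::matchPattern(q, Biostrings::DNAString(gen))
    expect_equal(alignmentStatus(aln), "contiguous")
    expect_equal(GenomicRanges::start(alignmentBlocks(aln)),
                 min(BiocGenerics::start(oracle)))
    expect_equal(aln@multiplicity, length(oracle))
  }
})

test_that("gene assignment follows half-open overlap semantics", {
  ref <- makeToyReference()
  exons <- ref$exons
  inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(35, 60))
  expect_equal(assignGenes(inside, exons), "geneA")
  # block ending exactly where an exon starts (half-open abutment in BED
  # coordinates): 1-based block [20, 30] vs exon starting at 31
  abut <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20, 30))
  expect_length(assignGenes(abut, exons), 0)
  # spliced blocks touching two genes report both
  two <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(35, ref$exon2_range[1] + 5L),
                             c(60, ref$exon2_range[1] + 15L)))
  g2 <- assignGenes(two, exons)
  expect_setequal(g2, c("geneA", "spliced"))
})

test_that("gene assignment matches a brute-force interval oracle", {
  set.seed(61)
  for (rep in 1:10) {
    n_ex <- 8
    starts <- sample(1000, n_ex)
    exons <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(starts, starts + sample(20:60, n_ex, TRUE)))
    S4Vectors::mcols(exons)$gene <- sample(letters[1:4], n_ex, TRUE)
    bs <- sample(1000, 2)
    blocks <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(bs, bs + sample(10:40, 2, TRUE)))
    oracle <- as.character(sort(unique(unlist(lapply(seq_along(blocks), function(i) {
      hits <- c()
      for (e in seq_along(exons)) {
        if (GenomicRanges::start(blocks)[i] <= GenomicRanges::end(exons)[e] &&
            GenomicRanges::end(blocks)[i] >= GenomicRanges::start(exons)[e]) {
          hits <- c(hits, S4Vectors::mcols(exons)$gene[e])
        }
      }
      hits
    })))))
    expect_equal(assignGenes(blocks, exons), oracle)
  }
})

test_that("BED round-trip preserves exon records and rejects malformed rows", {
  ref <- makeToyReference()
  d <- withr::local_tempdir()
  bed <- file.path(d, "exons.bed")
  anchorvar:::.writeBed(ref$exons, bed)
  back <- readExonBed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ref$exons))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ref$exons))
  expect_equal(S4Vectors::mcols(back)$gene, S4Vectors::mcols(ref$exons)$gene)

  writeLines(c("chr1\t10\t20\tg\t0\t+", "chr1\t30\t20\tg\t0\t+"),
             file.path(d, "bad.bed"))
  expect_error(readExonBed(file.path(d, "bad.bed")), "line 2")
})

test_that("classification cascade recovers constructed mechanisms", {
  ref <- makeToyReference()
  exons <- ref$exons
  anchor <- substr(ref$exon1, 28, 54)
  t_spliced <- substr(ref$exon2, 1, 27)
  t_intron <- substr(ref$intron, 1, 27)
  aln_spliced <- alignSequence(paste0(anchor, t_spliced), ref$genome)
  aln_intron <- alignSequence(paste0(anchor, t_intron), ref$genome)
  ir <- classifyEvent(aln_spliced, aln_intron, t_spliced, t_intron, exons)
  expect_equal(ir$category, "intron_retention")

  # same locus, 2 substitutions apart -> allelic/SNV
  qa <- substr(ref$geneA, 1, 54)
  ta <- substr(qa, 28, 54)
  tb <- ta
  substr(tb, 5, 5) <- if (substr(tb, 5, 5) == "A") "C" else "A"
  aln_a <- alignSequence(qa, ref$genome)
  al <- classifyEvent(aln_a, aln_a, ta, tb, exons)
  expect_equal(al$category, "allelic_or_snv")

  # different genes -> homolog pair
  qb <- substr(ref$geneB, 1, 54)
  hp <- classifyEvent(aln_a, alignSequence(qb, ref$genome),
                      ta, substr(qb, 28, 54), exons)
  expect_equal(hp$category, "homolog_pair")
  expect_setequal(hp$genes, c("geneA", "geneB"))

  una <- classifyEvent(aln_a, alignSequence(randomKmer(54), ref$genome),
                       ta, randomKmer(27), exons)
  expect_equal(una$category, "unaligned_target")
  both <- classifyEvent(alignSequence(randomKmer(54), ref$genome),
                        alignSequence(randomKmer(54), ref$genome),
                        randomKmer(27), randomKmer(27), exons)
  expect_equal(both$category, "both_unaligned")
})

test_that("concatenated export encodes anchor and rank and round-trips", {
  cfg <- smallSimConfig(seed = 16)
  out <- simulateDataset(cfg, withr::local_tempdir())
  set <- applyAnchorFilters(buildAnchorTables(out$sample_sheet))
  a <- truthEvents(out$truth)$anchor[1]
  seqs <- concatTopTargets(a, set, n_targets = 10)
  expect_true(all(nchar(seqs) == 54))
  expect_true(all(startsWith(seqs, a)))
  id <- names(seqs)[2]
  parsed <- parseConcatId(id)
  expect_equal(parsed$anchor, a)
  expect_equal(parsed$rank, 2L)

  fa <- file.path(withr::local_tempdir(), "concat.fa")
  exportConcatFasta(a, set, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back), seqs)

  # no anchors -> empty FASTA
  fa0 <- file.path(withr::local_tempdir(), "empty.fa")
  exportConcatFasta(character(0), set, fa0)
  expect_length(Biostrings::readDNAStringSet(fa0), 0)
})

test_that("target fractions are per-sample shares with ND as NA", {
  counts <- matrix(c(3, 0, 1, 0), 2, 2,
                   dimnames = list(c("s1", "s2"), c("TA", "TB")))
  tab <- AnchorTable("X", counts)
  fr <- targetFractions(tab)
  expect_equal(unname(fr["s1", ]), c(0.75, 0.25))
  expect_true(all(is.na(fr["s2", ])))
  expect_equal(sum(fr["s1", ]), 1)
})

test_that("SAM import reproduces contiguous, spliced and unmapped placements", {
  skip_if_not_installed("Rsamtools")
  d <- withr::local_tempdir()
  sam <- file.path(d, "aln.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:1000",
    "q1\t0\tchr1\t100\t60\t54M\t*\t0\t0\t*\t*",
    "q2\t0\tchr1\t200\t60\t27M30N27M\t*\t0\t0\t*\t*",
    "q3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), sam)
  alns <- readSamAlignments(sam)
  expect_equal(alignmentStatus(alns$q1), "contiguous")
  expect_equal(GenomicRanges::start(alignmentBlocks(alns$q1)), 100L)
  expect_equal(GenomicRanges::end(alignmentBlocks(alns$q1)), 153L)
  expect_equal(alignmentStatus(alns$q2), "spliced")
  expect_equal(alignmentJunction(alns$q2), c(226L, 257L))
  expect_equal(alignmentStatus(alns$q3), "unaligned")
})
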