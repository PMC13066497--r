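# shared fixture builders for the test suite

randomKmer <- function(k = 27L) {
  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
}

# anchor table from a bare count matrix, with generated target/sample names
makeTable <- function(counts, anchor = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- vapply(seq_len(ncol(counts)), function(i)
      randomKmer(), character(1))
  }
  if (is.null(anchor)) anchor <- randomKmer()
  AnchorTable(anchor, counts)
}

# two-group signal fixture in the regime where the permutation oracle is
# informative (closed-form p above the Monte-Carlo floor of 1/(n_perm+1))
makeSignalFixture <- function(seed, n_per_group = 3L, depth = 5:9) {
  set.seed(seed)
  ns <- 2L * n_per_group
  counts <- t(sapply(seq_len(ns), function(j) {
    comp <- if (j <= n_per_group) c(0.65, 0.20, 0.15) else c(0.35, 0.45, 0.20)
    as.vector(rmultinom(1, sample(depth, 1), comp))
  }))
  rownames(counts) <- sprintf("s%02d", seq_len(ns))
  colnames(counts) <- vapply(1:3, function(i) randomKmer(), character(1))
  AnchorTable(randomKmer(), counts)
}

# small two-group planted-event simulation shared by integration tests
smallSimConfig <- function(seed = 11, n_per_class = 1L, ...) {
  simConfig(seed = seed, samples_per_group = 5L,
            event_specs = plantedEventSpecs(n_per_class),
            n_null_genes = 2L, ...)
}

expectedCategory <- c(
  allelic = "allelic_or_snv",
  intron_retention = "intron_retention",
  cryptic_splice = "cryptic_splice",
  homolog_switch = "homolog_pair",
  contaminant = "unaligned_target"
)

# invariant check: groups share a letter iff their pair is not significant
cldInvariantsHold <- function(letters_vec, sig) {
  k <- length(letters_vec)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      share <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                strsplit(letters_vec[j], "")[[1]])) > 0
      if (share == sig[i, j]) return(FALSE)
    }
  }
  all(nzchar(letters_vec))
}

# independent minimal-cover oracle: minimum number of cliques of the
# non-significance graph covering all vertices and edges, via exhaustive
# search over all vertex subsets that are cliques
cldMinimalLetters <- function(sig) {
  k <- nrow(sig)
  nonsig <- !sig
  diag(nonsig) <- TRUE
  subsets <- lapply(seq_len(2^k - 1),
                    function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  cliques <- Filter(function(s) all(nonsig[s, s]), subsets)
  edges <- which(nonsig & upper.tri(nonsig), arr.ind = TRUE)
  for (size in seq_len(k)) {
    for (sel in combn(length(cliques), size, simplify = FALSE)) {
      chosen <- cliques[sel]
      if (length(unique(unlist(chosen))) < k) next
      ok <- TRUE
      if (nrow(edges)) {
        for (e in seq_len(nrow(edges))) {
          if (!any(vapply(chosen, function(cc)
            all(c(edges[e, 1], edges[e, 2]) %in% cc), logical(1)))) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) return(size)
    }
  }
  k
}
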