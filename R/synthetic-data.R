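# Synthetic data generator: a toy reference (genome, exon annotation,
# haplotypes, foreign sequences) and per-sample FASTQ reads whose
# anchor/target composition encodes known group-dependent events.
#
# Every event plants two isoforms sharing a 27-nt prefix region and diverging
# right after it, so a shared anchor with two distinct targets exists by
# construction. Group membership controls the isoform mixture through
# per-group probabilities.

EVENT_KINDS <- c("allelic", "intron_retention", "cryptic_splice",
                 "homolog_switch", "contaminant")

#' Planted event specification
#'
#' @param kind one of `"allelic"`, `"intron_retention"`, `"cryptic_splice"`,
#'   `"homolog_switch"`, `"contaminant"`.
#' @param gene_id gene identifier (homolog events derive a second id from it).
#' @param group_proportions per-group probability that a read of this event
#'   comes from isoform/allele 1; one entry per group, each in `[0, 1]`.
#' @param expression_per_sample expected read count per sample for this event.
#' @return a list of class `event_spec`.
#' @export
eventSpec <- function(kind, gene_id, group_proportions,
                      expression_per_sample = 300) {
  kind <- match.arg(kind, EVENT_KINDS)
  stopifnot(all(group_proportions >= 0), all(group_proportions <= 1),
            expression_per_sample > 0)
  spec <- list(kind = kind, gene_id = gene_id,
               group_proportions = as.numeric(group_proportions),
               expression_per_sample = expression_per_sample)
  class(spec) <- c("event_spec", "list")
  spec
}

#' Balanced set of planted event specifications
#'
#' Convenience builder for validation designs: `n_per_class` events of each
#' requested kind, all with the same group proportions and expression.
#'
#' @param n_per_class events per kind.
#' @param kinds event kinds to include.
#' @param proportions per-group isoform-1 probabilities (default 0.9/0.1,
#'   the two-group validation design).
#' @param expression expected reads per sample per event.
#' @return list of [eventSpec()] objects.
#' @export
plantedEventSpecs <- function(n_per_class = 1L, kinds = EVENT_KINDS,
                              proportions = c(0.9, 0.1), expression = 300) {
  specs <- list()
  for (kind in kinds) {
    for (i in seq_len(n_per_class)) {
      specs[[length(specs) + 1L]] <- eventSpec(
        kind, sprintf("%s_%03d", kind, i), proportions, expression
      )
    }
  }
  specs
}

#' Simulation configuration
#'
#' Defaults encode the validation design used throughout: two groups of ten
#' samples, 54-nt reads, error-free sequencing (substitution errors can be
#' switched on via `error_rate`), and 300 expected reads per sample per gene.
#'
#' @param seed master seed; all outputs are deterministic given the config.
#' @param n_groups number of sample groups.
#' @param samples_per_group samples per group.
#' @param reads_per_sample total reads per sample, allocated multinomially
#'   across events and null genes proportional to expression; defaults to the
#'   summed expected expressions.
#' @param read_length read length in nt; must be at least
#'   anchor+gap+target (54 at defaults) and at most the shortest isoform.
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param n_null_genes single-isoform genes with no group dependence.
#' @param event_specs list of [eventSpec()] objects.
#' @param null_expression expected reads per sample per null gene.
#' @param genome_length optional cap on genome length; an error is raised if
#'   the requested genes do not fit.
#' @param contaminant_sample_fraction fraction of samples that receive a
#'   contaminant event's foreign isoform at all (the rest express only the
#'   host isoform), emulating presence/absence of an organism across samples.
#' @return a validated list of class `sim_config`.
#' @export
simConfig <- function(seed = 1L, n_groups = 2L, samples_per_group = 10L,
                      reads_per_sample = NULL, read_length = 54L,
                      error_rate = 0, n_null_genes = 5L,
                      event_specs = plantedEventSpecs(),
                      null_expression = 300,
                      genome_length = NULL,
                      contaminant_sample_fraction = 0.7) {
  stopifnot(n_groups >= 1, samples_per_group >= 1, read_length >= 54,
            error_rate >= 0, error_rate <= 0.05, n_null_genes >= 0,
            contaminant_sample_fraction > 0, contaminant_sample_fraction <= 1)
  for (spec in event_specs) {
    if (length(spec$group_proportions) != n_groups) {
      stop("event ", spec$gene_id, ": group_proportions must have one entry",
           " per group (", n_groups, ")")
    }
  }
  if (is.null(reads_per_sample)) {
    expr <- sum(vapply(event_specs, `[[`, numeric(1),
                       "expression_per_sample"))
    reads_per_sample <- round(expr + n_null_genes * null_expression)
  }
  stopifnot(reads_per_sample > 0)
  cfg <- list(seed = as.integer(seed), n_groups = as.integer(n_groups),
              samples_per_group = as.integer(samples_per_group),
              reads_per_sample = as.integer(reads_per_sample),
              read_length = as.integer(read_length),
              error_rate = error_rate,
              n_null_genes = as.integer(n_null_genes),
              event_specs = event_specs,
              null_expression = null_expression,
              genome_length = genome_length,
              contaminant_sample_fraction = contaminant_sample_fraction)
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Sample names and groups implied by a simulation config
#'
#' @param config a [simConfig()].
#' @return data.frame with `sample_id` and `group` (integer) and `label`.
#' @export
simSamples <- function(config) {
  grp <- rep(seq_len(config$n_groups), each = config$samples_per_group)
  idx <- rep(seq_len(config$samples_per_group), times = config$n_groups)
  data.frame(sample_id = sprintf("g%d_s%02d", grp, idx),
             group = grp,
             label = sprintf("group%d", grp),
             stringsAsFactors = FALSE)
}

# random DNA free of disallowed homopolymer runs
cleanDNA <- function(n, max_run = 7L) {
  repeat {
    s <- randomDNA(n)
    if (!hasHomopolymer(s, max_run + 1L)) return(s)
  }
}

# random DNA whose first base differs from `avoid` (used to keep planted
# splice junctions unambiguous for an exact prefix-maximal matcher)
cleanDNAAvoidFirst <- function(n, avoid) {
  repeat {
    s <- cleanDNA(n)
    if (substr(s, 1, 1) != avoid) return(s)
  }
}

# --- per-kind event construction -------------------------------------------
# each builder returns: loci (list of list(seq, exons = data.frame(rel_start,
# rel_end, gene))), event row fields, and optional foreign sequence

.buildAllelic <- function(spec) {
  hap1 <- cleanDNA(108)
  n_snp <- sample(1:3, 1)
  pos <- sort(sample(28:54, n_snp))
  hap2_chars <- strsplit(hap1, "")[[1]]
  subs <- data.frame(pos = pos, ref = hap2_chars[pos],
                     alt = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(pos)) {
    alt <- sample(setdiff(DNA_BASES, hap2_chars[pos[k]]), 1)
    subs$alt[k] <- alt
    hap2_chars[pos[k]] <- alt
  }
  hap2 <- paste(hap2_chars, collapse = "")
  list(
    loci = list(
      list(seq = hap1, exons = data.frame(rel_start = 1, rel_end = 108,
                                          gene = spec$gene_id)),
      list(seq = hap2, exons = data.frame(rel_start = 1, rel_end = 108,
                                          gene = spec$gene_id))
    ),
    iso1 = hap1, iso2 = hap2,
    anchor = substr(hap1, 1, 27),
    target1 = substr(hap1, 28, 54), target2 = substr(hap2, 28, 54),
    gene_ids = spec$gene_id,
    haplotypes = cbind(gene_id = spec$gene_id, subs),
    foreign = NULL
  )
}

.buildHomolog <- function(spec) {
  prefix <- cleanDNA(27)
  body1 <- cleanDNA(81)
  repeat {
    body2 <- cleanDNA(81)
    if (hammingDist(substr(body1, 1, 27), substr(body2, 1, 27)) > 5) break
  }
  g1 <- paste0(prefix, body1)
  g2 <- paste0(prefix, body2)
  gene2 <- paste0(spec$gene_id, "b")
  list(
    loci = list(
      list(seq = g1, exons = data.frame(rel_start = 1, rel_end = 108,
                                        gene = spec$gene_id)),
      list(seq = g2, exons = data.frame(rel_start = 1, rel_end = 108,
                                        gene = gene2))
    ),
    iso1 = g1, iso2 = g2,
    anchor = prefix,
    target1 = substr(body1, 1, 27), target2 = substr(body2, 1, 27),
    gene_ids = paste(spec$gene_id, gene2, sep = ","),
    haplotypes = NULL, foreign = NULL
  )
}

.buildIntronRetention <- function(spec) {
  exon1 <- cleanDNA(54)
  intron <- paste0("GT", cleanDNA(26), "AG")
  exon2 <- cleanDNAAvoidFirst(54, "G")
  locus <- paste0(exon1, intron, exon2)
  list(
    loci = list(list(
      seq = locus,
      exons = data.frame(rel_start = c(1, 85), rel_end = c(54, 138),
                         gene = spec$gene_id)
    )),
    iso1 = paste0(exon1, exon2),
    iso2 = locus,
    anchor = substr(exon1, 28, 54),
    target1 = substr(exon2, 1, 27), target2 = substr(intron, 1, 27),
    gene_ids = spec$gene_id,
    haplotypes = NULL, foreign = NULL
  )
}

.buildCrypticSplice <- function(spec) {
  exon1 <- cleanDNA(54)
  # 40-nt intron with a cryptic GT donor after 13 bases; the skipped piece
  # intron[14..40] is itself GT..AG
  intron <- paste0("GT", cleanDNA(11), "GT", cleanDNA(23), "AG")
  exon2 <- cleanDNAAvoidFirst(54, "G")
  locus <- paste0(exon1, intron, exon2)
  list(
    loci = list(list(
      seq = locus,
      exons = data.frame(rel_start = c(1, 95), rel_end = c(54, 148),
                         gene = spec$gene_id)
    )),
    iso1 = paste0(exon1, exon2),
    iso2 = paste0(exon1, substr(intron, 1, 13), exon2),
    anchor = substr(exon1, 28, 54),
    target1 = substr(exon2, 1, 27),
    target2 = paste0(substr(intron, 1, 13), substr(exon2, 1, 14)),
    gene_ids = spec$gene_id,
    haplotypes = NULL, foreign = NULL,
    acceptor14 = substr(exon2, 1, 14)
  )
}

.buildContaminant <- function(spec) {
  host <- cleanDNA(108)
  foreign <- cleanDNA(81)
  list(
    loci = list(list(
      seq = host,
      exons = data.frame(rel_start = 1, rel_end = 108, gene = spec$gene_id)
    )),
    iso1 = host,
    iso2 = paste0(substr(host, 1, 27), foreign),
    anchor = substr(host, 1, 27),
    target1 = substr(host, 28, 54), target2 = substr(foreign, 1, 27),
    gene_ids = spec$gene_id,
    haplotypes = NULL, foreign = foreign
  )
}

.buildEvent <- function(spec) {
  switch(spec$kind,
    allelic = .buildAllelic(spec),
    intron_retention = .buildIntronRetention(spec),
    cryptic_splice = .buildCrypticSplice(spec),
    homolog_switch = .buildHomolog(spec),
    contaminant = .buildContaminant(spec)
  )
}

.assembleGenome <- function(all_loci, spacer_len = 20L) {
  spacers <- vapply(seq_len(length(all_loci) + 1L), function(i)
    randomDNA(spacer_len), character(1))
  offsets <- integer(length(all_loci))
  pos <- nchar(spacers[1])
  pieces <- list(spacers[1])
  for (i in seq_along(all_loci)) {
    offsets[i] <- pos  # 0-based offset of locus start
    pieces[[length(pieces) + 1L]] <- all_loci[[i]]$seq
    pieces[[length(pieces) + 1L]] <- spacers[i + 1L]
    pos <- pos + nchar(all_loci[[i]]$seq) + nchar(spacers[i + 1L])
  }
  list(genome = paste(unlist(pieces), collapse = ""), offsets = offsets)
}

#' Build the synthetic reference bundle and ground truth
#'
#' Generates, deterministically from the config seed, a single-chromosome
#' genome containing every event's locus (both haplotype/homolog copies where
#' applicable) plus null genes, exon annotation, planted haplotype variants,
#' and foreign sequences guaranteed to share no 27-mer with the genome.
#' Cryptic splice junctions planted in isoform 2 are absent from the
#' annotation by construction.
#'
#' @param config a [simConfig()].
#' @return a [GroundTruth-class] (realized counts empty until simulation).
#' @export
buildReference <- function(config = simConfig()) {
  set.seed(config$seed)
  samples <- simSamples(config)
  built <- lapply(config$event_specs, .buildEvent)
  # null genes: single isoform, no group dependence
  null_genes <- list()
  for (i in seq_len(config$n_null_genes)) {
    null_genes[[i]] <- list(
      seq = cleanDNA(108),
      exons = data.frame(rel_start = 1, rel_end = 108,
                         gene = sprintf("null_%03d", i))
    )
  }

  # contaminant events: draw the subset of samples carrying the foreign form
  contam_samples <- vector("list", length(built))
  for (i in seq_along(built)) {
    if (config$event_specs[[i]]$kind == "contaminant") {
      n_carry <- max(1L, round(config$contaminant_sample_fraction *
                                 nrow(samples)))
      contam_samples[[i]] <- sort(sample(samples$sample_id, n_carry))
    }
  }

  # assembly + verification: foreign sequences must share no 27-mer with the
  # genome, and cryptic acceptor seeds must be unique so the planted junction
  # is recovered exactly; violated events are deterministically regenerated
  for (pass in 1:10) {
    all_loci <- c(do.call(c, lapply(built, `[[`, "loci")),
                  if (length(null_genes)) null_genes)
    asm <- .assembleGenome(all_loci)
    if (!is.null(config$genome_length) &&
        nchar(asm$genome) > config$genome_length) {
      stop("genome sizing error: requested genes need ", nchar(asm$genome),
           " bp but genome_length is ", config$genome_length)
    }
    genome_kmers <- unique(kmersOf(asm$genome, 27L))
    ok <- TRUE
    for (i in seq_along(built)) {
      spec <- config$event_specs[[i]]
      if (spec$kind == "contaminant") {
        shared <- intersect(unique(kmersOf(built[[i]]$foreign, 27L)),
                            genome_kmers)
        if (length(shared)) {
          built[[i]] <- .buildContaminant(spec)
          ok <- FALSE
        }
      } else if (spec$kind == "cryptic_splice") {
        hits <- gregexpr(built[[i]]$acceptor14, asm$genome,
                         fixed = TRUE)[[1]]
        if (length(hits[hits > 0]) != 1L) {
          built[[i]] <- .buildCrypticSplice(spec)
          ok <- FALSE
        }
      }
    }
    if (ok) break
    if (pass == 10) stop("could not satisfy reference constraints")
  }

  # absolute exon coordinates (asm and all_loci come from the clean pass)
  exon_rows <- vector("list", length(all_loci))
  for (i in seq_along(all_loci)) {
    ex <- all_loci[[i]]$exons
    exon_rows[[i]] <- data.frame(
      chrom = "chr1",
      start = asm$offsets[i] + ex$rel_start,  # 1-based inclusive
      end = asm$offsets[i] + ex$rel_end,
      gene = ex$gene,
      stringsAsFactors = FALSE
    )
  }
  exon_df <- do.call(rbind, exon_rows)
  exons <- GRanges("chr1", IRanges(exon_df$start, exon_df$end), strand = "+")
  mcols(exons)$gene <- exon_df$gene

  events <- data.frame(
    event_id = vapply(config$event_specs, `[[`, character(1), "gene_id"),
    kind = vapply(config$event_specs, `[[`, character(1), "kind"),
    gene_id = vapply(config$event_specs, `[[`, character(1), "gene_id"),
    gene_ids = vapply(built, `[[`, character(1), "gene_ids"),
    anchor = vapply(built, `[[`, character(1), "anchor"),
    target1 = vapply(built, `[[`, character(1), "target1"),
    target2 = vapply(built, `[[`, character(1), "target2"),
    expression = vapply(config$event_specs, `[[`, numeric(1),
                        "expression_per_sample"),
    proportions = vapply(config$event_specs, function(s)
      paste(s$group_proportions, collapse = ","), character(1)),
    contam_samples = vapply(contam_samples, function(x)
      if (is.null(x)) "" else paste(x, collapse = ","), character(1)),
    iso1 = vapply(built, `[[`, character(1), "iso1"),
    iso2 = vapply(built, `[[`, character(1), "iso2"),
    stringsAsFactors = FALSE
  )
  if (nrow(events)) {
    events$seq1 <- paste0(events$anchor, events$target1)
    events$seq2 <- paste0(events$anchor, events$target2)
    # simulated transcripts are the discriminating fragments themselves, so
    # a planted anchor receives the event's full per-sample expression; the
    # complete loci (exons, introns, flanks) live in the genome and are
    # exercised by the annotation stage
    events$iso1 <- events$seq1
    events$iso2 <- events$seq2
  } else {
    events$seq1 <- character(0)
    events$seq2 <- character(0)
  }

  haps <- do.call(rbind, Filter(Negate(is.null),
                                lapply(built, `[[`, "haplotypes")))
  if (is.null(haps)) {
    haps <- data.frame(gene_id = character(0), pos = integer(0),
                       ref = character(0), alt = character(0))
  }
  foreign <- Filter(Negate(is.null), lapply(built, `[[`, "foreign"))
  contaminants <- if (length(foreign)) {
    idx <- which(vapply(built, function(b) !is.null(b$foreign), logical(1)))
    DNAStringSet(setNames(unlist(foreign), events$gene_id[idx]))
  } else {
    DNAStringSet()
  }

  genome <- DNAStringSet(setNames(asm$genome, "chr1"))
  new("GroundTruth", config = unclass(config), genome = genome,
      exons = exons, haplotypes = haps, contaminants = contaminants,
      events = events,
      realized = data.frame(event_id = character(0), sample_id = character(0),
                            iso1_count = integer(0), iso2_count = integer(0)))
}

# draw read substrings from an isoform: uniform start positions, optional
# per-base substitution errors
.drawReads <- function(iso, n, read_len, error_rate) {
  if (n == 0L) return(character(0))
  L <- nchar(iso)
  if (read_len > L) {
    stop("read_length (", read_len, ") exceeds isoform length (", L, ")")
  }
  starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
  reads <- substring(iso, starts, starts + read_len - 1L)
  if (error_rate > 0) {
    n_err <- rbinom(n, read_len, error_rate)
    for (i in which(n_err > 0L)) {
      chars <- strsplit(reads[i], "")[[1]]
      pos <- sample.int(read_len, n_err[i])
      for (p in pos) {
        chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
      }
      reads[i] <- paste(chars, collapse = "")
    }
  }
  reads
}

#' Simulate the reads of one sample
#'
#' The sample's total read count is allocated multinomially across events and
#' null genes proportional to their expected expression. Within each event,
#' isoform-1 reads are drawn binomially with the sample group's proportion
#' (contaminant events fall back to isoform 1 in samples not carrying the
#' foreign form); read start positions are uniform; substitution errors are
#' applied at the configured rate.
#'
#' @param truth a [GroundTruth-class] from [buildReference()].
#' @param sample_id sample name.
#' @param group integer group index of the sample.
#' @param seed RNG seed for this sample.
#' @return list with `reads` (data.frame of `read_id`, `sequence`) and
#'   `realized` (per-event isoform read counts for this sample).
#' @export
simulateSample <- function(truth, sample_id, group, seed) {
  config <- truth@config
  stopifnot(group >= 1, group <= config$n_groups)
  set.seed(seed)
  events <- truth@events
  n_units <- nrow(events) + config$n_null_genes
  weights <- c(events$expression,
               rep(config$null_expression, config$n_null_genes))
  alloc <- as.vector(rmultinom(1, config$reads_per_sample,
                               weights / sum(weights)))
  reads <- character(0)
  realized <- data.frame(event_id = character(0), sample_id = character(0),
                         iso1_count = integer(0), iso2_count = integer(0))
  for (i in seq_len(nrow(events))) {
    n_ev <- alloc[i]
    props <- as.numeric(strsplit(events$proportions[i], ",")[[1]])
    p1 <- props[group]
    if (events$kind[i] == "contaminant" && nzchar(events$contam_samples[i])) {
      carriers <- strsplit(events$contam_samples[i], ",")[[1]]
      if (!sample_id %in% carriers) p1 <- 1
    }
    n1 <- rbinom(1, n_ev, p1)
    n2 <- n_ev - n1
    reads <- c(reads,
               .drawReads(events$iso1[i], n1, config$read_length,
                          config$error_rate),
               .drawReads(events$iso2[i], n2, config$read_length,
                          config$error_rate))
    realized <- rbind(realized, data.frame(
      event_id = events$event_id[i], sample_id = sample_id,
      iso1_count = n1, iso2_count = n2, stringsAsFactors = FALSE
    ))
  }
  # null genes: single isoform each
  null_ids <- sprintf("null_%03d", seq_len(config$n_null_genes))
  exon_genes <- mcols(truth@exons)$gene
  genome_chr <- as.character(truth@genome[[1]])
  for (k in seq_len(config$n_null_genes)) {
    idx <- which(exon_genes == null_ids[k])[1]
    iso <- substr(genome_chr, start(truth@exons)[idx], end(truth@exons)[idx])
    reads <- c(reads, .drawReads(iso, alloc[nrow(events) + k],
                                 config$read_length, config$error_rate))
  }
  list(reads = data.frame(
         read_id = sprintf("%s_r%06d", sample_id, seq_along(reads)),
         sequence = reads, stringsAsFactors = FALSE),
       realized = realized)
}

.writeFastq <- function(reads, path) {
  x <- DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  quals <- BStringSet(strrep("I", nchar(reads$sequence)))
  writeXStringSet(x, path, format = "fastq", qualities = quals)
}

.writeBed <- function(exons, path) {
  df <- data.frame(
    chrom = as.character(seqnames(exons)),
    start = start(exons) - 1L,  # BED is 0-based half-open
    end = end(exons),
    name = mcols(exons)$gene,
    score = 0L,
    strand = as.character(strand(exons))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Write a complete synthetic dataset to disk
#'
#' Writes one FASTQ per sample, a space-delimited sample sheet, the genome
#' FASTA, exon BED, contaminant FASTA (when present), a sample metadata table,
#' and the ground-truth event registry (including the two discriminating
#' 54-nt sequences per event). Re-running with the same config produces
#' byte-identical files.
#'
#' @param truth a [GroundTruth-class].
#' @param out_dir output directory (created if needed).
#' @return list of file paths plus the updated `truth` (realized counts
#'   filled in).
#' @export
writeDataset <- function(truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- truth@config
  samples <- simSamples(config)
  fastq_paths <- file.path(out_dir, paste0(samples$sample_id, ".fastq"))
  realized_all <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    seed_i <- as.integer((config$seed + 1000003 * i) %% 2147483647)
    sim <- simulateSample(truth, samples$sample_id[i], samples$group[i],
                          seed_i)
    .writeFastq(sim$reads, fastq_paths[i])
    realized_all[[i]] <- sim$realized
  }
  truth@realized <- do.call(rbind, c(realized_all,
                                     list(make.row.names = FALSE)))

  sheet_path <- file.path(out_dir, "samples.txt")
  writeLines(paste(samples$sample_id, fastq_paths), sheet_path)

  genome_path <- file.path(out_dir, "genome.fa")
  writeXStringSet(truth@genome, genome_path)

  bed_path <- file.path(out_dir, "exons.bed")
  .writeBed(truth@exons, bed_path)

  contam_path <- NULL
  if (length(truth@contaminants)) {
    contam_path <- file.path(out_dir, "contaminants.fa")
    writeXStringSet(truth@contaminants, contam_path)
  }

  meta_path <- file.path(out_dir, "metadata.tsv")
  write.table(samples[, c("sample_id", "label")], meta_path, sep = "\t",
              quote = FALSE, row.names = FALSE)

  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(truth@events[, c("event_id", "kind", "gene_id", "gene_ids",
                               "anchor", "target1", "target2",
                               "seq1", "seq2", "expression", "proportions")],
              truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  realized_path <- file.path(out_dir, "realized.tsv")
  write.table(truth@realized, realized_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(truth = truth, dir = out_dir, sample_sheet = sheet_path,
       fastq = setNames(fastq_paths, samples$sample_id),
       genome = genome_path, bed = bed_path, contaminants = contam_path,
       metadata = meta_path, truth_file = truth_path,
       realized_file = realized_path)
}

#' Build a reference and write a dataset in one call
#'
#' @param config a [simConfig()].
#' @param out_dir output directory.
#' @return as [writeDataset()].
#' @export
simulateDataset <- function(config = simConfig(), out_dir) {
  truth <- buildReference(config)
  writeDataset(truth, out_dir)
}

#' Simulate null anchor tables
#'
#' Generates anchor tables with target composition shared across samples (the
#' null of the significance test): each anchor draws a random composition
#' over `n_targets` targets, each sample a depth uniform in `depth_range`,
#' and per-sample counts are multinomial with the shared composition.
#'
#' @param n_anchors number of anchors.
#' @param n_samples samples per anchor.
#' @param n_targets targets per anchor.
#' @param depth_range integer range of per-sample depths (inclusive).
#' @param seed RNG seed.
#' @return list of [AnchorTable-class] objects with random 27-nt anchors.
#' @export
nullAnchorTables <- function(n_anchors = 1000L, n_samples = 20L,
                             n_targets = 5L, depth_range = c(50L, 500L),
                             seed = 1L) {
  set.seed(seed)
  out <- vector("list", n_anchors)
  sample_ids <- sprintf("s%02d", seq_len(n_samples))
  for (i in seq_len(n_anchors)) {
    anchor <- randomDNA(27)
    comp <- -log(runif(n_targets))  # Dirichlet(1)
    comp <- comp / sum(comp)
    depths <- sample(seq(depth_range[1], depth_range[2]), n_samples,
                     replace = TRUE)
    counts <- t(vapply(depths, function(d) as.vector(rmultinom(1, d, comp)),
                       numeric(n_targets)))
    targets <- vapply(seq_len(n_targets), function(t) randomDNA(27),
                      character(1))
    dimnames(counts) <- list(sample_ids, targets)
    out[[i]] <- AnchorTable(anchor, counts)
  }
  out
}
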