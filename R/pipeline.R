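# Pipeline orchestration: extraction -> significance -> artifact screen ->
# annotation -> regulation, with a manifest, per-stage logging and TSV/JSON
# report files.

#' Parse a space-delimited sample sheet
#'
#' One sample per line as "name path"; blank lines and lines starting with
#' `#` are skipped. Duplicate sample names and missing files are fatal.
#'
#' @param path sample sheet path.
#' @return data.frame with `name` and `path`, in file order.
#' @export
parseSampleSheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 2L) {
      stop("sample sheet line ", i, ": expected 'name path'")
    }
    out[[length(out) + 1L]] <- data.frame(name = f[1], path = f[2], line = i,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("sample sheet is empty: ", path)
  df <- do.call(rbind, out)
  dup <- duplicated(df$name)
  if (any(dup)) {
    stop("duplicate sample name '", df$name[dup][1], "' at sample sheet line ",
         df$line[dup][1])
  }
  missing <- !file.exists(df$path)
  if (any(missing)) {
    stop("FASTQ file not found for sample '", df$name[missing][1], "': ",
         df$path[missing][1])
  }
  df[, c("name", "path")]
}

#' Pipeline run configuration
#'
#' Bundles the per-stage configurations with the input/output paths and a
#' master seed; stage defaults equal the published run parameters.
#'
#' @param sample_sheet path to the sample sheet.
#' @param out_dir output directory.
#' @param genome optional genome FASTA path (enables annotation).
#' @param exon_bed optional exon BED path (required with `genome`).
#' @param contaminants optional contaminant FASTA (enables artifact screen).
#' @param metadata optional metadata TSV (enables regulation).
#' @param seed master seed.
#' @param extraction an [extractionConfig()].
#' @param test a [testConfig()] (its seed is overridden by `seed`).
#' @param min_intron,max_intron spliced-placement gap bounds.
#' @param hamming_threshold allelic-vs-homolog Hamming cutoff.
#' @param alpha pairwise test significance level.
#' @param extra named list of unrecognized options, accepted and logged as
#'   no-ops for compatibility with the original tool's flags.
#' @return list of class `run_config`.
#' @export
runConfig <- function(sample_sheet, out_dir, genome = NULL, exon_bed = NULL,
                      contaminants = NULL, metadata = NULL, seed = 1L,
                      extraction = extractionConfig(), test = testConfig(),
                      min_intron = 21L, max_intron = 1000000L,
                      hamming_threshold = 5L, alpha = 0.05,
                      extra = list()) {
  test$seed <- as.integer(seed)
  cfg <- list(sample_sheet = sample_sheet, out_dir = out_dir,
              genome = genome, exon_bed = exon_bed,
              contaminants = contaminants, metadata = metadata,
              seed = as.integer(seed), extraction = extraction, test = test,
              min_intron = min_intron, max_intron = max_intron,
              hamming_threshold = hamming_threshold, alpha = alpha,
              extra = extra)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a run configuration from a file
#'
#' Accepts YAML (when the yaml package is available) or flat `key = value`
#' lines. Unrecognized keys are accepted and logged as no-ops.
#'
#' @param path config file path.
#' @return a [runConfig()].
#' @export
readRunConfig <- function(path) {
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, "\\s*[=:]\\s*")
    vals <- setNames(lapply(kv, function(x) utils::type.convert(x[2],
                                                                as.is = TRUE)),
                     vapply(kv, `[[`, character(1), 1))
  }
  known <- c("sample_sheet", "out_dir", "genome", "exon_bed", "contaminants",
             "metadata", "seed", "min_intron", "max_intron",
             "hamming_threshold", "alpha")
  ext_keys <- intersect(names(vals), names(formals(extractionConfig)))
  test_keys <- intersect(names(vals), names(formals(testConfig)))
  extra <- vals[setdiff(names(vals), c(known, ext_keys, test_keys))]
  if (length(extra)) {
    message("ignoring unrecognized config options: ",
            paste(names(extra), collapse = ", "))
  }
  args <- vals[intersect(names(vals), known)]
  args$extraction <- do.call(extractionConfig, vals[ext_keys])
  args$test <- do.call(testConfig, vals[test_keys])
  args$extra <- extra
  do.call(runConfig, args)
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes extraction, significance testing, artifact screening, annotation
#' and regulation in order; stages whose inputs are absent (reference,
#' contaminants, metadata) are skipped with a logged notice. Writes
#' `anchors.tsv`, `events.tsv`, `regulation.tsv`, `summary.txt` and
#' `manifest.json` under the output directory.
#'
#' @param config a [runConfig()].
#' @return invisible list with all stage objects: `set` (filtered
#'   [AnchorTableSet-class]), `results` ([AnchorTestResults-class]),
#'   `anchors` (annotated result table), `events`, `regulation`,
#'   `intersection`, `summary`, `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "anchorvar",
                   version = as.character(utils::packageVersion("anchorvar")),
                   seed = config$seed,
                   parameters = list(extraction = config$extraction,
                                     test = unclass(config$test)),
                   stages = list())
  if (length(config$extra)) {
    .stageLog("config", "accepted no-op options: ",
              paste(names(config$extra), collapse = ", "))
  }

  # stage 1: extraction
  sheet <- parseSampleSheet(config$sample_sheet)
  raw <- buildAnchorTables(sheet, config$extraction)
  set <- applyAnchorFilters(raw, config$extraction)
  .stageLog("extraction", length(raw), " anchors counted, ",
            length(set), " pass filters")
  manifest$stages$extraction <- list(samples = nrow(sheet),
                                     anchors_counted = length(raw),
                                     anchors_kept = length(set))

  # stage 2: significance
  results <- testAnchors(set, config$test)
  res <- resultTable(results)
  .stageLog("significance", nrow(res), " anchors tested, ",
            sum(res$significant), " significant at FDR ",
            config$test$fdr_threshold)
  manifest$stages$significance <- list(tested = nrow(res),
                                       significant = sum(res$significant))
  res$artifact <- FALSE

  # stage 3: artifact screen
  if (!is.null(config$contaminants)) {
    index <- buildContaminantIndex(config$contaminants,
                                   k = config$extraction$anchor_len)
    res$artifact <- screenAnchors(res$anchor, index)
    .stageLog("contaminants", sum(res$artifact), " anchors flagged as artifacts")
    manifest$stages$contaminants <- list(index_kmers = length(index),
                                         flagged = sum(res$artifact))
  } else {
    .stageLog("contaminants", "skipped (no contaminant FASTA)")
  }
  sig_anchors <- res$anchor[res$significant & !res$artifact]

  # stage 4: annotation
  events <- NULL
  unaligned <- character(0)
  if (!is.null(config$genome) && !is.null(config$exon_bed)) {
    genome <- loadGenome(config$genome)
    exons <- readExonBed(config$exon_bed)
    events <- classifyEvents(sig_anchors, set, genome, exons,
                             config$min_intron, config$max_intron,
                             config$hamming_threshold)
    if (!is.null(events) && nrow(events)) {
      unaligned <- events$anchor[events$status1 == "unaligned" |
                                   events$status2 == "unaligned"]
      exportConcatFasta(sig_anchors, set,
                        file.path(config$out_dir, "concatenated.fa"))
    }
    .stageLog("annotation", length(sig_anchors), " anchors classified, ",
              length(unaligned), " with an unaligned top-2 target")
    manifest$stages$annotation <- list(classified = length(sig_anchors),
                                       unaligned = length(unaligned))
  } else {
    .stageLog("annotation", "skipped (no genome/BED)")
  }

  # stage 5: regulation
  regulation <- NULL
  intersection <- NULL
  if (!is.null(config$metadata)) {
    meta <- readMetadata(config$metadata)
    labels <- setNames(meta$group, meta$sample_id)
    reg_rows <- vector("list", length(sig_anchors))
    for (i in seq_along(sig_anchors)) {
      a <- sig_anchors[i]
      tab <- anchorTable(set, a)
      ranked <- rankedTargets(tab)
      top2 <- anchorCounts(tab)[, ranked[1:2], drop = FALSE]
      glm_res <- glmMetadataDependence(top2, labels,
                                       seed = anchorSeed(a, config$seed))
      frac <- targetFractions(tab)[, ranked[1]]
      tuk <- tryCatch(anovaTukey(frac, labels, config$alpha),
                      error = function(e) NULL)
      reg_rows[[i]] <- data.frame(
        anchor = a,
        max_abs_coefficient = glm_res$max_abs_coefficient,
        regulated = glm_res$regulated,
        evaluable = glm_res$evaluable,
        F = if (is.null(tuk)) NA_real_ else tuk$F,
        anova_p = if (is.null(tuk)) NA_real_ else tuk$p,
        letters = if (is.null(tuk)) NA_character_ else
          paste(paste0(names(tuk$letters), "=", tuk$letters), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
    regulation <- do.call(rbind, c(reg_rows, list(make.row.names = FALSE)))
    regulated <- if (is.null(regulation)) character(0) else
      regulation$anchor[!is.na(regulation$regulated) & regulation$regulated]
    es <- setNames(res$effect_size, res$anchor)
    intersection <- intersectUnalignedRegulated(sig_anchors, unaligned,
                                                regulated, es)
    .stageLog("regulation", length(regulated), " regulated anchors, ",
              intersection$n_intersection, " also unaligned")
    manifest$stages$regulation <- list(
      evaluated = if (is.null(regulation)) 0L else nrow(regulation),
      regulated = length(regulated),
      intersection = intersection$n_intersection
    )
  } else {
    .stageLog("regulation", "skipped (no metadata)")
  }

  run <- list(set = set, results = results, anchors = res, events = events,
              regulation = regulation, intersection = intersection,
              config = config)
  run$summary <- summarizeRun(run)
  manifest$summary <- run$summary
  run$manifest <- manifest

  # report files
  write.table(res, file.path(config$out_dir, "anchors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeAnchorCounts(set, file.path(config$out_dir, "counts.tsv"))
  if (!is.null(intersection)) {
    write.table(
      data.frame(anchor = intersection$anchors,
                 effect_size = res$effect_size[match(intersection$anchors,
                                                     res$anchor)]),
      file.path(config$out_dir, "intersection.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(events)) {
    write.table(events, file.path(config$out_dir, "events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(regulation)) {
    write.table(regulation, file.path(config$out_dir, "regulation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(formatSummary(run$summary),
             file.path(config$out_dir, "summary.txt"))
  write_json(manifest, file.path(config$out_dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(run)
}

#' Summary counts and percentages of a run
#'
#' Reports the total number of significant anchors, how many have one (or
#' both) of the top-2 targets unaligned, how many are metadata-regulated, and
#' the regulated-and-unaligned intersection, with percentages computed from
#' the integer counts.
#'
#' @param run the list returned by [runPipeline()], or counts via
#'   [summarizeCounts()].
#' @return list of counts and percentages.
#' @export
summarizeRun <- function(run) {
  res <- run$anchors
  n_sig <- sum(res$significant & !res$artifact)
  ev <- run$events
  n_unaligned <- 0L
  n_both <- 0L
  if (!is.null(ev) && nrow(ev)) {
    one_un <- xor(ev$status1 == "unaligned", ev$status2 == "unaligned")
    both_un <- ev$status1 == "unaligned" & ev$status2 == "unaligned"
    n_unaligned <- sum(one_un)
    n_both <- sum(both_un)
  }
  n_reg <- if (is.null(run$regulation)) 0L else
    sum(!is.na(run$regulation$regulated) & run$regulation$regulated)
  n_int <- if (is.null(run$intersection)) 0L else
    run$intersection$n_intersection
  summarizeCounts(n_sig, n_unaligned, n_both, n_reg, n_int)
}

#' @rdname summarizeRun
#' @param n_significant total significant anchors.
#' @param n_unaligned significant anchors with exactly one top-2 target
#'   unaligned.
#' @param n_both_unaligned significant anchors with both top-2 targets
#'   unaligned.
#' @param n_regulated metadata-regulated anchors.
#' @param n_intersection regulated anchors that are also unaligned.
#' @export
summarizeCounts <- function(n_significant, n_unaligned,
                            n_both_unaligned = 0L, n_regulated = 0L,
                            n_intersection = 0L) {
  list(
    n_significant = n_significant,
    n_unaligned = n_unaligned,
    n_both_unaligned = n_both_unaligned,
    n_regulated = n_regulated,
    n_intersection = n_intersection,
    pct_unaligned = percentOf(n_unaligned, n_significant),
    pct_unaligned_str = formatPercent(n_unaligned, n_significant),
    pct_intersection = percentOf(n_intersection, n_regulated),
    pct_intersection_str = formatPercent(n_intersection, n_regulated)
  )
}

#' @rdname summarizeRun
#' @param summary a summary list from [summarizeRun()].
#' @export
formatSummary <- function(summary) {
  c(
    sprintf("significant anchors: %d", summary$n_significant),
    sprintf("one of top-2 targets unaligned: %d (%s%%)",
            summary$n_unaligned, summary$pct_unaligned_str),
    sprintf("both top-2 targets unaligned: %d", summary$n_both_unaligned),
    sprintf("metadata-regulated anchors: %d", summary$n_regulated),
    sprintf("regulated and unaligned: %d (%s%%)",
            summary$n_intersection, summary$pct_intersection_str)
  )
}
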