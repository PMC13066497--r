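# Regulation stage: call metadata-dependent anchors by penalized multinomial
# regression on top-2 target counts, run pairwise group tests with compact
# letter summaries, and apply the triage filters and intersections used for
# prioritizing anchors.

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id` and `group` (the combined
#'   metadata grouping, e.g. tissue+treatment concatenated).
#' @return data.frame with `sample_id` and `group`.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if ("label" %in% names(df) && !"group" %in% names(df)) {
    df$group <- df$label
  }
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("metadata must have columns sample_id and group")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df[, c("sample_id", "group")]
}

#' Metadata dependence of an anchor by penalized multinomial regression
#'
#' Fits an L1-penalized multinomial logistic model predicting the sample's
#' metadata group from the counts of the anchor's top two targets (ND samples
#' excluded). Predictors are standardized to unit variance by default so the
#' fixed coefficient rule is scale-free. The penalty is chosen by K-fold
#' cross-validated deviance with K = min(10, n_samples) and seeded folds. The
#' anchor is called regulated iff the largest absolute (non-intercept)
#' coefficient across classes and predictors exceeds 1.
#'
#' @param counts samples x 2 matrix of top-2 target counts (rownames =
#'   sample ids).
#' @param labels metadata group per sample (named by sample id, or aligned
#'   with the rows of `counts`).
#' @param seed fold seed.
#' @param standardize standardize predictors to unit variance (default TRUE).
#' @return list with `max_abs_coefficient`, `regulated`, `evaluable` and
#'   `n_used`.
#' @export
glmMetadataDependence <- function(counts, labels, seed = 1L,
                                  standardize = TRUE) {
  counts <- as.matrix(counts)
  if (!is.null(names(labels)) && !is.null(rownames(counts))) {
    labels <- labels[rownames(counts)]
  }
  stopifnot(length(labels) == nrow(counts))
  not_evaluable <- list(max_abs_coefficient = NA_real_, regulated = NA,
                        evaluable = FALSE, n_used = 0L)
  use <- rowSums(counts) > 0 & !is.na(labels)
  x <- counts[use, , drop = FALSE]
  y <- factor(labels[use])
  not_evaluable$n_used <- nrow(x)
  if (nrow(x) < 4L) return(not_evaluable)
  tab <- table(y)
  if (sum(tab >= 2L) < 2L || length(tab) < 2L) return(not_evaluable)
  if (standardize) {
    sds <- apply(x, 2, sd)
    sds[sds == 0] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }
  if (all(apply(x, 2, sd) == 0)) {
    return(list(max_abs_coefficient = 0, regulated = FALSE,
                evaluable = TRUE, n_used = nrow(x)))
  }
  set.seed(seed)
  K <- min(10L, nrow(x))
  foldid <- sample(rep(seq_len(K), length.out = nrow(x)))
  # cv.glmnet warns when folds hold few observations of a class; expected at
  # these sample sizes and harmless for the coefficient-magnitude rule
  fit <- tryCatch(
    suppressWarnings(
      cv.glmnet(x, y, family = "multinomial", alpha = 1, foldid = foldid,
                standardize = FALSE)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(not_evaluable)
  cf <- coef(fit, s = "lambda.min")
  max_abs <- max(vapply(cf, function(m) {
    v <- as.matrix(m)[-1, , drop = FALSE]  # drop intercept
    if (length(v)) max(abs(v)) else 0
  }, numeric(1)))
  list(max_abs_coefficient = max_abs, regulated = max_abs > 1,
       evaluable = TRUE, n_used = nrow(x))
}

#' One-way ANOVA and Tukey HSD on a target fraction
#'
#' Compares the fraction of reads from a target across metadata groups.
#' ND samples (NA fractions) are excluded; groups left without usable samples
#' are dropped with a warning. Pairwise Tukey-adjusted p-values are summarized
#' as a compact letter display.
#'
#' @param fractions per-sample fraction of the target (NA = ND), named by
#'   sample id or aligned with `labels`.
#' @param labels metadata group per sample.
#' @param alpha pairwise significance level (default 0.05).
#' @return list with `F`, `p`, `pairwise` (data.frame `group1`, `group2`,
#'   `diff`, `p_adj`, `significant`), `letters` (named character) and
#'   `n_used`.
#' @export
anovaTukey <- function(fractions, labels, alpha = 0.05) {
  if (!is.null(names(fractions)) && !is.null(names(labels))) {
    labels <- labels[names(fractions)]
  }
  stopifnot(length(fractions) == length(labels))
  use <- !is.na(fractions) & !is.na(labels)
  dropped <- setdiff(unique(labels[!is.na(labels)]), unique(labels[use]))
  if (length(dropped)) {
    warning("groups with no usable (non-ND) samples dropped: ",
            paste(dropped, collapse = ", "))
  }
  y <- fractions[use]
  g <- factor(labels[use])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("fewer than 2 usable groups")
  groups <- levels(g)
  pairs <- t(combn(groups, 2))
  if (sum(tapply(y, g, function(v) sum(!is.na(v))) >= 1L) < 2L) {
    stop("fewer than 2 usable groups")
  }
  if (max(y) - min(y) < .Machine$double.eps^0.5) {
    # no variation at all: F = 0, nothing significant
    pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2], diff = 0,
                     p_adj = 1, significant = FALSE,
                     stringsAsFactors = FALSE)
    letters <- setNames(rep("a", length(groups)), groups)
    return(list(F = 0, p = 1, pairwise = pw, letters = letters,
                n_used = length(y)))
  }
  fit <- aov(y ~ g)
  sm <- summary(fit)[[1]]
  Fval <- sm[["F value"]][1]
  pval <- sm[["Pr(>F)"]][1]
  mse <- sm[["Mean Sq"]][2]
  if (is.na(mse) || mse < .Machine$double.eps) {
    # zero residual variance but group means differ: separation is exact
    means <- tapply(y, g, mean)
    pw <- data.frame(
      group1 = pairs[, 1], group2 = pairs[, 2],
      diff = means[pairs[, 2]] - means[pairs[, 1]],
      p_adj = as.numeric(means[pairs[, 1]] == means[pairs[, 2]]),
      stringsAsFactors = FALSE
    )
    pw$significant <- pw$p_adj <= alpha
    Fval <- Inf
    pval <- 0
  } else {
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
    key <- paste(pairs[, 2], pairs[, 1], sep = "-")
    pw <- data.frame(
      group1 = pairs[, 1], group2 = pairs[, 2],
      diff = tk[key, "diff"],
      p_adj = tk[key, "p adj"],
      stringsAsFactors = FALSE
    )
    pw$significant <- pw$p_adj <= alpha
  }
  rownames(pw) <- NULL
  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (r in seq_len(nrow(pw))) {
    sig[pw$group1[r], pw$group2[r]] <- pw$significant[r]
    sig[pw$group2[r], pw$group1[r]] <- pw$significant[r]
  }
  letters <- compactLetterDisplay(sig)
  list(F = Fval, p = pval, pairwise = pw, letters = letters,
       n_used = length(y))
}

# all maximal cliques of an undirected graph given as a logical adjacency
# matrix (k <= ~12); simple Bron-Kerbosch on index vectors
.maximalCliques <- function(adj) {
  k <- nrow(adj)
  cliques <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- sort(R)
      return(invisible())
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(k), integer(0))
  cliques
}

#' Compact letter display from pairwise significance decisions
#'
#' Assigns letters to groups so that two groups share a letter iff they are
#' not significantly different: letters correspond to a minimum-size set of
#' cliques of the non-significance graph covering all its vertices and edges
#' (exhaustive search over maximal cliques, exact for the group counts used
#' in practice).
#'
#' @param sig symmetric logical matrix; `TRUE` = the pair is significantly
#'   different. Dimnames give group names.
#' @param groups group names (defaults to `rownames(sig)`).
#' @return named character vector of letter strings, one per group.
#' @export
compactLetterDisplay <- function(sig, groups = rownames(sig)) {
  sig <- as.matrix(sig)
  k <- nrow(sig)
  if (is.null(groups)) groups <- paste0("G", seq_len(k))
  stopifnot(ncol(sig) == k, isTRUE(all(sig == t(sig))))
  if (k > 12L) stop("compactLetterDisplay supports up to 12 groups")
  nonsig <- !sig
  diag(nonsig) <- FALSE
  if (k == 1L) return(setNames("a", groups))
  cl <- .maximalCliques(nonsig)
  # bitmask cover search: letters = minimum set of cliques covering all
  # vertices and all non-significance edges
  masks <- vapply(cl, function(cc)
    Reduce(bitwOr, bitwShiftL(1L, cc - 1L)), integer(1))
  full <- bitwShiftL(1L, k) - 1L
  edges <- which(nonsig & upper.tri(nonsig), arr.ind = TRUE)
  edge_masks <- if (nrow(edges)) {
    bitwOr(bitwShiftL(1L, edges[, 1] - 1L), bitwShiftL(1L, edges[, 2] - 1L))
  } else {
    integer(0)
  }
  covers <- function(sel) {
    mm <- masks[sel]
    if (Reduce(bitwOr, mm) != full) return(FALSE)
    for (em in edge_masks) {
      if (!any(bitwAnd(mm, em) == em)) return(FALSE)
    }
    TRUE
  }
  best <- NULL
  for (sz in seq_along(cl)) {
    combos <- combn(length(cl), sz, simplify = FALSE)
    for (sel in combos) {
      if (covers(sel)) {
        best <- cl[sel]
        break
      }
    }
    if (!is.null(best)) break
  }
  # order letters by the smallest group index they contain
  best <- best[order(vapply(best, min, numeric(1)))]
  out <- setNames(rep("", k), groups)
  for (i in seq_along(best)) {
    out[best[[i]]] <- paste0(out[best[[i]]], letters[i])
  }
  out
}

#' Intersect unaligned and metadata-regulated anchors
#'
#' Returns the intersection sorted by decreasing effect size, together with
#' the two summary percentages: unaligned anchors as a share of all
#' significant anchors, and the intersection as a share of regulated anchors.
#'
#' @param significant character vector of all significant anchors.
#' @param unaligned significant anchors with one of the top-2 targets
#'   unaligned.
#' @param regulated metadata-regulated anchors.
#' @param effect_sizes named numeric vector of effect sizes.
#' @return list with `anchors`, counts, numeric percentages (`pct_unaligned`,
#'   `pct_intersection`) and their display strings.
#' @export
intersectUnalignedRegulated <- function(significant, unaligned, regulated,
                                        effect_sizes = NULL) {
  inter <- intersect(unaligned, regulated)
  if (!is.null(effect_sizes) && length(inter)) {
    es <- effect_sizes[inter]
    es[is.na(es)] <- -Inf
    inter <- inter[order(-es)]
  }
  list(
    anchors = inter,
    n_significant = length(significant),
    n_unaligned = length(unaligned),
    n_regulated = length(regulated),
    n_intersection = length(inter),
    pct_unaligned = percentOf(length(unaligned), length(significant)),
    pct_intersection = percentOf(length(inter), length(regulated)),
    pct_unaligned_str = formatPercent(length(unaligned), length(significant)),
    pct_intersection_str = formatPercent(length(inter), length(regulated))
  )
}

#' High-effect anchor triage filter
#'
#' Keeps anchors with at least `min_aligned` aligned concatenated sequences
#' among their top 10 targets and at least `min_reads` total reads, sorts by
#' decreasing effect size and truncates to the top `top_n`.
#'
#' @param stats data.frame with columns `anchor`, `effect_size`, `M` and
#'   `n_aligned_top10`.
#' @param min_aligned minimum aligned top-10 concatenated sequences.
#' @param min_reads minimum total reads M.
#' @param top_n output size cap.
#' @return the filtered, ranked data.frame.
#' @export
highEffectFilter <- function(stats, min_aligned = 7L, min_reads = 500L,
                             top_n = 500L) {
  stopifnot(all(c("anchor", "effect_size", "M", "n_aligned_top10") %in%
                  names(stats)))
  keep <- stats$n_aligned_top10 >= min_aligned & stats$M >= min_reads &
    !is.na(stats$effect_size)
  out <- stats[keep, , drop = FALSE]
  out <- out[order(-out$effect_size), , drop = FALSE]
  head(out, top_n)
}
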