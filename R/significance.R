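# Significance stage: per-anchor test for sample-dependent target composition.
#
# Counts are split into a train and a test half. On the train half an
# alternating maximization finds a sample embedding c in {-1,+1} and a target
# embedding f in {0,1} maximizing the linear statistic
#   S(c, f) = sum_j c_j ( sum_t f(t) X_jt - n_j * mu(f) ),  mu(f) = sum_t f(t) N_t / M.
# The embeddings are then frozen and evaluated on the held-out test half,
# where a Hoeffding bound on the self-centered statistic gives a closed-form,
# always-valid p-value (see anchorPValue for the exact form).

#' Significance test configuration
#'
#' Defaults follow the published run parameters: a 0.25 train fraction, 10
#' random restarts of the alternating maximization, 50 iterations each, BH
#' FDR threshold 0.05, and effect sizes emitted only for anchors with
#' p <= 0.10.
#'
#' @param train_fraction fraction of each count routed to the train half.
#' @param n_restarts random initializations of the target embedding.
#' @param max_iters maximum alternating-maximization iterations per restart.
#' @param fdr_threshold BH threshold declaring anchors significant.
#' @param max_pval_for_effect_size effect sizes are only computed when the
#'   anchor's p-value is at or below this.
#' @param seed master seed; per-anchor streams are derived from it and the
#'   anchor sequence, so results do not depend on processing order.
#' @return a validated list of class `test_config`.
#' @export
testConfig <- function(train_fraction = 0.25, n_restarts = 10L,
                       max_iters = 50L, fdr_threshold = 0.05,
                       max_pval_for_effect_size = 0.10, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_restarts >= 1,
            max_iters >= 1, fdr_threshold > 0, fdr_threshold <= 1)
  cfg <- list(train_fraction = train_fraction,
              n_restarts = as.integer(n_restarts),
              max_iters = as.integer(max_iters),
              fdr_threshold = fdr_threshold,
              max_pval_for_effect_size = max_pval_for_effect_size,
              seed = as.integer(seed))
  class(cfg) <- c("test_config", "list")
  cfg
}

#' Binomially split counts into train and test halves
#'
#' Each cell count is split as train ~ Binomial(count, train_fraction), with
#' test = count - train, so X + Y reproduces the input cell-wise. Uses the
#' current RNG state; callers seed beforehand.
#'
#' @param counts sample x target count matrix.
#' @param train_fraction probability a read is routed to the train half
#'   (boundary values 0 and 1 are allowed here for diagnostics).
#' @return list with matrices `X` (train) and `Y` (test).
#' @export
splitCounts <- function(counts, train_fraction = 0.25) {
  stopifnot(train_fraction >= 0, train_fraction <= 1)
  X <- matrix(rbinom(length(counts), as.integer(counts), train_fraction),
              nrow = nrow(counts), dimnames = dimnames(counts))
  list(X = X, Y = counts - X)
}

# trivial embeddings for degenerate inputs; S = 0 and the downstream p-value
# guard forces p = 1
.trivialEmbedding <- function(counts) {
  list(c = setNames(rep(1, nrow(counts)), rownames(counts)),
       f = setNames(rep(0, ncol(counts)), colnames(counts)),
       S = 0, mu = 0, degenerate = TRUE)
}

#' Alternating maximization of the train statistic
#'
#' Starting from a random target embedding f in `{0,1}^T`, alternates
#' c_j := sign(sum_t f(t) X_jt - n_j mu(f)) and
#' f(t) := 1 iff sum_j c_j (X_jt - n_j N_t / M) > 0, each step an exact
#' maximization of S given the other embedding, so |S| never decreases. The
#' best of `n_restarts` restarts is returned. Uses the current RNG state.
#'
#' @param X train count matrix (samples x targets).
#' @param config a [testConfig()].
#' @return list with `c` (named, -1/+1 per sample), `f` (named, 0/1 per
#'   target), `S` (final train statistic, >= 0), `mu` (f-weighted train mean)
#'   and `degenerate` flag.
#' @export
altMaximize <- function(X, config = testConfig()) {
  n <- rowSums(X)
  N <- colSums(X)
  M <- sum(X)
  if (sum(n > 0) < 2L || sum(N > 0) < 2L) return(.trivialEmbedding(X))
  Tn <- ncol(X)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    f <- as.numeric(runif(Tn) < 0.5)
    S_prev <- -Inf
    cvec <- rep(1, nrow(X))
    for (it in seq_len(config$max_iters)) {
      mu <- sum(f * N) / M
      resid <- as.numeric(X %*% f) - n * mu
      cvec <- ifelse(resid >= 0, 1, -1)
      g <- as.numeric(crossprod(X, cvec)) - (N / M) * sum(n * cvec)
      f_new <- as.numeric(g > 0)
      S_new <- sum(f_new * g)
      # both half-steps are exact maximizations, so S must not decrease
      stopifnot(S_new >= S_prev - 1e-9)
      if (identical(f_new, f) && S_new <= S_prev + 1e-12) {
        S_prev <- S_new
        break
      }
      f <- f_new
      S_prev <- S_new
    }
    mu <- sum(f * N) / M
    if (is.null(best) || S_prev > best$S) {
      best <- list(c = setNames(cvec, rownames(X)),
                   f = setNames(f, colnames(X)),
                   S = S_prev, mu = mu, degenerate = FALSE)
    }
  }
  best
}

#' Closed-form p-value bound on the test half
#'
#' Evaluates the self-centered test statistic
#' `S = sum_j c_j (sum_t f(t) Y_jt - m_j * vbar)` where `vbar` is the
#' f-weighted mean target value of the test half itself. Writing
#' `cbar = sum_j c_j m_j / sum_j m_j`, each test read contributes
#' `(c_j - cbar) f(t)`, a zero-mean sum of independent terms bounded in
#' intervals of length `|c_j - cbar|`, so Hoeffding's inequality gives the
#' always-valid two-sided bound
#' `p = min(1, 2 exp(-2 S^2 / sum_j m_j (c_j - cbar)^2))`.
#' Centering on the test half removes the error of the train-estimated mean,
#' which would otherwise inject a deterministic offset whenever the sample
#' embedding is unbalanced. Returns 1 when the test half is empty, when the
#' centered denominator vanishes, or when the embedding is pathologically
#' unbalanced (`|cbar| > 0.9`).
#'
#' @param Y test count matrix (samples x targets).
#' @param c_vec per-sample embedding in -1/+1 (from the train half).
#' @param f_vec per-target embedding in `[0,1]` (from the train half).
#' @return p-value in (0, 1].
#' @export
anchorPValue <- function(Y, c_vec, f_vec) {
  m <- rowSums(Y)
  M_test <- sum(m)
  if (M_test == 0) return(1)
  cbar <- sum(c_vec * m) / M_test
  if (abs(cbar) > 0.9) return(1)
  fw <- as.numeric(Y %*% f_vec)
  vbar <- sum(fw) / M_test
  S <- sum(c_vec * (fw - m * vbar))
  denom <- sum(m * (c_vec - cbar)^2)
  if (denom <= 0) return(1)
  min(1, 2 * exp(-2 * S^2 / denom))
}

#' Permutation p-value for the test statistic
#'
#' Independent oracle for [anchorPValue()]: test reads are pooled and randomly
#' reassigned to samples (preserving per-sample totals m_j), and the two-sided
#' permutation tail probability of the same centered statistic is returned.
#' The closed-form bound is conservative, so on fixtures where the
#' permutation p is estimable it should be at least this value.
#'
#' @param Y test count matrix.
#' @param c_vec,f_vec frozen embeddings, as in [anchorPValue()].
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return permutation p-value in `[1/(n_perm+1), 1]`.
#' @export
permutationPValue <- function(Y, c_vec, f_vec, n_perm = 10000L, seed = 1L) {
  set.seed(seed)
  m <- rowSums(Y)
  M_test <- sum(m)
  if (M_test == 0) return(1)
  # per-read centered coefficients and f-values
  vals <- numeric(0)
  coefs <- numeric(0)
  cbar <- sum(c_vec * m) / M_test
  for (j in seq_len(nrow(Y))) {
    cnt <- Y[j, ]
    vals <- c(vals, rep(f_vec, cnt))
    coefs <- c(coefs, rep(c_vec[j] - cbar, m[j]))
  }
  S_obs <- sum(coefs * vals)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    S_perm <- sum(coefs * vals[sample.int(length(vals))])
    if (abs(S_perm) >= abs(S_obs) - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Mean Hamming distance of targets to the top target
#'
#' Unweighted mean Hamming distance from each non-top target to the top
#' (most frequent) target; 0 when only one target is present.
#'
#' @param targets character vector of equal-length targets, top target first.
#' @return mean distance in bases.
#' @export
meanHammingToTop <- function(targets) {
  stopifnot(length(targets) >= 1L)
  if (length(targets) == 1L) return(0)
  top <- targets[1]
  mean(vapply(targets[-1], hammingDist, numeric(1), a = top))
}

#' Test one anchor table for sample-dependent target composition
#'
#' Composes the binomial train/test split, alternating maximization on the
#' train half, and the closed-form bound on the test half. The effect size
#' |w+ - w-| (the difference in f-weighted target usage between the two
#' sample groups induced by c, computed on the full table) is emitted only
#' when p <= `max_pval_for_effect_size`.
#'
#' @param table an [AnchorTable-class] (already filtered).
#' @param config a [testConfig()].
#' @param seed per-anchor seed; defaults to a hash of the anchor sequence and
#'   the master seed (see [anchorSeed()]).
#' @return list with `anchor`, `p_value`, `effect_size` (NA when not
#'   emitted), `c`, `f`, `mu_train`, `S_train`, `n_unique_targets`,
#'   `mean_hamming_to_top`, `M`, `m_j` (test totals).
#' @export
anchorTest <- function(table, config = testConfig(),
                       seed = anchorSeed(anchorSequence(table), config$seed)) {
  counts <- anchorCounts(table)
  set.seed(seed)
  halves <- splitCounts(counts, config$train_fraction)
  emb <- altMaximize(halves$X, config)
  p <- anchorPValue(halves$Y, emb$c, emb$f)
  effect <- NA_real_
  if (!emb$degenerate && p <= config$max_pval_for_effect_size) {
    n_full <- rowSums(counts)
    fw <- as.numeric(counts %*% emb$f)
    plus <- emb$c > 0
    if (any(plus) && any(!plus) &&
        sum(n_full[plus]) > 0 && sum(n_full[!plus]) > 0) {
      w_plus <- sum(fw[plus]) / sum(n_full[plus])
      w_minus <- sum(fw[!plus]) / sum(n_full[!plus])
      effect <- abs(w_plus - w_minus)
    }
  }
  list(anchor = anchorSequence(table),
       p_value = p,
       effect_size = effect,
       c = emb$c, f = emb$f, mu_train = emb$mu, S_train = emb$S,
       n_unique_targets = table@totalTargets,
       mean_hamming_to_top = meanHammingToTop(rankedTargets(table)),
       M = sum(counts),
       m_j = rowSums(halves$Y))
}

#' Benjamini-Hochberg adjustment across anchors
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param fdr_threshold significance threshold on q-values.
#' @return list with `q_values` and logical `significant`.
#' @export
bhAdjust <- function(p_values, fdr_threshold = 0.05) {
  if (!length(p_values)) {
    return(list(q_values = numeric(0), significant = logical(0)))
  }
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, significant = q <= fdr_threshold)
}

#' Test all anchors of a set (or list of tables)
#'
#' Runs [anchorTest()] per anchor with order-independent per-anchor seeds and
#' applies Benjamini-Hochberg correction across anchors.
#'
#' @param x an [AnchorTableSet-class] (already filtered) or a list of
#'   [AnchorTable-class] objects.
#' @param config a [testConfig()].
#' @return an [AnchorTestResults-class].
#' @export
setGeneric("testAnchors",
           function(x, config = testConfig()) standardGeneric("testAnchors"))

.testAnchorList <- function(tables, config) {
  res <- lapply(tables, anchorTest, config = config)
  p <- vapply(res, `[[`, numeric(1), "p_value")
  adj <- bhAdjust(p, config$fdr_threshold)
  df <- data.frame(
    anchor = vapply(res, `[[`, character(1), "anchor"),
    p_value = p,
    q_value = adj$q_values,
    effect_size = vapply(res, `[[`, numeric(1), "effect_size"),
    n_unique_targets = vapply(res, `[[`, numeric(1), "n_unique_targets"),
    mean_hamming_to_top = vapply(res, `[[`, numeric(1), "mean_hamming_to_top"),
    M = vapply(res, `[[`, numeric(1), "M"),
    significant = adj$significant,
    row.names = NULL, stringsAsFactors = FALSE
  )
  emb <- lapply(res, function(r) {
    r[c("c", "f", "mu_train", "S_train", "m_j")]
  })
  names(emb) <- df$anchor
  new("AnchorTestResults", results = df, embeddings = emb,
      config = unclass(config))
}

#' @rdname testAnchors
#' @export
setMethod("testAnchors", "AnchorTableSet", function(x, config) {
  anchors <- anchorNames(x)
  tables <- lapply(anchors, anchorTable, set = x)
  .testAnchorList(tables, config)
})

#' @rdname testAnchors
#' @export
setMethod("testAnchors", "list", function(x, config) {
  stopifnot(all(vapply(x, is, logical(1), "AnchorTable")))
  .testAnchorList(x, config)
})
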