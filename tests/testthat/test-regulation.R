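# regulation: penalized multinomial GLM, ANOVA/Tukey, compact letter display,
# intersections and triage filters

twoGroupCounts <- function(seed, n = 20, depth = 300, p = c(0.9, 0.1)) {
  set.seed(seed)
  labels <- rep(c("A", "B"), each = n / 2)
  c1 <- rbinom(n, depth, p[as.integer(factor(labels))])
  counts <- cbind(t1 = c1, t2 = depth - c1)
  rownames(counts) <- paste0("s", seq_len(n))
  list(counts = counts, labels = setNames(labels, rownames(counts)))
}

test_that("separating counts are called regulated; permuted labels are not", {
  fx <- twoGroupCounts(1)
  r <- glmMetadataDependence(fx$counts, fx$labels, seed = 1)
  expect_true(r$evaluable)
  expect_true(r$regulated)
  expect_gt(r$max_abs_coefficient, 1)

  set.seed(2)
  rp <- glmMetadataDependence(fx$counts, setNames(sample(fx$labels),
                                                  names(fx$labels)), seed = 1)
  expect_true(rp$evaluable)
  expect_false(rp$regulated)
})

test_that("constant composition and tiny designs are handled", {
  counts <- matrix(50, 10, 2,
                   dimnames = list(paste0("s", 1:10), c("t1", "t2")))
  labels <- setNames(rep(c("A", "B"), each = 5), rownames(counts))
  r <- glmMetadataDependence(counts, labels, seed = 1)
  expect_true(r$evaluable)
  expect_false(r$regulated)

  # fewer than 4 usable samples -> not evaluable (not reported as false)
  small <- counts[1:3, ]
  rs <- glmMetadataDependence(small, labels[1:3], seed = 1)
  expect_false(rs$evaluable)
  expect_true(is.na(rs$regulated))

  # ND samples are excluded before the n >= 4 rule
  nd <- counts
  nd[5:10, ] <- 0
  rn <- glmMetadataDependence(nd, labels, seed = 1)
  expect_false(rn$evaluable)
})

test_that("anovaTukey separates well-separated groups and agrees with a permutation oracle", {
  set.seed(33)
  # 5 per group so a two-sample permutation test can resolve p < 0.05
  vals <- c(rnorm(5, 0.9, 0.005), rnorm(5, 0.1, 0.005), rnorm(5, 0.5, 0.005))
  labels <- rep(c("g1", "g2", "g3"), each = 5)
  names(vals) <- names(labels) <- paste0("s", 1:15)
  rep_ <- anovaTukey(vals, labels)
  expect_true(all(rep_$pairwise$significant))
  expect_lt(rep_$p, 1e-6)
  expect_setequal(unname(rep_$letters), c("a", "b", "c"))

  # permutation oracle per pair: group-label shuffles of the mean difference
  for (r in seq_len(nrow(rep_$pairwise))) {
    g1 <- rep_$pairwise$group1[r]; g2 <- rep_$pairwise$group2[r]
    x <- vals[labels == g1]; y <- vals[labels == g2]
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    set.seed(r)
    perm <- replicate(5000, {
      idx <- sample(10, 5)
      abs(mean(pool[idx]) - mean(pool[-idx]))
    })
    p_perm <- (1 + sum(perm >= obs - 1e-12)) / 5001
    expect_lt(p_perm, 0.05)  # oracle agrees the pair differs
  }
})

test_that("identical group values give F = 0, p = 1 and one shared letter", {
  vals <- rep(0.5, 6)
  labels <- rep(c("A", "B"), each = 3)
  names(vals) <- names(labels) <- paste0("s", 1:6)
  rep_ <- anovaTukey(vals, labels)
  expect_equal(rep_$F, 0)
  expect_equal(rep_$p, 1)
  expect_false(any(rep_$pairwise$significant))
  expect_equal(unname(rep_$letters), c("a", "a"))
})

test_that("Tukey-adjusted p is at least the pooled pairwise p", {
  set.seed(44)
  for (i in 1:10) {
    vals <- rnorm(12, sd = 0.2) + rep(runif(4), each = 3)
    labels <- rep(paste0("g", 1:4), each = 3)
    names(vals) <- names(labels) <- paste0("s", 1:12)
    rep_ <- anovaTukey(vals, labels)
    # unadjusted pooled-variance pairwise p-values
    fit <- aov(vals ~ factor(labels))
    mse <- summary(fit)[[1]][["Mean Sq"]][2]
    df <- summary(fit)[[1]][["Df"]][2]
    for (r in seq_len(nrow(rep_$pairwise))) {
      m1 <- mean(vals[labels == rep_$pairwise$group1[r]])
      m2 <- mean(vals[labels == rep_$pairwise$group2[r]])
      tstat <- abs(m1 - m2) / sqrt(mse * (2 / 3))
      p_unadj <- 2 * pt(tstat, df, lower.tail = FALSE)
      expect_gte(rep_$pairwise$p_adj[r] + 1e-12, p_unadj)
    }
  }
})

test_that("groups that are entirely ND are dropped with a warning", {
  vals <- c(0.2, 0.3, NA, NA, 0.8, 0.9)
  labels <- rep(c("A", "B", "C"), each = 2)
  names(vals) <- names(labels) <- paste0("s", 1:6)
  expect_warning(rep_ <- anovaTukey(vals, labels), "dropped")
  expect_setequal(names(rep_$letters), c("A", "C"))
  expect_error(suppressWarnings(anovaTukey(vals[1:4], labels[1:4])),
               "2 usable groups")
})

test_that("compact letter display handles the canonical examples", {
  sig <- matrix(FALSE, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  sig["A", "B"] <- sig["B", "A"] <- TRUE
  sig["A", "C"] <- sig["C", "A"] <- TRUE
  cld <- compactLetterDisplay(sig)
  expect_equal(unname(cld), c("a", "b", "b"))

  none <- matrix(FALSE, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_equal(unname(compactLetterDisplay(none)), rep("a", 4))

  all_sig <- !none
  diag(all_sig) <- FALSE
  expect_equal(unname(compactLetterDisplay(all_sig)), letters[1:4])
})

test_that("CLD invariants and minimality hold on random decision matrices", {
  set.seed(55)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    sig <- matrix(FALSE, k, k)
    pairs <- which(upper.tri(sig), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.4
    for (r in seq_len(nrow(pairs))) {
      sig[pairs[r, 1], pairs[r, 2]] <- on[r]
      sig[pairs[r, 2], pairs[r, 1]] <- on[r]
    }
    dimnames(sig) <- list(paste0("g", 1:k), paste0("g", 1:k))
    cld <- compactLetterDisplay(sig)
    expect_true(cldInvariantsHold(unname(cld), sig))
    if (k <= 5) {
      n_letters <- length(unique(unlist(strsplit(paste(cld, collapse = ""),
                                                 ""))))
      expect_equal(n_letters, cldMinimalLetters(sig))
    }
  }
})

test_that("intersection report reproduces the printed count ratios", {
  r <- intersectUnalignedRegulated(
    significant = paste0("a", 1:544476)[1:100],  # counts matter, not names
    unaligned = character(0), regulated = character(0)
  )
  expect_equal(r$pct_unaligned, 0)

  # printed sorghum ratios: 11,501 of 544,476 and 408 of 10,567
  expect_equal(percentOf(11501, 544476), 2.11)
  expect_equal(percentOf(408, 10567), 3.86)
  expect_equal(formatPercent(408, 10567), "3.86")

  u <- paste0("u", 1:20)
  reg <- c(u[1:5], paste0("r", 1:15))
  es <- setNames(seq_along(u) / 20, u)
  out <- intersectUnalignedRegulated(paste0("s", 1:100), u, reg, es)
  expect_equal(out$anchors, u[5:1])  # sorted by decreasing effect size
  expect_equal(out$n_intersection, 5L)
  expect_equal(out$pct_intersection, percentOf(5, 20))
})

test_that("high-effect filter applies alignment, depth and rank rules", {
  stats <- data.frame(
    anchor = paste0("a", 1:4),
    effect_size = c(0.9, 0.8, 0.7, 0.6),
    M = c(1000, 499, 1000, 1000),
    n_aligned_top10 = c(6, 10, 7, 10)
  )
  out <- highEffectFilter(stats)
  expect_equal(out$anchor, c("a3", "a4"))  # a1: 6/10 aligned, a2: M=499

  set.seed(66)
  many <- data.frame(
    anchor = paste0("x", 1:600),
    effect_size = runif(600),
    M = 1000,
    n_aligned_top10 = 10
  )
  top <- highEffectFilter(many, top_n = 500)
  expect_equal(nrow(top), 500L)
  expect_true(all(diff(top$effect_size) <= 0))
})
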