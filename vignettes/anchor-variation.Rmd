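---
title: "Detecting sample-dependent transcript variation without a reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sample-dependent transcript variation without a reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorvar)
```

## The model

`anchorvar` looks for positions in a transcriptome where the sequence
*following* a constant context differs between samples. Reads are tiled into
pairs of adjacent k-mers: a 27-nt **anchor** and the 27-nt **target**
immediately after it (no gap; the pair span of 54 nt is also the tiling step,
so pairs from one read are disjoint and approximately independent — the
assumption behind the significance bound). Everything downstream operates on
the per-anchor contingency table of samples × targets.

The null hypothesis for one anchor is that every sample draws its targets
from the same multinomial composition. The alternative is deliberately
unstructured: *any* sample-dependent composition counts, which is what lets
one test discover allelic variation, splicing changes, homolog switches and
foreign organisms at once.

### Train/test split and alternating maximization

Testing a composition difference with embeddings chosen on the same data
would invalidate any closed-form p-value. The counts of each cell are
therefore split binomially: a fraction `train_fraction = 0.25` of reads forms
the train half `X`, the rest the test half `Y`. On `X`, we choose a sample
embedding `c ∈ {−1, +1}` per sample and a target embedding `f ∈ {0, 1}` per
target to maximize

$$ S(c, f) = \sum_j c_j \Big( \sum_t f(t) X_{jt} - n_j \hat\mu(f) \Big),
   \qquad \hat\mu(f) = \frac{\sum_t f(t) N_t}{M}. $$

Both conditional updates are exact maximizations — `c_j` is the sign of the
sample's residual, and `f(t)` switches on exactly the targets with positive
aggregate signed residual — so the statistic is non-decreasing over
iterations (asserted in the loop) and converges in a handful of steps.
`n_restarts = 10` random initializations of `f` guard against local optima;
`max_iters = 50` caps the alternation.

### The closed-form bound

On the held-out half, with `(c, f)` frozen, the package evaluates the
self-centered statistic

$$ S_{\text{test}} = \sum_j c_j \Big( \sum_t f(t) Y_{jt} - m_j \bar v \Big), $$

where `m_j` are test totals and $\bar v$ is the f-weighted mean target value
of the test half itself. Each read contributes $(c_j - \bar c) f(t)$ with
$\bar c = \sum_j c_j m_j / \sum_j m_j$, a zero-mean independent term bounded
in an interval of length $|c_j - \bar c|$, so Hoeffding's inequality yields

$$ p = \min\Big(1,\; 2 \exp\big(-2 S_{\text{test}}^2 \big/ \textstyle\sum_j
   m_j (c_j - \bar c)^2\big)\Big), $$

valid for every sample size and every data-dependent train-half choice of the
embeddings. Two numerical choices deserve comment:

* **Self-centering.** An earlier formulation centered the test statistic with
  the train-estimated mean $\hat\mu$. When the sample embedding is
  unbalanced, the estimation error of $\hat\mu$ enters the statistic as a
  deterministic offset that the bound does not account for; on small tables
  this produced p-values below a permutation oracle. Centering on the test
  half removes the offset exactly, and the denominator
  $\sum_j m_j (c_j - \bar c)^2$ is the correct squared-range sum for the
  centered coefficients. Validity is the contract here: the package keeps
  whichever form is provably conservative.
* **Unbalance guard.** If $|\bar c| > 0.9$ the p-value is set to 1 outright.
  With self-centering this is belt-and-braces (the denominator already
  shrinks to zero as $|\bar c| \to 1$), but it documents that a nearly
  one-sided embedding carries no usable contrast.

Degenerate train halves (fewer than two non-empty samples or targets) return
trivial embeddings with `S = 0`, which the guard maps to `p = 1`.

p-values are corrected across anchors by Benjamini–Hochberg
(`fdr_threshold = 0.05`). One p-value is produced per anchor — the restarts
select a single `(c, f)` before the test half is touched, so no additional
multiplicity correction is needed. Per-anchor random streams are seeded by
hashing the anchor sequence with the master seed, making results independent
of processing order.

### Effect size

For anchors with `p ≤ max_pval_for_effect_size = 0.10`, the effect size is
$|w_+ - w_-|$: the difference between the f-weighted mean target usage of the
`c = +1` and `c = −1` samples, computed on the full (unsplit) table. It lives
in `[0, 1]`, equals 1 exactly when the two sample groups use disjoint target
sets, and ≈ |p₁ − p₂| when groups mix two targets with proportions p₁ and p₂.

## Filters and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `anchor_len`, `target_len`, `gap_len` | 27, 27, 0 nt | pair geometry |
| `poly_ACGT_len` | 8 nt | discard anchors/targets containing a homopolymer run this long |
| `anchor_count_threshold` | 50 reads | minimum total count M per anchor |
| `anchor_samples_threshold` | 1 sample | samples that must reach the per-sample count |
| `anchor_sample_counts_threshold` | 5 reads | per-sample count defining an observed sample |
| `anchor_unique_targets_threshold` | 1 | anchors need strictly more distinct targets than this |
| `n_most_freq_targets` | 10 | targets retained per anchor (ties broken lexicographically) |
| `train_fraction` | 0.25 | train share of the binomial split |
| `n_restarts`, `max_iters` | 10, 50 | alternating-maximization schedule |
| `fdr_threshold` | 0.05 | BH threshold |
| `min_intron`, `max_intron` | 21, 1e6 nt | allowed spliced-placement gap |
| `hamming_threshold` | 5 | allelic-vs-homolog target distance cutoff |

Reads are processed as-is (no reverse-complement canonicalization), matching
stranded transcript discovery; N-containing pairs are skipped; the
homopolymer filter applies to anchor and target independently.

## Annotation and classification

Significant anchors are interpreted by placing the 54-nt anchor+target
concatenations of their top targets on a reference. The built-in matcher is
exact: a contiguous exact occurrence wins; otherwise the best two-block exact
split is sought — prefix at one locus, suffix downstream within
`[min_intron, max_intron]` — maximizing the prefix length, with ties broken
by a GT..AG intron motif, then by smaller gap. Both strands are searched. A
quick rejection uses the fact that any valid split leaves one block of at
least 27 nt, which must contain the query's first or last 20-mer. Exact
matching is the right dialect for error-free synthetic validation; for real
reads the SAM import path (`readSamAlignments()`) accepts placements from an
external spliced aligner instead, so the classification logic is shared
between both routes.

The category cascade over the top-2 targets' placements is total:

1. both unaligned → `both_unaligned`;
2. exactly one unaligned → `unaligned_target` (foreign sequence, absent
   haplotype, or missing annotation);
3. both contiguous: same gene and target Hamming distance ≤ 5 →
   `allelic_or_snv`; otherwise `homolog_pair` (a 27-nt window separates
   SNP-level divergence from paralogs cleanly; the cutoff is configurable);
4. one spliced, one contiguous reading into the spliced-out interval →
   `intron_retention`;
5. otherwise splice variation: `cryptic_splice` if any junction is missing
   from the annotation (donor/acceptor compared exactly against introns
   implied by consecutive exons of a gene), else
   `annotated_splice_variation`.

Gene assignment intersects blocks with exon intervals (half-open BED
semantics; all equal-best placements are reported and multiplicity is
flagged).

## Metadata dependence

Two complementary calls, both excluding ND samples (no reads for the anchor):

* **Penalized regression.** `glmnet` fits an L1-penalized multinomial model
  predicting the sample's combined metadata label from the counts of the top
  two targets; the penalty is chosen by K-fold cross-validated deviance
  (K = min(10, n), seeded folds). An anchor is *regulated* iff the largest
  absolute non-intercept coefficient exceeds 1. Raw counts are standardized
  to unit variance by default so the fixed threshold is scale-free — with
  raw counts the same rule would depend on sequencing depth; the
  unstandardized variant remains available behind a flag. Anchors observed
  in fewer than 4 samples are reported as not evaluable rather than as
  negative.
* **Pairwise tests.** One-way ANOVA on the top-target fraction with Tukey HSD
  pairwise p-values, summarized as a compact letter display: letters are a
  minimum-size set of cliques of the non-significance graph covering all its
  vertices and edges, found by exhaustive search over maximal cliques (exact
  for the ≤ 8 groups that occur in practice). Groups share a letter iff they
  are not significantly different. Zero-variance fixtures are answered
  F = 0, p = 1 (and exact separation with zero residual variance by p = 0)
  rather than NaN.

Run summaries report the unaligned and regulated counts and their
percentages. Percentages are rounded to two decimals with trailing zeros
dropped below 1% — the convention that reproduces the published style of
count-ratio reporting.

## What the synthetic data emulate — and what they do not

The generator (`simConfig()`, `buildReference()`, `simulateDataset()`) builds
a single-chromosome genome of planted loci: two-haplotype gene copies sharing
one gene id (allelic events, 1–3 substitutions inside the target window),
homolog pairs sharing an exact 27-nt prefix, two-exon genes with 30-nt
GT..AG introns (intron retention), 40-nt introns with a cryptic GT donor 13
bases in (cryptic splicing), and host genes whose second isoform diverges
into a foreign sequence sharing no 27-mer with the genome (contaminants,
present in a 70% subset of carrier samples with group-skewed abundance).
Null genes have a single isoform and no group dependence. Constraints that
keep the planted junctions unambiguous for an exact matcher (first divergent
base directly after a 27-nt shared region, acceptor seeds unique in the
genome, splice sites with canonical motifs) are verified after assembly and
violating events are regenerated deterministically.

The default design — two groups of ten samples, isoform-1 proportions
0.9/0.1, 300 expected reads per sample per event, error-free 54-nt reads —
is the validation condition under which the suite demands ≥ 90% recovery and
exact classification. Simulated event transcripts are the 54-nt
discriminating fragments themselves, so a planted anchor receives the full
per-sample expression; the complete loci live in the genome and are exercised
by the annotation stage, and the 108-nt null genes exercise uniform read
starts and the abundance filters. Reads are single-end with constant quality
(qualities are never used), substitution errors only (no indels — this keeps
the exact-alignment oracle exact), no PCR duplicates, no coverage biases, and
no 3'/5' positional effects. Passing these tests therefore demonstrates the
statistical and combinatorial machinery, not robustness to real library
artifacts; on real data the abundance filters and the artifact screen carry
that load, and alignment should come from a spliced aligner via SAM import.

## Problem sizes used by the validation suite

The suite fixes: 5 × 1,000 null anchors (20 samples, 5 targets, depths
50–500) for false-positive control; 100 planted events (20 per class) for
recovery and classification; 50 two-group fixtures (6 samples, depths 5–9,
compositions 0.65/0.20/0.15 vs 0.35/0.45/0.20) against a 10,000-shuffle
permutation oracle — a regime chosen so the closed-form p-value stays well
above the oracle's Monte-Carlo floor of 1/10,001, where the dominance
comparison is informative; all 1,024 five-group decision matrices for the
letter display; and 40 planted/permuted fixtures for the regulation call.

## Known limitations

* The built-in matcher is exact-match only; real-data sensitivity to
  sequencing errors and small indels requires the SAM import path.
* Chimeric (two-chromosome) placements are not searched; multi-junction SAM
  records keep all blocks but only the first junction is classified.
* The `> 1` coefficient rule is scale-free only under the default
  standardization; with `standardize = FALSE` it inherits the counts' scale.
* Significance assumes disjoint read tiles; overlapping tiles
  (`tiling_step < 54`) are supported for sensitivity studies but correlate
  pairs and make the bound only approximately valid.
* The two-sided bound pays a factor 2 and Hoeffding slack; at very low
  depths the test is conservative rather than powerful.
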