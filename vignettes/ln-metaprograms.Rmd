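---
title: "Leukocyte meta-programs and predictive panels: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leukocyte meta-programs and predictive panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

lnmeta implements an analysis chain for lupus nephritis (LN)
transcriptomics: discovery of shared leukocyte transcriptional
*meta-programs* from single-cell expression by consensus non-negative
matrix factorization (cNMF), a dual-ranking algorithm that partitions genes
into nonoverlapping per-factor modules, a feature-selector × classifier
combination framework scored by the concordance index (C-index) across
case/control cohorts, and downstream clinical-association stages
(case/control tests, glomerular filtration rate correlation,
pathological-stage comparisons, hypergeometric over-representation).
Because the real kidney single-cell data and the four GEO bulk cohorts
require downloads and harmonization that are out of scope here, every stage
is driven and validated by a synthetic-data generator with known ground
truth; the `analysis/` scripts run the whole chain on that substrate.

# The generative model

## Single-cell counts

`generate_sc_dataset()` draws a genes × cells matrix of negative-binomial
counts whose per-cell mean is

```
mu(g, c) = libsize(c) * softmax_g( log b_g
                                   + eff * 1[g is a marker of type(c)]
                                   + (usage %*% spectra)(c, g) )
```

with `eff = effect_log2fc * log 2`. Design choices that matter:

* **Gene baselines** `b_g` are log-normal with log-SD 0.5. The planted
  activity programs — not per-gene expression scale — must carry the
  dominant variance structure, otherwise the number of planted programs is
  not what a rank-selection diagnostic can identify. Real scRNA-seq
  baselines span more orders of magnitude; the HVG + variance-scaling step
  that precedes factorization is what makes the two regimes comparable.
* **Library sizes** are log-normal with log-SD 0.1. A narrow depth spread
  keeps count marginals near the pure NB model (variance/mean → 1 in the
  large-dispersion limit, which the tests verify within 10% at 5,000
  cells) and prevents sequencing depth from forming a spurious extra NMF
  component.
* **Program activity is binary-gated**: a cell either carries a
  Gamma(2, 0.5)-distributed usage of a program or exactly 0, giving the
  factorization a recoverable block structure. Each program is active in
  `program_activity_fraction` of cells (default 0.3). Every cell expresses
  at least one program: a leukocyte is always in some transcriptional
  state, and full coverage keeps the planted K equal to the effective NMF
  rank — with a sizeable pure-background population the factorization
  must spend one component on background expression and one planted
  program becomes unrecoverable at k = K.
* **Marker and program gene blocks are pairwise disjoint**, assigned from
  the front of the gene vector; the constructor rejects parameter
  combinations whose blocks exceed the gene universe.

What the generator does *not* emulate: doublets, ambient RNA,
zero-inflation beyond NB, batch structure across donors, or realistic
platform mixtures. Passing recovery tests therefore show the algorithms
are correct and calibrated on their intended data-generating model, not
that any particular real dataset has recoverable programs.

## Bulk cohorts

`generate_bulk_cohorts()` produces samples × genes matrices on a
continuous log-like scale (the real cohorts are array/RNA-seq mixtures and
all downstream stages consume normalized values):

```
x(s, g) = baseline_g + batch(cohort, g) + delta * score(s) * 1[g in signal] + noise
```

Each sample carries a latent disease score `score = label + N(0, 0.5)`,
so the case-minus-control expectation of a signal gene is exactly `delta`
(default 1.5 noise-SDs). Coupling expression to the *score* rather than
the binary label is deliberate: the ordinal pathological class
(II/III/IV, cases only, proportional-odds on the score with thresholds
0.75 and 2.0) and the GFR
(`100 − 20 · gfr_beta · score + N(0, 8)` mL/min/1.73 m², i.e. healthy
controls near 100 and cases declining with severity) must both be
reachable from expression for the stage-comparison and GFR-correlation
stages to have planted effects to find. Per-cohort batch offsets are
N(0, 0.5) per gene; cohorts are balanced by construction.

# Consensus NMF and the component number

`fit_nmf()` minimizes the Frobenius loss by the classic multiplicative
updates from uniform random initialization; the per-iteration loss trace
is retained and is non-increasing (the update guarantee, asserted on every
test input). `consensus_factorize()` repeats the fit `n_runs` times,
pools all spectra as unit vectors, discards components whose mean distance
to their `floor(n_runs/3)` nearest neighbors exceeds `density_threshold`
(default 0.5, the common consensus choice), clusters survivors by seeded
k-means, takes component-wise medians as consensus spectra, and refits
usages by nonnegative least squares. The "100 iterations" convention of
the consensus approach is read as replicate factorizations, not
multiplicative-update steps; update count is a separate `max_iter`
(default 500 for single fits, 150–200 in the consensus experiments where
`tol = 1e-4` stops runs early).

`k_selection_diagnostics()` scans k over a range (the pipeline uses 4–9)
and records the mean silhouette of the component clustering (cosine
distance) and the relative reconstruction error; the k maximizing
stability is suggested, but the choice stays with the caller.

The factorization input follows consensus practice: library-size log
normalization, selection of highly variable genes by binned standardized
dispersion, then per-gene variance scaling (`prepare_matrix`,
`variance_scale = TRUE`). Variance scaling on the *full* gene space would
down-weight exactly the gated program genes (they have the highest
variance), so scaling is always applied after HVG restriction.

Problem sizes in the recovery experiments are the package's own choices
sized for a single CPU: spectra recovery runs at 2,000 cells × 1,000
genes with 30 replicate runs and k = 4; the ten-master-seed k-selection
experiment runs a proportional scale-down (1,000 cells × 500 genes, 30
genes per program, 150 HVGs, 10 runs per k). Planted-versus-recovered
matching uses greedy maximum Pearson correlation (a brute-force optimal
matcher backs the small-k tests).

# Nonoverlapping gene modules

`rank_contributions()` builds the two rank matrices: genes ranked within
each factor by contribution, and factors ranked within each gene. Ties
break by gene symbol (within factor) and factor index (within gene), so
both matrices are exact permutations and the procedure is deterministic.
`assign_disjoint_modules()` traverses each factor's genes in within-factor
rank order and collects a gene only while this factor is the gene's rank-1
factor. The natural-language rule "until a gene's contribution to another
factor becomes more significant" is ambiguous about what happens after the
first such gene, so both readings are implemented: `mode = "stop"` (the
default, literal "until") ends the module there; `mode = "skip"` passes
over non-assignable genes and keeps collecting. Because a gene's rank-1
factor is unique, modules are pairwise disjoint in both modes and each
stop-mode module is a prefix of its skip-mode counterpart — both
properties are exercised on a thousand random spectra.

Meta-programs are formed by Pearson-correlating program spectra over their
shared gene universe and cutting an average-linkage tree on `1 − r` into a
caller-fixed number of groups (the pipeline uses 4; no automatic
cut-height selection is attempted). Labels MP1..MPn are ordered by group
size, then mean internal correlation.

# The selector × classifier framework

The registry mirrors the study's twelve algorithm families: LASSO, Ridge
and elastic-net logistic regression (glmnet; penalty strength by internal
5-fold cross-validation with seed-fixed folds — the only hyperparameter
searched), stepwise logistic selection in three directions (AIC),
componentwise linear L2 boosting (the glmBoost family, implemented
in-package; 100 steps of shrinkage 0.1 as a classifier, early-stopped at
30 steps in the selector role where the stopping point *is* the selection
mechanism), linear discriminant analysis, partial-least-squares logistic
regression (two PLS components feeding a logit), a probability random
forest (the classification analogue of the random survival forest, since
the outcome is binary disease status), stochastic gradient-boosted trees
with classic GBM settings (shrinkage 0.05, depth 3, 80% subsampling) and
XGBoost defaults on the xgboost engine, a radial-kernel SVM with Platt
probabilities, and Gaussian naive Bayes. Selector-capable entries are the
sparse penalties, the stepwise searches, boosting, and forest importance
(features above mean impurity importance).

`harmonize_cohorts()` restricts cohorts to their shared genes and z-scores
each gene within each cohort; selectors and classifiers are always fit on
the pooled, per-cohort-standardized training cohorts. Feature panels are
the intersections of each meta-program's top genes with each curated-style
gene set; the pipeline crosses *every* meta-program with every set and
lets validation scoring rank the combinations, so the disease-relevant
panel is discovered rather than assumed. An empty selection falls back to
the full panel with a warning; a classifier failure on a degenerate panel
(e.g. a one-gene spurious intersection) is recorded in the result and the
sweep continues. The C-index (= AUROC for binary labels, computed by the
rank-sum identity and checked exactly against pair enumeration) is
reported per cohort, averaged over all cohorts, and averaged over
validation cohorts; the leaderboard sorts by the validation mean and
optionally applies an explicit C-index floor, reporting how many rows it
dropped — making suboptimal-model exclusion reproducible bookkeeping
rather than an implicit step.

Null calibration uses the same penalized-linear + naive-Bayes combination
as the power experiment, averaged over 20 seeds of the no-signal
generator: ranking null models by validation C-index and then reading the
top model's score would be biased upward by selection and test nothing.

# Association stages

The two-group default is the rank-sum test (the source figures star group
differences without naming a test); Welch's t is available by flag.
Benjamini–Hochberg is applied within each reported family, and the
working threshold is P < 0.05 throughout. GFR correlation defaults to
Spearman, robust to the skewed clinical distributions the generator
emulates. Stage comparisons run pairwise rank-sum tests plus a
Jonckheere-style trend statistic (Kendall correlation of expression with
the ordinal stage rank). Over-representation is an upper-tail
hypergeometric test against an explicit gene universe — a generic,
database-free replacement for external enrichment services — verified
against exhaustive subset enumeration on small universes, including the
closed-form C(5,3)/C(10,3) case.

# Numerical and degenerate-input conventions

* All randomness flows from one master seed through `derive_seed()`
  sub-streams, so partial regeneration is stable and identical
  config + seed reproduce identical output tables byte-for-byte.
* Zero-variance genes: dropped with a warning before variance scaling and
  harmonization; a constant gene in a case/control test returns p = 1 and
  direction "none"; a zero-variance spectrum correlates 0 by convention.
* `qc_filter` iterates cell and gene filters to a fixed point so both
  bounds hold simultaneously on the returned matrix (hence idempotence).
* HVG selection on fully degenerate input falls back to gene-symbol order
  rather than erroring.
* MatrixMarket files keep their native 1-based convention; internal labels
  are 0-based (cluster ids); gene identifiers are case-sensitive symbols
  with no mapping layer.

# Known limitations

* The synthetic substrate is far simpler than the kidney biopsy data that
  motivated the chain; none of the headline real-data quantities (22
  leukocyte subtypes, the specific MP1 gene content, validation AUCs near
  0.93/0.90) are reproducible here, and the package does not attempt them.
* Graph clustering delegates to Louvain modularity; community counts at a
  given resolution depend on graph density, so cluster-number assertions
  are made only on well-separated synthetic geometries.
* The stepwise selectors refit from scratch in the selector role; on
  panels wider than the sample count they inherit the usual instability of
  stepwise logistic regression.
* t-SNE layouts are visualization-only; nothing downstream consumes the
  coordinates.
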