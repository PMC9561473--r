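---
title: "Cluster-free marker identification: model, parameters, and design notes"
author: "freemarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-free marker identification: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freemarkers)
```

## The model

`freemarkers` defines a marker feature without reference to clusters: a
feature (gene, accessible region, spatially measured transcript) is a
marker if it is preferentially detected, or preferentially absent, in a
set of mutually similar cells. Both halves of that definition are made
operational through a *similarity neighbourhood* anchored at a reference
cell.

Let $e_i \in \mathbb{R}^d$ be cell $i$'s coordinates in a low-dimensional
embedding (multidimensional UMAP components, principal components, or 2D
spatial coordinates). The similarity of every cell to a reference cell $c$
is the RBF kernel

$$ y_c[i] = \exp\left(-\gamma\, \lVert e_i - e_c \rVert^2\right), $$

a smooth, soft neighbourhood indicator: $1$ at the reference itself,
decaying with squared Euclidean distance at a rate set by $\gamma$.
Cosine similarity is available as an alternative metric for workflows
that prefer it, with zero-norm rows mapped to similarity 0 (with a
warning) so downstream regression stays defined.

The enrichment of feature $f$ in reference cell $c$ is the
ordinary-least-squares slope of the intercept model

$$ y_c = \alpha + \beta\, x_f + \varepsilon, \qquad
   \hat\beta_{c,f} = \frac{\operatorname{cov}(x_f, y_c)}
                          {\operatorname{var}(x_f)}. $$

The **intercept is a deliberate choice**. With nonnegative expression and
nonnegative similarity, a through-the-origin slope could never be
negative; the centered slope is what lets features that are selectively
*undetected* near $c$ receive negative scores, which is half of the
marker definition. Zero-variance features (e.g. genes detected nowhere)
score exactly 0 rather than NaN — they are uninformative, not missing.
Population ($1/n$) moments are used throughout; the $1/(n-1)$ variant
gives the identical ratio. Scores are computed on whatever values are
supplied (log-normalized expression, tf-idf weights, binarized
accessibility): the package applies no hidden normalization, and the
score scale therefore inherits the data scale (the slope divides by the
feature's variance, so features should be on comparable scales before
their scores are compared against a common null — in practice, log-scale
expression).

### Significance

Shuffling every feature vector independently across cells destroys the
feature–embedding association while preserving each feature's marginal
distribution. Scoring the shuffled features against every reference cell
yields a per-reference-cell empirical null; calls are made in SD units,
$n_{sd} = (\hat\beta - \mu_{null}) / \sigma_{null}$. One permutation round
is the default (each feature contributes one shuffled copy, so the null
already holds one score per feature); `n_rounds` can be raised for small
feature sets, and a warning is emitted when the null holds fewer than 30
scores per reference cell.

p-values default to the Gaussian tail of $n_{sd}$. The empirical rank
within the null is available (`p_method = "empirical"`) but saturates at
$1/(F \cdot \text{rounds} + 1)$, which is useless at the 8–20 SD
thresholds this method operates at; the Gaussian approximation extends
smoothly into that regime and is the documented default. Bonferroni is
applied over all $F \times R$ tests; Benjamini–Hochberg is applied within
each reference cell, treating each reference cell's marker list as its
own discovery family. Both choices are conventions, stated here because
reasonable alternatives exist.

Discovery mode is two-sided by default (presence *and* absence markers);
annotation mode is one-sided ($n_{sd} \ge$ cutoff, positive enrichment
only), matching how a marker panel is used to label cells. The global
feature ranking uses the two-sample Kolmogorov–Smirnov statistic between
a feature's $R$ observed scores and the *pooled* null (all shuffled
features $\times$ all reference cells). Comparing against each shuffled
feature separately would be a defensible variant; pooling is implemented
because it gives the KS test a stable, large reference sample even for
small $R$.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | none (0.8 suits multidimensional UMAP; 0.001-ish suits raw 2D spatial coordinates) | inverse neighbourhood size of the RBF kernel; unitless, tied to the embedding's coordinate scale |
| `n` | user choice (benchmark harness: 0.5% of cells, floor 5) | number of reference cells |
| `k` | $\max(0, \lfloor N/n \rfloor - 1)$ | neighbours excluded per selection step |
| `sd_cutoff` | 5 (discovery), 8 (annotation) | SD-unit significance threshold |
| `n_rounds` | 1 | permutation rounds behind the null |
| `min_dist_frac` | 0.2 | grid selection: minimum pairwise distance as a fraction of the grid-cell diagonal |

`gamma` deliberately has **no universal default**: $\exp(-\gamma d^2)$
only means something relative to the scale of $d$. Too small and every
cell is "near", washing out local markers; too large and only the
reference cell itself has nonzero similarity. Where no conventional value
exists (e.g. the PCA embeddings the simulator produces), `suggest_gamma()`
applies the median heuristic, $\gamma = 1/\operatorname{median}(d^2)$
over (a 1000-row subsample of) pairwise squared distances, which puts a
typical cell pair at similarity $e^{-1}$; the benchmark harness uses it
by default.

### Reference cell selection

The dissimilarity walk evaluates "most dissimilar" against the **last
selected cell only** — it is intentionally not farthest-point sampling,
which is a different (and separately benchmarkable) selector. The
per-step exclusion of the anchor cell's $k$ nearest neighbours is what
prevents the walk from bouncing between two extremes of the embedding.
Two details the method leaves open were fixed as follows:

* $k = \lfloor N/n \rfloor - 1$, so $n$ selections approximately exhaust
  the sample; callers may override `k`.
* the start cell (`start = "auto"`) is the cell nearest the embedding
  centroid — deterministic and reproducible, with any cell index
  accepted instead.

Ties in minimum similarity (common in degenerate or discretized
embeddings) are broken uniformly at random under a caller-supplied seed;
runs without a seed draw one and report it. Selection stops early, with a
warning, when fewer than $k$ candidates remain.

Grid selection spans the exact bounding box of the coordinates, corners
included, visiting lattice points in row-major order; a candidate within
$d = \texttt{min\_dist\_frac} \times$ (grid-cell diagonal) of a previous
selection is skipped, which by construction guarantees all pairwise
distances among selected cells are $\ge d$ and prevents over-selection at
the embedding's edge.

## The simulator, and what passing tests do not show

`simulate_groups()` / `simulate_paths()` implement the standard
gamma–Poisson benchmark design: gene base means from
$\Gamma(\text{shape}=0.6, \text{rate}=0.3)$ (typical of UMI data), each
gene DE in each group with probability `de_prob`, multiplicative factors
drawn log-uniformly from `de_factor_range` and inverted with probability
$1/2$, mean-1 log-normal cell size factors (`lib_size_sd = 0.25`), and
negative-binomial sampling with dispersion 0.1. A factor of exactly 1
means "not DE in that group" and is the ground truth the AUROC harness
scores against. Path mode assigns each cell a pseudotime
$t \sim U(0,1)$ and interpolates DE means log-linearly,
$\mu = \text{base} \cdot \text{factor}^t$, so the branch end carries the
full factor.

The simulator reproduces the two properties the benchmark actually needs
— ground-truth DE labels and realistic overdispersion — and deliberately
omits dropout beyond what the NB produces, batch effects, gene–gene
correlation, and scATAC-style extreme sparsity. Recovery numbers on this
generator therefore bound what the arithmetic of the method can do under
clean conditions; they do not certify performance on real data, where
embedding quality and normalization dominate. The permutation null also
breaks gene–gene correlation by design, exactly as it does on real data.

The benchmark harness mirrors the standard evaluation protocol: PCA test
embedding of $\log(1+x)$ counts (10 components), 0.5% of cells as
references (floor 5) via the dissimilarity walk, RBF scoring of the
$\log(1+x)$ matrix, one-round permutation null, and per-gene probability
$1 - \min_c p_{c,f}$ for the AUROC. The min-$p$ aggregation across
reference cells is a documented choice, not the only defensible one;
`max_abs_nsd` is available.

## Numerical conventions

* Squared distances in the batched kernel are computed via the
  cross-product identity and clamped at 0 against rounding; the
  reference's self-similarity is set to exactly 1.
* Zero-variance features: detected by a relative tolerance
  ($\operatorname{var} < 10^{-13}\,\overline{x^2}$) because floating-point
  moment differences of constant columns are not exactly 0; such features
  score exactly 0.
* A degenerate null column ($\sigma_{null} = 0$) yields $n_{sd} = 0$ for
  every feature, never $\pm\infty$.
* Sparse matrices are consumed natively (cross-product moments; per-column
  index permutation for the null) and are never densified feature by
  feature.
* The PCA embedding fixes each component's sign by making its
  largest-magnitude loading positive, so results are platform-stable.
* Result TSVs are sorted by feature id then reference cell id and render
  floats with 6 significant digits; identical inputs give byte-identical
  files, which the test suite enforces across every CLI subcommand.
* tf-idf uses the single-cell dialect
  $\text{tf} \times \ln(1 + N/\text{df})$ (within-cell proportion times
  detection rarity); features detected nowhere get idf 0 by convention,
  and all-zero cells are rejected because tf is undefined. Other idf
  dialects exist; this one is stated in the function's documentation.

## Problem sizes in the test suite

The suite exercises the mathematics at desk scale, chosen so the whole
suite runs in well under a minute of compute per file: regression-oracle
equivalence on 1000 random instances; selection replay against a naive
re-simulation on 50 instances of up to 500 cells; null calibration with
2000 features over a 500-cell embedding; end-to-end recovery on 500
cells × 1000 genes (2 groups, `de_prob` 0.1, factors 3–6), asserting
AUROC ≥ 0.90; coverage of a 2000-cell, 10-component Gaussian mixture in
20 seeded runs; 200 randomized grid-selection trials; and a 400-spot
block-marker lattice for 8-SD annotation. Larger instances change
constants, not conclusions, and are left to the user.

## Known limitations

* $\gamma$ is not learned from data; the median heuristic is a fallback,
  not an optimum, and annotation granularity is sensitive to it.
* Scores from features on wildly different scales share one null per
  reference cell; normalize first (the slope's $1/\operatorname{var}(x)$
  makes raw counts and log counts incompatible).
* The Gaussian-tail p-values are an approximation to the permutation
  distribution's extreme tail; they are calibrated in SD units by
  construction but should be read as ranking devices at 15+ SD.
* The KS global ranking needs several reference cells to be meaningful
  ($R = 1$ triggers a warning).
* The simulator's scope is stated above; it is a benchmark generator,
  not a data model.
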