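---
title: "Ordering cells along a differentiation time course: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering cells along a differentiation time course: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellwave)
```

## The problem

Cells collected at a handful of clock times during a differentiation run —
say human embryonic stem cells moving through mesendoderm toward definitive
endoderm — are not synchronized: at any collection time the population spans
a range of progression states. A single-cell RNA-seq snapshot at each time
therefore mixes earlier and later cells, and questions about *when* a
regulator turns on cannot be answered at the resolution of collection times
alone. `cellwave` reconstructs a finer, one-dimensional ordering of the
cells from the expression of a small panel of preselected marker genes,
under one hard constraint: cells from different collection times may never
interleave, because the clock-time labels are trusted at the block level
even though progression within a block is not.

## The ordering objective

Let the marker panel be $G$ genes, each standardized to mean 0 and unit
variance across cells. For a candidate order of $n$ cells, map rank
positions to equally spaced points $x_i \in [0, 1]$ and fit each marker $g$
with a degree-$d$ polynomial

$$\hat y_g(x) = \beta_{g0} + \beta_{g1} x + \cdots + \beta_{gd} x^d,$$

by least squares. The objective is the **aggregated MSE**

$$\mathrm{MSE}(\text{order}) = \sum_{g \in G} \frac{1}{n} \sum_{i=1}^n
  \left(y_{g,i} - \hat y_g(x_i)\right)^2,$$

the summed residual noise left after smoothing every marker along the
order. An order that sorts cells by true progression makes every marker
profile smooth simultaneously and so minimizes this sum. Standardization
matters: it puts all markers on the same scale so no single
highly-expressed gene dominates the sum.

Because the order itself carries no more information than ranks, equal
spacing of the abscissa is the natural choice; the fit is computed from the
thin QR factorization of the position design matrix, so evaluating a
candidate order costs one small matrix multiply and agrees with an explicit
normal-equations solve to machine precision.

The polynomial degree defaults to 3: marker profiles along a
differentiation course fall, peak, or rise, and a cubic is the lowest
degree accommodating all three shapes with a single inflection. Degrees 1-5
are supported; at very low cell numbers the effective degree is capped at
$n - 1$ so the design retains full column rank.

## Search: constrained extended nearest insertion, then 2-opt

Minimizing the aggregated MSE over all block-respecting permutations is
combinatorial, so the package uses a two-stage heuristic.

**Extended nearest insertion (ENI).** Start from one randomly chosen cell
per collection time, arranged in course order. Repeatedly draw one of the
remaining cells at random and evaluate every admissible insertion slot —
each position inside the cell's own time block, including the block's two
edges — keeping the slot that minimizes the aggregated MSE. Ties resolve to
the earliest slot, so the construction is deterministic given the seed. The
admissible-slot rule is what enforces the no-interleaving constraint by
construction.

**2-opt refinement.** Greedy insertion leaves local structure behind, so a
classical 2-opt pass follows: random contiguous segments with both
endpoints in one time block are reversed, and a reversal is kept only if
the aggregated MSE strictly decreases. The objective trace is therefore
non-increasing. By default up to 20000 proposals are made, stopping early
after 2000 consecutive rejections; a swap move (exchanging two cells of a
block) is available behind a flag for users who prefer the
pairwise-exchange variant.

**Restarts.** Both stages are greedy, and on small instances a single
ENI + 2-opt run settles into a reversal-local minimum a noticeable fraction
of the time. `wavecrest_order()` therefore runs the pair from several
independent random starts (default 5) and keeps the lowest-MSE order. In
our checks against exhaustive enumeration on instances small enough to
enumerate (two blocks of four cells, three markers), five restarts
recovered the global minimum essentially always, where one start failed on
roughly a fifth of instances. `exhaustive_oracle()` remains in the package
so users can certify the heuristic on their own small problems.

A structural caveat: a polynomial fit cannot distinguish the orientation of
a block-internal segment that is symmetric under reversal, so within-block
direction is only weakly identified near block edges. Accuracy checks
should compare orders by absolute Kendall correlation within blocks
(`order_concordance()`), not by raw rank agreement.

## Fishing: permutation testing for trend genes

Given a recovered order (often a single time point's slice — the window
where a fate decision happens), candidate genes are scored by the MSE of
their own polynomial fit along the order. Significance comes from a
permutation null: each draw picks a gene uniformly from the universe under
consideration, permutes its cell order uniformly, refits, and records the
MSE. The p-value is the fraction of null MSEs at or below the observed one:

$$p = \frac{\#\{\mathrm{MSE}_\mathrm{perm} \le \mathrm{MSE}_\mathrm{obs}\}}
          {\#\mathrm{permutations}}.$$

This literal formula admits $p = 0$; the standard $(k+1)/(n+1)$ correction
is reported alongside, and the two differ by at most $1/n_\mathrm{perm}$.
The null pool is shared across candidates by default — the null hypothesis
is about a generic unordered gene, and sharing makes $10^5$ permutations
affordable for thousands of candidates — with a per-candidate mode behind a
flag for users who want each gene permuted against itself. Trend direction
is the sign of a separate linear fit on the same points; a slope of exactly
zero (measure-zero on real data) falls to "up" with a flag and a warning.
Ranked gene lists are split by direction and sorted by ascending MSE.

## Bulk-supervised PCA

PCA fitted directly on single-cell data tends to align its leading axes
with technical noise. When matched bulk RNA-seq samples exist, the package
fits PCA on the bulk data — each gene standardized across samples — and
projects standardized single cells onto the bulk-derived loadings:

$$\mathrm{score}_{j,n} = \sum_g W_{g,n}\, \tilde X_{g,j},$$

where $W$ are the bulk loadings and $\tilde X$ the single-cell data
standardized with its *own* per-gene statistics (the bulk and single-cell
platforms differ in scale, so each side is standardized separately). Two
conventions make outputs reproducible: each component's sign is fixed so
its largest-magnitude loading is positive, and gene sets are intersected by
exact ID with mismatches reported, never imputed. Projecting the bulk
samples themselves through the same formula reproduces the bulk PCA scores
exactly, which the tests exploit as a self-consistency check. Absolute
loadings $|W_{g,n}|$ are exported as per-gene weights for downstream
weighted enrichment tools; the enrichment itself is out of scope. By
default the full gene intersection is used for projection, since no
variance filter is part of the model.

## KS expression paths

To flag genes that change anywhere along the ordered conditions, each pair
of adjacent collection times is compared with a directional two-sample
Kolmogorov-Smirnov test. The statistic's magnitude is the usual KS distance
$D = \max(D^+, D^-)$ and its sign is that of the dominant one-sided
component, positive meaning the later condition is stochastically larger
(an increase, "Up"). The asymptotic two-sided p-value is used, and
p-values are Benjamini-Hochberg adjusted across genes within each
transition by default. A transition is called Up or Down when its adjusted
p-value is at or below `alpha`, otherwise EE (equal expression); the calls
compose into a path such as `EE-Up-EE`, and a gene is differentially
expressed if any transition is not EE. This is deliberately a thresholded
KS path composer — a transparent, non-parametric stand-in for full
posterior-probability path models — and it retains their call rule (DE iff
the path is not all-EE) without their empirical-Bayes machinery. Dropout
zeros stay in the empirical distributions by default, because removing them
changes the null; a flag excludes them for users who want the
positive-expression comparison.

## Preprocessing rules

The preprocessing chain mirrors standard single-cell practice for
full-length, plate- or chip-based protocols:

* **Cell QC** (TPM matrices): a cell is kept when at least 5000 genes
  exceed 1 TPM. The count is inclusive at the threshold; the comparison is
  strict at 1 TPM.
* **Normalization**: median-by-ratio size factors — per cell, the median
  over reference genes of the count divided by the gene's geometric mean
  across cells. The classical reference set (genes positive in every cell)
  is the default; `min_frac` relaxes it for sparse data, with geometric
  means then taken over positive entries only. Note that the size factors
  are equivariant to planted per-cell multipliers only up to one shared
  constant, because the multipliers also shift every geometric mean by
  $(\prod_j c_j)^{1/n}$; relative size factors and all normalized ratios
  are invariant.
* **Gene filter**: genes with median normalized expression below 10 are
  dropped — a gene must be reliably detected in at least half the cells to
  contribute to ordering.
* **Standardization**: optional $\log_2(x + 1)$ transform (default on;
  expression profiles are judged on the log scale), then per-gene mean 0,
  unit *sample* variance ($n - 1$ denominator — this makes the
  three-point row $(1, 2, 3)$ standardize exactly to $(-1, 0, 1)$).
  Zero-variance genes are dropped and listed rather than kept as
  uninformative zero rows.

Whether ordering should run on the log or the raw normalized scale is a
genuinely open choice; both are supported and log is the default, matching
the scale on which marker profiles are usually displayed and keeping
high-expression cells from dominating the fit.

The knockdown screen's **Differentiation Score** — the ratio of
CXCR4-positive to reporter-positive cell percentages, normalized so a
non-targeting control scores exactly 1 — is included as a small utility
because it is the downstream readout this kind of ordering analysis feeds.

## The simulator and what it does (not) emulate

`sim_config()` / `simulate_time_course()` generate time-course data with
known ground truth. Cells at collection time $i$ of $T$ draw latent
pseudotime uniformly from the $i$-th of $T$ equal windows on $[0, 1]$,
widened so consecutive windows overlap by 25% — the asynchrony that
motivates ordering in the first place. Each gene follows a smooth profile
class on the log2 scale (monotone up, monotone down, Gaussian peak, or
flat), counts are negative-binomial with variance $\mu + \phi\mu^2$, and an
independent Bernoulli dropout mask zeroes entries with probability
$p_0 e^{-\lambda \mu}$, so dropout is near-certain for near-zero means and
negligible above a few hundred counts.

Defaults describe strong differentiation markers profiled with a deep
full-length protocol: amplitude 5 log2 units (about 32-fold, modest next to
the orders-of-magnitude induction of canonical lineage markers), baseline
log2 means uniform on $[3, 8]$, dispersion $\phi = 0.15$ (count CV near
40% at high expression), $p_0 = 1$, $\lambda = 0.05$, and a desk-scale
default size of 4 time points x 40 cells x 600 genes. These choices were
made once, on the phenomenology above, and are the conditions under which
all simulation-based properties are evaluated.

Under these conditions the within-block order is only partly identifiable:
cells close in pseudotime differ by less than the per-cell noise, so *no*
estimator can recover their relative order. Concretely, an oracle that
knows each marker's true response curve and inverts it per cell reaches a
within-block absolute Kendall correlation of roughly 0.78-0.80 on default
courses, and the package's recovered orders sit close behind while
attaining an aggregated MSE *below* that of the true-pseudotime order —
the optimizer is at the identifiability ceiling, and residual disagreement
with the latent order reflects noise, not search failure. Users simulating
easier regimes (larger amplitude, lower dispersion, less overlap) will see
correspondingly higher concordance.

What the simulator does **not** emulate: batch and capture-site ordering
effects, library-size gradients confounded with time, doublets, branching
fates, or realistic gene-gene correlation beyond the shared latent
pseudotime. Passing the simulation-based checks therefore shows the
machinery is correct and calibrated under the declared generative model; it
does not certify performance on data whose noise violates that model.

## Numerical and degenerate-input conventions

* Least squares via thin QR; MSE is RSS$/n$ (not $n - p$), matching the
  "mean squared error of the fit" reading used throughout.
* Strict-improvement acceptance everywhere (insertions, 2-opt) with a
  $10^{-12}$ slack, so floating-point ties cannot cause drift; ties prefer
  the earliest slot / the incumbent.
* All randomized routines take an explicit integer seed and restore the
  caller's RNG state; identical seeds give bit-identical results, and the
  CLI defaults every seed to 1 rather than wall-clock.
* Degenerate inputs: identical cells order deterministically; constant
  genes are dropped at standardization; a time point with a single cell is
  legal for ordering (its block is trivially ordered) but KS path calling
  requires at least 3 cells per condition; `n_perm < 100` is refused
  unless forced.

## Problem sizes used in the shipped checks

The test suite and the acceptance script evaluate: exhaustive-oracle
comparisons on 50 instances of 2 blocks x 4 cells with 3 markers at degree
2; order recovery on 20 default-sized simulated courses (160 cells, 8
markers); fishing calibration on 500 null genes with 2000 permutations and
power on 10 planted trend genes among 500 nulls over 20 seeds; KS path
calibration on 120 genes x 3 conditions x 50 cells over 20 seeds. These
sizes were chosen to make the checks sharp at desk scale; all of them
complete in a few minutes on one CPU.
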