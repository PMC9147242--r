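---
title: "ANOVA-based multivariate analysis of designed metabolomics experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ANOVA-based multivariate analysis of designed metabolomics experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metanova)
```

## The problem

Designed LC-MS metabolomics experiments produce matrices with hundreds to
thousands of variables (m/z-defined features or retention-time channels of a
total ion current chromatogram) measured on very few samples (6–16), arranged
by an experimental design: extraction protocol, exposure dose, and so on.
Two questions dominate the statistical analysis:

1. **Is a design factor significant?** Does the factor explain more variance
   than chance assignment of samples to groups would?
2. **Which variables carry the effect?** The selected variables are the
   candidate markers on which all downstream biology rests.

`metanova` implements three multivariate ANOVA-based answers — ASCA,
regularized MANOVA (rMANOVA) and group-wise ASCA (GASCA) — together with the
reference methods they are usually compared against (PLS-DA with VIP scores
and selectivity ratio, univariate tests with Benjamini–Hochberg correction),
a shared sum-of-squares permutation engine, and the concordance machinery
(top-k sets, Venn partitions, profile correlations, coincidence counts)
needed to compare the selections.

## The shared ANOVA decomposition

All three methods start from the same partition of the mean-centered data
matrix $X$ (samples × variables). For a one-factor design with $k$ levels,

$$X_c = X - \bar{X} = E + R,$$

where row $i$ of the *effect matrix* $E$ is the mean of $X_c$ over the level
of sample $i$, and $R$ holds the residuals. With a second factor (and at most
one two-factor interaction) the partition extends term by term: interaction
rows are cell means minus both level means plus the grand mean. The sum of
squared elements of each matrix (`ssq`) measures the variance attributable to
each term; in balanced designs the term SSQs and the residual SSQ add up
exactly to the SSQ of $X_c$ (`decompose_effects` checks and reports the
balance flag).

Unbalanced data are supported for one-factor models, where effects and
residuals remain orthogonal; multi-factor unbalanced decompositions would
require type II/III corrections that are out of scope, so the package rejects
them and offers `balance_by_removal()` — random removal of samples from
over-represented levels, the standard practical fix when one replicate is
lost (e.g. trimming an 8 vs 7 design to 7 vs 7).

## Significance: the SSQ permutation test

The significance engine (`permutation_test`) is shared. The observed
statistic is computed on the true sample-to-design assignment; each of $N$
permutations (default 10,000) shuffles the rows of $X$ against the whole
design uniformly at random and recomputes the decomposition and statistic.
The p-value is

$$p = \frac{b + 1}{N + 1},$$

where $b$ counts permuted statistics **strictly larger** than the observed
one. Two deliberate conventions:

* **Strict exceedance.** In a balanced $n_1 = n_2 = 7$ design, a random
  permutation recreates the observed partition (or its label swap) with
  probability $2/\binom{14}{7} \approx 6\times 10^{-4}$, producing an exact
  tie. Counting ties as exceedances would put the attainable floor near
  $7\times10^{-4}$ rather than the $1/(N+1) = 10^{-4}$ floor that a strongly
  significant factor should reach at 10,000 permutations. Exact ties are
  detected with a relative tolerance of $10^{-10}$ so that floating-point
  reordering noise cannot turn a tie into an exceedance. The cost is a
  slightly anti-conservative test when the assignment space is tiny; the
  calibration tests therefore use designs with at least
  $\binom{10}{5} = 252$ distinct assignments, where the distortion at
  $\alpha = 0.05$ is within about one percentage point.
* **One permutation stream.** Permutations are drawn from the seeded stream
  before the statistic is evaluated, so different statistics see identical
  permutations seed-for-seed. This makes the rMANOVA $\delta = 1$ / ASCA
  equivalence exact (below), not merely approximate.

For tiny designs, `permutation_test(..., exact = TRUE)` enumerates all
distinct label assignments (e.g. all 20 of a 3 vs 3 comparison) and returns
the exact enumeration p-value under the same counting rule.

## ASCA

ASCA scores and loadings come from the singular value decomposition of the
effect matrix (`fit_sca`). Because effect rows are level means, pure-effect
scores are identical within a group; `augmented_scores` project
$E + R$ onto the same loadings and restore the within-group spread, which is
what one usually wants to *look at*. Both are emitted, since score plots in
the field are made both ways. The permutation statistic is `ssq(E)`.

ASCA implicitly assumes uncorrelated variables with equal variance (its
statistic and loadings ignore the residual covariance entirely). That is
exactly the weakness the other two methods address.

## Regularized MANOVA

rMANOVA replaces the identity-covariance assumption with a shrunk estimate of
the within-group covariance. With $H = E^\top E$ (between-group scatter),
$S = R^\top R/(n-k)$ (pooled within scatter) and $\gamma = \mathrm{tr}(S)/p$:

$$W_\delta = (1-\delta)\,S + \delta\,\gamma I, \qquad
  T(\delta) = \mathrm{tr}\!\left(W_\delta^{-1} H\right).$$

* $\delta = 0$, $n > p$: $T$ is the classical Lawley–Hotelling MANOVA trace.
* $\delta = 1$: $W = \gamma I$ and $T = \mathrm{ssq}(E)/\gamma$. For a
  one-factor model $\mathrm{ssq}(E) + \mathrm{ssq}(R)$ is invariant under row
  permutation, so $T$ is a strictly increasing transform of the ASCA
  statistic and the permutation p-values coincide seed-for-seed.
* $0 < \delta < 1$: the usual operating regime for p ≫ n data.

**Shrinkage intensity.** The source method names only the Ledoit–Wolf
theorem for choosing $\delta$, so the package transcribes the original
single-target Ledoit–Wolf estimator for shrinkage toward the scaled identity:
with within-group-centered rows $r_i$ and pilot covariance
$S_n = R^\top R/n$,

$$m = \tfrac{\mathrm{tr}(S_n)}{p},\quad
  d^2 = \tfrac{\lVert S_n - mI\rVert_F^2}{p},\quad
  \bar b^2 = \tfrac{1}{n^2 p}\sum_i \lVert r_i r_i^\top - S_n\rVert_F^2,\quad
  \hat\delta = \frac{\min(\bar b^2, d^2)}{d^2}.$$

The pilot uses the $1/n$ convention; the within scatter in the statistic uses
the unbiased $n-k$ divisor. `estimate_delta` is clipped to $[0,1]$; it
approaches 1 for p ≫ n and 0 for n ≫ p with a dispersed covariance spectrum.
(When the true covariance *is* isotropic, $d^2 \to 0$ and shrinkage toward
the — then correct — target is harmless; the implementation returns 0 in the
exactly-degenerate case.) Under `delta = "auto"` the intensity is
re-estimated inside every permutation: the estimator is part of the
procedure, which keeps the permutation null exchangeable.

**Computation.** For p ≤ n the statistic is a dense solve. For p > n it is
evaluated in sample space with a Woodbury identity on the Gram matrix
$RR^\top$ (all operations $O(n^2 p)$), which is what makes
999–10,000-permutation runs on 14 × 500 matrices take seconds. The two routes
are property-tested against each other. Canonical variates (for variable
ranking) are eigenvectors of $W_\delta^{-1}H$ computed through the
symmetrized whitened form $W^{-1/2} H W^{-1/2}$ for numerical stability.
$\delta = 0$ with $p \ge n-k$ makes $W$ singular; the package refuses with an
explicit instruction to use $\delta > 0$. rMANOVA is restricted to
single-factor terms, matching its within-scatter definition
$R^\top R/(n-k)$ with $k$ groups.

## Group-wise ASCA

GASCA makes loadings interpretable for correlated metabolite panels by
restricting each component's support to one *group* of correlated variables:

1. **Grouping** (`find_groups`): variables are nodes, edges join pairs with
   $|r| \ge$ threshold (default 0.7), groups are connected components. This
   deterministic proxy replaces the more elaborate group-identification
   algorithms used with group-wise PCA elsewhere; it is a documented
   simplification, and user-supplied (possibly overlapping) groups are
   accepted via `variable_groups()`. Column correlations are invariant under
   row permutation, so the groups of every permuted matrix equal the observed
   ones and are computed once per test.
2. **Fitting** (`fit_gasca`): for each candidate group, the leading right
   singular vector of the effect submatrix and the SSQ it explains; the best
   group wins (ties to the first), the loading is embedded with zeros outside
   the group, and the effect matrix is deflated by the rank-1 fit.
3. **Testing**: the permutation statistic is the SSQ explained by the *first*
   group-wise component, not the total effect SSQ. This makes the test
   sensitive to group-concentrated structure and stricter than ASCA on
   diffuse effects — consistent with group-wise methods' reputation of
   declaring significance only for strong, concentrated factors. In the
   permutation loop the statistic is evaluated through a $k\times k$
   eigenproblem per group (the effect matrix has at most $k$ distinct rows),
   tested equal to the full SVD route.

## Reference methods

* **PLS-DA** (`fit_plsda`): NIPALS PLS2 on the scaled matrix against a
  class-indicator response (a single 0/1 column for two classes, one column
  per class for three). Feature matrices are conventionally autoscaled, TIC
  matrices mean-centered. The default of 2 latent variables is the smallest
  interpretable model; the comparison machinery fixes it explicitly.
* **VIP scores** (`vip_scores`):
  $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a \mathrm{SSY}_a}$
  with unit-norm weight columns; the mean of squared VIPs is exactly 1 by
  construction (asserted to $10^{-10}$ in the acceptance suite), which is
  what justifies the conventional VIP > 1 threshold.
* **Selectivity ratio** (`selectivity_ratio`): the data are projected on the
  normalized regression vector (target projection); SR per variable is the
  explained-to-residual variance ratio of the rank-1 reconstruction, capped
  at $10^{12}$ where the residual is numerically zero so rankings never
  contain infinities.
* **Stability** (`stability_replicates`): 1000 refits by default, each
  removing a uniform-random 1–10% of the variables and recording top-k (or
  VIP > 1) membership; a removed variable cannot be selected in that
  replicate.
* **Univariate** (`univariate_tests` + `bh_adjust`): equal-variance t-tests
  for two groups (not Welch — the parametric convention of the source
  workflow), one-way ANOVA F-tests for three, Benjamini–Hochberg step-up
  adjustment with the 0.05 significance convention. Step-up BH is *not*
  idempotent (`bh_adjust(c(0.1, 0.5))` is `c(0.2, 0.5)`, adjusting again
  gives 0.4) — a property sometimes misstated; the tests pin the behaviour
  against a brute-force oracle and `stats::p.adjust`.

## Comparing the selections

`select_top_k` ranks ANOVA methods by the absolute first-component loading
(SCA, canonical, or group-wise loading respectively) and PLS references by
the VIP/SR value itself, with ties broken by ascending variable index; k
defaults to 50, the conventional size that keeps chance overlaps small.
`venn_partition` returns exact counts for every region signature;
`coincidence_with_reference` counts overlaps with the PLS-DA VIP reference;
`profile_correlation` correlates relevance profiles. Because loadings are
signed while VIP/SR are non-negative, profiles of the ANOVA methods are
correlated on absolute values by default (`absolute_loadings` in
`run_workflow` exposes the choice). `run_workflow` chains the whole pipeline
from a JSON/list configuration and writes a deterministic `report.json`
(timestamps only in the log file). Configuration files are JSON; YAML is not
supported to keep the dependency set to the pinned environment.

## The synthetic-data generator

`generate_feature_dataset` emulates the structure that makes this problem
hard — p ≫ n, sparsity, correlation, drift — with known ground truth:

* per-variable baseline log-intensities $\mu_j \sim N(\texttt{baseline\_log\_mean},
  \texttt{baseline\_log\_sd}^2)$ (defaults 11 and 1: areas around $6\times10^4$
  spanning roughly two orders of magnitude);
* within-group log-scale noise with **unit** standard deviation, so
  `effect_size` *is* the group-mean shift in within-group sd units; marker
  offsets are monotone in level order (0, $e$, $2e$ for three groups,
  emulating control < low < high dose designs);
* correlated blocks built from shared factors
  ($\epsilon = \sqrt{\rho}\,f + \sqrt{1-\rho}\,e$);
* zero-inflation applied after effect injection, never on internal
  standards, keeping normalization well defined;
* a per-sample multiplicative drift $e^{d_i}$, $d_i \sim N(0,
  \texttt{drift\_sd}^2)$ (default 0.3), shared by *all* variables including
  the noise-free internal-standard channels — so `normalize_features`
  (division by the IS mean times sample amount) removes it exactly, which
  the tests assert;
* a single RNG stream per dataset keyed by `seed`, with stage draws in fixed
  order, giving bit-identical reproduction.

`generate_tic_dataset` builds chromatograms as sums of Gaussian peaks with
log-normal heights; differential peaks shift their log height by
`effect_size` within-group height-sd units per level, and truth channels are
those within two peak widths of a differential apex. Zero-inflation and
internal standards do not apply to TIC channels. `generate_centroid_scans`
plants m/z traces (stable m/z, jitter below half the ROI tolerance,
intensities above threshold, ≥ `min_consecutive_scans` consecutive scans)
that the simplified ROI extractor must recover exactly.

What the generator does **not** emulate: isotope patterns, adducts,
chromatographic tailing, retention-time misalignment, batch structure beyond
the single drift term, or intensity-dependent (heteroscedastic) noise. A
green test therefore establishes the statistical machinery on data with the
right shape, not robustness to every artefact of real spectra. The default
effect sizes are package choices — real studies do not come with reported
effect magnitudes — and the calibration experiments (500 null datasets × 199
permutations per method, 5 samples/group, 15 variables) were sized for the
permutation engine's runtime envelope and a rich enough assignment space, as
discussed above.

## Simplified ROI extraction

`roi_features` is a deliberately simplified stand-in for full published ROI
algorithms: greedy trace building (a centroid extends the nearest open trace
within `mz_tolerance` of its running mean m/z if the trace was touched in the
current or previous scan), thresholding on `min_intensity`, a
`min_consecutive_scans` length filter, area = summed trace intensity, and
variable IDs from the mean m/z rounded to 4 decimals (collisions suffixed
`_2`, `_3`, …). Defaults (0.01 Da, threshold 0, 3 scans) are package
choices. Vendor format conversion and cross-sample alignment beyond exact
ID matching are out of scope.

## Known limitations

* Two-factor models must be balanced (no type II/III SSQ), and rMANOVA is
  one-factor only.
* Permutations are unrestricted row shuffles even in two-factor models;
  restricted schemes are future work.
* GASCA's grouping is a deterministic correlation-component proxy; published
  group-wise analyses using other grouping algorithms or permutation
  statistics can legitimately give different p-values.
* PLS-DA is fit without cross-validated component selection; the stability
  replicates and permutation guard are the only overfitting checks.
* The strict-exceedance p-value convention is mildly anti-conservative for
  designs with very few distinct assignments (use `exact = TRUE` there).
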