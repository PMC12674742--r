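---
title: "Reproducibility-optimized moderated statistics: model and methods"
author: "modrots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility-optimized moderated statistics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The testing problem

Label-free proteomics and metabolomics experiments produce a complete (after
upstream imputation) matrix of log2 intensities for G features across n
samples, with a condition of interest and possibly nuisance covariates such
as batch, injection order or demographics. Feature-wise variance estimates at
these sample sizes (often 3–5 per group) are unstable, and the best trade-off
between fold-change evidence and variance standardization differs between
datasets. `modrots` addresses both issues at once: variances are stabilized by
empirical Bayes shrinkage toward a global prior, and the weighting between
effect size and standard error in the test statistic is *learned from the
data* by maximizing the reproducibility of top-k feature lists under
resampling.

# The model

## Feature-wise linear model

For each feature $i$ the expected log2 intensity is modeled as
$E[x_i] = X\beta_i$ with a shared design matrix $X$ (intercept,
treatment-coded condition columns, covariates). Ordinary least squares gives
the tested contrast effect $\hat\beta_i = c^T\hat\beta$, the residual variance
$s_i^2 = \mathrm{RSS}_i/f$ with $f = n - \mathrm{rank}(X)$, and the design
constant $u = \sqrt{c^T(X^TX)^{-1}c}$, the unscaled standard deviation that
converts a residual standard deviation into the standard error of the
contrast. One orthogonal decomposition of $X$ is computed and reused across
all features; because the matrix is complete and the design shared, $f$ is a
single scalar.

Missing values are rejected, not imputed: imputation belongs upstream of this
model and silently imputing here would hide a modelling decision from the
user. Metadata rows are aligned to expression columns by sample id, never by
position.

## Variance shrinkage

Observed variances are shrunk toward a global prior via
$$\tilde s_i^2 = \frac{f_0 s_0^2 + f s_i^2}{f_0 + f},$$
the posterior mean under a scaled inverse-chi-square prior. The prior
$(f_0, s_0^2)$ is estimated once from all features by moment matching on the
log scale: with $e_g = \log s_g^2 - \psi(f/2) + \log(f/2)$, $f_0$ solves
$\psi'(f_0/2) = \mathrm{var}(e) - \psi'(f/2)$ by Newton inversion of the
trigamma function, and $s_0^2 = \exp\{\overline e + \psi(f_0/2) -
\log(f_0/2)\}$. When the spread of the variances does not exceed what
sampling noise alone explains ($\mathrm{var}(e) \le \psi'(f/2)$), $f_0 =
\infty$ and every $\tilde s_i^2 = s_0^2$. Zero variances (exact fits) are
excluded from the moment estimation — they carry no information on the log
scale — but are still shrunk: Eq. above gives them $f_0 s_0^2/(f_0+f) > 0$,
so no separate variance floor is needed. The estimator is implemented from
these formulas directly; the test suite cross-checks it against the
independent implementation in `limma` to $10^{-6}$.

## The moderated ranking statistic

$$d_i = \frac{\hat\beta_i}{\alpha_1 + \alpha_2\, (u\,\tilde s_i)}.$$

The pair $(\alpha_1, \alpha_2)$ interpolates between two classical extremes:
$(1, 0)$ ranks by raw log2 fold change, $(0, 1)$ is exactly the
empirical-Bayes moderated t-statistic. Features are ranked by $|d_i|$
(two-sided; the method reports both up- and down-regulation), with ties broken
by ascending feature index so that rankings — and everything downstream —
are deterministic.

## Choosing the scaling by reproducibility

For a candidate $(\alpha, k)$, reproducibility is the expected top-k overlap
across pairs of stratified bootstrap datasets:
$$R_k = \frac{1}{B}\sum_b \frac{\#\{i:\ r(\alpha, D_1^{(b)}) \le k \ \wedge\
r(\alpha, D_2^{(b)}) \le k\}}{k},$$
with bootstrap standard deviation $S_k$ (denominator $B-1$) and a null level
$R^0_k$ computed identically on label-permuted data. The selected parameters
maximize $Z_k = (R_k - R^0_k)/S_k$ over a lattice of $(\alpha, k)$ cells, so
no top-list size has to be pre-specified. Each bootstrap dataset resamples
samples with replacement *within* condition strata (stratum sizes preserved
exactly); covariate values travel with their sample. The default is B = 1000
bootstrap pairs, the established recommendation for this optimization family.

Two points were genuinely open and are resolved as follows:

* **The null ensemble for $R^0$.** One fresh uniform permutation of the
  condition labels is drawn per pair (covariates stay attached to their
  samples), shared by both members; each member is then an independent
  stratified bootstrap under the permuted labels — permuted data
  "bootstrapped exactly like the observed data". An independent ensemble,
  rather than a reuse of the observed bootstrap indices, keeps $R^0$ an
  unbiased picture of reproducibility without condition signal.
* **Shared plans across the lattice.** All $(\alpha, k)$ cells score the same
  bootstrap/permutation ensemble. This makes $Z$ comparable across cells and
  costs a factor $|\text{lattice}|$ less than per-cell resampling.
* The prior $(f_0, s_0^2)$ is a global property of the observed dataset; it
  is estimated once and reused in every refit, so the null cannot drift.

The default $\alpha$ lattice is the parent method's grid — $(a, 1)$ for $a$
in $0{:}0.20$ step $0.01$, $0.22{:}1.00$ step $0.02$, $1.2{:}5.0$ step $0.2$
— plus $(1, 0)$, making the pure fold-change statistic a candidate (82 pairs
total). The k grid is ~40 log-spaced integers from $\max(5, \lceil 0.005
G\rceil)$ to $\lfloor G/4 \rfloor$; $k = G$ is excluded because overlap there
is identically 1 in both ensembles and $Z$ degenerates to $0/0$. Cells with
$S_k = 0$ get a $-\infty$ sentinel (zero bootstrap spread means
reproducibility is uninformative there); ties in $Z$ are broken toward
smaller $\alpha_1$, then larger $k$.

## Significance

The observed statistics at the optimum $(\alpha^*, k^*)$ are compared with a
pooled null: the model is refitted under each of P label permutations
(exhaustively enumerated when the number of distinct assignments is ≤ P,
otherwise Monte Carlo), $d$ is computed at $\alpha^*$, and all $G \times P$
null values are pooled. Empirical p-values use the add-one convention
$p_i = (1 + \#\{|z| \ge |d_i|\})/(1 + N)$, which is finite-sample valid and
strictly positive; the optimization is *not* re-run per permutation — the
null is for the statistic at the chosen scaling, and re-optimizing would test
a different (and vastly costlier) procedure. Benjamini–Hochberg adjustment is
the default ("adjusted p-value" with a 0.05 cutoff defines significance); a
Storey-type $\hat\pi_0$-scaled variant is available via
`adjustPValues(method = "storey")`. P defaults to B: the pooled null then has
$G \times B$ entries, dense enough that BH granularity is never limited by
the permutation count at these scales.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `B` | 1000 | bootstrap pairs for the reproducibility estimate |
| `P` | `B` | label permutations for the significance null |
| `fdrCutoff` | 0.05 | adjusted-p threshold for `significant` calls |
| `alphaGrid` | 82 pairs | scaling lattice (see above) |
| `kGrid` | ~40 values | top-list sizes, log-spaced, $< G/4$ |
| `seed` | — | master seed; every resampling stream derives from it |

Each bootstrap pair, null pair and permutation draws from its own
deterministically derived RNG stream, so results are reproducible and
independent of evaluation order.

# The synthetic data generator

`simulateSpikeIn()` emulates a two-group spike-in benchmark on the log2
scale: per-feature noise variances are drawn from the scaled
inverse-chi-square prior ($f_0 = 4$, $s_0^2 = 0.25$ by default) — exactly the
model the shrinkage assumes, which makes prior-recovery tests meaningful —
baselines are log-uniform (cosmetic), and a known fraction of features
(default 10%) is shifted by a known effect (default 2 log2 units, i.e. 4
prior standard deviations, with random sign) in the non-reference condition.
The default group size of 5 + 5 mirrors typical spike-in designs.

`batchSpec()`/`injectBatchEffect()` add technical structure: a uniform log2
shift (default range 5–20; use a degenerate range for a fixed shift) applied
to a random subset of non-differential features in the samples of one batch
only, with the drawn features and shifts logged for exact inversion. The
default batch layout crosses two batches with the condition at an unbalanced
(~2:1) ratio, the confounded arrangement in which ignoring the batch turns
shifted features into false positives and inflates the variance prior —
modelling the batch as a covariate recovers the clean analysis.

What the generator does **not** emulate: missing values and their
mechanisms, intensity-dependent variance trends, peptide-level structure and
summarization artifacts, correlated features, and acquisition-mode specifics.
Passing the package's benchmarks therefore demonstrates correctness of the
statistical machinery under its own model assumptions, not performance on any
particular real acquisition workflow.

# Numerical choices

* Trigamma inversion: Newton iteration from the asymptotic initializer
  $x_0 = 0.5 + 1/y$, tolerance $10^{-8}$, at most 50 iterations; estimates of
  $f_0$ above $10^7$ are reported as $\infty$.
* Exact fits: residual sums of squares at rounding-noise level (relative to
  the feature's total sum of squares) are counted as zero variance, so a
  constant matrix fails cleanly in prior estimation rather than propagating
  garbage.
* Rank-deficient refit designs (a covariate level can vanish from a bootstrap
  resample): aliased columns are dropped via pivoted QR, provided the tested
  contrast does not load on them; the condition columns are always estimable
  because resampling is stratified by condition.
* All randomness flows through derived per-unit seeds below $2^{31}$; the
  caller's `.Random.seed` is never disturbed.
* pAUC is normalized by the FPR bound so it lies in $[0, 1]$; note the chance
  level under this simple normalization is $\mathrm{fprMax}/2$, not 0.5,
  for bounds below 1 (the raw area is available with `normalize = FALSE`).
  Tied scores are collapsed into single ROC/PR steps (trapezoidal
  interpolation), matching the average-rank AUC convention.

# Scales used by the test suite

The distributed tests exercise the method at desk scale, the package's own
choice for a self-contained suite: oracle comparisons at $G \le 30$, $B \le
5$ against a fully naive reference implementation; error control and power on
$G = 500$–$1000$ with $B = P = 100$ across 3 seeds; covariate benefit on
batch-injected data across 5 seeds. `scripts/acceptance.R` re-runs the
pipeline end to end on freshly simulated data and reports the headline
quantities it computes.

# Known limitations

* One contrast per run (iterate over contrasts for multi-group designs);
  no F-type multi-coefficient tests and no one-sided variants.
* Free label permutations: with covariates present, permutations are not
  restricted to covariate blocks. Block-restricted permutation is a natural
  extension point; the free scheme is the standard reading of label
  permutation and keeps nuisance structure attached to samples.
* No weighted regression, mixed effects, per-feature missing-data designs, or
  abundance-dependent variance trends.
* The optimization shares one resampling ensemble across the lattice; with
  very small n the number of distinct bootstrap datasets is limited and the
  $Z$ surface becomes coarse.
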