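---
title: "Metabolite deregulation analysis: model and methods"
author: "metadereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite deregulation analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadereg)
```

# The problem

Untargeted metabolomics of a two-group design — here the cortex of
Mecp2-deficient (`KO`) versus wildtype (`WT`) mice, a standard model of
Rett syndrome — produces a feature-by-sample intensity table from several
acquisition platforms (reversed-phase UPLC-MS in positive and negative
ionization mode, plus GC-MS). Only a minority of features can be
annotated to reference compounds, some ambiguously ("coeluting"
matches), and small group sizes (six animals per genotype) make
per-feature variance estimates unstable. `metadereg` implements the full
inference chain for this setting:

1. per-platform median normalization, log transformation, mean
   imputation;
2. per-metabolite moderated t-tests with empirical-Bayes variance
   shrinkage and Benjamini–Hochberg (BH) false-discovery-rate control;
3. a rotation-based (ROAST-style) test of pathway deregulation against
   GMT-format metabolite sets;
4. descriptive outputs: PCA sample scores, volcano tables, clustered
   heatmap orderings, and group phenotype statistics.

# Preprocessing

**Normalization.** Within each platform, sample $j$'s present
intensities are multiplied by one factor $f_j = \tilde m / m_j$, where
$m_j$ is the sample median on that platform and $\tilde m$ the median of
all per-sample medians. This equalizes sample loading per platform while
preserving relative feature differences. We deliberately do *not* scale
each genotype group to its own median: that reading of "group-median
normalization" would remove exactly the group differences the analysis
is meant to detect.

Median normalization assumes that differences in sample medians reflect
loading, not biology. When a large, directionally unbalanced fraction of
the metabolome truly shifts, the sample medians move with it and
normalization transfers part of that shift onto every feature. This is a
known limitation of all global-scaling methods and is visible in
simulations with strong asymmetric deregulation; the package therefore
keeps normalization a separate, skippable stage.

**Log transform.** Intensities are log-transformed to stabilize
variance. The default base 2 makes the downstream group-mean difference
directly a log2 fold change. A pseudocount (default 0) must be supplied
when exact zeros occur.

**Imputation.** Each missing value of a feature is replaced by the mean
of that feature's present values across *all* samples. Imputing the
grand mean rather than the group mean is the conservative choice: for a
truly shifted feature it pulls the two group means together, biasing the
test toward the null rather than away from it. The complementary cost is
variance inflation: an imputed grand-mean value sits half a fold-change
away from either group mean, so strongly shifted features with missing
cells get inflated residual variances. Group-wise imputation is
available (`impute_missing(..., groupwise = TRUE)`). Imputation runs
after the log transform and is performed exactly once; downstream code
never sees missing values.

# Per-metabolite inference

For feature $g$ with group means $\bar y_{KO,g}, \bar y_{WT,g}$ and
pooled within-group variance $s_g^2$ on $d = n_1 + n_2 - 2$ degrees of
freedom:

$$\mathrm{logFC}_g = \bar y_{KO,g} - \bar y_{WT,g}.$$

**Variance shrinkage.** The $s_g^2$ are modeled as draws from a scaled
inverse chi-square distribution with prior degrees of freedom $d_0$ and
prior variance $s_0^2$. Writing
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$ (with $\psi$ the digamma
function), the hyperparameters are estimated by moment matching on the
log scale:

$$\psi'(d_0/2) = \mathrm{var}(e_g) - \overline{\psi'(d/2)}, \qquad
  s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\},$$

solving for $d_0$ by Newton inversion of the (monotone) trigamma
function. When the observed spread of $e_g$ does not exceed pure
sampling noise, the right-hand side is non-positive: the variances are
then consistent with a single common value, $d_0 = \infty$, and the
pooled estimate $s_0^2 = \overline{s_g^2}$ is used (the log-scale
back-transform is upward-biased in this degenerate case). This matches
the behaviour of the standard reference implementation, which the test
suite uses as an independent cross-check.

**Moderated t.** The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$ yields

$$t_g = \frac{\mathrm{logFC}_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}}$$

on $d + d_0$ total degrees of freedom (standard normal when
$d_0 = \infty$). $d_0 = 0$ recovers the ordinary pooled two-sample
t-test exactly. Two-sided p-values are BH-adjusted; the family size $m$
is the number of rows actually tested. Because the published analysis's
$m$ is not recoverable, the pipeline defaults to testing the uniquely
identified metabolites (the rows that appear in result tables) and
records $m$ in the run manifest.

**z-scores.** For pathway aggregation each $t_g$ is mapped to its
standard-normal equivalent $z_g = \Phi^{-1}(F_t(t_g; d + d_0))$,
computed on the smaller tail in log-probability space so that large
statistics do not saturate; $|z|$ is clamped at 37, beyond
double-precision tail resolution. On the z scale identical two-sided
p-values are preserved and metabolites from features with different
residual structure become comparable.

# Pathway deregulation

**Set construction.** Pathway membership (GMT format; the description
field carries the pathway category) is intersected with the uniquely
identified, tested metabolites. Coeluting features never enter a set —
an ambiguous identity must not vote in any pathway. Sets with fewer than
three members are discarded.

**Statistic.** Each pathway's deregulation score is the arithmetic mean
of its members' z-scores, $S_P = \overline{z_g}$; its sign gives the
direction (`Up`/`Down`). Members with $|z| > \sqrt 2$ (strict) are
counted as up/down *contributors* — under the null,
$P(|Z| > \sqrt 2) \approx 0.157$, so contributors are metabolites
carrying clearly more than their share of the pathway signal.

**Rotation null.** Permutation is hopeless at $n = 6 + 6$; instead, each
feature's samples are reduced to rotation coordinates
$y_g = (u_g, r_g)$: the effect coordinate
$u_g = \mathrm{logFC}_g/\sqrt{1/n_1 + 1/n_2}$ along the
intercept-orthogonal group contrast, and $d$ residual coordinates with
$\lVert r_g \rVert^2 = d\, s_g^2$ (so the unmoderated t is
$u_g / \sqrt{\lVert r_g\rVert^2/d}$). For each of $B$ rotations one
random unit vector $\rho_b$ — normalized standard-normal draws — is
shared across *all* features, preserving inter-metabolite correlation.
The rotated effect $u^*_g = \rho_b^\top y_g$ and variance
$s^{*2}_g = (\lVert y_g\rVert^2 - u^{*2}_g)/d$ are pushed through the
same moderation and z-transform as the observed data, with $(d_0, s_0^2)$
held fixed at their observed-data estimates (re-estimating per rotation
is costly and the reference method also freezes them).

P-values use the $+1$ conventions, $p_{up} = (\#\{S^* \ge S_{obs}\} + 1)/(B+1)$
and symmetrically for $p_{down}$; ties count as exceeding, which is
conservative. The default *directional* alternative reports
$p = \min(1,\, 2\min(p_{up}, p_{down}))$, matching the signed direction
column; a *mixed* alternative (one-sided on the mean squared z,
sensitive to deregulation with discordant signs within a pathway) is
available but non-default, since the published results report one
direction per pathway. $B$ defaults to 9999, so p-values have a floor of
$10^{-4}$; published pathway p-values as small as $10^{-6}$ imply a much
larger rotation count (or an approximation) in the original analysis, so
$B$ is a config knob and the floor is always recorded. Pathway p-values
are BH-adjusted across all tested pathways.

# Descriptive summaries

* **PCA**: samples as observations, features centered but not scaled
  (all values share the log2 scale); explained-variance percentages from
  squared singular values; a deterministic sign convention (largest
  loading positive) makes results reproducible.
* **Volcano**: log2 fold change vs $-\log_{10}$ adjusted p, significance
  flagged at adjusted $p < 0.05$ (strict, following the figure
  convention), with the customary $\pm 1$ fold-change guide lines.
* **Heatmap ordering**: features z-scored per row, Euclidean distance,
  average linkage, rows/columns sorted by id before clustering so the
  tree does not depend on input order. Distance and linkage are
  configurable choices, not inferences; the published figures do not
  state theirs.
* **Phenotype statistics**: group means, SDs with divisor $n$
  (population convention — the convention check against the published
  cohort table is part of the test suite; divisor $n-1$ does not
  reproduce its printed SDs), and pooled-variance two-sided t-tests
  (Welch's test does not reproduce the printed p-values either).

# Synthetic data

Since the study's raw intensities are unpublished, the package ships a
generator whose defaults mirror the study conditions: 6 + 6 samples;
features split ~49/48/3% across `uplc_pos`/`uplc_neg`/`gcms`; 28% of
features annotated and 11% of those coeluting; log2 baselines uniform on
[11, 27] (the published average-expression range); per-feature variances
$\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ with $(d_0, s_0^2) = (4, 0.04)$;
40 pathways of 3–20 members over the unique compounds, half deregulated
with mean log2 shifts of magnitude 0.5–2.5 (random sign, per-metabolite
jitter SD 0.3, mirroring the coherent single-direction shifts seen in
real pathway tables); 3% missingness, completely at random (an
intensity-dependent option exists but is off by default, since MCAR
keeps the imputation properties testable). The default size of 600
features keeps the test suite fast; `full_scale_spec()` provides the
full 4143/283/32 geometry. Generation is a pure function of the spec,
including its seed.

Pathways may share compounds, as real databases do; a metabolite claimed
by several deregulated pathways takes the shift of the first. The
`disjoint_pathways` option removes this overlap for calibration and
power studies where per-pathway truth must be unambiguous.

What the generator does *not* emulate: chromatographic drift, batch
effects, intensity-dependent variance on the raw scale, adducts and
isotopes, or annotation errors. Passing tests on synthetic data
therefore demonstrate the correctness and calibration of the inference
chain under its stated model, not robustness to those artifacts.

# Numerical and design choices

* Trigamma inversion by Newton iteration from the start value
  $0.5 + 1/y$, with asymptotic branches for extreme arguments;
  convergence tolerance $10^{-10}$ (relative).
* `t_to_z` works on the smaller tail with `log.p = TRUE` end to end;
  $|z|$ clamp at 37.
* Zero residual variance with zero effect yields $t = 0$; with non-zero
  effect it is an error rather than a silent infinity.
* Rotation draws: one $\mathcal N(0, I_{d+1})$ vector per rotation,
  normalized; fixed seed gives bit-identical results.
* BH via the standard step-up implementation; ties resolved by stable
  sorting, so adjusted values are order-independent.
* Metabolite significance uses adjusted $p < 0.05$ (strict) while
  pathway significance uses adjusted $p \le 0.05$; the two source
  conventions differ and both thresholds are exposed.
* The problem sizes used by the test suite and the acceptance script —
  600-feature datasets, 50 size-3 null pathways at $B = 9999$, 20
  pathways with shifts of 2–2.5 at $B = 999$, $B = 10^5$ for the
  singleton calibration check — were chosen so each check has clear
  expected behaviour at negligible runtime.

# Known limitations

* Two-group designs only: no covariates, batch terms, paired samples, or
  robust/trended variance priors.
* Median normalization, as discussed, partially absorbs strong
  directionally unbalanced deregulation.
* Grand-mean imputation inflates the residual variance of strongly
  shifted features with missing cells (conservative for those features).
* Rotation p-values are discrete with resolution $1/(B+1)$; at the
  default $B$ no pathway p-value can fall below $10^{-4}$.
* Coeluting features are excluded from pathway analysis entirely rather
  than fractionally assigned; published tables suggest such features
  were carried with duplicated statistics at the metabolite level, which
  the pipeline does not reproduce by default.
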