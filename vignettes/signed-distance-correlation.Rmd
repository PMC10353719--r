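---
title: "Signed and partial distance correlation for omics networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed and partial distance correlation for omics networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidcor)
```

## The problem

Data-driven network reconstruction in metabolomics and lipidomics usually
starts from a matrix of pairwise feature associations. Pearson and Spearman
correlations capture only linear or monotone trends; metabolite pairs coupled
through saturating, periodic or U-shaped kinetics are invisible to them.
Distance correlation (dCor) is a non-parametric dependence measure that is
zero only under full independence and is sensitive to arbitrary (including
non-linear) relationships, which makes it a natural edge weight for
metabolomic networks. Its one drawback for network interpretation is that it
is non-negative: it carries no directionality. This package restores a
direction by attaching the sign of the Pearson correlation of the same pair —
the *signed distance correlation* — and adds a partial-correlation variant
for separating direct from mediated associations.

## The statistics

For a feature pair $(X, Y)$ observed in $n$ samples, pairwise Euclidean
distance matrices $a_{jk} = |x_j - x_k|$ and $b_{jk} = |y_j - y_k|$ are
doubly centered,

$$A_{jk} = a_{jk} - \bar a_{j\cdot} - \bar a_{\cdot k} + \bar a_{\cdot\cdot},$$

so that every row and column of $A$ (and $B$) sums to zero. Then

$$\mathrm{dCov}^2(X,Y) = \frac{1}{n^2}\sum_{j,k} A_{jk}B_{jk}, \qquad
  \mathrm{dVar}(X) = \frac{1}{n^2}\sum_{j,k} A_{jk}^2,$$

and the distance correlation on the correlation scale is

$$\mathrm{dCor}(X,Y) = \sqrt{\frac{\mathrm{dCov}^2(X,Y)}
  {\sqrt{\mathrm{dVar}(X)\,\mathrm{dVar}(Y)}}} \in [0, 1].$$

This is the plain V-statistic estimator; the bias-corrected variant and the
fast $O(n\log n)$ univariate algorithm are deliberately out of scope — sample
sizes in the target domain are tens to low hundreds, where the $O(n^2)$
computation is instantaneous and the V-statistic is the conventional choice.

Three analysis modes are provided:

* **one-to-one** — dCor for every pair of features;
* **one-to-all** — dCor between each feature's distance structure and the
  *joint* Euclidean distance structure of all remaining features in
  $(m-1)$-dimensional space, a per-feature summary of embeddedness in the
  global dependence structure;
* **partial** — partial correlations from the Gaussian-graphical-model route:
  the $m \times m$ distance covariance matrix $\Sigma$
  ($\Sigma_{ij} = \mathrm{dCov}(X_i, X_j)$, diagonal $\mathrm{dVar}$) is
  pseudo-inverted to a precision matrix $\omega = \Sigma^{+}$, and
  $\rho_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\omega_{jj}}$.

Significance for dCor uses the Student-$t$ construction
$t = \mathrm{dCor}\sqrt{n-2}/\sqrt{1-\mathrm{dCor}^2}$ with $n-2$ degrees of
freedom and two-sided $p = 2(1 - F_t(t))$. Because dCor is non-negative,
$t \ge 0$ always and the doubling is kept literally. This formula is borrowed
from the Pearson test; we make no claim that it is calibrated under
independence (the permutation-based energy test would be the calibrated
alternative and is intentionally not implemented). Partial correlations get
Fisher-z p-values: $z = \operatorname{arctanh}(\rho)$,
$p = 2(1 - \Phi(|z|\sqrt{N - M - 1}))$ with $N$ samples and $M$ features.

## Design choices in the open corners

Several details of the method admit more than one reading; the choices below
are fixed and, where reasonable, switchable:

* **One-to-all metric.** The joint distance is the true Euclidean norm in
  $(m-1)$-space (square root of the summed squared per-feature differences).
  The squared-Euclidean variant would silently change the metric and is
  rejected.
* **Fisher degrees of freedom.** The multiplier on $z$ is
  $\sqrt{N - M - 1}$ — the standard Fisher approximation. The un-rooted
  product $z \cdot (N - M - 1)$ is dimensionally implausible but remains
  available via `df_exponent = 1` for sensitivity analysis. $M$ counts all
  features of the matrix (not only the $M-2$ controlled covariates); this is
  the conservative choice and is also switchable by passing a different `M`
  to `fisher_pvalue()`.
* **Sign of $z$.** $|z|$ is used inside $\Phi$ so that strong *negative*
  partials are flagged significant too.
* **Sign tie-break.** A Pearson correlation with $|r| < 10^{-15}$ (e.g. a
  perfectly symmetric quadratic) resolves to sign $+1$, making the signed
  value deterministic.
* **One-to-all sign.** The pairwise sign rule does not directly apply when
  the second argument is a feature block; the sign is taken from the Pearson
  correlation between the feature and the per-sample mean of the other
  features, reported as a convention, and the unsigned `dcor` column is
  always present.
* **z-scoring.** Applied automatically per feature (column) with the sample
  standard deviation ($n-1$). dCor is invariant to affine rescaling of either
  variable, so this choice does not alter dCor values; it does affect the
  joint one-to-all distances (it equalizes feature scales, which is the
  intent) and the covariance scale of $\Sigma$ (partial $\rho$ is invariant
  to a global rescaling of $\Sigma$).
* **Σ from covariances, not correlations.** The partial model inverts the
  distance *covariance* matrix; inverting the dCor matrix instead is exposed
  as `use_dcor = TRUE` for sensitivity analysis only.
* **Orientation.** Rows are samples, columns are features; `transpose = TRUE`
  handles tables stored the other way.

## Numerical policy

* Squared distance covariances can come out marginally negative in floating
  point; magnitudes below $10^{-12}$ are clamped to zero, anything larger
  raises an internal-consistency error rather than being hidden.
* dCor values are clamped into $[0,1]$; for valid inputs the clamp never
  moves a value by more than $10^{-12}$.
* The pseudo-inverse truncates singular values below
  $10^{-12} \times \sigma_{\max}$ (configurable via `tol`); for non-singular
  $\Sigma$ it agrees with direct inversion to $10^{-8}$.
* Constant (zero-variance) features make $\mathrm{dVar} = 0$ and dCor
  undefined; they are flagged and excluded from every pairwise computation
  with a warning, never zero-filled and never a hard error for the whole run.
* Missing cells are a hard error listing every offending
  (sample, feature) coordinate; imputation is the user's responsibility and
  no imputation is built in.
* Partial correlations with $m \ge n$ features sit on a rank-deficient
  $\Sigma$; the run refuses unless `override_feature_guard = TRUE`, and then
  proceeds with a warning.

## What the synthetic generator emulates — and what it does not

`simulate_scenario()` produces seeded samples-by-features tables with known
dependence structure: i.i.d. noise, linear, quadratic, sinusoidal and
circular pairs, and two multivariate-normal graphs — a Markov chain
(adjacent correlation 0.7, the conventional "strong but not degenerate"
setting for structure-recovery benchmarks) and a hub (hub-leaf correlation
0.7, leaves conditionally independent given the hub). The RNG is pinned to
Mersenne-Twister with inversion normals so a seed reproduces a fixture
bit-for-bit. Default problem sizes (50 samples, 5 features; 200 samples for
the graph-recovery properties, 50 replicates) were chosen to match the
tens-of-samples scale of metabolomics studies while keeping estimator noise
well below the effects being detected.

The generator deliberately does *not* mimic real lipidomic intensity
distributions: no log-normal abundances, no heteroscedastic measurement
error, no batch effects, no missing-not-at-random patterns (its missing-cell
defects are uniform, for error-path testing only). Passing tests therefore
demonstrate the estimators' algebraic and statistical correctness under
clean Gaussian-and-deterministic structure, not robustness to the full
messiness of instrument data.

## Limitations

* The $t$-based dCor p-value is a pragmatic analogue, not a calibrated test;
  for inference-critical edges a permutation test should be preferred.
* The GGM partial correlation removes *linear* contributions of the other
  features from the distance-covariance structure; it is not the
  projection-based partial distance correlation, and it inherits the
  Gaussian-graphical reading of zeros in the precision matrix.
* Unequal-length vectors are not supported; all features must be observed in
  the same samples.
* With many features the one-to-one mode is $O(m^2 n^2)$ time and
  $O(m n^2)$ memory (distance matrices are cached per feature, with results
  contractually identical to uncached computation).

## A worked run

```{r example}
rt <- simulate_scenario("gaussian_chain", n_samples = 200, n_features = 3,
                        seed = 1)
sidcor_run(rt, mode = "one_to_one", quiet = TRUE)[,
  c("feature_a", "feature_b", "signed_dcor", "p_dcor")]
sidcor_run(rt, mode = "partial", quiet = TRUE)
```

The chain's conditional independence of F1 and F3 given F2 is visible only
in the partial mode: the marginal distance correlation of the (F1, F3) pair
is sizable, while its partial correlation collapses towards zero.
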