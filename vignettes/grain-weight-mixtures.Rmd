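---
title: "Gamma-mixture grain weight distributions and their genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-mixture grain weight distributions and their genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainfill)
```

## The model

A rice panicle carries a mix of filled grains — which reach close to the
cultivar's attainable ("sink capacity") weight — and unfilled or partially
filled grains. The single-grain weight distribution is therefore typically
bimodal, and its shape carries information about a cultivar's grain-filling
ability that scalar summaries (mean weight, a fixed unfilled-grain
threshold) miss. `grainfill` models the density of a single grain weight
$x$ (mg) as a two-component gamma mixture,

$$
f(x) = p\,\Gamma(x;\,a_1, b_1) + (1 - p)\,\Gamma(x;\,a_2, b_2),
$$

with mixing proportion $p$ (the unfilled fraction), shapes $a_1, a_2$ and
scales $b_1, b_2$ (mg). Components are always labeled so the left
(unfilled) component has the smaller mean, $a_1 b_1 \le a_2 b_2$; the EM
likelihood is symmetric under relabeling, so a deterministic rule is
required. Gamma components keep the support positive and let the left
component be strongly right-skewed, which Gaussian mixtures cannot do
without leaking mass below zero.

Because raw shape/scale values are hard to read, four *feature values*
summarize a fit: `mode1` $= \max((a_1-1)b_1, 0)$, `skewness1`
$= 2/\sqrt{b_1}$, `mu2` $= a_2 b_2$, and `var2` $= a_2 b_2^2$. The
skewness convention follows the field literature this package targets and
uses the scale parameter; the textbook gamma skewness $2/\sqrt{a_1}$ is
exposed via `feature_values(..., skewness = "shape")` since the two differ
and readers may expect either.

## Fitting: EM with Minka's gamma updates

`fit_with_restarts()` maximizes the mixture likelihood by EM. The E-step
computes left-component responsibilities in log space; the M-step sets $p$
to the mean responsibility and refits each component by weighted gamma
maximum likelihood (`weighted_gamma_mle()`), solving
$\ln\hat a - \psi(\hat a) = \ln \bar x_w - \overline{\ln x}_w$ with
Minka's generalized-Newton fixed-point iteration on $1/a$ (converging to
$|\Delta \ln a| < 10^{-10}$, with a bisection fallback), then
$\hat b = \bar x_w / \hat a$.

Initialization follows a moment-matched draw: $p_0 = 0.5$; two distinct
grain weights $x'$ are sampled without replacement and each seeds one
component with $a_0 = x'^2/\mathrm{Var}(x)$, $b_0 = \mathrm{Var}(x)/x'$
(so the component mean starts at the sampled weight); the lighter draw
seeds the left component. Tied draws are redrawn. Because the likelihood
surface is multimodal, the fit is restarted from independent draws — 100
by default in production (`fit_cultivars()`, the CLI), fewer in tests —
and the converged restart with the highest log-likelihood wins. On
well-separated data, essentially all restarts reach the same optimum; the
spread of restart log-likelihoods (`restart_logliks`) is the practical
convergence diagnostic.

Numerical choices: EM stops when the log-likelihood gain drops below
$10^{-8}$ or after 1000 iterations (the likelihood is checked to be
non-decreasing to $10^{-9}$ slack every iteration). Weights at or below a
0.1 mg floor are excluded before fitting and counted (`n_excluded_zero`):
gamma support excludes zero, and 0-mg balance readings would make the
likelihood infinite. Cultivars with fewer than 50 retained grains are
flagged rather than fit. All replicate panicles of a cultivar are pooled
before fitting.

## Boundary analysis and grain classification

The *boundary point* is the interior density minimum between the two
component modes — the weight that best separates unfilled from filled
grains. `boundary_analysis()` scans a 10^4^-point grid on
$[\max(\text{mode1}, \varepsilon), (a_2-1)b_2]$ and refines the bracketing
cell by golden-section search; a 10^6^-point brute-force scan agrees to
well under 0.01 mg. The probability mass within ±0.1 mg of the boundary
(*boundary probability*), the same mass around the right-component mode,
and their ratio quantify how distinguishable the two grain classes are.
When the right component has no interior mode ($a_2 \le 1$) or the density
is monotone between the modes, the mixture is flagged `bimodal = FALSE`
and the boundary fields are `NA` — a unimodal fit is a legitimate outcome,
not an error.

Individual grains (e.g. superior/inferior positional grains) are
classified by the posterior probability of the filled component,
$(1-p)f_2(x)/f(x) > 0.5$ (`posterior_filled()`,
`positional_classification_summary()`).

## Conventional traits

For comparison with breeding practice, `conventional_traits()` computes:
the fraction of grains strictly below 23 mg (`p_23mg`; the threshold is a
flag because a single cut-off confounds grain size with filling); the
fraction below 90% of the cultivar's own 95th-percentile weight
(`p_90pct`); and the sink-filling rate, total grain weight over
(95th-percentile weight × grain count). Percentiles use linear
interpolation of order statistics (`stats::quantile` type 7) — the
convention matters for reproducibility and is therefore fixed and
documented. "Lighter than" is strict.

## Distances between distribution shapes

The squared L2 distance between two mixtures has a closed form built from
two kernels: the self-energy
$g(\alpha, \beta) = \int \Gamma(x;\alpha,\beta)^2\,dx =
2^{1-2\alpha} / ((2\alpha - 1)\,\beta\,B(\alpha,\alpha))$
(finite only for $\alpha > 1/2$) and twice the cross-energy
$h(\alpha_1,\alpha_2,\beta_1,\beta_2) = 2\beta_1^{\alpha_2-1}
\beta_2^{\alpha_1-1} / ((\alpha_1{+}\alpha_2{-}1)
(\beta_1{+}\beta_2)^{\alpha_1+\alpha_2-1} B(\alpha_1,\alpha_2))$
(finite for $\alpha_1 + \alpha_2 > 1$). Both are evaluated in log space:
filled-grain components are routinely fit with shapes near 100, where
naive powers overflow.

`squared_l2_distance()` expands
$\int (p f_1 + q f_2 - \hat p \hat f_1 - \hat q \hat f_2)^2$ termwise
($q = 1-p$). The expansion was re-derived from the algebraic square rather
than transcribed: each *within*-density cross term enters with a **plus**
sign, including the predicted-density term
$+\hat p \hat q\, h(\hat a_1, \hat a_2, \hat b_1, \hat b_2)$ — a sign on
which typeset sources are easy to get wrong. Every term was validated
against adaptive quadrature; the test suite includes a check that flipping
that final sign produces detectable disagreement with quadrature. Tiny
negative totals from floating-point cancellation are clamped to zero.
Fitted shapes at or below 0.5 abort with a clear message rather than
returning infinity: they indicate a degenerate fit upstream, and silence
would hide it.

Over a cultivar population, `press()` sums the squared distances between
observed and predicted densities, and `q2_shape()` normalizes:
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{PRESS}_0$, where $\mathrm{PRESS}_0$
predicts every cultivar by the mixture built from the per-parameter means
of the observed population. $Q^2 = 1$ is perfect, $0$ matches the
mean-parameter predictor, and negative values (worse than the mean) are
reported unclamped.

## Genomic prediction

Markers are biallelic codes (−1 reference homozygote, 0 heterozygote, +1
alternate homozygote). `filter_markers()` drops markers with missing
calls, heterozygote fraction ≥ 5% (cultivars are assumed essentially
fixed), monomorphic columns, minor allele frequency < 0.025
(heterozygotes count half), and exact-duplicate columns including
sign-flipped ones (complete linkage; no r² threshold is imposed because
none is defined for this pipeline). `genomic_relationship()` builds the
VanRaden method-1 GRM, $K = ZZ^\top / (2\sum_k p_k(1-p_k))$ on centered
codes. Any positive rescaling of $K$ is prediction-equivalent — the
variance ratio re-estimates compensate — and this invariance is tested.

**GBLUP.** `gblup_fit()` fits $y = 1\mu + g + e$,
$g \sim N(0, \sigma_g^2 K)$, by REML, profiling the likelihood on
$\lambda = \sigma_g^2/\sigma_e^2$ via the spectral decomposition of $K$
(one eigendecomposition; each candidate ratio costs $O(n)$). The ratio is
located on a 201-point grid over $\log\lambda \in [-20, 20]$ plus
golden-section refinement; the wide grid matters because at the
no-signal boundary a clamped edge value would break the rescaling
invariance of predictions. Held-out cultivars are predicted by
$\hat\mu + K_{\text{new,train}}\,\alpha$ with
$\alpha = \lambda(\lambda K + I)^{-1}(y - \hat\mu)$.

The reported genetic variance is per cultivar,
$\sigma_g^2 \cdot \overline{\mathrm{diag}(K)}$, so the narrow-sense
heritability $h^2 = \sigma_g^2/(\sigma_g^2 + \sigma_e^2)$ is invariant to
the GRM's scale. This matters concretely: for a fully inbred ±1 panel the
VanRaden matrix has mean diagonal near 2, and without the correction a
simulated $h^2 = 0.5$ is systematically reported as ≈ 0.36.

**PLS.** `pls_fit()` is NIPALS PLS2: successive orthogonal score vectors
maximizing covariance with the response block; centered, unscaled by
default (per-column scaling is an option because the five parameters
differ by orders of magnitude — and the unscaled default means the
right-component shape, with the largest variance, dominates pooled
models, reproducing the characteristic near-identity of the one-group and
three-group schemes on $a_2, b_2$). Three grouping schemes are offered:
one model for all five parameters (`pls1`), three models for $\{p\}$,
$\{a_1,b_1\}$, $\{a_2,b_2\}$ (`pls3`), and one model per parameter
(`plsE`).

**Component selection.** The number of PLS components (≤ 30) is chosen by
leave-one-out shape $Q^2$: candidate counts are scored by the $Q^2$ of
the LOO-predicted mixture population, with parameters outside the model
under selection held at their observed values so the criterion isolates
that model; ties break toward fewer components. Two protocols are
offered: `select = "per-fold"` (the default) repeats selection inside
every outer LOO fold, so the held-out cultivar never influences its own
component count; `select = "global"` selects once on the full set — the
protocol the original study describes, retained for fidelity and because
it is roughly two orders of magnitude cheaper.

**Evaluation.** `run_prediction_experiment()` reports, per scheme,
Pearson accuracies of fitted (training) and LOO-predicted values for the
five parameters; derived traits evaluated by plugging predicted
parameters into their formulas (`mode1`, `skewness1`, `mu2`, `var2`,
boundary point/probability, plug-in `p23mg` = $F(23)$, `p90pct`,
sink-filling rate = mean/$q_{95}$); for GBLUP additionally the direct
route — a separate model per trait value — mirroring the parenthesized
accuracies of the conventional reporting layout; and PRESS/$Q^2$ of the
fitted and predicted populations. Predicted parameter vectors are
unconstrained linear outputs, so before any density-based evaluation they
are clamped into the mixture domain ($p \in [0,1]$, shapes ≥ 0.55, scales
≥ 10^{-4}); clamping is deliberately mild and only guards the $g/h$
domain conditions.

Negative LOO accuracies occur and are reported as computed. They are a
real artifact of leave-one-out with near-null signal: as
$\sigma_g^2 \to 0$ the held-out prediction approaches the training mean
$(S - y_i)/(n-1)$, which is perfectly anti-correlated with $y_i$, so
weakly heritable traits can show substantially negative correlations.

## The synthetic-data generator

`make_dataset()` generates the complete study design so every stage is
testable without field or sequencing data: an inbred marker panel (codes
±1, allele frequencies uniform on MAF 0.05–0.5, independent markers; a
heterozygosity rate and duplicated columns can be switched on to exercise
the filters), additively heritable mixture parameters, and per-cultivar
grain weights drawn from each cultivar's mixture with membership labels
retained.

Parameters are made heritable on link scales — logit for $p$, log for
shapes and scales — around baselines chosen to match the regime the
package targets: unfilled fraction centered at 0.175, unfilled component
$a_1 = 1.5, b_1 = 4$ (mean 6 mg, right-skewed), filled component
$a_2 = 100, b_2 = 0.25$ (mean 25 mg, SD 2.5 mg). All five parameters
share one causal-marker set with independent effect sizes, which induces
genetic correlation among parameters as observed in real panels. Effects
are rescaled so the genetic share of the latent variance equals the
target $h^2$ exactly in-sample. Latent total SDs (0.45 logit for $p$;
0.25, 0.25, 0.2, 0.12 log for $a_1, b_1, a_2, b_2$) give realized
parameter spreads comparable to a diverse cultivar panel.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: linkage disequilibrium and population
structure (markers are independent, so there is no LD decay and no
kinship clusters), genotype-by-environment interaction, panicle
architecture (superior/inferior position effects must be injected
explicitly in tests), measurement rounding, and non-additive genetic
effects. Results on simulated data bound what the machinery can do under
its own assumptions; they are not field validation.

## Problem sizes and runtime choices

The test and verification suites use scaled-down but structurally
faithful configurations, chosen as a balance between statistical power
and a suite that runs in minutes: EM recovery uses 20 cultivars × 4000
grains with 10 restarts; REML calibration uses 20 replicates of 300
cultivars × 2000 markers; the heritability-response sweep uses 20
replicates × 3 levels at 150 cultivars × 500 markers; the acceptance
script simulates 100 cultivars × 800 markers × 1200 grains with 20
restarts and global component selection. The production defaults (100 EM
restarts, per-fold selection) remain the package defaults.

## Known limitations

- Exactly two components: unimodal-vs-bimodal model selection and k > 2
  mixtures are out of scope; flat or unimodal real distributions fit as
  heavily overlapping components and are flagged only via the boundary
  analysis.
- The L2 geometry requires all shapes > 0.5; degenerate fits must be
  resolved upstream rather than smoothed over.
- The LOO mean artifact makes accuracy near zero hard to interpret;
  PRESS/$Q^2$ on the full density is the more stable shape-level metric.
- `filter_markers`' complete-linkage rule removes only exact duplicates;
  thinning by an r² threshold is a different operation, deliberately not
  implied.
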