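# grainfill

Distribution-valued phenotyping of rice grain filling, and genomic
prediction of the resulting parameters.

## What problem this solves

The single-grain weight distribution of a rice panicle is typically
bimodal: a right-skewed cluster of unfilled/partially filled grains and a
sharp cluster of filled grains near the cultivar's sink capacity. Scalar
summaries (mean weight, a fixed 23 mg threshold) lose this structure.
`grainfill` is for quantitative geneticists and breeders who want to

1. describe each cultivar's grain weight density as a two-component gamma
   mixture

   f(x) = p Γ(x; a₁, b₁) + (1 − p) Γ(x; a₂, b₂),

   with genotype-specific parameters (p, a₁, b₁, a₂, b₂) estimated by
   multi-restart EM with Minka's fixed-point gamma MLE updates;
2. derive interpretable grain-filling statistics: mode1 = (a₁−1)b₁,
   skewness1 = 2/√b₁, mu2 = a₂b₂, var2 = a₂b₂², the boundary point (the
   density minimum separating unfilled from filled grains) and its ±0.1 mg
   probability mass, posterior filled/unfilled classification of
   individual grains, and conventional traits (p.23mg, p.90%,
   sink-filling rate);
3. measure distances between whole distribution shapes in closed form:
   the squared-L2 distance between two gamma mixtures via beta-function
   kernels, summed into PRESS over a population and normalized into a
   shape-level Q² skill score (1 = perfect, 0 = mean-parameter predictor);
4. predict the five parameters from genome-wide biallelic markers:
   VanRaden genomic relationship, GBLUP with REML variance components
   (narrow-sense heritabilities included), and multi-response NIPALS PLS
   in three grouping schemes — all evaluated by leave-one-out
   cross-validation with component selection by shape Q²;
5. simulate the whole study design (inbred marker panel, additively
   heritable mixture parameters with tunable h², grain-weight samples) so
   every stage is testable without field or sequencing data.

## Worked example

```r
library(grainfill)

truth <- mixture_params(0.175, 1.5, 4, 100, 0.25)   # typical cultivar
w <- simulate_grain_weights(truth, 2000, seed = 42)$weights
fit <- fit_with_restarts(grain_sample(w, "Koshihikari-like"),
                         n_restarts = 20, seed = 1)
fit$params
#> gamma mixture: p = 0.1762 | left (a1 = 1.577, b1 = 3.847, mean 6.066 mg)
#>                | right (a2 = 99.85, b2 = 0.251, mean 25.07 mg)
```

The fitted mixing proportion (p = 0.176 vs true 0.175) says 17.6% of
grains sit in the unfilled component. The derived statistics:

```r
feature_values(fit$params)
#> mode1 = 2.22 mg, skewness1 = 1.02, mu2 = 25.07 mg, var2 = 6.29 mg^2
boundary_analysis(fit$params)
#> boundary point = 16.82 mg, boundary probability = 0.00034, ratio = 0.0129
```

Filled grains average 25.07 mg with variance 6.29 mg²; grains are
classified unfilled/filled at 16.82 mg, and the near-zero boundary
probability (0.03% of mass within ±0.1 mg of it) means the two classes
are cleanly separated. Conventional traits from the same sample:

```r
c(p_23mg(w), p_90pct(w), sink_filling_rate(w))
#> p23mg = 0.346, p90pct = 0.723, sink-filling rate = 0.749
```

For the genomic layer, `make_dataset(sim_config(...))` produces markers,
true parameters and grain weights; `fit_cultivars()` fits every cultivar;
`run_prediction_experiment()` runs GBLUP and the three PLS schemes with
leave-one-out cross-validation and reports accuracies, PRESS, Q², and
heritabilities (`write_report_json()` serializes the report).

A command-line interface wrapping the same functions ships at
`inst/cli/grainfill.R` with subcommands `simulate`, `fit`, `traits`,
`predict`, `report`.

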