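---
title: "Surrogate modelling and multi-objective optimization of ultrasound-assisted extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modelling and multi-objective optimization of ultrasound-assisted extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(uaeopt)
library(dplyr)
```

## The problem

Ultrasound-assisted extraction (UAE) recovers phenolics, flavonoids and other
bioactive constituents from plant by-products such as strawberry pomace.
Three process factors dominate the outcome: sonication time (minutes), bath
temperature (°C), and the sample-to-solvent ratio (mL of solvent per gram of
material, the `R` of a `1:R g/mL` ratio). A campaign varies these factors over
a design and measures, for each extract, a panel of bioactivity responses —
here thirteen: total phenolic and flavonoid content (TPC, TFC), six
antioxidant assays (DPPH, ABTS, CUPRAC, FRAP, metal chelation, and the
phosphomolybdenum assay) and five enzyme-inhibition assays (AChE, BChE,
tyrosinase, α-amylase, α-glucosidase), each in equivalents of its reference
standard per gram.

The package bundles one such campaign — a 15-run incomplete factorial with
triplicate means and SDs over time ∈ {10, 20, 30} min, temperature ∈
{25, 50, 75} °C, ratio ∈ {10, 15, 20} mL/g — together with the three
published multilayer-perceptron (MLP) surrogates fitted to it, and
implements the full analysis chain: surrogate training, formula-defined
validation statistics, chemometrics, Pareto optimization, and
standard-score ranking.

```{r}
design <- load_design()
responses <- load_responses()
design
```

## The surrogate model

Each surrogate is a single-hidden-layer perceptron

$$ Y = g\big(W_2\, f(W_1 X + B_1) + B_2\big), $$

with $X$ the three scaled process factors, $f$ the hidden activation, $g$
the output activation, and $(W_1, B_1, W_2, B_2)$ the weights and biases.
Three architectures partition the responses: 3-9-2 (tanh/identity; TPC,
TFC), 3-10-6 (tanh/tanh; the antioxidant assays) and 3-10-5
(logistic/identity; the enzyme-inhibition assays).

Training minimizes the sum-of-squares loss on the training partition with
BFGS, under a protocol tuned to the extreme scarcity of data (15 runs):

* **Scaling.** Inputs are min-max scaled to [0, 1]. Outputs are scaled to
  the codomain of the output activation: [0, 1] for identity outputs and
  [−1, 1] for tanh. The original study normalized both sides but did not
  record the convention; [0, 1] inputs were adopted because the published
  ANN1 weights, evaluated under that convention, rank-correlate strongly
  (Spearman ≈ 0.94) with the measured TPC, against ≈ 0.4 under [−1, 1].
  Scalers extrapolate linearly outside the fitted range — never clip — so
  optimizers may probe the box edges.
* **Split.** Samples are shuffled (seeded) into 60/20/20
  training/testing/validation partitions; 15 samples give 9/3/3.
* **Early stopping.** The optimizer is capped at 70 iterations
  (`early_stop_epoch`), the point beyond which training on this data begins
  to memorize noise; the hard cap is 100.
* **Restarts.** Weights start uniform in [−0.5, 0.5] with a
  restart-indexed seed; the restart with the best training r² wins. The
  default is 200 restarts — a desk-scale stand-in for the exhaustive
  100,000-configuration search used originally, with identical
  best-of-restarts semantics. Because restart *k* always draws the same
  initialization for a given seed, adding restarts can only improve the
  selected fit.

```{r}
fit <- mlp_train(design, responses, hidden = 9, outputs = c("TPC", "TFC"),
                 control = train_control(restarts = 50, seed = 1))
glance(fit)
```

With ~50 free parameters against 9 training points these networks
interpolate: training r² reaches 1 while held-out r² is erratic (see
*Limitations*). The analyses that matter downstream — ranking and optimum
readout — are therefore run on measured responses by default, with the
surrogate path available for prediction and optimization.

`sweep_hidden_sizes()` reproduces the hidden-layer-size selection (training
r² against size, smallest size at the maximum recommended), and
`load_published_model()` gives the published weight matrices directly for
forward evaluation with `predict()`.

## Validation statistics

`fit_report()` applies the study's validation battery per response: reduced
chi-square $\chi^2 = \mathrm{SSE}/(N - n)$, RMSE, mean bias error, mean
percentage error, SSE, absolute average relative deviation, and r². Two
conventions needed fixing from the published numbers themselves:

* **`n_constants = 2`.** The published table's SSE-to-χ² ratios equal
  13 = 15 − 2 across rows, pinning the `n` subtracted in the reduced
  chi-square at 2.
* **AARD in percent.** The published TPC AARD of 0.975 is implausible as a
  fraction (97.5%) next to an MPE of 0.557%, and plausible as 0.975%; AARD
  is therefore reported ×100, like MPE.

One published row is internally inconsistent: the ABTS SSE (1.072)
disagrees with its own RMSE (15·0.291² = 1.270) and χ² (0.097·13 = 1.261)
far beyond rounding; the test suite documents this rather than hiding it.

## Chemometrics

* `correlation_matrix()` — pairwise Pearson correlation with two-sided
  significance across the 15 samples.
* `pca_responses()` — PCA of the standardized responses, i.e. of the
  correlation matrix. Standardization is the only defensible default here
  because the thirteen responses carry heterogeneous units; it also
  reproduces the published variance split (PC1 ≈ 46%, PC2 ≈ 16%).
  Components are sign-fixed so each loading vector's largest-magnitude
  entry is positive.
* `hcluster_responses()` — complete-linkage agglomerative clustering on
  City-block (Manhattan) distances over the **raw** response means. Raw
  units are deliberate: merge heights are then sums of absolute response
  differences, which is the scale on which the best extract separates from
  the rest at a linkage distance above 100. (Standardized columns could
  never reach such heights.)

```{r}
pca_responses(responses)
hcluster_responses(responses)
```

### A corrected transcription error

The bundled response table is stored exactly as published, with one
documented exception applied at load time: the metal-chelation value of
sample 15 is printed as 8.611, yet its own significance letter group
contains only values between roughly 17.4 and 18.5, and the published PCA
percentages are reproduced only with 18.611 — a dropped leading digit.
`load_responses(corrected = FALSE)` returns the verbatim table;
the correction affects that single cell and nothing else.

## Ranking and optimization

`zscore_rank()` collapses the thirteen responses into one score per sample.
Two conventions are implemented:

* `method = "minmax"` (default): each response is rescaled to [0, 1] over
  the samples and averaged. This unit-interval "standard score" is the
  convention behind the published combined score of 0.794 for the best
  extract (the package computes 0.797 on the corrected table).
* `method = "zscore"`: classic standard scores (x − mean)/SD, with a
  sample/population SD switch (the two differ by √(14/15) at n = 15).

All conventions agree on the ranking itself; sample 6 — 20 min, 50 °C,
1:20 g/mL — is first under every one. By default all thirteen responses are
treated as maximize (higher bioactivity is better); `senses` can flip
individual responses (e.g. `c("alpha-amylase" = "min")`) when a response is
undesirable for a given application.

`ga_optimize()` runs an NSGA-II style genetic algorithm over the factor box
with the surrogates as objective functions: simulated binary crossover
(η = 15), polynomial mutation (η = 20, rate 1/3), binary tournament on
(front rank, crowding distance), elitist truncation, population 100, and a
front cap of 50 enforced by crowding-distance thinning that keeps objective
extremes. Runs stop once the front has not changed for 20 generations (or
at the hard cap of 200); the published generation counts (88, 69, 84) are
treated as outcomes of such a convergence rule, not as inputs.
`select_optimum()` then scores the front (or the measured campaign) and
returns the winning condition with its responses.

```{r}
select_optimum(responses, design = design)[, 1:7]
```

## The synthetic campaign generator

`surface_spec()` defines, per response, a full quadratic in the three
factors (intercept, linear, pure quadratic, pairwise interactions) plus
independent Gaussian replicate noise; `simulate_responses()` reports the
mean and SD of `n_replicates = 3` noisy evaluations per design point,
mirroring a triplicate wet-lab campaign. The quadratic-with-interactions
family is the simplest one that can exhibit an interior optimum like the
campaign's, and an MLP can approximate it closely — which is what makes
end-to-end parameter-recovery tests meaningful.

`default_surface_spec()` calibrates the generator against the bundled
campaign at call time: least-squares quadratic fits to the 15 response
means, then a per-response affine rescale so that the surface's range over
the design equals the measured range exactly (least squares alone flattens
the best run's spike), with replicate noise set to each response's median
printed SD. The calibration is deterministic.

What the generator does **not** emulate: replicate correlation across
responses (noise is independent; nothing in the data constrains it),
non-Gaussian measurement error, and any extraction kinetics — it is a
statistical stand-in, so passing recovery tests demonstrate that the
pipeline recovers optima of smooth noisy surfaces, not that it models
extraction chemistry.

`true_optimum()` is the oracle for those tests: a dense grid argmax of the
noiseless surface with lexicographic tie-breaking (lowest time, then
temperature, then ratio).

## Numerical choices and problem sizes

* Degenerate inputs: constant columns min-max scale to the interval
  midpoint and z-score to 0 (with a warning); constant responses contribute
  0 to rankings and are flagged; relative error metrics refuse zero
  experimental values, naming the index.
* Dominance is non-strict on ties, so duplicated candidates never eliminate
  each other and the front is stable as a set.
* Dendrogram merge tables use the `stats::hclust()` convention (negative
  ids are leaves); tie-breaking follows its smallest-index-first order.
* The test suite runs the recovery experiment at desk scale: 27-run
  campaigns, 20 seeded repetitions, 12 restarts of a 6-neuron network, GA
  population 30 — sizes chosen so the full suite completes in well under a
  minute of compute per experiment while keeping the statistics stable.
  The acceptance refit uses the full protocol (200 restarts per
  architecture).

## Limitations

* **Generalization of the surrogates.** Selected by training r² on 9
  points, the networks interpolate; their held-out r² varies widely from
  seed to seed (median ≈ 0.8 on synthetic quadratic campaigns, far worse on
  some splits). The published near-unity testing/validation performances
  could not be reproduced under any scaling convention tried, and nothing
  in this package claims them.
* **Published-weight forward passes** reproduce rankings, not values: the
  original normalization is unrecorded, so predictions from
  `load_published_model()` are useful directionally (Spearman ≈ 0.9
  against measured TPC) but are not the published fitted values.
* **The combined-score convention** had to be reverse-identified from the
  published score itself; both conventions are exposed and agree on the
  ranking, but only the unit-interval score reproduces 0.794.
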