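---
title: "Uncertainty-aware genomic prediction of athletic potential: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware genomic prediction of athletic potential: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapred)
```

## The problem

`gapred` predicts a continuous *athletic potential score* — the
standardized mean of three z-scored physical indicators (speed, endurance,
strength) — from high-dimensional genotype dosages, while quantifying how
much each prediction should be trusted. Three features distinguish it from
a plain regression:

* a **manifold constraint**: individuals with similar genotypes should
  receive nearby latent representations and nearby predictions;
* a **heteroscedastic likelihood**: observation noise varies across
  individuals, so the model predicts a per-individual variance alongside
  the mean;
* a **Monte-Carlo dropout posterior**: repeated stochastic forward passes
  decompose predictive variance into an aleatoric part (irreducible noise,
  the predicted \(\sigma^2_i\)) and an epistemic part (model uncertainty,
  the spread of the per-pass means).

Because the cohorts this class of model is built for are managed-access
resources, the package ships a first-class synthetic cohort simulator that
reproduces the statistical structure the method assumes, so every stage is
testable end to end without any external data.

## The model

Given a normalized feature matrix \(X \in \mathbb{R}^{n\times d}\), the
predictor is a three-stage network:

1. **Encoder**: a linear embedding to 128 units, then three stacked layers
   (linear → layer normalization → ReLU → dropout) of widths 256, 128 and
   64, producing the latent matrix \(Z\).
2. **Planner**: a two-layer MLP (hidden width 128) mapping \(Z\) to an
   action matrix \(A \in \mathbb{R}^{n\times 3}\), one action per
   capability component. The planner's reward is realized as a loss,
   \(L_{\text{reward}} = \frac{1}{3n}\sum_i \lVert A_i - y^{(3)}_i
   \rVert^2\), pulling actions toward the observed standardized
   indicators; this is auxiliary multi-task supervision that anchors the
   intermediate representation to interpretable components.
3. **Forecaster**: a shared ReLU trunk on \(A\) with two affine heads
   emitting the mean \(\mu_i\) and the log-variance \(\log\sigma^2_i\);
   \(\sigma^2_i = e^{\log\sigma^2_i}\) clamped to
   \([10^{-6}, 10^{6}]\).

The training objective combines four terms:

\[
L = \underbrace{\tfrac{1}{n}\sum_i \Big[\tfrac{(y_i-\mu_i)^2}{2\sigma_i^2}
 + \tfrac12\log\sigma_i^2\Big]}_{\text{Gaussian NLL}}
 + \lambda_m \underbrace{\tfrac{1}{|E|}\sum_{(i,j)} C_{ij}\lVert Z_i-Z_j
 \rVert^2}_{\text{manifold}}
 + \lambda_r L_{\text{reward}}
 + \lambda_c \underbrace{\tfrac{\sum_{(i,j)} C_{ij}(\mu_i-\mu_j)^2}
 {\sum_{(i,j)} C_{ij}}}_{\text{smoothness}}
\]

where the graph sums run over ordered pairs without the diagonal (each
undirected edge counted twice), and \(C\) is a k-nearest-neighbour graph
(default \(k=10\)) on the normalized genotype features with Gaussian
kernel weights \(C_{ij} = \exp(-d_{ij}^2/2h^2)\), bandwidth \(h\) set to
the median kNN distance. A standalone variance-sum penalty is *not* used
as an objective: minimizing \(\sum_i \sigma_i^2\) alone drives every
variance to the floor, whereas the \(\tfrac12\log\sigma^2\) term of the
NLL already regulates over- and under-confidence in both directions.

Hard constraints of the conceptual formulation are realized exclusively as
these soft penalties; either of the two composite-objective variants in
the conceptual description is recoverable by zeroing weights.

### Numerical and design choices

* **Edge normalization.** Both graph penalties are normalized (manifold by
  the ordered-edge count, smoothness by the total weight) so that the
  \(\lambda\) coefficients remain comparable across cohort sizes and
  neighbourhood sizes. Defaults are \(\lambda_m = 0.1\) (the stated
  regularization coefficient) and \(\lambda_r = \lambda_c = 0.1\), the
  same order, since only the manifold coefficient is pinned externally.
* **Graph-penalty warm-up.** A Laplacian-type penalty is globally
  minimized by a *collapsed* embedding (all \(Z_i\) equal, all \(\mu_i\)
  equal). If applied at full strength from the first step, it can trap the
  encoder in that degenerate optimum before the data term has
  differentiated individuals — we observed exactly this failure on harder
  signal structures. The training loop therefore ramps
  \(\lambda_m, \lambda_c\) linearly from 0 to their full values over the
  first quarter of training (`graph_warmup = 0.25`), the standard guard
  used for consistency-style regularizers.
* **Batch subgraphs.** Each minibatch uses the similarity subgraph induced
  on the batch (edges with both endpoints inside), a stochastic estimate
  of the full-graph penalty.
* **Optimizer.** Adam (\(\beta_1 = 0.9, \beta_2 = 0.999\)) with learning
  rate 0.001, weight decay 0.0001 added to the gradient, batch size 64,
  120 epochs by default, cosine annealing of the learning rate to zero,
  and dropout 0.1 after every encoder and planner ReLU (none on the
  heads). The parameters of the epoch with the best validation RMSE are
  returned. All parameters initialize fan-in-scaled uniform; every
  stochastic element (initialization, shuffling, dropout) derives from one
  integer seed, so runs are bit-reproducible.
* **Variance parameterization.** \(\sigma^2 = \exp(\text{head output})\)
  keeps the head unconstrained while guaranteeing positivity; clamping
  bounds the loss. Clamped values receive zero gradient.
* **Prediction.** `predict()` runs \(T = 20\) stochastic passes with
  dropout active: \(\mu = \overline{\mu_t}\), aleatoric variance
  \(\overline{\sigma^2_t}\), epistemic variance the population variance
  (denominator \(T\)) of \(\mu_t\), total their sum. With dropout 0 the
  epistemic part is exactly zero. The conceptual pair "mean +
  variance" is treated as exactly that — a distribution's two
  parameters — never as a literal sum, which would be dimensionally
  incoherent.

## The synthetic cohort

`sim_config()` / `simulate_cohort()` emulate the structure the method
assumes:

* **Genotypes**: markers in contiguous blocks; within a block the two
  latent gametes of each individual share an equicorrelated Gaussian
  factor (`within_block_rho`, default 0.5), thresholded per marker at
  Hardy–Weinberg proportions for an allele frequency drawn from
  `maf_range`. Marginal dosage frequencies are therefore exact
  Hardy–Weinberg while within-block linkage disequilibrium is positive —
  the simplest structure with an analytic handle on both.
* **Phenotypes**: an additive polygenic value over `n_causal` markers with
  standard-normal effects; each indicator mixes a common genetic factor
  with an indicator-specific one (`shared_factor_loading`, default 0.9 —
  three physical-capacity measures share most of their genetic basis, and
  at 0.9 the common factor carries \(0.9^2/(0.9^2+0.1^2) \approx 99\%\) of
  the genetic variance, so the per-indicator variance explained by the
  stored genetic value recovers the configured heritability to well within
  sampling error). Genetic and noise components are scaled so
  \(\mathrm{Var(genetic)}/\mathrm{Var(total)} = h^2\) exactly in
  expectation.
* **Heteroscedasticity**: per-individual noise SD is
  \(s_0(1 + c\,z_i)\) with \(z_i\) a min–max-scaled dosage burden on a
  fixed marker subset — uncertainty that is *predictable from the
  genotype*, which is what the variance head is supposed to learn.
* **Nonlinearity** (`nonlinear_frac`, default 0): an optional epistatic
  component built from pairwise products of causal markers, carrying the
  stated fraction of genetic variance. This is the regime in which a
  linear baseline is structurally mis-specified.
* **Historical records**: assessment-time indicators plus independent
  noise (`historical_noise_sd`, default 0.5). The prediction target is
  built from assessment-time indicators; feeding the *historical* (earlier,
  noisier) indicators as features avoids constructing the target from its
  own inputs. A `features = "genotype-only"` switch drops them entirely.
* **Defects**: exact duplicates, missing cells (`NA`) and planted
  `mean + 10 SD` outliers, each with a manifest, to exercise the cleaning
  rules.

What the simulator does **not** emulate: population structure and
admixture, sex chromosomes, platform-specific genotyping error, and
pedigree/twin relatedness. Passing tests on simulated cohorts therefore
demonstrate correctness of the machinery and qualitative behaviour of the
method, not performance on any real cohort.

## Preprocessing

Cleaning applies, in fixed order: duplicate removal by ID (first
occurrence kept), removal of rows with any missing cell, and a
three-standard-deviation rule per indicator with mean and sample SD
computed *once* over the post-missing rows (iterating the rule would
change counts; a single pass matches the stated procedure). Splits are
8:1:1 at the individual level: after a seeded permutation the first
\(\lfloor 0.8n \rfloor\) IDs train, the next \(\lfloor 0.1n \rfloor\)
validate, the rest test. All normalization statistics — genotype min–max,
indicator means and sample SDs, and the potential score's final
standardization — are fitted on the training partition only. Constant
genotype columns map to 0; out-of-range values are *not* clipped, keeping
the transform affine and invertible. Sample SDs (denominator \(n-1\)) are
used throughout.

## Evaluation harnesses

* **Metrics**: Pearson, RMSE, \(R^2 = 1 - SS_{res}/SS_{tot}\), MAE.
  Zero-variance inputs make Pearson undefined (`NA` with a warning); the
  rest are still reported.
* **Calibration**: the CDF-discrepancy notion of calibration is
  discretized as the mean absolute central-interval coverage gap over
  nominal levels \(q \in \{0.05, \dots, 0.95\}\): a per-individual
  integral over the real line is not estimable from one observation each,
  while interval coverage is the standard estimable surrogate.
* **Stratification**: rank by predicted score (descending, stable ties),
  cut top 20% / middle 60% / bottom 20%, summarize true scores and
  indicators per group.
* **Uncertainty triage**: a *median* split of the total predictive
  variance into low/high halves (consistent with an even split of the
  reported group statistics), plus exclusion of the top
  \(\lfloor 0.1n \rfloor\) most-uncertain individuals.
* **Ablations**: `full`, `no_manifold` (\(\lambda_m = 0\), encoder reduced
  to the embedding plus a single 64-unit layer), `no_planner` (\(Z\) feeds
  the trunk, \(\lambda_r = 0\)), `no_uncertainty` (single mean head,
  squared-error loss, no MC sampling), `no_constraint`
  (\(\lambda_c = 0\)). The named variants are defined structurally here
  since only their names are given externally.
* **Baseline**: closed-form OLS (ridge \(10^{-6}\) when features reach
  the training-row count).

## Problem sizes used in tests and the packaged benchmark

The packaged benchmark (`gap_benchmark()`) is a 2,000-individual,
200-marker cohort (20 LD blocks, \(\rho = 0.5\), 50 causal markers,
\(h^2 = 0.5\), `hetero_coeff = 1`, genotype-only features) trained for 40
epochs — large enough that the polygenic signal, heteroscedasticity and
calibration behaviour are all measurable, small enough for a single CPU.
The ablation harness uses its `nonlinear = TRUE` variant (30% epistatic
genetic variance): components whose purpose is modelling heteroscedastic
noise and nonlinear genotype–phenotype structure can only show their
contribution where such structure exists; on a purely additive cohort the
simpler ablated models are expected to tie. Simulator property checks
(heritability recovery, calibration of the true generative model) use
\(n = 5000\).

## A worked run

```{r, eval = FALSE}
ds <- gap_benchmark(seed = 42)
model <- gap_fit(ds, control = benchmark_control(seed = 42))
report <- evaluate_model(model, ds, "test")
report
po <- attr(report, "prediction")
te <- which(ds$ids %in% ds$split$test)
uncertainty_triage(ds$y[te], po$mu, po$var_total)
```

## Known limitations

* The kNN similarity graph is built from the same normalized genotype
  features the encoder consumes; a graph from external biological
  annotation (pathways, LD maps) is out of scope.
* The epistemic component from MC dropout is a coarse posterior
  approximation; variational alternatives are not implemented.
* Dense distance computation limits graph construction to cohorts of a
  few tens of thousands of individuals.
* The simulator's defects and noise are planted under idealized models;
  real cohort artifacts (batch effects, platform drift) are absent.
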