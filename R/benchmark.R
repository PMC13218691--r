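## Packaged benchmark fixture: a reproducible mid-size cohort used by the
## evaluation harnesses, tests and the acceptance script.

#' Packaged benchmark dataset
#'
#' A fixed mid-size synthetic cohort for harness runs: 2,000 individuals,
#' 200 markers in 20 LD blocks (within-block correlation 0.5), 50 causal
#' markers, heritability 0.5, heteroscedastic noise (`hetero_coeff = 1`,
#' so per-individual noise SD spans a twofold range), genotype-only
#' features.  With `nonlinear = TRUE` a 30% epistatic share of the genetic
#' variance is switched on (pairwise products of causal markers), the
#' regime where a linear baseline is structurally mis-specified.
#'
#' @param seed Integer seed for both simulation and split.
#' @param nonlinear Enable the epistatic signal component.
#' @param n_individuals,n_markers Cohort size (defaults 2000 x 200).
#' @return A `gap_dataset`; the generating `sim_config` is attached as
#'   attribute `"config"`.
#' @export
gap_benchmark <- function(seed = 42, nonlinear = FALSE,
                          n_individuals = 2000, n_markers = 200) {
  cfg <- sim_config(
    n_individuals = n_individuals, n_markers = n_markers, n_blocks = 20,
    within_block_rho = 0.5, maf_range = c(0.1, 0.5), n_causal = 50,
    heritability = 0.5, shared_factor_loading = 0.9, hetero_coeff = 1,
    nonlinear_frac = if (nonlinear) 0.3 else 0,
    historical_noise_sd = 0.5, seed = seed)
  cohort <- simulate_cohort(cfg)
  ds <- build_dataset(cohort, seed = seed, features = "genotype-only")
  attr(ds, "config") <- cfg
  ds
}

#' Benchmark training configuration
#'
#' The shortened training schedule used with [gap_benchmark()]: 40 epochs,
#' otherwise the standard optimizer settings.
#'
#' @param seed Integer seed.
#' @param epochs Training epochs (default 40).
#' @param ... Further overrides passed to [gap_control()].
#' @return A `gap_control`.
#' @export
benchmark_control <- function(seed = 42, epochs = 40, ...) {
  gap_control(epochs = epochs, seed = seed, ...)
}
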