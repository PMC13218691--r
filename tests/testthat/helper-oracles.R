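# Independent brute-force oracles used to cross-check the vectorized
# implementations.  Each is a direct double-loop transcription of the
# defining formula, kept deliberately naive.

oracle_nll <- function(y, mu, sigma2) {
  total <- 0
  for (i in seq_along(y))
    total <- total + (y[i] - mu[i])^2 / (2 * sigma2[i]) + 0.5 * log(sigma2[i])
  total / length(y)
}

oracle_manifold <- function(Z, C, normalize = TRUE) {
  n <- nrow(Z)
  total <- 0; n_edges <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && C[i, j] > 0) {
      total <- total + sum((Z[i, ] - Z[j, ])^2) * C[i, j]
      n_edges <- n_edges + 1
    }
  }
  if (normalize && n_edges > 0) total / n_edges else total
}

oracle_smoothness <- function(yhat, C) {
  n <- length(yhat)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      num <- num + C[i, j] * (yhat[i] - yhat[j])^2
      den <- den + C[i, j]
    }
  }
  num / den
}

oracle_reward <- function(A, y3) {
  total <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    total <- total + (A[i, j] - y3[i, j])^2
  total / (nrow(A) * ncol(A))
}

oracle_metrics <- function(y, mu) {
  n <- length(y)
  ssr <- 0; sst <- 0; sae <- 0
  ym <- sum(y) / n
  for (i in seq_len(n)) {
    ssr <- ssr + (y[i] - mu[i])^2
    sst <- sst + (y[i] - ym)^2
    sae <- sae + abs(y[i] - mu[i])
  }
  list(pearson = stats::cor(y, mu), rmse = sqrt(ssr / n),
       r2 = 1 - ssr / sst, mae = sae / n)
}

with_seed_for_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# hand-built cohort with plain Gaussian phenotypes and ids id1..idN
new_cohort_for_test <- function(n, p = 5, seed = 1234) {
  with_seed_for_test(seed, {
    geno <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
    ph <- data.frame(speed = stats::rnorm(n), endurance = stats::rnorm(n),
                     strength = stats::rnorm(n))
    hist <- ph + matrix(stats::rnorm(n * 3, sd = 0.3), n, 3)
    colnames(hist) <- paste0("hist_", colnames(ph))
    gapred:::new_cohort(ids = paste0("id", seq_len(n)), genotypes = geno,
                        phenotypes = ph, historical = hist)
  })
}

# small deterministic cohort for pipeline-level tests
tiny_cohort <- function(n = 120, p = 30, seed = 99, ...) {
  simulate_cohort(sim_config(n_individuals = n, n_markers = p,
                             n_blocks = max(2, p %/% 10), n_causal = min(10, p),
                             heritability = 0.5, seed = seed, ...))
}

tiny_dataset <- function(n = 120, p = 30, seed = 99, ...) {
  build_dataset(tiny_cohort(n, p, seed, ...), seed = seed)
}
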