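#' Configuration for the synthetic cohort simulator
#'
#' Bundles every knob of the genotype--phenotype simulator.  The simulator
#' emulates a population cohort carrying linkage-disequilibrium (LD)
#' correlated genotype dosages and three standardized physical indicators
#' (speed, endurance, strength) driven by a shared additive polygenic
#' signal, with optional heteroscedastic observation noise and injectable
#' data defects (duplicates, missing cells, outliers).
#'
#' @param n_individuals Number of individuals.
#' @param n_markers Number of genotype markers (dosage columns).
#' @param n_blocks Number of contiguous LD blocks the markers are
#'   partitioned into.
#' @param within_block_rho Latent correlation shared by markers within a
#'   block, in `[0, 1)`.
#' @param maf_range Length-2 numeric: minor-allele-frequency bounds in
#'   `(0, 0.5]`; each marker's frequency is drawn uniformly between them.
#' @param n_causal Number of causal markers (must not exceed `n_markers`);
#'   causal markers are spread uniformly across blocks.
#' @param heritability Fraction `h^2` in `[0, 1]` of each indicator's
#'   variance explained by its genetic component.
#' @param shared_factor_loading Mixing weight in `[0, 1]` of the common
#'   genetic factor relative to indicator-specific genetic factors.
#' @param hetero_coeff Nonnegative scalar; per-individual noise SD is
#'   `base_sd * (1 + hetero_coeff * z_i)` where `z_i` is a min--max scaled
#'   score over a designated marker subset.  `0` gives homoscedastic noise.
#' @param nonlinear_frac Fraction in `[0, 1)` of genetic variance carried by
#'   pairwise (epistatic) products of causal markers rather than additive
#'   dosage effects.  Default `0` (purely additive).
#' @param historical_noise_sd SD of the independent Gaussian perturbation
#'   separating historical records from assessment-time indicators.
#' @param defect_rates Named or positional length-3 numeric
#'   `(duplicate_rate, missing_rate, outlier_rate)`, each in `[0, 1)`.
#' @param seed Integer seed; identical configurations are bit-reproducible.
#'
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_cohort()], [inject_data_defects()]
#' @export
sim_config <- function(n_individuals = 5000, n_markers = 500, n_blocks = 50,
                       within_block_rho = 0.5, maf_range = c(0.05, 0.5),
                       n_causal = min(50, n_markers), heritability = 0.5,
                       shared_factor_loading = 0.9, hetero_coeff = 0,
                       nonlinear_frac = 0, historical_noise_sd = 0.5,
                       defect_rates = c(duplicate = 0, missing = 0, outlier = 0),
                       seed = 42) {
  maf_range <- as.numeric(unlist(maf_range))
  defect_rates <- as.numeric(unlist(defect_rates))
  stop_if(n_individuals < 1 || n_markers < 1 || n_blocks < 1,
          "n_individuals, n_markers and n_blocks must be positive")
  stop_if(n_blocks > n_markers, "n_blocks must not exceed n_markers")
  stop_if(within_block_rho < 0 || within_block_rho >= 1,
          "within_block_rho must lie in [0, 1)")
  stop_if(length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
            maf_range[1] > maf_range[2],
          "maf_range must be two frequencies in (0, 0.5], low <= high")
  stop_if(n_causal > n_markers, "n_causal must not exceed n_markers")
  stop_if(heritability < 0 || heritability > 1, "heritability must lie in [0, 1]")
  stop_if(shared_factor_loading < 0 || shared_factor_loading > 1,
          "shared_factor_loading must lie in [0, 1]")
  stop_if(hetero_coeff < 0, "hetero_coeff must be nonnegative")
  stop_if(nonlinear_frac < 0 || nonlinear_frac >= 1,
          "nonlinear_frac must lie in [0, 1)")
  stop_if(historical_noise_sd < 0, "historical_noise_sd must be nonnegative")
  stop_if(length(defect_rates) != 3 || any(defect_rates < 0) || any(defect_rates >= 1),
          "defect_rates must be three rates in [0, 1)")
  names(defect_rates) <- c("duplicate", "missing", "outlier")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_markers = as.integer(n_markers),
    n_blocks = as.integer(n_blocks),
    within_block_rho = within_block_rho,
    maf_range = maf_range,
    n_causal = as.integer(n_causal),
    heritability = heritability,
    shared_factor_loading = shared_factor_loading,
    hetero_coeff = hetero_coeff,
    nonlinear_frac = nonlinear_frac,
    historical_noise_sd = historical_noise_sd,
    defect_rates = defect_rates,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate LD-correlated genotype dosages
#'
#' Draws an `n x p` matrix of dosages in `{0, 1, 2}`.  Markers are split
#' into `n_blocks` contiguous blocks; within a block the two latent gametes
#' of each individual share an equicorrelated Gaussian structure with
#' correlation `within_block_rho`, thresholded per marker at Hardy--Weinberg
#' proportions for an allele frequency drawn uniformly from `maf_range`.
#' Summing the two thresholded gametes yields dosages whose marginal
#' distribution is exactly Hardy--Weinberg at that frequency while
#' within-block dosages stay positively correlated.
#'
#' @param config A [sim_config()].
#' @return List with `dosages` (n x p integer matrix) and `markers`
#'   (data.frame: marker, block, maf, causal flag).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_individuals; p <- config$n_markers
    blocks <- sort(rep_len(seq_len(config$n_blocks), p))
    maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    rho <- config$within_block_rho
    dos <- matrix(0L, n, p)
    for (b in seq_len(config$n_blocks)) {
      idx <- which(blocks == b)
      m <- length(idx)
      ## equicorrelated latents via a shared block factor, one per gamete
      for (g in 1:2) {
        shared <- stats::rnorm(n)
        lat <- sqrt(rho) * shared +
          sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
        thr <- stats::qnorm(maf[idx])  # carrier iff latent below quantile
        dos[, idx] <- dos[, idx] +
          (lat < matrix(thr, n, m, byrow = TRUE))
      }
    }
    storage.mode(dos) <- "integer"
    causal <- integer(0)
    if (config$n_causal > 0) {
      ## spread causal markers uniformly across the marker range
      causal <- unique(round(seq(1, p, length.out = config$n_causal)))
      while (length(causal) < config$n_causal)
        causal <- sort(union(causal, sample(setdiff(seq_len(p), causal), 1)))
    }
    markers <- data.frame(
      marker = paste0("m", seq_len(p)), block = blocks, maf = maf,
      causal = seq_len(p) %in% causal
    )
    list(dosages = dos, markers = markers)
  })
}

#' Simulate phenotypes, historical records and ground truth
#'
#' Builds the additive polygenic value `g_i = sum_k beta_k x_ik` over the
#' causal markers (plus an optional epistatic component, see
#' `nonlinear_frac`), mixes a common genetic factor with indicator-specific
#' factors, and scales genetic and noise components so that
#' `Var(genetic) / Var(total) = heritability` for every indicator.  Noise
#' may be heteroscedastic: per-individual SD is
#' `base_sd * (1 + hetero_coeff * z_i)` with `z_i` a min--max scaled dosage
#' score on a designated marker subset (the first `min(20, p)` markers).
#' Historical records are the assessment-time indicators plus independent
#' `N(0, historical_noise_sd^2)` perturbations.
#'
#' @param genotypes Result of [simulate_genotypes()] under the same config.
#' @param config The same [sim_config()].
#' @return List with data.frames `phenotypes` (speed, endurance, strength),
#'   `historical`, and vectors `true_genetic_value`, `true_noise_sd`
#'   (both n-long; noise SD is shared across the three indicators).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  h2 <- config$heritability
  with_seed(derive_seed(config$seed, 2L), {
    X <- genotypes$dosages
    n <- nrow(X)
    causal <- which(genotypes$markers$causal)
    standardize <- function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    additive_score <- function() {
      if (length(causal) == 0) return(rep(0, n))
      beta <- stats::rnorm(length(causal))
      as.vector(X[, causal, drop = FALSE] %*% beta)
    }
    genetic_factor <- function() {
      g <- standardize(additive_score())
      if (config$nonlinear_frac > 0 && length(causal) >= 2) {
        ## epistatic part: products of consecutive causal marker pairs
        i1 <- causal[-length(causal)]; i2 <- causal[-1]
        gamma <- stats::rnorm(length(i1))
        ep <- standardize(as.vector((X[, i1, drop = FALSE] *
                                       X[, i2, drop = FALSE]) %*% gamma))
        g <- sqrt(1 - config$nonlinear_frac) * g +
          sqrt(config$nonlinear_frac) * ep
        g <- standardize(g)
      }
      g
    }
    g_common <- genetic_factor()
    lam <- config$shared_factor_loading

    ## heteroscedasticity driver: min-max scaled dosage burden on a fixed
    ## marker subset
    sub <- seq_len(min(20L, ncol(X)))
    burden <- rowSums(X[, sub, drop = FALSE])
    rng <- range(burden)
    z <- if (rng[2] > rng[1]) (burden - rng[1]) / (rng[2] - rng[1]) else rep(0.5, n)
    shape <- 1 + config$hetero_coeff * z

    inds <- c("speed", "endurance", "strength")
    pheno <- matrix(0, n, 3, dimnames = list(NULL, inds))
    for (j in 1:3) {
      g_spec <- genetic_factor()
      gen <- standardize(lam * g_common + (1 - lam) * g_spec)
      eps <- stats::rnorm(n)
      ## scale noise so that Var(gen)/Var(total) = h2, preserving the
      ## per-individual heteroscedastic shape
      if (h2 >= 1) {
        noise <- rep(0, n)
      } else {
        raw <- shape * eps
        target_var <- (1 - h2) / max(h2, .Machine$double.eps)
        if (h2 == 0) { gen <- rep(0, n); target_var <- 1 }
        noise <- raw / sqrt(mean(shape^2)) * sqrt(target_var)
      }
      ## gen has unit variance, noise variance is (1-h2)/h2 * h2-scaled:
      ## with signal sqrt(h2)*gen the variance ratio is exactly h2
      pheno[, j] <- if (h2 > 0) sqrt(h2) * gen + sqrt(h2) * noise else noise
    }
    base_sd <- if (h2 >= 1 || h2 == 0) {
      if (h2 >= 1) 0 else 1 / sqrt(mean(shape^2))
    } else sqrt((1 - h2)) / sqrt(mean(shape^2))
    true_noise_sd <- base_sd * shape

    hist <- pheno + matrix(stats::rnorm(n * 3, sd = config$historical_noise_sd),
                           n, 3)
    colnames(hist) <- paste0("hist_", inds)
    list(
      phenotypes = as.data.frame(pheno),
      historical = as.data.frame(hist),
      true_genetic_value = g_common,
      true_noise_sd = true_noise_sd
    )
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genotypes()] and
#' [simulate_phenotypes()] and assembling a `cohort` object: row-aligned
#' ids, dosage matrix, assessment-time phenotypes, historical records and
#' simulator ground truth.
#'
#' @param config A [sim_config()].
#' @param defects If `TRUE`, also apply [inject_data_defects()] at the
#'   configured rates.
#' @return An object of class `"cohort"`.
#' @export
simulate_cohort <- function(config, defects = FALSE) {
  geno <- simulate_genotypes(config)
  phen <- simulate_phenotypes(geno, config)
  cohort <- new_cohort(
    ids = sprintf("id%05d", seq_len(config$n_individuals)),
    genotypes = geno$dosages,
    phenotypes = phen$phenotypes,
    historical = phen$historical,
    true_genetic_value = phen$true_genetic_value,
    true_noise_sd = phen$true_noise_sd,
    markers = geno$markers
  )
  if (defects) cohort <- inject_data_defects(cohort, config)$cohort
  cohort
}

new_cohort <- function(ids, genotypes, phenotypes, historical = NULL,
                       true_genetic_value = NULL, true_noise_sd = NULL,
                       markers = NULL) {
  stopifnot(length(ids) == nrow(genotypes),
            nrow(phenotypes) == nrow(genotypes))
  structure(list(
    ids = as.character(ids), genotypes = genotypes,
    phenotypes = as.data.frame(phenotypes),
    historical = if (!is.null(historical)) as.data.frame(historical),
    true_genetic_value = true_genetic_value,
    true_noise_sd = true_noise_sd,
    markers = markers
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", length(x$ids), "individuals,",
      ncol(x$genotypes), "markers\n")
  cat("  phenotypes:", paste(colnames(x$phenotypes), collapse = ", "), "\n")
  if (!is.null(x$historical))
    cat("  historical records present\n")
  if (!is.null(x$true_genetic_value))
    cat("  simulator ground truth present\n")
  invisible(x)
}

#' Inject data defects into a cohort
#'
#' Plants the defects the cleaning pipeline is meant to remove: appends
#' `floor(duplicate_rate * n)` exact duplicate rows (same ID), sets
#' `floor(missing_rate * n * p)` random genotype cells and
#' `floor(missing_rate * n * 3)` phenotype cells to `NA`, and replaces
#' `floor(outlier_rate * n)` phenotype values with `mean + 10 * SD` of their
#' column.  Returns the defective cohort together with a manifest listing
#' every planted defect.
#'
#' @param cohort A `cohort`.
#' @param config The [sim_config()] carrying `defect_rates` and `seed`.
#' @return List with `cohort` and `manifest` (list of `duplicate_ids`,
#'   `missing_genotype_cells`, `missing_phenotype_cells`, `outlier_cells`).
#' @export
inject_data_defects <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "sim_config"))
  rates <- config$defect_rates
  with_seed(derive_seed(config$seed, 3L), {
    n <- length(cohort$ids); p <- ncol(cohort$genotypes)
    manifest <- list(duplicate_ids = character(0),
                     missing_genotype_cells = matrix(integer(0), 0, 2),
                     missing_phenotype_cells = matrix(integer(0), 0, 2),
                     outlier_cells = matrix(integer(0), 0, 2))

    n_dup <- floor(rates[["duplicate"]] * n)
    if (n_dup > 0) {
      rows <- sample(n, n_dup)
      manifest$duplicate_ids <- cohort$ids[rows]
      cohort$ids <- c(cohort$ids, cohort$ids[rows])
      cohort$genotypes <- rbind(cohort$genotypes, cohort$genotypes[rows, , drop = FALSE])
      cohort$phenotypes <- rbind(cohort$phenotypes, cohort$phenotypes[rows, , drop = FALSE])
      if (!is.null(cohort$historical))
        cohort$historical <- rbind(cohort$historical, cohort$historical[rows, , drop = FALSE])
      if (!is.null(cohort$true_genetic_value))
        cohort$true_genetic_value <- c(cohort$true_genetic_value,
                                       cohort$true_genetic_value[rows])
      if (!is.null(cohort$true_noise_sd))
        cohort$true_noise_sd <- c(cohort$true_noise_sd, cohort$true_noise_sd[rows])
    }

    n_mg <- floor(rates[["missing"]] * n * p)
    if (n_mg > 0) {
      cells <- sample(n * p, n_mg)  # defects planted in original rows only
      rc <- cbind(((cells - 1) %% n) + 1, ((cells - 1) %/% n) + 1)
      storage.mode(cohort$genotypes) <- "double"
      cohort$genotypes[rc] <- NA
      manifest$missing_genotype_cells <- rc
    }
    n_mp <- floor(rates[["missing"]] * n * 3)
    if (n_mp > 0) {
      cells <- sample(n * 3, n_mp)
      rc <- cbind(((cells - 1) %% n) + 1, ((cells - 1) %/% n) + 1)
      for (k in seq_len(nrow(rc))) cohort$phenotypes[rc[k, 1], rc[k, 2]] <- NA
      manifest$missing_phenotype_cells <- rc
    }

    n_out <- floor(rates[["outlier"]] * n)
    if (n_out > 0) {
      rows <- sample(setdiff(seq_len(n), unique(c(
        manifest$missing_phenotype_cells[, 1]))), n_out)
      cols <- sample(3, n_out, replace = TRUE)
      for (k in seq_len(n_out)) {
        col <- cohort$phenotypes[[cols[k]]]
        ok <- !is.na(col)
        cohort$phenotypes[rows[k], cols[k]] <-
          mean(col[ok]) + 10 * stats::sd(col[ok])
      }
      manifest$outlier_cells <- cbind(rows, cols)
    }
    list(cohort = cohort, manifest = manifest)
  })
}
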