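## Metrics, calibration, stratification, uncertainty triage, ablation and
## sensitivity harnesses, plus the ordinary-least-squares reference
## baseline.

#' Regression metrics
#'
#' Pearson correlation, RMSE, coefficient of determination
#' (`R^2 = 1 - SS_res / SS_tot` about the mean of `y`) and MAE.  When `y`
#' or `mu` has zero variance the Pearson coefficient is undefined and
#' reported as `NA` with a warning; the other metrics are still computed.
#'
#' @param y Observed targets.
#' @param mu Predicted means.
#' @return A `metrics_report`: list with `pearson`, `rmse`, `r2`, `mae`,
#'   `n`.
#' @export
regression_metrics <- function(y, mu) {
  stop_if(length(y) != length(mu), "y and mu must have equal length")
  stop_if(length(y) < 2, "need at least 2 observations")
  pearson <- if (stats::sd(y) == 0 || stats::sd(mu) == 0) {
    warning("zero variance in y or mu: Pearson correlation is undefined")
    NA_real_
  } else stats::cor(y, mu)
  structure(list(
    pearson = pearson,
    rmse = sqrt(mean((y - mu)^2)),
    r2 = 1 - sum((y - mu)^2) / sum((y - mean(y))^2),
    mae = mean(abs(y - mu)),
    n = length(y)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics (n = %d): Pearson %.4f  RMSE %.4f  R2 %.4f  MAE %.4f\n",
              x$n, x$pearson, x$rmse, x$r2, x$mae))
  invisible(x)
}

#' Evaluate a fitted model on a dataset partition
#'
#' @param model A `gap_model`.
#' @param dataset A `gap_dataset`.
#' @param part Partition to evaluate (default `"test"`).
#' @param T,seed Monte-Carlo settings passed to [predict.gap_model()].
#' @return The `metrics_report`, with the `predictive_output` attached as
#'   attribute `"prediction"` and, for heteroscedastic models with enough
#'   samples, the calibration error as attribute `"calibration"`.
#' @export
evaluate_model <- function(model, dataset, part = "test", T = NULL,
                           seed = 42) {
  rows <- split_rows(dataset, part)
  po <- predict(model, dataset$X[rows, , drop = FALSE], T = T, seed = seed)
  y <- dataset$y[rows]
  rep <- regression_metrics(y, po$mu)
  attr(rep, "prediction") <- po
  if (model$spec$heteroscedastic && length(y) >= 20 && all(po$var_total > 0))
    attr(rep, "calibration") <- calibration_error(y, po$mu, po$var_total)
  rep
}

#' Calibration error of Gaussian predictive intervals
#'
#' Discretizes the CDF-discrepancy notion of calibration as the mean
#' absolute central-interval coverage gap: for each nominal level `q` on
#' the grid, the empirical coverage is the fraction of `y_i` falling
#' inside the central `q`-probability interval of `N(mu_i, var_i)`, and
#' the error is `mean_q |coverage(q) - q|`.  Zero in the infinite-sample
#' limit for a perfectly specified model.
#'
#' @param y Observed targets (`n >= 20`).
#' @param mu Predictive means.
#' @param var_total Predictive variances, strictly positive.
#' @param grid Nominal central-coverage levels (default 0.05 to 0.95 in
#'   steps of 0.05).
#' @return Scalar in `[0, 1)`.
#' @export
calibration_error <- function(y, mu, var_total,
                              grid = seq(0.05, 0.95, by = 0.05)) {
  stop_if(length(y) < 20, "calibration needs at least 20 samples")
  stop_if(any(var_total <= 0), "var_total must be strictly positive")
  stop_if(length(grid) < 1, "grid must be non-empty")
  sdv <- sqrt(var_total)
  absz <- abs(y - mu) / sdv
  cover <- vapply(grid, function(q)
    mean(absz <= stats::qnorm(0.5 + q / 2)), 0)
  mean(abs(cover - grid))
}

#' Stratify individuals by predicted potential
#'
#' Ranks individuals by predicted score (descending, ties broken by stable
#' input order) and cuts top 20% / middle 60% / bottom 20% groups, then
#' summarizes the true potential score and the three standardized
#' indicators per group.
#'
#' @param mu Predicted scores (`n >= 10`).
#' @param y True potential scores.
#' @param indicators Optional `n x 3` matrix of standardized indicators.
#' @return A `stratification_report`: data.frame with one row per group
#'   (size, mean and SD of the true score, and of each indicator when
#'   supplied); attribute `"groups"` holds the per-individual labels.
#' @export
stratify_by_prediction <- function(mu, y, indicators = NULL) {
  n <- length(mu)
  stop_if(n < 10, "stratification needs at least 10 individuals")
  stop_if(length(y) != n, "mu and y must be aligned")
  rank_desc <- order(-mu)            # stable for ties
  n_top <- floor(0.2 * n); n_bot <- floor(0.2 * n)
  labels <- rep("middle", n)
  labels[rank_desc[seq_len(n_top)]] <- "top"
  labels[rank_desc[(n - n_bot + 1):n]] <- "bottom"
  groups <- factor(labels, levels = c("top", "middle", "bottom"))
  summ <- function(v) c(mean = mean(v), sd = stats::sd(v))
  out <- data.frame(group = levels(groups),
                    n = as.vector(table(groups)))
  sc <- t(vapply(levels(groups), function(g) summ(y[groups == g]), c(0, 0)))
  out$score_mean <- sc[, 1]; out$score_sd <- sc[, 2]
  if (!is.null(indicators)) {
    indicators <- as.matrix(indicators)
    for (j in seq_len(ncol(indicators))) {
      nm <- colnames(indicators)[j] %||% paste0("ind", j)
      sj <- t(vapply(levels(groups), function(g)
        summ(indicators[groups == g, j]), c(0, 0)))
      out[[paste0(nm, "_mean")]] <- sj[, 1]
      out[[paste0(nm, "_sd")]] <- sj[, 2]
    }
  }
  structure(out, class = c("stratification_report", "data.frame"),
            groups = groups)
}

#' Uncertainty triage report
#'
#' Selective-prediction analysis: individuals are split into low- and
#' high-uncertainty halves at the median of the total predictive
#' variance, and additionally the top 10% most-uncertain individuals are
#' excluded.  RMSE and MAE are reported for all samples, each half, and
#' the post-exclusion set.
#'
#' @param y Observed targets (`n >= 20`).
#' @param mu Predicted means.
#' @param var_total Total predictive variances.
#' @return A `triage_report` data.frame (rows: all, low_uncertainty,
#'   high_uncertainty, excluded_top10); attribute `"groups"` holds the
#'   low/high labels, attribute `"excluded"` the excluded indices.
#' @export
uncertainty_triage <- function(y, mu, var_total) {
  n <- length(y)
  stop_if(n < 20, "triage needs at least 20 samples")
  stop_if(length(mu) != n || length(var_total) != n,
          "y, mu and var_total must be aligned")
  ord <- order(var_total)            # ascending uncertainty, stable
  low <- ord[seq_len(floor(n / 2))]
  high <- setdiff(ord, low)
  n_ex <- floor(0.1 * n)
  excl <- ord[(n - n_ex + 1):n]
  keep <- setdiff(seq_len(n), excl)
  row <- function(idx) c(n = length(idx),
                         rmse = sqrt(mean((y[idx] - mu[idx])^2)),
                         mae = mean(abs(y[idx] - mu[idx])))
  out <- as.data.frame(rbind(all = row(seq_len(n)),
                             low_uncertainty = row(low),
                             high_uncertainty = row(high),
                             excluded_top10 = row(keep)))
  out$setting <- rownames(out)
  out <- out[, c("setting", "n", "rmse", "mae")]
  rownames(out) <- NULL
  labels <- rep("high", n); labels[low] <- "low"
  structure(out, class = c("triage_report", "data.frame"),
            groups = labels, excluded = excl,
            threshold_median = stats::median(var_total))
}

#' Ordinary-least-squares reference baseline
#'
#' Closed-form linear regression of the potential score on the feature
#' matrix, fitted on the training partition and evaluated on the test
#' partition.  When the feature count reaches the training-row count the
#' fit falls back to ridge regression with penalty `1e-6`.
#'
#' @param dataset A `gap_dataset`.
#' @param ridge Ridge penalty used in the fallback.
#' @return A `metrics_report` on the test split; attributes
#'   `"coefficients"` and `"prediction"`.
#' @export
ols_baseline <- function(dataset, ridge = 1e-6) {
  tr <- split_rows(dataset, "train"); te <- split_rows(dataset, "test")
  Xtr <- cbind(1, dataset$X[tr, , drop = FALSE])
  Xte <- cbind(1, dataset$X[te, , drop = FALSE])
  ytr <- dataset$y[tr]
  if (ncol(Xtr) >= nrow(Xtr)) {
    XtX <- crossprod(Xtr) + diag(ridge, ncol(Xtr))
    beta <- solve(XtX, crossprod(Xtr, ytr))
  } else {
    fit <- stats::lm.fit(Xtr, ytr)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
  }
  mu <- as.vector(Xte %*% beta)
  rep <- regression_metrics(dataset$y[te], mu)
  attr(rep, "coefficients") <- beta
  attr(rep, "prediction") <- mu
  rep
}

ablation_variants <- function() {
  c("full", "no_manifold", "no_planner", "no_uncertainty", "no_constraint")
}

## apply a named surgery to (spec, weights)
apply_variant <- function(variant, spec, weights) {
  sp <- spec; w <- weights
  switch(variant,
    full = NULL,
    no_manifold = {       # drop manifold term, shrink encoder to one layer
      w$lambda_manifold <- 0
      sp <- gap_spec(spec$input_dim, embed_dim = spec$embed_dim,
                     encoder_dims = 64L,
                     planner_hidden = spec$planner_hidden,
                     action_dim = spec$action_dim,
                     forecaster_hidden = spec$forecaster_hidden,
                     dropout_p = spec$dropout_p,
                     variance_floor = spec$variance_floor,
                     variance_ceiling = spec$variance_ceiling,
                     use_planner = spec$use_planner,
                     heteroscedastic = spec$heteroscedastic)
    },
    no_planner = {        # route Z straight into the forecaster trunk
      w$lambda_reward <- 0
      sp$use_planner <- FALSE
    },
    no_uncertainty = {    # single mean head, squared-error loss, no MC
      sp$heteroscedastic <- FALSE
    },
    no_constraint = w$lambda_constraint <- 0,
    stop("unknown ablation variant: ", variant, call. = FALSE)
  )
  list(spec = sp, weights = w)
}

#' Ablation study harness
#'
#' Retrains the model with one named component surgically removed and
#' reports test metrics per variant, averaged over seeds.  Variants:
#' `full`; `no_manifold` (manifold weight zeroed, encoder reduced to the
#' embedding plus a single 64-unit layer); `no_planner` (planner bypassed,
#' reward weight zeroed); `no_uncertainty` (mean head only, squared-error
#' loss, no Monte-Carlo sampling); `no_constraint` (smoothness weight
#' zeroed).
#'
#' @param dataset A `gap_dataset`.
#' @param spec,weights,control As in [gap_fit()].
#' @param variants Subset of the five variant names.
#' @param n_seeds Seeds per variant (`control$seed + 0:(n_seeds-1)`).
#' @return Data.frame: one row per variant with mean (and, when
#'   `n_seeds > 1`, SD) of Pearson, RMSE, R2, MAE; heteroscedastic
#'   variants also report the calibration error (`NA` where no variance
#'   exists).
#' @export
ablation_suite <- function(dataset, spec = NULL, weights = loss_weights(),
                           control = gap_control(),
                           variants = ablation_variants(), n_seeds = 1) {
  if (is.null(spec)) spec <- gap_spec(ncol(dataset$X))
  stop_if(!all(variants %in% ablation_variants()),
          "unknown variant name(s)")
  rows <- lapply(variants, function(v) {
    vw <- apply_variant(v, spec, weights)
    per_seed <- lapply(seq_len(n_seeds) - 1, function(off) {
      ctl <- control; ctl$seed <- as.integer(control$seed + off)
      m <- gap_fit(dataset, vw$spec, vw$weights, ctl)
      rep <- evaluate_model(m, dataset, "test")
      c(pearson = rep$pearson, rmse = rep$rmse, r2 = rep$r2, mae = rep$mae,
        calibration = attr(rep, "calibration") %||% NA_real_)
    })
    M <- do.call(rbind, per_seed)
    out <- data.frame(variant = v, t(colMeans(M)))
    if (n_seeds > 1)
      for (cn in colnames(M)) out[[paste0(cn, "_sd")]] <- stats::sd(M[, cn])
    out
  })
  do.call(rbind, rows)
}

#' Hyperparameter sensitivity harness
#'
#' Retrains the model along one-dimensional grids (embedding dimension,
#' encoder depth, manifold regularization strength, genotype
#' feature-noise SD) with identical seeds throughout and reports test
#' metrics per configuration.
#'
#' @param dataset A `gap_dataset`.
#' @param grids Named list of grids; defaults:
#'   `embed_dim = c(64, 128, 256)`, `encoder_depth = c(2, 3, 4)`,
#'   `lambda_manifold = c(0.01, 0.1, 1)`,
#'   `feature_noise_sd = c(0, 0.05, 0.1)`.
#' @param spec,weights,control As in [gap_fit()].
#' @return Data.frame: one row per (grid, value) configuration.
#' @export
sensitivity_suite <- function(dataset,
                              grids = list(embed_dim = c(64, 128, 256),
                                           encoder_depth = c(2, 3, 4),
                                           lambda_manifold = c(0.01, 0.1, 1),
                                           feature_noise_sd = c(0, 0.05, 0.1)),
                              spec = NULL, weights = loss_weights(),
                              control = gap_control()) {
  stop_if(length(grids) == 0 || any(lengths(grids) == 0),
          "grids must be non-empty")
  if (is.null(spec)) spec <- gap_spec(ncol(dataset$X))
  known <- c("embed_dim", "encoder_depth", "lambda_manifold",
             "feature_noise_sd")
  stop_if(!all(names(grids) %in% known),
          "unknown grid name(s); known: ", paste(known, collapse = ", "))
  depth_dims <- function(depth) {
    full <- c(256L, 128L, 64L, 32L)
    ## depth layers ending at a 64-or-narrower bottleneck
    if (depth <= 3) utils::tail(c(256L, 128L, 64L), depth) else full[1:depth]
  }
  rows <- list()
  for (g in names(grids)) for (val in grids[[g]]) {
    sp <- spec; w <- weights; ds <- dataset
    if (g == "embed_dim") sp$embed_dim <- as.integer(val)
    if (g == "encoder_depth") sp$encoder_dims <- depth_dims(val)
    if (g == "lambda_manifold") w$lambda_manifold <- val
    if (g == "feature_noise_sd" && val > 0)
      ds <- inject_feature_noise(ds, val, seed = control$seed)
    m <- gap_fit(ds, sp, w, control)
    rep <- evaluate_model(m, ds, "test")
    rows[[length(rows) + 1]] <- data.frame(
      grid = g, value = val, pearson = rep$pearson, rmse = rep$rmse,
      r2 = rep$r2, mae = rep$mae)
  }
  do.call(rbind, rows)
}
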