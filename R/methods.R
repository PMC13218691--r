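## S3 methods for the fitted model object.

resolve_X <- function(object, newdata) {
  if (inherits(newdata, "gap_dataset")) newdata$X else as.matrix(newdata)
}

#' Predict from a fitted genomic predictor
#'
#' Monte-Carlo dropout prediction: `T` stochastic forward passes yield the
#' predictive mean and the aleatoric / epistemic / total variance
#' decomposition.  For a homoscedastic model (ablation without the
#' variance head) a single deterministic pass returns the mean only.
#'
#' @param object A `gap_model`.
#' @param newdata A `gap_dataset` or a normalized feature matrix with the
#'   columns the model was trained on.
#' @param T Monte-Carlo passes (defaults to the training configuration).
#' @param seed Seed for the dropout masks.
#' @param type `"predictive"` (full `predictive_output`) or `"mean"`
#'   (numeric vector).
#' @param ... Unused.
#' @return A `predictive_output`, or a numeric vector for
#'   `type = "mean"`.
#' @export
predict.gap_model <- function(object, newdata, T = NULL, seed = 42,
                              type = c("predictive", "mean"), ...) {
  type <- match.arg(type)
  X <- resolve_X(object, newdata)
  T <- T %||% object$control$T_mc
  if (!object$spec$heteroscedastic || type == "mean") {
    if (!object$spec$heteroscedastic) {
      mu <- gap_forward(object$fit, X, training = FALSE)$mu
      return(if (type == "mean") mu else
        mc_combine(matrix(mu, ncol = 1)))
    }
  }
  po <- mc_predict(object$fit, X, T = T, seed = seed)
  if (type == "mean") po$mu else po
}

#' @export
print.gap_model <- function(x, ...) {
  cat("gap_model: uncertainty-aware genomic predictor\n")
  cat(sprintf("  architecture: %d -> embed %d -> encoder [%s] -> %s -> trunk %d -> %s\n",
              x$spec$input_dim, x$spec$embed_dim,
              paste(x$spec$encoder_dims, collapse = ", "),
              if (x$spec$use_planner)
                sprintf("planner %d -> %d", x$spec$planner_hidden,
                        x$spec$action_dim) else "(planner bypassed)",
              x$spec$forecaster_hidden,
              if (x$spec$heteroscedastic) "mean + log-variance heads"
              else "mean head"))
  cat(sprintf("  trained %d epochs (best validation RMSE %.4f at epoch %d)\n",
              nrow(x$log), x$best_val_rmse, x$best_epoch))
  invisible(x)
}

#' @export
summary.gap_model <- function(object, ...) {
  n_par <- length(flatten_params(object$fit$params))
  structure(list(model = object, n_parameters = n_par,
                 final = object$log[nrow(object$log), ],
                 weights = object$weights), class = "summary.gap_model")
}

#' @export
print.summary.gap_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  parameters: %d\n", x$n_parameters))
  cat(sprintf("  loss weights: manifold %.3g, reward %.3g, constraint %.3g\n",
              x$weights$lambda_manifold, x$weights$lambda_reward,
              x$weights$lambda_constraint))
  cat(sprintf("  final epoch: train %.4f (data %.4f), val RMSE %.4f\n",
              x$final$train_total, x$final$train_data, x$final$val_rmse))
  invisible(x)
}

#' @export
coef.gap_model <- function(object, ...) object$fit$params

#' Residuals of a fitted genomic predictor
#'
#' Deterministic-forward residuals `y - mu` on a partition of the dataset
#' the model was trained on (or any compatible dataset).
#'
#' @param object A `gap_model`.
#' @param dataset A `gap_dataset`.
#' @param part Partition: `"test"` (default), `"validation"` or
#'   `"train"`.
#' @param ... Unused.
#' @return Numeric vector of residuals.
#' @export
residuals.gap_model <- function(object, dataset, part = "test", ...) {
  rows <- split_rows(dataset, part)
  mu <- gap_forward(object$fit, dataset$X[rows, , drop = FALSE],
                    training = FALSE)$mu
  dataset$y[rows] - mu
}

#' Training-curve plot
#'
#' Plots the per-epoch training loss and validation RMSE.
#'
#' @param x A `gap_model`.
#' @param ... Passed to [plot()].
#' @export
plot.gap_model <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(log$epoch, log$train_total, type = "l", xlab = "epoch",
       ylab = "training loss", main = "composite objective", ...)
  plot(log$epoch, log$val_rmse, type = "l", xlab = "epoch",
       ylab = "validation RMSE", main = "validation", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Simulate from the predictive distribution
#'
#' Draws `nsim` replicates of the target from the per-individual Gaussian
#' predictive distribution `N(mu_i, var_total_i)` given features.
#'
#' @param object A `gap_model`.
#' @param nsim Number of replicate draws.
#' @param seed Integer seed.
#' @param newdata A `gap_dataset` or feature matrix.
#' @param ... Unused.
#' @return `n x nsim` matrix of simulated targets.
#' @export
simulate.gap_model <- function(object, nsim = 1, seed = 42, newdata, ...) {
  po <- predict(object, newdata, seed = seed)
  sd_tot <- sqrt(pmax(po$var_total, 0))
  with_seed(derive_seed(seed, 9L), {
    matrix(stats::rnorm(length(po$mu) * nsim, mean = po$mu, sd = sd_tot),
           length(po$mu), nsim)
  })
}
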