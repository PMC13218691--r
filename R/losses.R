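## The composite training objective: heteroscedastic Gaussian negative
## log-likelihood plus manifold, reward and output-smoothness penalties.

#' Heteroscedastic Gaussian negative log-likelihood
#'
#' `mean_i [ (y_i - mu_i)^2 / (2 sigma2_i) + log(sigma2_i) / 2 ]`.
#' The first term penalizes errors scaled by the predicted variance, the
#' second keeps the model from inflating its variance estimates.
#'
#' @param y,mu Aligned numeric vectors of targets and predicted means.
#' @param sigma2 Predicted variances, strictly positive.
#' @return Scalar loss.
#' @export
gaussian_nll <- function(y, mu, sigma2) {
  stop_if(length(y) != length(mu) || length(y) != length(sigma2),
          "y, mu and sigma2 must have equal length")
  stop_if(any(sigma2 <= 0), "sigma2 must be strictly positive")
  mean((y - mu)^2 / (2 * sigma2) + 0.5 * log(sigma2))
}

## gradients of gaussian_nll w.r.t. mu and log(sigma2)
gaussian_nll_grads <- function(y, mu, sigma2) {
  n <- length(y)
  list(d_mu = (mu - y) / (n * sigma2),
       d_log_var = (0.5 - (y - mu)^2 / (2 * sigma2)) / n)
}

#' Planner reward loss
#'
#' The planner's actions are rewarded for matching the observed
#' standardized indicators; recast as a loss it is the mean squared
#' action--indicator error, averaged over samples and the three capability
#' components.  Zero exactly when `A == y3`.
#'
#' @param A `n x 3` action matrix.
#' @param y3 `n x 3` matrix of z-scored observed indicators.
#' @return Nonnegative scalar.
#' @export
reward_loss <- function(A, y3) {
  A <- as.matrix(A); y3 <- as.matrix(y3)
  stop_if(!all(dim(A) == dim(y3)), "A and y3 must have identical dimensions")
  mean((A - y3)^2)
}

reward_loss_grad <- function(A, y3) 2 * (A - y3) / length(A)

#' Composite training objective with component breakdown
#'
#' `L_total = NLL + lambda_manifold * L_manifold(Z) + lambda_reward *
#' L_reward(A) + lambda_constraint * C(mu)` evaluated on a batch, where the
#' manifold and smoothness terms use the similarity subgraph induced on the
#' batch.  For a homoscedastic model (no variance head) the data term is
#' the mean squared error.
#'
#' @param model A `gap_params`.
#' @param X,y,y3 Batch features, targets and standardized indicators.
#' @param graph A `similarity_graph` over the batch rows (e.g. from
#'   [induce_subgraph()] via [total_loss_on()]), or `NULL` to skip the
#'   graph terms.
#' @param weights A [loss_weights()].
#' @param training Activate dropout during the forward pass.
#' @return List with `total`, `components` (named: data, manifold, reward,
#'   constraint — unweighted values), `weighted` (the weighted parts, which
#'   re-sum to `total`), and the forward cache.
#' @export
total_loss <- function(model, X, y, y3 = NULL, graph = NULL,
                       weights = loss_weights(), training = FALSE) {
  stopifnot(inherits(model, "gap_params"))
  spec <- model$spec
  fwd <- gap_forward(model, X, training = training)
  data_term <- if (spec$heteroscedastic) gaussian_nll(y, fwd$mu, fwd$sigma2)
               else mean((y - fwd$mu)^2)
  man <- con <- rew <- 0
  if (!is.null(graph) && nrow(graph$edges) > 0) {
    if (weights$lambda_manifold > 0) man <- manifold_loss(fwd$Z, graph)
    if (weights$lambda_constraint > 0) con <- output_smoothness(fwd$mu, graph)
  }
  if (spec$use_planner && weights$lambda_reward > 0 && !is.null(y3))
    rew <- reward_loss(fwd$A, y3)
  weighted <- c(data = data_term,
                manifold = weights$lambda_manifold * man,
                reward = weights$lambda_reward * rew,
                constraint = weights$lambda_constraint * con)
  list(total = sum(weighted),
       components = c(data = data_term, manifold = man, reward = rew,
                      constraint = con),
       weighted = weighted, fwd = fwd)
}

#' Loss weights of the composite objective
#'
#' @param lambda_manifold Manifold regularization coefficient (default
#'   0.1).
#' @param lambda_reward Planner reward coefficient (default 0.1).
#' @param lambda_constraint Output-smoothness coefficient (default 0.1).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_manifold = 0.1, lambda_reward = 0.1,
                         lambda_constraint = 0.1) {
  stop_if(any(c(lambda_manifold, lambda_reward, lambda_constraint) < 0),
          "loss weights must be nonnegative")
  structure(list(lambda_manifold = lambda_manifold,
                 lambda_reward = lambda_reward,
                 lambda_constraint = lambda_constraint),
            class = "loss_weights")
}

## Loss + full parameter gradient on a batch (one backprop pass with the
## penalty gradients injected at mu, log_var, A and Z).
batch_loss_grads <- function(model, X, y, y3, graph, weights,
                             training = TRUE) {
  spec <- model$spec
  tl <- total_loss(model, X, y, y3, graph, weights, training = training)
  fwd <- tl$fwd
  n <- length(y)
  if (spec$heteroscedastic) {
    g <- gaussian_nll_grads(y, fwd$mu, fwd$sigma2)
    d_mu <- g$d_mu; d_lv <- g$d_log_var
  } else {
    d_mu <- 2 * (fwd$mu - y) / n; d_lv <- NULL
  }
  d_A <- d_Z <- NULL
  if (!is.null(graph) && nrow(graph$edges) > 0) {
    if (weights$lambda_constraint > 0)
      d_mu <- d_mu + weights$lambda_constraint *
        output_smoothness_grad(fwd$mu, graph)
    if (weights$lambda_manifold > 0)
      d_Z <- weights$lambda_manifold * manifold_loss_grad(fwd$Z, graph)
  }
  if (spec$use_planner && weights$lambda_reward > 0 && !is.null(y3))
    d_A <- weights$lambda_reward * reward_loss_grad(fwd$A, y3)
  grads <- gap_backward(model, fwd, d_mu, d_lv, d_A, d_Z)
  list(loss = tl, grads = grads)
}

#' Paired two-sided t-test on per-seed metrics
#'
#' Standard paired t statistic with `n - 1` degrees of freedom; refuses
#' the degenerate zero-variance case rather than reporting a spurious
#' p-value.
#'
#' @param a,b Equal-length metric vectors (length >= 2) from paired runs.
#' @return List with `t` and `p`.
#' @export
paired_ttest <- function(a, b) {
  stop_if(length(a) != length(b) || length(a) < 2,
          "a and b must have equal length >= 2")
  d <- a - b
  stop_if(stats::sd(d) == 0,
          "differences have zero variance; paired t-test is degenerate")
  res <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(res$statistic), p = res$p.value)
}
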