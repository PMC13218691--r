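## The three-stage predictor network, authored in base R:
##   encoder  : linear embed (d -> embed_dim), then stacked
##              linear -> layer-norm -> ReLU -> dropout layers
##   planner  : two-layer MLP mapping the latent Z to an action matrix A
##   forecaster: shared ReLU trunk on A with a mean head and (for the
##              heteroscedastic model) a log-variance head
## Forward passes cache activations; gap_backward() implements exact
## backpropagation for the composite objective.

LN_EPS <- 1e-5

#' Architecture specification of the predictor
#'
#' @param input_dim Number of input features `d`.
#' @param embed_dim Embedding width of the first linear layer (default 128).
#' @param encoder_dims Widths of the stacked encoder layers (default
#'   `c(256, 128, 64)`), each linear -> layer-norm -> ReLU -> dropout.
#' @param planner_hidden Hidden width of the two-layer planner MLP
#'   (default 128).
#' @param action_dim Width `m` of the planner's action matrix; defaults to
#'   3, one action per athletic capability component.
#' @param forecaster_hidden Width of the shared forecaster trunk
#'   (default 64).
#' @param dropout_p Dropout probability in `[0, 1)` after every encoder and
#'   planner ReLU; none on the forecaster heads.
#' @param variance_floor,variance_ceiling Clamp bounds for the predicted
#'   variance `exp(log_var)`.
#' @param use_planner If `FALSE` the planner is bypassed and the encoder
#'   output feeds the forecaster trunk directly (ablation variant).
#' @param heteroscedastic If `FALSE` the log-variance head is dropped and
#'   the model is a plain mean regressor (ablation variant).
#' @return A `gap_spec` object.
#' @export
gap_spec <- function(input_dim, embed_dim = 128, encoder_dims = c(256, 128, 64),
                     planner_hidden = 128, action_dim = 3,
                     forecaster_hidden = 64, dropout_p = 0.1,
                     variance_floor = 1e-6, variance_ceiling = 1e6,
                     use_planner = TRUE, heteroscedastic = TRUE) {
  stop_if(input_dim < 1, "input_dim must be positive")
  stop_if(any(c(embed_dim, encoder_dims, planner_hidden, action_dim,
                forecaster_hidden) < 1), "all layer widths must be positive")
  stop_if(dropout_p < 0 || dropout_p >= 1, "dropout_p must lie in [0, 1)")
  stop_if(variance_floor <= 0 || variance_ceiling <= variance_floor,
          "need 0 < variance_floor < variance_ceiling")
  structure(list(
    input_dim = as.integer(input_dim), embed_dim = as.integer(embed_dim),
    encoder_dims = as.integer(encoder_dims),
    planner_hidden = as.integer(planner_hidden),
    action_dim = as.integer(action_dim),
    forecaster_hidden = as.integer(forecaster_hidden),
    dropout_p = dropout_p, variance_floor = variance_floor,
    variance_ceiling = variance_ceiling,
    use_planner = isTRUE(use_planner),
    heteroscedastic = isTRUE(heteroscedastic)
  ), class = "gap_spec")
}

## fan-in-scaled uniform initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_linear <- function(fan_in, fan_out) {
  lim <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
       b = stats::runif(fan_out, -lim, lim))
}

#' Initialize model parameters
#'
#' Deterministic given `(spec, seed)`: fan-in-scaled uniform weights and
#' biases, unit layer-norm gains, zero layer-norm shifts.
#'
#' @param spec A [gap_spec()].
#' @param seed Integer seed.
#' @return A `gap_params` list.
#' @export
init_gap_params <- function(spec, seed = 42) {
  stopifnot(inherits(spec, "gap_spec"))
  with_seed(derive_seed(seed, 6L), {
    p <- list(embed = init_linear(spec$input_dim, spec$embed_dim))
    prev <- spec$embed_dim
    p$encoder <- lapply(spec$encoder_dims, function(h) {
      l <- init_linear(prev, h)
      l$gamma <- rep(1, h); l$beta <- rep(0, h)
      prev <<- h
      l
    })
    z_dim <- prev
    if (spec$use_planner) {
      p$planner1 <- init_linear(z_dim, spec$planner_hidden)
      p$planner2 <- init_linear(spec$planner_hidden, spec$action_dim)
      trunk_in <- spec$action_dim
    } else {
      trunk_in <- z_dim
    }
    p$trunk <- init_linear(trunk_in, spec$forecaster_hidden)
    p$mu_head <- init_linear(spec$forecaster_hidden, 1L)
    if (spec$heteroscedastic)
      p$lv_head <- init_linear(spec$forecaster_hidden, 1L)
    structure(list(params = p, spec = spec, seed = as.integer(seed)),
              class = "gap_params")
  })
}

affine <- function(X, l) sweep(X %*% l$W, 2, l$b, "+")

check_finite <- function(M, layer) {
  if (!all(is.finite(M)))
    stop("non-finite activations in layer '", layer, "'", call. = FALSE)
  M
}

layernorm_fwd <- function(X, gamma, beta) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, gamma, "*") + matrix(beta, nrow(X), ncol(X),
                                                 byrow = TRUE),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, gamma) {
  H <- ncol(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  ## dX = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX,
       dgamma = colSums(dY * cache$xhat),
       dbeta = colSums(dY))
}

## Forward pass.  training=TRUE activates dropout (masks drawn from the
## current RNG stream).  Returns activations plus caches for backprop.
gap_forward <- function(model, X, training = FALSE) {
  stopifnot(inherits(model, "gap_params"))
  spec <- model$spec; p <- model$params
  X <- as.matrix(X)
  stop_if(ncol(X) != spec$input_dim,
          "X has ", ncol(X), " columns but the model expects ", spec$input_dim)
  stop_if(anyNA(X), "X must be fully observed")
  keep <- 1 - spec$dropout_p
  drop_mask <- function(n, m) {
    if (!training || spec$dropout_p == 0) NULL
    else matrix(stats::rbinom(n * m, 1, keep) / keep, n, m)
  }
  cache <- list()
  H <- check_finite(affine(X, p$embed), "embed")
  cache$embed_in <- X
  cur <- H
  cache$enc <- vector("list", length(p$encoder))
  for (i in seq_along(p$encoder)) {
    l <- p$encoder[[i]]
    lin <- affine(cur, l)
    ln <- layernorm_fwd(lin, l$gamma, l$beta)
    act <- pmax(ln$out, 0)
    mask <- drop_mask(nrow(act), ncol(act))
    out <- if (is.null(mask)) act else act * mask
    cache$enc[[i]] <- list(input = cur, ln = ln, act = act, mask = mask)
    cur <- check_finite(out, paste0("encoder", i))
  }
  Z <- cur
  if (spec$use_planner) {
    ph <- affine(Z, p$planner1)
    ph_act <- pmax(ph, 0)
    pmask <- drop_mask(nrow(ph_act), ncol(ph_act))
    ph_out <- if (is.null(pmask)) ph_act else ph_act * pmask
    A <- check_finite(affine(ph_out, p$planner2), "planner")
    cache$planner <- list(pre = ph, act = ph_act, mask = pmask, out = ph_out)
    trunk_in <- A
  } else {
    A <- NULL
    trunk_in <- Z
  }
  t_pre <- affine(trunk_in, p$trunk)
  t_act <- pmax(t_pre, 0)
  mu <- as.vector(affine(t_act, p$mu_head))
  check_finite(matrix(mu), "mu_head")
  if (spec$heteroscedastic) {
    log_var <- as.vector(affine(t_act, p$lv_head))
    check_finite(matrix(log_var), "lv_head")
    sigma2 <- pmin(pmax(exp(log_var), spec$variance_floor),
                   spec$variance_ceiling)
  } else {
    log_var <- NULL; sigma2 <- NULL
  }
  cache$trunk <- list(input = trunk_in, pre = t_pre, act = t_act)
  list(Z = Z, A = A, mu = mu, log_var = log_var, sigma2 = sigma2,
       cache = cache)
}

## Backward pass.  Takes upstream gradients at the network's output nodes
## (d_mu, d_log_var as n-vectors; d_A, d_Z as matrices or NULL) and returns
## a gradient list shaped like model$params.
gap_backward <- function(model, fwd, d_mu, d_log_var = NULL, d_A = NULL,
                         d_Z = NULL) {
  spec <- model$spec; p <- model$params; cache <- fwd$cache
  ## heads
  t_act <- cache$trunk$act
  d_tact <- matrix(0, nrow(t_act), ncol(t_act))
  g_mu <- list(W = crossprod(t_act, matrix(d_mu)), b = sum(d_mu))
  d_tact <- d_tact + matrix(d_mu) %*% t(p$mu_head$W)
  g_lv <- NULL
  if (spec$heteroscedastic) {
    dlv <- if (is.null(d_log_var)) numeric(length(fwd$log_var)) else d_log_var
    ## clamp: gradient is zero where exp(log_var) was clipped
    clipped <- exp(fwd$log_var) < spec$variance_floor |
      exp(fwd$log_var) > spec$variance_ceiling
    dlv[clipped] <- 0
    g_lv <- list(W = crossprod(t_act, matrix(dlv)), b = sum(dlv))
    d_tact <- d_tact + matrix(dlv) %*% t(p$lv_head$W)
  }
  d_tpre <- d_tact * (cache$trunk$pre > 0)
  g_trunk <- list(W = crossprod(cache$trunk$input, d_tpre),
                  b = colSums(d_tpre))
  d_trunk_in <- d_tpre %*% t(p$trunk$W)

  if (spec$use_planner) {
    dA <- d_trunk_in
    if (!is.null(d_A)) dA <- dA + d_A
    pc <- cache$planner
    g_p2 <- list(W = crossprod(pc$out, dA), b = colSums(dA))
    d_pout <- dA %*% t(p$planner2$W)
    if (!is.null(pc$mask)) d_pout <- d_pout * pc$mask
    d_ppre <- d_pout * (pc$pre > 0)
    g_p1 <- list(W = crossprod(fwd$Z, d_ppre), b = colSums(d_ppre))
    dZ <- d_ppre %*% t(p$planner1$W)
  } else {
    dZ <- d_trunk_in
    g_p1 <- g_p2 <- NULL
  }
  if (!is.null(d_Z)) dZ <- dZ + d_Z

  g_enc <- vector("list", length(p$encoder))
  d_out <- dZ
  for (i in rev(seq_along(p$encoder))) {
    ec <- cache$enc[[i]]
    d_act <- if (is.null(ec$mask)) d_out else d_out * ec$mask
    d_ln_out <- d_act * (ec$ln$out > 0)
    lnb <- layernorm_bwd(d_ln_out, ec$ln, p$encoder[[i]]$gamma)
    g_enc[[i]] <- list(W = crossprod(ec$input, lnb$dX),
                       b = colSums(lnb$dX),
                       gamma = lnb$dgamma, beta = lnb$dbeta)
    d_out <- lnb$dX %*% t(p$encoder[[i]]$W)
  }
  g_embed <- list(W = crossprod(cache$embed_in, d_out), b = colSums(d_out))

  out <- list(embed = g_embed, encoder = g_enc)
  if (spec$use_planner) { out$planner1 <- g_p1; out$planner2 <- g_p2 }
  out$trunk <- g_trunk
  out$mu_head <- g_mu
  if (spec$heteroscedastic) out$lv_head <- g_lv
  out
}

#' Monte-Carlo dropout prediction with uncertainty decomposition
#'
#' Runs `T` stochastic forward passes with dropout active and decomposes
#' predictive variance by the law of total variance: the aleatoric part is
#' the mean of the per-pass predicted variances, the epistemic part is the
#' population variance (denominator `T`) of the per-pass means, and the
#' total is their sum.
#'
#' @param model A `gap_params` (or `gap_model`) object.
#' @param X Feature matrix.
#' @param T Number of Monte-Carlo passes (default 20).
#' @param seed Integer seed for the dropout masks.
#' @param keep_draws Retain the per-pass mean matrix.
#' @return A `predictive_output`: list with `mu`, `var_aleatoric`,
#'   `var_epistemic`, `var_total`, `T`, optionally `draws`.
#' @export
mc_predict <- function(model, X, T = 20, seed = 42, keep_draws = FALSE) {
  if (inherits(model, "gap_model")) model <- model$fit
  stopifnot(inherits(model, "gap_params"))
  stop_if(T < 1, "T must be at least 1")
  spec <- model$spec
  n <- nrow(as.matrix(X))
  mu_t <- matrix(0, n, T)
  s2_t <- if (spec$heteroscedastic) matrix(0, n, T)
  with_seed(derive_seed(seed, 7L), {
    for (t in seq_len(T)) {
      fwd <- gap_forward(model, X, training = spec$dropout_p > 0)
      mu_t[, t] <- fwd$mu
      if (spec$heteroscedastic) s2_t[, t] <- fwd$sigma2
    }
  })
  mc_combine(mu_t, s2_t, floor = spec$variance_floor, keep_draws = keep_draws)
}

#' Combine Monte-Carlo predictive draws
#'
#' The decomposition used by [mc_predict()], exposed for direct use on any
#' per-pass mean matrix (and optional per-pass variance matrix).
#'
#' @param mu_t `n x T` matrix of per-pass predictive means.
#' @param sigma2_t Optional `n x T` matrix of per-pass predicted variances.
#' @param floor Lower bound applied to the aleatoric part.
#' @param keep_draws Retain `mu_t` in the result.
#' @return A `predictive_output`.
#' @export
mc_combine <- function(mu_t, sigma2_t = NULL, floor = 0, keep_draws = FALSE) {
  mu_t <- as.matrix(mu_t)
  T <- ncol(mu_t)
  mu <- rowMeans(mu_t)
  var_epi <- rowMeans((mu_t - mu)^2)          # population variance over T
  var_alea <- if (is.null(sigma2_t)) numeric(nrow(mu_t))
              else pmax(rowMeans(as.matrix(sigma2_t)), floor)
  structure(list(mu = mu, var_aleatoric = var_alea, var_epistemic = var_epi,
                 var_total = var_alea + var_epi, T = as.integer(T),
                 draws = if (keep_draws) mu_t),
            class = "predictive_output")
}

#' @export
print.predictive_output <- function(x, ...) {
  cat("predictive_output:", length(x$mu), "individuals,", x$T, "MC passes\n")
  cat(sprintf("  mean total variance %.4g (aleatoric %.4g + epistemic %.4g)\n",
              mean(x$var_total), mean(x$var_aleatoric), mean(x$var_epistemic)))
  invisible(x)
}

## flatten / unflatten parameter lists (used by the optimizer and the
## finite-difference gradient check)
flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

unflatten_params <- function(template, v) {
  pos <- 0
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  rebuild(template)
}

#' Save / load a model checkpoint
#'
#' The parameter blob is serialized with [saveRDS()]; a JSON sidecar
#' records the architecture, initialization seed and a hash of the
#' training configuration so predictions are reproducible from checkpoint
#' plus input alone.
#'
#' @param model A `gap_params` or `gap_model`.
#' @param path Checkpoint path (`.rds`); sidecar gets `.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  m <- if (inherits(model, "gap_model")) model$fit else model
  meta <- list(spec = unclass(m$spec), init_seed = m$seed,
               package_version = as.character(utils::packageVersion("gapred")))
  if (inherits(model, "gap_model"))
    meta$train_config_hash <- model$config_hash
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
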