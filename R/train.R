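## Training loop: Adam with decoupled-from-nothing (coupled, gradient-added)
## weight decay, cosine-annealed learning rate, per-epoch validation
## monitoring and best-validation-RMSE checkpointing.

#' Training configuration
#'
#' Defaults follow the study configuration: 120 epochs, batch size 64,
#' Adam with initial learning rate 0.001 and weight decay 0.0001, cosine
#' annealing of the learning rate towards zero, seed 42, 20 Monte-Carlo
#' passes at prediction time.
#'
#' @param epochs,batch_size,lr,weight_decay Optimizer settings.
#' @param scheduler `"cosine"` or `"constant"`.
#' @param graph_warmup Fraction of training during which the manifold and
#'   smoothness penalty weights ramp linearly from 0 to their full values.
#'   A Laplacian-type penalty is minimized by a collapsed (constant)
#'   embedding, so applying it at full strength before the representation
#'   has differentiated individuals can trap training in that degenerate
#'   optimum; ramping it in is the standard guard.  `0` disables the
#'   ramp.
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout.
#' @param T_mc Monte-Carlo passes used by [predict.gap_model()].
#' @param graph_k,graph_h Similarity-graph parameters used when
#'   [gap_fit()] has to build the graph itself.
#' @param verbose Print one line per epoch.
#' @return A `gap_control` list.
#' @export
gap_control <- function(epochs = 120, batch_size = 64, lr = 0.001,
                        weight_decay = 1e-4,
                        scheduler = c("cosine", "constant"), seed = 42,
                        T_mc = 20, graph_k = 10, graph_h = "median",
                        graph_warmup = 0.25, verbose = FALSE) {
  stop_if(epochs < 1 || batch_size < 1 || lr <= 0,
          "epochs, batch_size and lr must be positive")
  stop_if(weight_decay < 0, "weight_decay must be nonnegative")
  stop_if(graph_warmup < 0 || graph_warmup > 1,
          "graph_warmup must lie in [0, 1]")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay,
                 scheduler = match.arg(scheduler), seed = as.integer(seed),
                 T_mc = as.integer(T_mc), graph_k = as.integer(graph_k),
                 graph_h = graph_h, graph_warmup = graph_warmup,
                 verbose = isTRUE(verbose)),
            class = "gap_control")
}

cosine_lr <- function(lr0, epoch, epochs, scheduler) {
  if (scheduler == "constant") return(lr0)
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / epochs))
}

#' Fit the uncertainty-aware genomic predictor
#'
#' Trains the three-stage network on the training partition of a
#' `gap_dataset` by minimizing the composite objective (data NLL +
#' manifold + reward + output-smoothness penalties) with Adam, monitoring
#' validation NLL and RMSE after every epoch and returning the parameters
#' of the epoch with the best validation RMSE.
#'
#' @param dataset A `gap_dataset` from [build_dataset()].
#' @param spec A [gap_spec()]; defaults to the standard architecture for
#'   the dataset's feature count.
#' @param weights A [loss_weights()].
#' @param control A [gap_control()].
#' @param graph Optional pre-built `similarity_graph` over the training
#'   rows (in training-row order); built from the training genotype
#'   features when missing and a graph term is active.
#' @return A `gap_model` with elements `fit` (best parameters), `log`
#'   (per-epoch data.frame), `graph`, `spec`, `weights`, `control`,
#'   `best_epoch`, and the normalization parameters needed to predict on
#'   new cohorts.
#' @export
gap_fit <- function(dataset, spec = NULL, weights = loss_weights(),
                    control = gap_control(), graph = NULL) {
  stopifnot(inherits(dataset, "gap_dataset"))
  if (is.null(spec)) spec <- gap_spec(ncol(dataset$X))
  stopifnot(inherits(spec, "gap_spec"), inherits(weights, "loss_weights"),
            inherits(control, "gap_control"))
  tr <- split_rows(dataset, "train")
  va <- split_rows(dataset, "validation")
  stop_if(length(tr) < 2 || length(va) < 1,
          "dataset must carry non-empty train and validation partitions")
  Xtr <- dataset$X[tr, , drop = FALSE]; ytr <- dataset$y[tr]
  y3tr <- dataset$y3[tr, , drop = FALSE]
  Xva <- dataset$X[va, , drop = FALSE]; yva <- dataset$y[va]

  need_graph <- weights$lambda_manifold > 0 || weights$lambda_constraint > 0
  if (need_graph && is.null(graph)) {
    graph <- build_similarity(Xtr[, dataset$genotype_cols, drop = FALSE],
                              k = min(control$graph_k, length(tr) - 1),
                              h = control$graph_h)
  }

  model <- init_gap_params(spec, control$seed)
  template <- model$params
  theta <- flatten_params(template)
  m_t <- v_t <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; step <- 0

  n_tr <- length(tr)
  log_rows <- vector("list", control$epochs)
  best <- list(rmse = Inf, params = model$params, epoch = 0L)

  with_seed(derive_seed(control$seed, 8L), {
    for (epoch in seq_len(control$epochs)) {
      lr <- cosine_lr(control$lr, epoch, control$epochs, control$scheduler)
      ## graph penalties ramp in linearly over the warm-up fraction
      warm_epochs <- control$graph_warmup * control$epochs
      ramp <- if (warm_epochs > 0) min(1, (epoch - 1) / warm_epochs) else 1
      ew <- weights
      ew$lambda_manifold <- weights$lambda_manifold * ramp
      ew$lambda_constraint <- weights$lambda_constraint * ramp
      perm <- sample(n_tr)
      comp_sums <- c(data = 0, manifold = 0, reward = 0, constraint = 0)
      total_sum <- 0; n_batches <- 0
      for (start in seq(1, n_tr, by = control$batch_size)) {
        idx <- perm[start:min(start + control$batch_size - 1, n_tr)]
        sub <- if (need_graph) induce_subgraph(graph, idx)
        bl <- tryCatch(
          batch_loss_grads(model, Xtr[idx, , drop = FALSE], ytr[idx],
                           y3tr[idx, , drop = FALSE], sub, ew,
                           training = TRUE),
          error = function(e)
            stop("training diverged at epoch ", epoch, ": ",
                 conditionMessage(e), call. = FALSE))
        if (!is.finite(bl$loss$total))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        g <- flatten_params(bl$grads) + control$weight_decay * theta
        step <- step + 1
        m_t <- beta1 * m_t + (1 - beta1) * g
        v_t <- beta2 * v_t + (1 - beta2) * g^2
        mhat <- m_t / (1 - beta1^step)
        vhat <- v_t / (1 - beta2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + adam_eps)
        model$params <- unflatten_params(template, theta)
        comp_sums <- comp_sums + bl$loss$weighted
        total_sum <- total_sum + bl$loss$total
        n_batches <- n_batches + 1
      }
      ## validation pass, dropout off
      fv <- gap_forward(model, Xva, training = FALSE)
      val_rmse <- sqrt(mean((yva - fv$mu)^2))
      val_nll <- if (spec$heteroscedastic)
        gaussian_nll(yva, fv$mu, fv$sigma2) else mean((yva - fv$mu)^2)
      if (is.finite(val_rmse) && val_rmse < best$rmse) {
        best <- list(rmse = val_rmse, params = model$params, epoch = epoch)
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_total = total_sum / n_batches,
        train_data = comp_sums[["data"]] / n_batches,
        train_manifold = comp_sums[["manifold"]] / n_batches,
        train_reward = comp_sums[["reward"]] / n_batches,
        train_constraint = comp_sums[["constraint"]] / n_batches,
        val_nll = val_nll, val_rmse = val_rmse)
      if (control$verbose)
        cat(sprintf("epoch %3d  lr %.5f  train %.4f  val RMSE %.4f  val NLL %.4f\n",
                    epoch, lr, total_sum / n_batches, val_rmse, val_nll))
    }
  })
  model$params <- best$params
  structure(list(
    fit = model, spec = spec, weights = weights, control = control,
    graph = graph, log = do.call(rbind, log_rows), best_epoch = best$epoch,
    best_val_rmse = best$rmse,
    norm_params = dataset$params, features = dataset$features,
    genotype_cols = dataset$genotype_cols,
    config_hash = config_hash(list(spec = unclass(spec),
                                   weights = unclass(weights),
                                   control = unclass(control)))
  ), class = "gap_model")
}

config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  ## small rolling hash; provenance identifier, not cryptographic
  sum_ <- 0
  for (ch in utf8ToInt(as.character(s))) sum_ <- (sum_ * 31 + ch) %% 2^31
  sprintf("%08x", sum_)
}

#' Repeat training over multiple seeds
#'
#' Re-trains with seeds `base, base + 1, ..., base + n_runs - 1` and
#' summarizes the four test-set regression metrics as mean and sample SD
#' across runs.
#'
#' @param dataset A `gap_dataset`.
#' @param spec,weights,control As in [gap_fit()]; `control$seed` is the
#'   base seed.
#' @param n_runs Number of repeats (>= 2; the study protocol uses 10).
#' @return A `run_summary`: list with `metrics` (one row per seed),
#'   `mean`, `sd`, `seeds`.
#' @export
multi_seed_runs <- function(dataset, spec = NULL, weights = loss_weights(),
                            control = gap_control(), n_runs = 10) {
  stop_if(n_runs < 2, "n_runs must be at least 2")
  seeds <- control$seed + seq_len(n_runs) - 1
  rows <- lapply(seeds, function(s) {
    ctl <- control; ctl$seed <- as.integer(s)
    m <- gap_fit(dataset, spec, weights, ctl)
    mets <- evaluate_model(m, dataset, "test")
    data.frame(seed = s, pearson = mets$pearson, rmse = mets$rmse,
               r2 = mets$r2, mae = mets$mae)
  })
  tab <- do.call(rbind, rows)
  structure(list(metrics = tab,
                 mean = colMeans(tab[, -1]),
                 sd = apply(tab[, -1], 2, stats::sd),
                 seeds = seeds), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("run_summary over", length(x$seeds), "seeds\n")
  for (m in names(x$mean))
    cat(sprintf("  %-8s %.4f +- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
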