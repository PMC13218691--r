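test_that("regression metrics match closed forms and the brute-force oracle", {
  y <- c(1, 2, 3)
  r <- regression_metrics(y, y)
  expect_equal(c(r$pearson, r$rmse, r$r2, r$mae), c(1, 0, 1, 0))

  expect_warning(rc <- regression_metrics(y, c(2, 2, 2)), "undefined")
  expect_true(is.na(rc$pearson))
  expect_equal(rc$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(rc$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(rc$r2, 0, tolerance = 1e-12)

  set.seed(61)
  for (trial in 1:5) {
    n <- sample(10:100, 1)
    yy <- stats::rnorm(n); mm <- stats::rnorm(n)
    got <- regression_metrics(yy, mm)
    want <- oracle_metrics(yy, mm)
    for (k in names(want))
      expect_equal(got[[k]], want[[k]], tolerance = 1e-10)
    expect_gte(got$rmse, got$mae)
    expect_lte(got$r2, 1)
  }
})

test_that("calibration error detects well- and mis-specified variances", {
  set.seed(62)
  n <- 5000
  mu <- stats::rnorm(n)
  sdv <- stats::runif(n, 0.5, 2)
  y <- stats::rnorm(n, mu, sdv)
  expect_lt(calibration_error(y, mu, sdv^2), 0.03)
  ## reporting half the true SD must look badly miscalibrated
  expect_gt(calibration_error(y, mu, (sdv / 2)^2), 0.10)
  ## a single level whose empirical coverage matches exactly gives zero:
  ## half the points sit at their mean, half far outside the 50% interval
  y0 <- c(rep(0, 10), rep(10, 10))
  expect_equal(calibration_error(y0, rep(0, 20), rep(1, 20), grid = 0.5), 0)
  expect_error(calibration_error(y[1:10], mu[1:10], sdv[1:10]^2), "20")
})

test_that("stratification cuts 20/60/20 and orders groups by skill", {
  set.seed(63)
  n <- 10
  y <- stats::rnorm(n)
  rep1 <- stratify_by_prediction(y, y)
  expect_equal(rep1$n, c(2, 6, 2))
  expect_gt(rep1$score_mean[rep1$group == "top"],
            rep1$score_mean[rep1$group == "bottom"])
  ## anti-correlated predictions invert the ordering
  rep2 <- stratify_by_prediction(-y, y)
  expect_lt(rep2$score_mean[rep2$group == "top"],
            rep2$score_mean[rep2$group == "bottom"])
  ## sizes always sum to n
  for (m in c(10, 23, 57)) {
    r <- stratify_by_prediction(stats::rnorm(m), stats::rnorm(m))
    expect_equal(sum(r$n), m)
  }
  expect_error(stratify_by_prediction(stats::rnorm(5), stats::rnorm(5)),
               "at least 10")
})

test_that("stratification summarizes indicators per group", {
  set.seed(64)
  n <- 50
  y <- stats::rnorm(n)
  ind <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("speed", "endurance", "strength")))
  rep <- stratify_by_prediction(y, y, ind)
  expect_true(all(c("speed_mean", "endurance_sd") %in% colnames(rep)))
  g <- attr(rep, "groups")
  expect_equal(rep$speed_mean[1], mean(ind[g == "top", "speed"]))
})

test_that("uncertainty triage groups coherently and floors the exclusion", {
  set.seed(65)
  n <- 200
  sdv <- stats::runif(n, 0.3, 2)
  mu <- stats::rnorm(n)
  y <- stats::rnorm(n, mu, sdv)
  tr <- uncertainty_triage(y, mu, sdv^2)
  expect_equal(tr$setting,
               c("all", "low_uncertainty", "high_uncertainty",
                 "excluded_top10"))
  expect_equal(tr$n, c(200, 100, 100, 180))
  groups <- attr(tr, "groups")
  expect_equal(sum(groups == "low") + sum(groups == "high"), n)
  excl <- attr(tr, "excluded")
  expect_length(excl, 20)
  expect_true(all(groups[excl] == "high"))
  ## oracle variances: low-uncertainty half must have lower RMSE
  expect_lt(tr$rmse[2], tr$rmse[3])
  expect_lt(tr$rmse[4], tr$rmse[1])
  ## n = 20 excludes exactly 2
  tr20 <- uncertainty_triage(y[1:20], mu[1:20], sdv[1:20]^2)
  expect_equal(tr20$n[4], 18)
  expect_error(uncertainty_triage(y[1:10], mu[1:10], sdv[1:10]^2), "20")
})

test_that("triage stays well-formed under constant predicted variance", {
  set.seed(66)
  n <- 60
  y <- stats::rnorm(n); mu <- stats::rnorm(n)
  tr <- uncertainty_triage(y, mu, rep(1, n))
  expect_true(all(is.finite(tr$rmse)))
  expect_equal(tr$n[2] + tr$n[3], n)
})

test_that("the OLS baseline recovers exact linear signal and rejects noise", {
  set.seed(67)
  ds <- tiny_dataset(200, 10, seed = 68)
  ## overwrite the target with an exactly linear, noiseless function
  beta <- stats::rnorm(ncol(ds$X))
  ds_lin <- ds
  ds_lin$y <- as.vector(ds$X %*% beta) + 0.5
  rep_lin <- ols_baseline(ds_lin)
  expect_gt(rep_lin$r2, 1 - 1e-8)
  expect_lt(rep_lin$rmse, 1e-6)
  ## independent target: test R^2 near zero
  ds_null <- ds
  set.seed(69)
  ds_null$y <- stats::rnorm(length(ds$y))
  rep_null <- ols_baseline(ds_null)
  expect_lt(rep_null$r2, 0.25)
  expect_lt(abs(rep_null$pearson), 0.5)
})

test_that("ridge fallback engages when features outnumber training rows", {
  co <- tiny_cohort(40, 60, seed = 70)
  ds <- build_dataset(co, seed = 70, features = "genotype-only")
  rep <- ols_baseline(ds)
  expect_true(is.finite(rep$rmse))
})

test_that("ablation surgeries produce the declared model variants", {
  sp <- gap_spec(12)
  w <- loss_weights()
  a <- gapred:::apply_variant("no_manifold", sp, w)
  expect_equal(a$weights$lambda_manifold, 0)
  expect_equal(a$spec$encoder_dims, 64L)
  b <- gapred:::apply_variant("no_planner", sp, w)
  expect_false(b$spec$use_planner)
  expect_equal(b$weights$lambda_reward, 0)
  c <- gapred:::apply_variant("no_uncertainty", sp, w)
  expect_false(c$spec$heteroscedastic)
  d <- gapred:::apply_variant("no_constraint", sp, w)
  expect_equal(d$weights$lambda_constraint, 0)
  expect_error(gapred:::apply_variant("bogus", sp, w), "unknown")
})

test_that("ablation and sensitivity harnesses run end to end", {
  ds <- tiny_dataset(250, 10, seed = 71)
  sp <- gap_spec(ncol(ds$X), embed_dim = 8, encoder_dims = c(8, 6),
                 planner_hidden = 6, forecaster_hidden = 6)
  ctl <- gap_control(epochs = 2, batch_size = 32, seed = 1)
  ab <- ablation_suite(ds, sp, control = ctl)
  expect_equal(nrow(ab), 5)
  expect_true(all(is.finite(ab$rmse)))
  ## the homoscedastic variant reports no calibration entry
  expect_true(is.na(ab$calibration[ab$variant == "no_uncertainty"]))
  expect_false(anyNA(ab$calibration[ab$variant == "full"]))

  sens <- sensitivity_suite(ds, grids = list(feature_noise_sd = c(0, 0.1)),
                            spec = sp, control = ctl)
  expect_equal(nrow(sens), 2)
  expect_true(all(is.finite(sens$rmse)))
  ## zero feature noise reproduces the baseline configuration exactly
  base <- gap_fit(ds, sp, loss_weights(), ctl)
  rep0 <- evaluate_model(base, ds, "test")
  expect_equal(sens$rmse[sens$value == 0], rep0$rmse, tolerance = 1e-12)
  expect_error(sensitivity_suite(ds, grids = list()), "non-empty")
  expect_error(sensitivity_suite(ds, grids = list(bogus = 1)), "unknown")
})
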