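test_that("cohort round-trips through TSV files", {
  co <- tiny_cohort(30, 8, seed = 21)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(file.path(dir, "genotypes.tsv"),
                      file.path(dir, "phenotypes.tsv"))
  expect_equal(back$ids, co$ids)
  expect_equal(unname(back$genotypes), unname(co$genotypes))
  expect_equal(back$phenotypes, co$phenotypes, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$true_genetic_value, co$true_genetic_value,
               tolerance = 1e-12)
})

test_that("read_cohort inner-joins on id and logs drops", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tm1\tm2", "a\t0\t1", "b\t1\t2", "c\t2\t0", "d\t1\t1"),
             file.path(dir, "genotypes.tsv"))
  writeLines(c("id\tspeed\tendurance\tstrength",
               "a\t1\t2\t3", "b\t2\t3\t4", "c\t0\t1\t2"),
             file.path(dir, "phenotypes.tsv"))
  co <- read_cohort(file.path(dir, "genotypes.tsv"),
                    file.path(dir, "phenotypes.tsv"))
  expect_equal(co$ids, c("a", "b", "c"))
  expect_equal(attr(co, "dropped"), "d")

  writeLines(c("id\tspeed\tspeed\tstrength", "a\t1\t2\t3"),
             file.path(dir, "bad.tsv"))
  expect_error(read_cohort(file.path(dir, "genotypes.tsv"),
                           file.path(dir, "bad.tsv")), "speed")
  writeLines(c("id\tspeed\tendurance\tstrength", "z\t1\t2\t3"),
             file.path(dir, "nooverlap.tsv"))
  expect_error(read_cohort(file.path(dir, "genotypes.tsv"),
                           file.path(dir, "nooverlap.tsv")), "overlap")
})

test_that("cleaning applies duplicate, missing and 3-SD rules in order", {
  co <- tiny_cohort(50, 6, seed = 22)
  clean0 <- clean_cohort(co)
  rep0 <- attr(clean0, "report")
  expect_equal(c(rep0$duplicates, rep0$missing, rep0$outliers), c(0, 0, 0))
  expect_equal(clean0$ids, co$ids)

  ## duplicate: append row 1 again; missing: NA a genotype cell of row 2
  co2 <- co
  co2$ids <- c(co2$ids, co2$ids[1])
  co2$genotypes <- rbind(co2$genotypes, co2$genotypes[1, ])
  co2$phenotypes <- rbind(co2$phenotypes, co2$phenotypes[1, ])
  co2$historical <- rbind(co2$historical, co2$historical[1, ])
  co2$true_genetic_value <- c(co2$true_genetic_value, co2$true_genetic_value[1])
  co2$true_noise_sd <- c(co2$true_noise_sd, co2$true_noise_sd[1])
  co2$genotypes[2, 3] <- NA
  cleaned <- clean_cohort(co2)
  rep <- attr(cleaned, "report")
  expect_equal(rep$duplicates, 1)
  expect_equal(rep$missing, 1)
  expect_false(co$ids[2] %in% cleaned$ids)
  expect_equal(sum(cleaned$ids == co$ids[1]), 1)
})

test_that("the 3-SD rule matches its brute-force arithmetic", {
  ## 100 zeros and one 50: mean ~0.495, sample SD ~4.975, 3 SD ~14.9 < 49.5
  n <- 101
  co <- new_cohort_for_test(n)
  co$phenotypes$speed <- c(rep(0, 100), 50)
  cleaned <- clean_cohort(co)
  expect_equal(attr(cleaned, "report")$outliers, 1)
  expect_false("id101" %in% cleaned$ids)
  x <- c(rep(0, 100), 50)
  expect_true(abs(50 - mean(x)) > 3 * stats::sd(x))

  ## small-n insensitivity: [0,0,0,0,100] removes nothing
  co5 <- new_cohort_for_test(5)
  co5$phenotypes$speed <- c(0, 0, 0, 0, 100)
  cleaned5 <- clean_cohort(co5)
  expect_equal(attr(cleaned5, "report")$outliers, 0)
  x5 <- c(0, 0, 0, 0, 100)
  expect_true(abs(100 - mean(x5)) < 3 * stats::sd(x5))
})

test_that("outlier removal is invariant to input row order", {
  co <- tiny_cohort(200, 6, seed = 23)
  co$phenotypes$speed[7] <- mean(co$phenotypes$speed) +
    12 * stats::sd(co$phenotypes$speed)
  removed1 <- attr(clean_cohort(co), "report")$removed_ids
  perm <- with_seed_for_test(1, sample(length(co$ids)))
  co_p <- co
  co_p$ids <- co$ids[perm]
  co_p$genotypes <- co$genotypes[perm, ]
  co_p$phenotypes <- co$phenotypes[perm, ]
  co_p$historical <- co$historical[perm, ]
  co_p$true_genetic_value <- co$true_genetic_value[perm]
  co_p$true_noise_sd <- co$true_noise_sd[perm]
  removed2 <- attr(clean_cohort(co_p), "report")$removed_ids
  expect_setequal(removed1, removed2)
})

test_that("splits follow 8:1:1 with floors and the remainder in test", {
  ids <- sprintf("s%04d", 1:1000)
  sp <- split_cohort(ids, seed = 1)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 800, validation = 100, test = 100))
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)

  sp2 <- split_cohort(sprintf("s%04d", 1:1003), seed = 1)
  expect_equal(lengths(sp2[c("train", "validation", "test")]),
               c(train = 802, validation = 100, test = 101))

  expect_identical(split_cohort(ids, seed = 5), split_cohort(ids, seed = 5))
  expect_false(identical(split_cohort(ids, seed = 5)$train,
                         split_cohort(ids, seed = 6)$train))
  expect_error(split_cohort(letters[1:9]), "at least 10")
})

test_that("partition property holds across sizes", {
  for (n in c(10, 11, 37, 250)) {
    ids <- as.character(seq_len(n))
    sp <- split_cohort(ids, seed = n)
    expect_setequal(c(sp$train, sp$validation, sp$test), ids)
    expect_equal(length(sp$train) + length(sp$validation) + length(sp$test), n)
    expect_length(intersect(sp$validation, sp$test), 0)
  }
})

test_that("normalization matches hand-computed values and does not clip", {
  ## genotype min-max: train [2,4,6] -> [0, 0.5, 1]; test 8 -> 1.5
  p <- structure(list(g_min = 2, g_max = 6,
                      ind_mean = c(speed = 2, endurance = 2, strength = 2),
                      ind_sd = c(speed = 1, endurance = 1, strength = 1),
                      hist_mean = NULL, hist_sd = NULL,
                      y_mean = 0, y_sd = 1, constant_cols = integer(0)),
                 class = "norm_params")
  g <- matrix(c(2, 4, 6, 8), 4, 1)
  rngv <- p$g_max - p$g_min
  expect_equal(as.vector((g - p$g_min) / rngv), c(0, 0.5, 1, 1.5))

  ## indicator z-score: [1,2,3] with sample SD 1 -> [-1, 0, 1]
  expect_equal(stats::sd(1:3), 1)
  expect_equal((c(1, 2, 3) - 2) / 1, c(-1, 0, 1))
})

test_that("normalizers are fitted on the training partition only", {
  ds <- tiny_dataset(150, 10, seed = 24)
  co <- tiny_cohort(150, 10, seed = 24)
  cleaned <- clean_cohort(co)
  refit <- fit_normalizers(cleaned, ds$split)
  expect_equal(refit, ds$params)
  ## perturbing a test-only row must not change the fitted parameters
  te_id <- ds$split$test[1]
  i <- which(cleaned$ids == te_id)
  cleaned$phenotypes$speed[i] <- cleaned$phenotypes$speed[i] + 100
  cleaned$genotypes[i, 1] <- cleaned$genotypes[i, 1] + 0  # dosage unchanged
  refit2 <- fit_normalizers(cleaned, ds$split)
  expect_equal(refit2, ds$params)
})

test_that("normalization is invertible for non-constant columns", {
  ds <- tiny_dataset(100, 12, seed = 25)
  co <- clean_cohort(tiny_cohort(100, 12, seed = 25))
  back <- inverse_normalize(ds$X, ds$params, ds$genotype_cols)
  expect_lt(max(abs(back[, ds$genotype_cols] - co$genotypes)), 1e-10)
})

test_that("the potential score is the standardized indicator average", {
  ds <- tiny_dataset(100, 8, seed = 26)
  tr <- which(ds$ids %in% ds$split$train)
  expect_equal(mean(ds$y[tr]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(ds$y[tr]), 1, tolerance = 1e-10)

  ## three identical indicator columns: y equals each indicator's z-score
  co <- new_cohort_for_test(30)
  v <- stats::rnorm(30)
  co$phenotypes$speed <- v; co$phenotypes$endurance <- v
  co$phenotypes$strength <- v
  sp <- split_cohort(co$ids, seed = 2)
  pr <- fit_normalizers(co, sp)
  y <- build_target(co, pr)
  tr_rows <- which(co$ids %in% sp$train)
  z <- (v - mean(v[tr_rows])) / stats::sd(v[tr_rows])
  z <- (z - mean(z[tr_rows])) / stats::sd(z[tr_rows])
  expect_equal(y, z, tolerance = 1e-10)

  ## 3-row worked example: indicators [[1,1,1],[2,2,2],[3,3,3]] -> [-1,0,1]
  z3 <- (1:3 - 2) / 1
  expect_equal((rowMeans(cbind(z3, z3, z3)) - 0) / 1, c(-1, 0, 1))
})

test_that("an individual at the train means scores zero", {
  co <- new_cohort_for_test(40)
  sp <- split_cohort(co$ids, seed = 3)
  pr <- fit_normalizers(co, sp)
  co$phenotypes[1, ] <- pr$ind_mean
  y <- build_target(co, pr)
  expect_equal(unname(y[1]), unname(-pr$y_mean / pr$y_sd), tolerance = 1e-12)
  ## with symmetric indicators the raw mean-score is ~0 at the means
  expect_equal(unname(y[1]) * pr$y_sd + pr$y_mean, 0, tolerance = 1e-12)
})

test_that("feature noise is Gaussian, seeded and genotype-only", {
  ds <- tiny_dataset(100, 20, seed = 27)
  expect_identical(inject_feature_noise(ds, 0), ds)
  n1 <- inject_feature_noise(ds, 0.05, seed = 5)
  n2 <- inject_feature_noise(ds, 0.05, seed = 5)
  expect_identical(n1, n2)
  hist_cols <- setdiff(seq_len(ncol(ds$X)), ds$genotype_cols)
  expect_identical(n1$X[, hist_cols], ds$X[, hist_cols])
  X <- matrix(0, 1000, 1000)
  Xn <- inject_feature_noise(X, 0.05, seed = 6)
  expect_equal(stats::sd(Xn - X), 0.05, tolerance = 0.001)
})

test_that("processed datasets persist and reload faithfully", {
  ds <- tiny_dataset(80, 10, seed = 28)
  dir <- withr::local_tempdir()
  save_dataset(ds, dir)
  back <- load_dataset(dir)
  expect_equal(unname(back$X), unname(ds$X))
  expect_equal(back$y, ds$y, tolerance = 1e-12)
  expect_equal(back$split$train, ds$split$train)
  expect_equal(back$genotype_cols, ds$genotype_cols)
})
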