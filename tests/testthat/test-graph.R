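test_that("kNN graph construction matches hand-worked geometry", {
  ## 1-D points at 0, 1, 3 with k = 1, h = 1
  X <- matrix(c(0, 1, 3), 3, 1)
  g <- build_similarity(X, k = 1, h = 1)
  expect_equal(g$edges$i, c(1, 2))
  expect_equal(g$edges$j, c(2, 3))
  expect_equal(g$edges$w, c(exp(-0.5), exp(-2)), tolerance = 1e-12)

  ## identical rows as mutual neighbours get weight exp(0) = 1
  X2 <- rbind(c(1, 2), c(1, 2), c(9, 9))
  g2 <- build_similarity(X2, k = 1, h = 1)
  e <- g2$edges[g2$edges$i == 1 & g2$edges$j == 2, ]
  expect_equal(e$w, 1)

  ## k = 0 gives the empty graph
  g0 <- build_similarity(X, k = 0)
  expect_equal(nrow(g0$edges), 0)
  expect_error(build_similarity(X, k = 3), "smaller")
})

test_that("graph weights are in [0,1], symmetric and zero-diagonal", {
  set.seed(31)
  X <- matrix(stats::rnorm(40 * 6), 40, 6)
  g <- build_similarity(X, k = 5)
  C <- graph_matrix(g)
  expect_true(all(g$edges$w > 0 & g$edges$w <= 1))
  expect_equal(C, t(C))
  expect_true(all(diag(C) == 0))
  expect_true(all(g$edges$i < g$edges$j))
})

test_that("median bandwidth falls back on duplicate-dominated inputs", {
  X <- matrix(rep(c(0, 0, 0, 5), each = 2), ncol = 1)
  expect_silent(g <- build_similarity(X, k = 1, h = "median"))
  expect_true(is.finite(g$h) && g$h > 0)
})

test_that("manifold and smoothness losses equal dense brute-force oracles", {
  set.seed(32)
  for (trial in 1:5) {
    n <- sample(10:50, 1)
    X <- matrix(stats::rnorm(n * 4), n, 4)
    g <- build_similarity(X, k = sample(2:5, 1))
    C <- graph_matrix(g)
    Z <- matrix(stats::rnorm(n * 3), n, 3)
    yhat <- stats::rnorm(n)
    expect_equal(manifold_loss(Z, g), oracle_manifold(Z, C), tolerance = 1e-10)
    expect_equal(manifold_loss(Z, g, normalize = FALSE),
                 oracle_manifold(Z, C, normalize = FALSE), tolerance = 1e-10)
    expect_equal(output_smoothness(yhat, g), oracle_smoothness(yhat, C),
                 tolerance = 1e-10)
  }
})

test_that("manifold loss worked example and degenerate cases hold", {
  ## two nodes, one undirected edge w = 0.5, Z = (0,0) and (1,0)
  g <- structure(list(edges = data.frame(i = 1, j = 2, w = 0.5), n = 2,
                      k = 1L, h = 1), class = "similarity_graph")
  Z <- rbind(c(0, 0), c(1, 0))
  expect_equal(manifold_loss(Z, g, normalize = FALSE), 1.0)
  expect_equal(manifold_loss(Z, g), 0.5)

  ## identical embeddings and empty graphs give zero
  expect_equal(manifold_loss(rbind(c(1, 1), c(1, 1)), g), 0)
  g0 <- structure(list(edges = data.frame(i = integer(0), j = integer(0),
                                          w = numeric(0)),
                       n = 2, k = 0L, h = 1), class = "similarity_graph")
  expect_equal(manifold_loss(Z, g0), 0)
})

test_that("smoothness is zero for constant output and scale-invariant", {
  g <- structure(list(edges = data.frame(i = 1, j = 2, w = 1), n = 2,
                      k = 1L, h = 1), class = "similarity_graph")
  expect_equal(output_smoothness(c(0, 1), g), 1.0)
  expect_equal(output_smoothness(c(3, 3), g), 0)
  g2 <- g; g2$edges$w <- 2 * g$edges$w
  y <- c(0.3, -1.2)
  expect_equal(output_smoothness(y, g), output_smoothness(y, g2))
  g0 <- structure(list(edges = data.frame(i = integer(0), j = integer(0),
                                          w = numeric(0)),
                       n = 2, k = 0L, h = 1), class = "similarity_graph")
  expect_warning(v <- output_smoothness(c(0, 1), g0), "empty")
  expect_equal(v, 0)
})

test_that("increasing one connected pairwise distance increases the loss", {
  set.seed(33)
  X <- matrix(stats::rnorm(20 * 3), 20, 3)
  g <- build_similarity(X, k = 3)
  Z <- matrix(stats::rnorm(20 * 2), 20, 2)
  base <- manifold_loss(Z, g, normalize = FALSE)
  ## stretch a single connected pair apart while leaving the loss
  ## contributions of that pair's other edges non-decreasing: isolate the
  ## pair's term by brute force on the dense matrix
  e <- g$edges[1, ]
  C <- graph_matrix(g)
  stretch <- function(f) {
    Z2 <- Z
    Z2[e$i, ] <- Z[e$j, ] + f * (Z[e$i, ] - Z[e$j, ])
    2 * C[e$i, e$j] * sum((Z2[e$i, ] - Z2[e$j, ])^2)
  }
  expect_gt(stretch(3), stretch(1))
  ## and globally: dilating all embeddings scales every term up
  expect_equal(manifold_loss(2 * Z, g, normalize = FALSE), 4 * base,
               tolerance = 1e-10)
})

test_that("losses are invariant under consistent node permutation", {
  set.seed(34)
  n <- 15
  X <- matrix(stats::rnorm(n * 3), n, 3)
  g <- build_similarity(X, k = 3)
  Z <- matrix(stats::rnorm(n * 2), n, 2)
  yhat <- stats::rnorm(n)
  perm <- sample(n)
  gp <- build_similarity(X[perm, , drop = FALSE], k = 3)
  expect_equal(manifold_loss(Z[perm, , drop = FALSE], gp),
               manifold_loss(Z, g), tolerance = 1e-10)
  expect_equal(output_smoothness(yhat[perm], gp), output_smoothness(yhat, g),
               tolerance = 1e-10)
})

test_that("graphs persist as edge TSV plus JSON sidecar", {
  set.seed(35)
  g <- build_similarity(matrix(stats::rnorm(30), 10, 3), k = 2)
  path <- file.path(withr::local_tempdir(), "graph.tsv")
  write_graph(g, path)
  back <- read_graph(path)
  expect_equal(back$edges$w, g$edges$w, tolerance = 1e-12)
  expect_equal(back$n, g$n)
  expect_equal(back$h, g$h, tolerance = 1e-12)
})

test_that("analytic penalty gradients match finite differences", {
  set.seed(36)
  n <- 8
  X <- matrix(stats::rnorm(n * 3), n, 3)
  g <- build_similarity(X, k = 2)
  Z <- matrix(stats::rnorm(n * 2), n, 2)
  ga <- gapred:::manifold_loss_grad(Z, g)
  eps <- 1e-6
  for (idx in sample(length(Z), 5)) {
    Zp <- Z; Zp[idx] <- Zp[idx] + eps
    Zm <- Z; Zm[idx] <- Zm[idx] - eps
    fd <- (manifold_loss(Zp, g) - manifold_loss(Zm, g)) / (2 * eps)
    expect_equal(ga[idx], fd, tolerance = 1e-5)
  }
  yhat <- stats::rnorm(n)
  gs <- gapred:::output_smoothness_grad(yhat, g)
  for (idx in sample(n, 4)) {
    yp <- yhat; yp[idx] <- yp[idx] + eps
    ym <- yhat; ym[idx] <- ym[idx] - eps
    fd <- (output_smoothness(yp, g) - output_smoothness(ym, g)) / (2 * eps)
    expect_equal(gs[idx], fd, tolerance = 1e-5)
  }
})
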