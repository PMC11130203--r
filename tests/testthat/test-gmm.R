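# independent oracle: log multivariate normal density via solve/determinant,
# a different code path from the fitting internals
oracle_mixture_logdens <- function(x, weights, means, covs, center, scale) {
  x <- as.matrix(x)
  d <- ncol(x)
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  dens <- sapply(seq_along(weights), function(k) {
    S <- matrix(covs[, , k], d, d)
    Sinv <- solve(S)
    dets <- determinant(S, logarithm = TRUE)$modulus
    apply(z, 1, function(r) {
      q <- as.numeric(t(r - means[k, ]) %*% Sinv %*% (r - means[k, ]))
      weights[k] * exp(-0.5 * (d * log(2 * pi) + dets + q))
    })
  })
  log(rowSums(as.matrix(dens))) - sum(log(scale))
}

test_that("a single-component fit is the closed-form Gaussian", {
  set.seed(5)
  x <- matrix(rnorm(200 * 3, c(1, -2, 0.5), c(2, 0.5, 1)), 200, 3,
              byrow = FALSE)
  colnames(x) <- c("a", "b", "c")
  g <- fit_gmm(x, 1, seed = 1)
  # standardized data has mean 0; MLE covariance uses the 1/n divisor
  expect_equal(as.numeric(g$means), rep(0, 3), tolerance = 1e-8)
  z <- scale(x)
  expect_equal(g$covariances[, , 1], crossprod(z) / 200 + diag(1e-6, 3),
               tolerance = 1e-6, ignore_attr = TRUE)
  # average log-likelihood agrees with the independent density oracle
  expect_equal(avg_log_likelihood(g, x),
               mean(oracle_mixture_logdens(x, g$weights, g$means,
                                           g$covariances, g$center,
                                           g$scale)),
               tolerance = 1e-8)
})

test_that("EM log-likelihood traces never decrease", {
  set.seed(11)
  for (i in 1:6) {
    n <- sample(50:150, 1); d <- sample(1:4, 1)
    K <- sample(1:3, 1)
    x <- matrix(rnorm(n * d), n, d) + sample(0:4, 1)
    g <- fit_gmm(x, K, seed = i)
    expect_true(all(diff(g$trace) >= -1e-7))
    # evaluated on its own fit data the average log-likelihood equals the
    # final trace value
    expect_equal(avg_log_likelihood(g, x), tail(g$trace, 1),
                 tolerance = 1e-8)
  }
})

test_that("two well-separated clusters are recovered", {
  set.seed(3)
  x <- rbind(matrix(rnorm(200 * 2, -5, 0.5), 200, 2),
             matrix(rnorm(200 * 2, 5, 0.5), 200, 2))
  colnames(x) <- c("u", "v")
  g <- fit_gmm(x, 2, seed = 4)
  mu_orig <- sweep(sweep(g$means, 2, g$scale, "*"), 2, g$center, "+")
  mu_sorted <- mu_orig[order(mu_orig[, 1]), ]
  expect_equal(mu_sorted[1, ], c(-5, -5), tolerance = 0.1,
               ignore_attr = TRUE)
  expect_equal(mu_sorted[2, ], c(5, 5), tolerance = 0.1,
               ignore_attr = TRUE)
  expect_equal(g$weights, c(0.5, 0.5), tolerance = 0.05)

  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  mc <- Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  mc_mu <- t(mc$parameters$mean)
  expect_equal(mu_sorted, mc_mu[order(mc_mu[, 1]), ], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("far-away points score far below in-distribution points", {
  set.seed(9)
  x <- matrix(rnorm(300 * 4), 300, 4)
  colnames(x) <- paste0("f", 1:4)
  g <- fit_gmm(x, 3, seed = 2)
  inside <- avg_log_likelihood(g, x)
  outside <- avg_log_likelihood(g, x + 50)
  expect_lt(outside, inside - 100)
})

test_that("one-dimensional mixture densities integrate to one", {
  set.seed(13)
  x <- matrix(c(rnorm(150, -2, 0.5), rnorm(150, 2, 1)), ncol = 1)
  colnames(x) <- "f"
  g <- fit_gmm(x, 2, seed = 6)
  grid <- matrix(seq(-10 * sd(x), 10 * sd(x), length.out = 20001), ncol = 1)
  colnames(grid) <- "f"
  dens <- exp(oracle_mixture_logdens(grid, g$weights, g$means,
                                     g$covariances, g$center, g$scale))
  integral <- sum(dens) * diff(grid[1:2, 1])
  expect_equal(integral, 1, tolerance = 1e-4)
})

test_that("BIC matches an independently coded criterion", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(60:120, 1); d <- sample(1:3, 1); K <- sample(1:3, 1)
    x <- matrix(rnorm(n * d), n, d)
    colnames(x) <- paste0("f", seq_len(d))
    g <- fit_gmm(x, K, seed = i)
    ll <- sum(oracle_mixture_logdens(x, g$weights, g$means, g$covariances,
                                     g$center, g$scale))
    p <- (K - 1) + K * d + K * d * (d + 1) / 2
    expect_equal(gmm_bic(g, x), -2 * ll + p * log(n), tolerance = 1e-8)
  }
  # K = 1, d = 1 has exactly two free parameters
  x1 <- matrix(rnorm(50), ncol = 1); colnames(x1) <- "f"
  g1 <- fit_gmm(x1, 1, seed = 1)
  ll1 <- sum(oracle_mixture_logdens(x1, g1$weights, g1$means,
                                    g1$covariances, g1$center, g1$scale))
  expect_equal(gmm_bic(g1, x1), -2 * ll1 + 2 * log(50), tolerance = 1e-8)
})

test_that("BIC selects one component for single-Gaussian data", {
  set.seed(17)
  x <- matrix(rnorm(500 * 4), 500, 4)
  colnames(x) <- paste0("f", 1:4)
  sel <- select_components(x, k_max = 4, seed = 3)
  expect_equal(sel$best_k, 1L)
  expect_length(sel$bic_curve, 4)
  expect_false(anyNA(sel$bic_curve))
})

test_that("degenerate mixture requests are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_gmm(x, 11), "exceeds")
  expect_error(fit_gmm(x, 0), "positive integer")
  g <- fit_gmm(x, 1)
  expect_error(avg_log_likelihood(g, matrix(0, 2, 3)), "dimension")
  expect_error(gmm_bic(g, x[1, , drop = FALSE]), "at least 2")
})
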