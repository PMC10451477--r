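test_that("the Gaussian density matches its closed form and integrates to 1", {
  expect_equal(gaussian_pdf(0, 0, matrix(1)), 1 / sqrt(2 * pi))
  # numerical quadrature over a fine 1-D grid
  grid <- seq(-8, 8, by = 0.001)
  dens <- gaussian_pdf(matrix(grid, ncol = 1), 0.3, matrix(1.7))
  expect_equal(sum(dens) * 0.001, 1, tolerance = 1e-3)
  # symmetry about the mean
  expect_equal(gaussian_pdf(c(0.3 + 0.9), 0.3, matrix(1.7)),
               gaussian_pdf(c(0.3 - 0.9), 0.3, matrix(1.7)))
  # multivariate value against the explicit formula
  mu <- c(1, -1)
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  x <- c(0.5, 0.2)
  direct <- exp(-0.5 * t(x - mu) %*% solve(S) %*% (x - mu)) /
    (2 * pi * sqrt(det(S)))
  expect_equal(gaussian_pdf(x, mu, S), as.numeric(direct))
  expect_error(gaussian_pdf(c(1, 2), c(0, 0), matrix(c(0, 0, 0, -1e6), 2)),
               "singular")
})

test_that("a one-component mixture has the closed-form MLE mean", {
  toy <- separable_toy(2, n_per_class = 20L, p = 3L)
  fit <- gmm_fit(toy$x, toy$y, K = 1L)
  expect_equal(as.numeric(fit$classes$Adeno$mu),
               colMeans(toy$x[1:20, ]))
  expect_equal(as.numeric(fit$classes$Meso$mu),
               colMeans(toy$x[21:40, ]))
  expect_equal(fit$priors, c(0.5, 0.5))
})

test_that("EM responsibilities are a simplex and the loglik ascends", {
  set.seed(6)
  x <- rbind(matrix(stats::rnorm(60, 0, 0.3), ncol = 2),
             matrix(stats::rnorm(60, 3, 0.3), ncol = 2),
             matrix(stats::rnorm(40, 10, 0.3), ncol = 2))
  y <- rep(c("Adeno", "Meso"), c(60, 20))
  fit <- gmm_fit(x, y, K = 2L, cov_type = "full")
  resp <- fit$classes$Adeno$responsibilities
  expect_equal(rowSums(resp), rep(1, nrow(resp)))
  trace <- fit$classes$Adeno$loglik_trace
  expect_true(all(diff(trace) > -1e-6))
})

test_that("EM recovers the generating means of two separated blobs", {
  ok <- vapply(1:10, function(s) {
    set.seed(7000 + s)
    n <- 80L
    centers <- rbind(c(0, 0), c(4, 4))
    x <- rbind(matrix(stats::rnorm(n, centers[1, 1], 0.5), ncol = 2),
               matrix(stats::rnorm(n, centers[2, 1], 0.5), ncol = 2))
    y <- rep("Adeno", nrow(x))
    y[1] <- y[1]                       # one-class fit via direct mixture
    fit <- gmm_fit(rbind(x, x[1:2, ] + 20), c(y, "Meso", "Meso"),
                   K = 2L, cov_type = "full", seed = s)
    mus <- fit$classes$Adeno$mu
    mus <- mus[order(mus[, 1]), ]
    se <- 0.5 / sqrt(n / 2)
    all(abs(mus - centers) < 3 * se)
  }, logical(1))
  expect_gte(sum(ok), 9L)
})

test_that("prediction follows the prior-weighted likelihood", {
  toy <- separable_toy(3, n_per_class = 25L, p = 2L)
  fit <- gmm_fit(toy$x, toy$y, K = 1L)
  expect_true(mean(gmm_predict(fit, toy$x) == toy$y) == 1)

  # symmetric equidistant point: posterior about 0.5 / 0.5 under equal priors
  sym_x <- rbind(matrix(c(0, 0), 1), matrix(c(2, 2), 1))
  fit2 <- gmm_fit(rbind(sym_x, sym_x, sym_x), rep(c("Adeno", "Meso"), 3),
                  K = 1L)
  post <- gmm_posterior(fit2, matrix(c(1, 1), 1))
  expect_equal(as.numeric(post), c(0.5, 0.5), tolerance = 1e-6)

  # class score ordering agrees with a brute-force density computation
  scores <- gmm_scores(fit, toy$x)
  brute <- vapply(seq_len(nrow(toy$x)), function(i) {
    log(0.5) + gaussian_pdf(toy$x[i, ], as.numeric(fit$classes$Adeno$mu),
                            fit$classes$Adeno$sigma[[1]], log = TRUE)
  }, numeric(1))
  expect_equal(scores[, 1], brute, tolerance = 1e-8)
})
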