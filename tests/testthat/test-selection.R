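test_that("Friedman statistic matches hand-ranked small cases", {
  # all methods tie in every block -> exactly 0, p = 1
  tied <- matrix(5, nrow = 3, ncol = 4)
  fr <- friedman_test(tied)
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p_value, 1)

  # k = 3, n = 2 with within-block ranks (1,2,3) in both blocks:
  # rank sums (2,4,6), 12/(2*3*4) * 56 - 3*2*4 = 28 - 24 = 4
  perf <- rbind(c(0.1, 0.5, 0.9), c(1, 2, 3))
  fr2 <- friedman_test(perf)
  expect_equal(fr2$rank_sums, c(2, 4, 6), ignore_attr = TRUE)
  expect_equal(fr2$statistic, 4)
  expect_equal(fr2$p_value, stats::pchisq(4, df = 2, lower.tail = FALSE))

  expect_error(friedman_test(matrix(1, 3, 1)), "2 methods")
})

test_that("Friedman statistic is rank-based and block-exchangeable", {
  set.seed(8)
  perf <- matrix(stats::runif(5 * 4), nrow = 5)
  base <- friedman_test(perf)$statistic
  expect_equal(friedman_test(exp(3 * perf))$statistic, base)  # monotone map
  expect_equal(friedman_test(perf[c(4, 1, 5, 3, 2), ])$statistic, base)

  # independent cross-check against the stock implementation
  ref <- stats::friedman.test(perf)
  expect_equal(base, unname(ref$statistic))
  expect_equal(friedman_test(perf)$p_value, ref$p.value)
})

test_that("wrapper fitness is zero for separable subsets and deterministic", {
  toy <- separable_toy(1, n_per_class = 20L, p = 4L)
  f <- spectral_feature_set(t(toy$x), toy$y)
  fit <- fitness_mse(1:4, f, axis = "rows")
  expect_lt(fit, 1e-6)
  expect_identical(fit, fitness_mse(1:4, f, axis = "rows"))
  expect_error(fitness_mse(c(1, 99), f, axis = "rows"), "outside")
  expect_error(fitness_mse(integer(0), f, axis = "rows"), "non-empty")
})

test_that("the full feature set beats a random half on planted problems", {
  wins <- 0L
  for (s in 1:20) {
    f <- planted_feature_set(400 + s, delta = 1, n = 60L)
    set.seed(s)
    half <- sort(sample.int(10L, 5L))
    full <- fitness_mse(1:10, f, axis = "rows", learner = "nbc")
    part <- fitness_mse(half, f, axis = "rows", learner = "nbc")
    wins <- wins + (full <= part)
  }
  expect_gte(wins, 15L)
})

test_that("subject-column selection trains on the chosen columns", {
  toy <- separable_toy(3, n_per_class = 10L, p = 3L)
  f <- spectral_feature_set(t(toy$x), toy$y)
  # a one-class subset cannot be trained on; penalty ceiling applies
  expect_equal(fitness_mse(1:5, f, axis = "columns"), 0.04)
  mixed <- c(1:5, 11:15)
  expect_lt(fitness_mse(mixed, f, axis = "columns"), 1e-6)
})

test_that("PSO recovers a planted feature subset and is reproducible", {
  hits <- 0L
  for (s in 1:5) {
    f <- planted_feature_set(200 + s)
    r <- pso_select(f, config = pso_config(3L, swarm_size = 15L,
                                           iterations = 20L, seed = s),
                    axis = "rows", learner = "nbc")
    hits <- hits + identical(r$selected_indices, 1:3)
    expect_true(all(diff(r$fitness_trace) <= 0))
    expect_equal(r$best_fitness,
                 fitness_mse(r$selected_indices, f, axis = "rows",
                             learner = "nbc"))
  }
  expect_gte(hits, 4L)

  f <- planted_feature_set(201)
  cfg <- pso_config(3L, swarm_size = 10L, iterations = 10L, seed = 9)
  r1 <- pso_select(f, config = cfg, axis = "rows", learner = "nbc")
  r2 <- pso_select(f, config = cfg, axis = "rows", learner = "nbc")
  expect_identical(r1$selected_indices, r2$selected_indices)
  expect_identical(r1$fitness_trace, r2$fitness_trace)
})

test_that("PSO with a zero iteration budget returns the best initial particle", {
  f <- planted_feature_set(202)
  r <- pso_select(f, config = pso_config(3L, swarm_size = 8L, iterations = 0L,
                                         seed = 2),
                  axis = "rows", learner = "nbc")
  expect_length(r$fitness_trace, 1L)
  expect_length(r$selected_indices, 3L)
})

test_that("harmony search recovers the planted subset and honours its memory", {
  hits <- 0L
  for (s in 1:5) {
    f <- planted_feature_set(300 + s)
    r <- hs_select(f, config = hs_config(3L, seed = s),
                   axis = "rows", learner = "nbc")
    hits <- hits + identical(r$selected_indices, 1:3)
    expect_true(all(diff(r$fitness_trace) <= 0))
  }
  expect_gte(hits, 4L)

  # HMCR -> 1, PAR -> 0: improvisations never leave the initial memory values
  set.seed(44)
  wide <- spectral_feature_set(abs(matrix(stats::rnorm(40 * 30), nrow = 40)),
                               rep(c("Adeno", "Meso"), each = 15))
  set.seed(5)
  init_union <- sort(unique(as.integer(
    t(vapply(1:6, function(i) sort(sample.int(40L, 3L)), integer(3L))))))
  # reproduce the initial memory draw: same seed, same sampling order
  r <- hs_select(wide, config = hs_config(3L, memory_size = 6L,
                                          iterations = 40L,
                                          hmcr = 1 - 1e-12, par = 0, seed = 5),
                 axis = "rows", learner = "nbc")
  expect_true(all(r$selected_indices %in% init_union))

  f <- planted_feature_set(301)
  cfg <- hs_config(3L, memory_size = 8L, iterations = 30L, seed = 4)
  r1 <- hs_select(f, config = cfg, axis = "rows", learner = "nbc")
  r2 <- hs_select(f, config = cfg, axis = "rows", learner = "nbc")
  expect_identical(r1$selected_indices, r2$selected_indices)
})

test_that("infeasible subset sizes are rejected", {
  f <- planted_feature_set(303)
  expect_error(pso_select(f, config = pso_config(11L, seed = 1), axis = "rows"),
               "subset_size")
  expect_error(hs_select(f, config = hs_config(11L, seed = 1), axis = "rows"),
               "subset_size")
  expect_error(pso_config(3L, swarm_size = 1L), "swarm_size")
  expect_error(hs_config(3L, memory_size = 1L), "memory_size")
})
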