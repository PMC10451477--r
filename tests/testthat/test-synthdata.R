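test_that("generator reproduces the cohort geometry and is deterministic", {
  d <- generate_dataset(synth_config(seed = 7))
  expect_equal(dim(d$values), c(12533L, 181L))
  expect_equal(sum(d$labels == "Adeno"), 150L)
  expect_equal(sum(d$labels == "Meso"), 31L)
  expect_true(all(d$values >= 0) && all(is.finite(d$values)))
  expect_equal(sum(d$informative), 200L)

  d2 <- generate_dataset(synth_config(seed = 7))
  expect_identical(d$values, d2$values)
  d3 <- generate_dataset(synth_config(seed = 8))
  expect_false(identical(d$values, d3$values))
})

test_that("generated intensities are heavy-tailed and right-skewed", {
  d <- generate_dataset(synth_config(n_genes = 4000L, seed = 2))
  v <- as.numeric(d$values)
  m <- mean(v)
  s2 <- mean((v - m)^2)
  skew <- mean((v - m)^3) / s2^1.5
  kurt <- mean((v - m)^4) / s2^2
  expect_gt(skew, 2)
  expect_gt(kurt, 10)
})

test_that("invalid generator configurations are refused", {
  expect_error(synth_config(n_genes = 0), "positive")
  expect_error(synth_config(noise_sd = 0), "positive")
  expect_error(synth_config(effect_size = -1), "effect_size")
  expect_error(synth_config(n_genes = 10, n_informative_genes = 11),
               "n_informative_genes")
})

test_that("zero effect size yields null-calibrated per-gene t tests", {
  cfg <- synth_config(n_genes = 4000L, n_adeno = 25L, n_meso = 25L,
                      effect_size = 0, n_informative_genes = 4000L, seed = 31)
  d <- generate_dataset(cfg)
  lv <- log(d$values)
  pvals <- vapply(seq_len(nrow(lv)), function(g) {
    stats::t.test(lv[g, d$labels == "Adeno"], lv[g, d$labels == "Meso"])$p.value
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  # binomial 3-se band around 0.05 with 4000 genes
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("the planted log-scale shift is recovered at its set size", {
  cfg <- synth_config(n_genes = 1000L, n_adeno = 50L, n_meso = 50L,
                      effect_size = 3, noise_sd = 0.1,
                      n_informative_genes = 100L, seed = 17)
  d <- generate_dataset(cfg)
  lv <- log(d$values)
  info <- which(d$informative)
  diffs <- rowMeans(lv[info, d$labels == "Meso", drop = FALSE]) -
    rowMeans(lv[info, d$labels == "Adeno", drop = FALSE])
  se <- 0.1 * sqrt(1 / 50 + 1 / 50) / sqrt(length(info))
  expect_lt(abs(mean(diffs) - 3), 3 * se)
})

test_that("matrix files round-trip with a numeric label row", {
  d <- generate_dataset(synth_config(n_genes = 5L, n_adeno = 2L, n_meso = 2L,
                                     n_informative_genes = 2L, seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(d, path)
  lines <- readLines(path)
  expect_length(lines, 6L)                           # 5 gene rows + label row
  expect_identical(lines[6L], "1\t1\t2\t2")
  back <- read_matrix(path)
  expect_equal(back$values, d$values, ignore_attr = TRUE)
  expect_equal(as.character(back$labels), as.character(d$labels))
})

test_that("malformed matrix files fail with located parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("1\t2", "3\t4", "1\t3"), path)       # unknown class code 3
  expect_error(read_matrix(path), "class code.*3")

  writeLines(c("1\t2\t3", "3\t4", "1\t2"), path)    # ragged row
  expect_error(read_matrix(path), "line 2")

  writeLines(character(0), path)                     # empty file
  expect_error(read_matrix(path), "parse error")

  writeLines(c("1\t-2", "1\t2"), path)               # negative intensity
  expect_error(read_matrix(path), "negative")

  d <- generate_dataset(synth_config(n_genes = 3L, n_adeno = 2L, n_meso = 2L,
                                     n_informative_genes = 1L, seed = 1))
  d$labels <- d$labels[1:3]                          # corrupt label count
  expect_error(write_matrix(d, path), "mismatch")
})

test_that("downstream accuracy is non-decreasing in the effect size", {
  acc_at <- function(effect) {
    mean(vapply(1:20, function(s) {
      d <- generate_dataset(synth_config(n_genes = 1024L, n_adeno = 30L,
                                         n_meso = 12L, effect_size = effect,
                                         seed = 900 + s))
      feats <- spectral_features(d, window_spec(256L, 128L, 256L))
      x <- scale_unit(t(feats$values))
      folds <- kfold_plan(feats$labels, k = 5L, seed = s)
      correct <- 0L
      for (f in 1:5) {
        m <- nbc_fit(x[folds != f, , drop = FALSE], feats$labels[folds != f])
        correct <- correct +
          sum(nbc_predict(m, x[folds == f, , drop = FALSE]) ==
                feats$labels[folds == f])
      }
      correct / length(folds)
    }, numeric(1)))
  }
  accs <- c(acc_at(0), acc_at(1), acc_at(3))
  expect_true(all(diff(accs) >= 0))
})
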