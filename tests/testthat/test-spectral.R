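test_that("Blackman window matches its defining cosine series", {
  w <- blackman_window(9L)
  expect_equal(w[1], 0.42 - 0.5 + 0.08)              # endpoint cancels to 0
  expect_equal(w[9], 0)
  expect_equal(w[5], 0.42 + 0.5 + 0.08)              # odd-length centre is 1

  # brute-force term-by-term evaluation for M = 8
  M <- 8L
  direct <- sapply(0:(M - 1), function(n) {
    0.42 - 0.5 * cos(2 * pi * n / (M - 1)) + 0.08 * cos(4 * pi * n / (M - 1))
  })
  expect_equal(blackman_window(M), direct, tolerance = 1e-15)

  expect_error(blackman_window(1L), "invalid argument")
})

test_that("stft equals a direct-sum DFT oracle on single frames", {
  set.seed(4)
  for (N in c(16L, 33L, 64L)) {
    nfft <- 64L
    x <- stats::rnorm(N)
    sp <- stft(x, window_spec(window_length = nfft, hop = nfft,
                              transform_size = nfft))
    expect_equal(ncol(sp), 1L)
    xp <- c(x, numeric(nfft - N)) * blackman_window(nfft)
    oracle <- vapply(0:(nfft / 2), function(k) {
      sum(xp * exp(-2i * pi * k * (0:(nfft - 1)) / nfft))
    }, complex(1))
    expect_lt(max(Mod(sp[, 1] - oracle)) / max(Mod(oracle)), 1e-9)
  }
})

test_that("stft locates a pure sinusoid at its bin and is linear in zero", {
  n <- 64L
  spec <- window_spec(n, n, n)
  tone <- sin(2 * pi * 4 * (0:(n - 1)) / n)
  mag <- Mod(stft(tone, spec)[, 1])
  expect_equal(which.max(mag) - 1L, 4L)              # bins are 0-based

  zeros <- stft(numeric(100), window_spec(32L, 16L, 32L))
  expect_true(all(Mod(zeros) == 0))
  expect_error(stft(numeric(0)), "empty")
})

test_that("each frame obeys the one-sided Parseval identity", {
  set.seed(9)
  x <- stats::rnorm(100)
  spec <- window_spec(32L, 16L, 32L)
  sp <- stft(x, spec)
  w <- blackman_window(32L)
  padded <- c(x, numeric((ncol(sp) - 1L) * 16L + 32L - length(x)))
  for (f in seq_len(ncol(sp))) {
    seg <- padded[(f - 1L) * 16L + 1:32] * w
    lhs <- Mod(sp[1, f])^2 + Mod(sp[17, f])^2 + 2 * sum(Mod(sp[2:16, f])^2)
    rhs <- 32 * sum(seg^2)
    expect_lt(abs(lhs - rhs) / max(rhs, 1e-12), 1e-6)
  }
})

test_that("feature extraction yields transform_size/2 + 1 features", {
  # the reference geometry: 12,533 genes -> 2049 spectral features
  one <- matrix(0, nrow = 12533L, ncol = 1L)
  f <- spectral_features(one)
  expect_equal(nrow(f$values), 2049L)
  expect_true(all(f$values == 0))                    # all-zero subject

  # feature count is set by the transform, not the signal length
  for (len in c(600L, 1000L)) {
    fs <- spectral_features(matrix(1, nrow = len, ncol = 1L),
                            window_spec(256L, 128L, 512L))
    expect_equal(nrow(fs$values), 257L)
  }
  expect_error(spectral_features(matrix(1, 100L, 1L), window_spec(256L, 128L, 256L)),
               "smaller window")
})

test_that("a one-frame configuration reduces to the windowed DFT magnitude", {
  set.seed(11)
  x <- stats::rnorm(64)
  spec <- window_spec(64L, 64L, 64L)
  f <- spectral_features(matrix(x, ncol = 1L), spec)
  expect_equal(as.numeric(f$values), Mod(stft(x, spec)[, 1]))
})

test_that("labels ride along with the spectral features", {
  d <- generate_dataset(synth_config(n_genes = 600L, n_adeno = 4L,
                                     n_meso = 3L, seed = 5))
  f <- spectral_features(d, window_spec(256L, 128L, 256L))
  expect_equal(as.character(f$labels), as.character(d$labels))
  expect_equal(ncol(f$values), 7L)
})
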