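# shared fixtures, all generated in code

# two well-separated classes on the unit interval (samples x features)
separable_toy <- function(seed, n_per_class = 30L, p = 2L,
                          centers = c(0.25, 0.75), sd = 0.05) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p, centers[1], sd), ncol = p),
             matrix(stats::rnorm(n_per_class * p, centers[2], sd), ncol = p))
  x <- pmin(pmax(x, 0), 1)
  list(x = x, y = rep(c("Adeno", "Meso"), each = n_per_class))
}

# 10 candidate feature rows of which the first 3 jointly carry the class
# signal: a moderate per-feature shift so that all three are needed for
# the lowest training error (any single one misclassifies a fair share)
planted_feature_set <- function(seed, delta = 1.5, n = 400L) {
  set.seed(seed)
  y <- rep(c("Adeno", "Meso"), each = n / 2L)
  vals <- matrix(stats::rnorm(10L * n), nrow = 10L)
  for (r in 1:3) vals[r, y == "Meso"] <- vals[r, y == "Meso"] + delta
  vals <- vals - min(vals)
  spectral_feature_set(vals, y)
}

# small expression matrix + matching reduced-scale pipeline configuration
scaled_synth <- function(effect_size, seed, n_genes = 2048L) {
  synth_config(n_genes = n_genes, effect_size = effect_size, seed = seed)
}

scaled_config <- function(seed, ...) {
  experiment_config(window = window_spec(512L, 256L, 512L), seed = seed, ...)
}
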