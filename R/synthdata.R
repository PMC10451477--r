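#' Configuration for the synthetic expression-matrix generator
#'
#' The generator emulates the Lung Harvard 2 cohort that motivates the
#' pipeline: 12,533 gene probes measured on 150 adenocarcinoma and 31
#' mesothelioma subjects, with non-negative, heavy-right-tailed intensities
#' (large positive skewness and kurtosis). Intensities are log-normal:
#' `exp(N(baseline_log_mean, baseline_log_sd^2) + noise)`, and a designated
#' block of `n_informative_genes` has its log-mean shifted by `effect_size`
#' in the Meso class, providing a controllable class-separating signal with
#' per-gene ground truth.
#'
#' @param n_genes number of gene rows (default 12533).
#' @param n_adeno,n_meso subjects per class (defaults 150 and 31).
#' @param baseline_log_mean,baseline_log_sd log-scale location and spread of
#'   the baseline intensity distribution (defaults 8 and 1).
#' @param n_informative_genes number of genes carrying the class signal
#'   (default 200).
#' @param effect_size log-scale mean shift applied to informative genes in
#'   Meso subjects; `0` means no signal (default 1).
#' @param noise_sd log-scale per-entry noise standard deviation (default 0.5).
#' @param seed integer seed; the generator is a pure function of the full
#'   configuration including the seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 12533L, n_adeno = 150L, n_meso = 31L,
                         baseline_log_mean = 8, baseline_log_sd = 1,
                         n_informative_genes = 200L, effect_size = 1,
                         noise_sd = 0.5, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_adeno = as.integer(n_adeno),
              n_meso = as.integer(n_meso),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              n_informative_genes = as.integer(n_informative_genes),
              effect_size = effect_size, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_adeno < 1L || cfg$n_meso < 1L) {
    stop("invalid config: counts must be positive")
  }
  if (cfg$n_informative_genes < 0L || cfg$n_informative_genes > cfg$n_genes) {
    stop("invalid config: n_informative_genes must lie in [0, n_genes]")
  }
  if (cfg$effect_size < 0) stop("invalid config: effect_size must be >= 0")
  if (cfg$baseline_log_sd <= 0 || cfg$noise_sd <= 0) {
    stop("invalid config: standard deviations must be positive")
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic LH2-like expression matrix
#'
#' @param config a [synth_config()].
#' @return An [expression_matrix()] of shape `n_genes x (n_adeno + n_meso)`
#'   with per-gene `informative` ground-truth flags.
#' @examples
#' d <- generate_dataset(synth_config(n_genes = 100, n_adeno = 10, n_meso = 4))
#' dim(d)
#' @export
generate_dataset <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  n_sub <- config$n_adeno + config$n_meso
  labels <- rep(c("Adeno", "Meso"), c(config$n_adeno, config$n_meso))
  # isolate the generator's RNG stream from the caller's
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(config$seed)
  # per-gene baseline log-level, shared by every subject
  gene_mu <- stats::rnorm(config$n_genes, config$baseline_log_mean,
                          config$baseline_log_sd)
  log_values <- matrix(stats::rnorm(config$n_genes * n_sub, 0, config$noise_sd),
                       nrow = config$n_genes) + gene_mu
  informative <- rep(FALSE, config$n_genes)
  if (config$n_informative_genes > 0L) {
    idx <- sample.int(config$n_genes, config$n_informative_genes)
    informative[idx] <- TRUE
    meso_cols <- which(labels == "Meso")
    log_values[idx, meso_cols] <- log_values[idx, meso_cols] + config$effect_size
  }
  expression_matrix(exp(log_values), labels, informative = informative)
}
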