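#' Gaussian naive Bayes classifier
#'
#' Class priors are the training class fractions; each feature is modelled
#' within each class by an independent Gaussian likelihood. Per-feature
#' class variances are floored at `alpha` times the feature's pooled
#' variance (the continuous-feature smoothing analogue of additive
#' smoothing; `alpha = 0.06` by default), so zero-variance features never
#' raise an error.
#'
#' @param x samples x features design matrix.
#' @param y binary labels; first level is the positive class.
#' @param alpha variance-smoothing fraction (default 0.06).
#' @return An `nbc_model` with `priors`, per-class `mu` and `var`
#'   (classes x features), and the class levels.
#' @export
nbc_fit <- function(x, y, alpha = 0.06) {
  x <- .check_design(x)
  y <- .as_binary_factor(y)
  if (alpha <= 0) stop("alpha must be positive")
  pooled <- apply(x, 2L, stats::var)
  floor_var <- alpha * pmax(pooled, .Machine$double.eps)
  mu <- t(matrix(vapply(levels(y), function(lv) {
    colMeans(x[y == lv, , drop = FALSE])
  }, numeric(ncol(x))), nrow = ncol(x)))
  v <- t(matrix(vapply(levels(y), function(lv) {
    xv <- x[y == lv, , drop = FALSE]
    if (nrow(xv) < 2L) rep(0, ncol(x)) else apply(xv, 2L, stats::var)
  }, numeric(ncol(x))), nrow = ncol(x)))
  v <- pmax(v, matrix(floor_var, nrow = nrow(v), ncol = ncol(v), byrow = TRUE))
  structure(list(priors = as.numeric(table(y)) / length(y),
                 mu = mu, var = v, levels = levels(y), alpha = alpha),
            class = "nbc_model")
}

# per-class joint log-likelihood (sum of per-feature Gaussian log densities)
.nbc_loglik <- function(model, x) {
  x <- .check_design(x)
  s <- vapply(seq_along(model$levels), function(k) {
    centered <- sweep(x, 2L, model$mu[k, ])
    -0.5 * (ncol(x) * base::log(2 * pi) + sum(base::log(model$var[k, ])) +
              rowSums(sweep(centered^2, 2L, model$var[k, ], "/")))
  }, numeric(nrow(x)))
  s <- matrix(s, nrow = nrow(x))
  colnames(s) <- model$levels
  s
}

#' Posterior class probabilities from a naive Bayes model
#'
#' @param model an `nbc_model` from [nbc_fit()].
#' @param x samples x features matrix.
#' @return Matrix of class posteriors summing to 1 per sample.
#' @export
nbc_posterior <- function(model, x) {
  s <- .nbc_loglik(model, x) +
    matrix(base::log(model$priors), nrow(as.matrix(x)), length(model$priors),
           byrow = TRUE)
  exp(s - .logsumexp_rows(s))
}

#' Predict classes with a naive Bayes model
#'
#' Argmax posterior; exact ties go to the first class, which for the lung
#' cohort is the majority (Adeno) class.
#'
#' @inheritParams nbc_posterior
#' @return Factor of predicted labels.
#' @export
nbc_predict <- function(model, x) {
  p <- nbc_posterior(model, x)
  idx <- ifelse(p[, 2L] > p[, 1L], 2L, 1L)
  factor(model$levels[idx], levels = model$levels)
}
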