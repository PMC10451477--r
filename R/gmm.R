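#' Multivariate Gaussian density
#'
#' `(2 pi)^(-n/2) |S|^(-1/2) exp(-(x - mu)' S^{-1} (x - mu) / 2)`. A
#' non-positive-definite covariance is ridge-regularized once (`ridge` added
#' to the diagonal); if it is still singular an error is raised.
#'
#' @param x numeric vector, or matrix with one observation per row.
#' @param mu mean vector.
#' @param sigma covariance matrix (or a vector of per-dimension variances,
#'   interpreted as a diagonal covariance).
#' @param ridge diagonal ridge used on failure (default 1e-6).
#' @param log return the log density?
#' @return Density (or log density) per observation.
#' @export
gaussian_pdf <- function(x, mu, sigma, ridge = 1e-6, log = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- .check_design(x)
  p <- length(mu)
  if (ncol(x) != p) stop("dimension mismatch between x and mu")
  if (is.null(dim(sigma))) {
    if (length(sigma) == 1L) sigma <- rep(sigma, p)
    if (any(sigma <= 0)) sigma <- sigma + ridge
    if (any(sigma <= 0)) stop("singular (non-positive) variance")
    centered <- sweep(x, 2L, mu)
    quad <- rowSums(sweep(centered^2, 2L, sigma, "/"))
    logdet <- sum(base::log(sigma))
  } else {
    sigma <- as.matrix(sigma)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- tryCatch(chol(sigma + ridge * diag(p)), error = function(e) NULL)
    }
    if (is.null(ch)) stop("covariance matrix is singular even after ridge regularization")
    centered <- sweep(x, 2L, mu)
    z <- backsolve(ch, t(centered), transpose = TRUE)
    quad <- colSums(z^2)
    logdet <- 2 * sum(base::log(diag(ch)))
  }
  ll <- -0.5 * (p * base::log(2 * pi) + logdet + quad)
  if (log) ll else exp(ll)
}

# log densities for each component of one mixture; X: n x p
.mixture_logdens <- function(X, mix) {
  ld <- vapply(seq_along(mix$pi), function(k) {
    base::log(mix$pi[k]) +
      gaussian_pdf(X, mix$mu[k, ], mix$sigma[[k]], log = TRUE)
  }, numeric(nrow(X)))
  matrix(ld, nrow = nrow(X))
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + base::log(rowSums(exp(m - mx)))
}

# EM for one Gaussian mixture; X: n x p
.fit_mixture <- function(X, K, cov_type, max_iter, tol, ridge, seed,
                         reseed_left = 1L) {
  n <- nrow(X)
  p <- ncol(X)
  if (n < K) stop("fewer samples than mixture components")
  make_sigma <- function(rows, resp = NULL) {
    if (cov_type == "diagonal") {
      v <- if (is.null(resp)) {
        apply(X[rows, , drop = FALSE], 2L, stats::var)
      } else resp
      v[!is.finite(v) | v < ridge] <- ridge
      v
    } else {
      s <- if (is.null(resp)) stats::cov(X[rows, , drop = FALSE]) else resp
      s + ridge * diag(p)
    }
  }
  # initialisation: K = 1 is closed form; otherwise k-means partition
  if (K == 1L) {
    mix <- list(pi = 1,
                mu = matrix(colMeans(X), nrow = 1L),
                sigma = list(make_sigma(seq_len(n))))
    ll <- sum(.logsumexp_rows(.mixture_logdens(X, mix)))
    mix$loglik_trace <- ll
    mix$responsibilities <- matrix(1, nrow = n, ncol = 1L)
    return(mix)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  cl <- tryCatch(stats::kmeans(X, centers = K, nstart = 5L)$cluster,
                 error = function(e) NULL)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  if (is.null(cl)) cl <- rep(seq_len(K), length.out = n)
  mix <- list(pi = as.numeric(table(factor(cl, levels = seq_len(K)))) / n,
              mu = t(matrix(vapply(seq_len(K), function(k) {
                colMeans(X[cl == k, , drop = FALSE])
              }, numeric(p)), nrow = p)),
              sigma = lapply(seq_len(K), function(k) {
                rows <- which(cl == k)
                if (length(rows) < 2L) make_sigma(seq_len(n)) else make_sigma(rows)
              }))
  trace <- numeric(0)
  resp <- NULL
  for (it in seq_len(max_iter)) {
    ld <- .mixture_logdens(X, mix)
    norm <- .logsumexp_rows(ld)
    ll <- sum(norm)
    resp <- exp(ld - norm)
    nk <- colSums(resp)
    if (any(nk < 1e-8) || !is.finite(ll)) {
      if (reseed_left > 0L) {
        return(.fit_mixture(X, K, cov_type, max_iter, tol, ridge, seed + 1L,
                            reseed_left - 1L))
      }
      stop("mixture component collapsed during EM")
    }
    trace <- c(trace, ll)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) break
    mix$pi <- nk / n
    mix$mu <- t(matrix(vapply(seq_len(K), function(k) {
      colSums(X * resp[, k]) / nk[k]
    }, numeric(p)), nrow = p))
    mix$sigma <- lapply(seq_len(K), function(k) {
      centered <- sweep(X, 2L, mix$mu[k, ])
      if (cov_type == "diagonal") {
        v <- colSums(centered^2 * resp[, k]) / nk[k]
        make_sigma(NULL, v)
      } else {
        s <- crossprod(centered * sqrt(resp[, k])) / nk[k]
        make_sigma(NULL, s)
      }
    })
  }
  mix$loglik_trace <- trace
  mix$responsibilities <- resp
  mix
}

#' Gaussian mixture classifier fitted by expectation-maximization
#'
#' One K-component Gaussian mixture is fitted per class by EM: component
#' responsibilities (posterior component memberships) in the E step,
#' mixing proportions, means and covariances maximizing the observed-data
#' log-likelihood in the M step. Iteration stops when the log-likelihood
#' changes by less than `tol` or after `max_iter` iterations. Covariances
#' are ridge-regularized; a collapsing component triggers one reseeded
#' restart before raising an error. `K = 1` has the closed-form maximum
#' likelihood solution (sample mean and covariance).
#'
#' @param x samples x features design matrix.
#' @param y binary labels; first level is the positive class.
#' @param K components per class (default 1).
#' @param cov_type `"diagonal"` (default, robust in high dimension) or
#'   `"full"` covariance per component.
#' @param max_iter EM iteration cap (default 1000).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param ridge covariance ridge (default 1e-6).
#' @param seed seed for the k-means initialisation when `K > 1`.
#' @return A `gmm_model` with a fitted mixture and prior per class.
#' @export
gmm_fit <- function(x, y, K = 1L, cov_type = c("diagonal", "full"),
                    max_iter = 1000L, tol = 1e-6, ridge = 1e-6, seed = 1L) {
  cov_type <- match.arg(cov_type)
  x <- .check_design(x)
  y <- .as_binary_factor(y)
  if (any(table(y) < K)) stop("each class needs at least K samples")
  classes <- lapply(levels(y), function(lv) {
    .fit_mixture(x[y == lv, , drop = FALSE], as.integer(K), cov_type,
                 max_iter, tol, ridge, seed)
  })
  names(classes) <- levels(y)
  structure(list(classes = classes,
                 priors = as.numeric(table(y)) / length(y),
                 levels = levels(y), K = as.integer(K), cov_type = cov_type),
            class = "gmm_model")
}

#' Per-class log-likelihood scores of a Gaussian mixture classifier
#'
#' @param model a `gmm_model`.
#' @param x samples x features matrix.
#' @return Matrix of prior-weighted class log scores (samples x classes).
#' @export
gmm_scores <- function(model, x) {
  x <- .check_design(x)
  s <- vapply(seq_along(model$levels), function(i) {
    base::log(model$priors[i]) +
      .logsumexp_rows(.mixture_logdens(x, model$classes[[i]]))
  }, numeric(nrow(x)))
  s <- matrix(s, nrow = nrow(x))
  colnames(s) <- model$levels
  s
}

#' Predict classes with a Gaussian mixture classifier
#'
#' The prior-weighted class likelihood decides; ties go to the first
#' (Adeno) class.
#'
#' @param model a `gmm_model` from [gmm_fit()].
#' @param x samples x features matrix.
#' @return Factor of predicted labels.
#' @export
gmm_predict <- function(model, x) {
  s <- gmm_scores(model, x)
  idx <- ifelse(s[, 2L] > s[, 1L], 2L, 1L)
  factor(model$levels[idx], levels = model$levels)
}

#' Posterior class probabilities of a Gaussian mixture classifier
#'
#' @inheritParams gmm_predict
#' @return Matrix of class posteriors summing to 1 per sample.
#' @export
gmm_posterior <- function(model, x) {
  s <- gmm_scores(model, x)
  exp(s - .logsumexp_rows(s))
}
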