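#' Kernel evaluation between two sample sets
#'
#' Linear `x'z`, polynomial `(gamma x'z + r)^d`, and radial basis
#' `exp(-|x - z|^2 / (2 sigma^2))`. With `gamma = 1`, `r = 0`, `d = 1` the
#' polynomial kernel equals the linear kernel exactly, and the RBF kernel
#' is 1 at zero distance.
#'
#' @param x,z matrices with one sample per row (same feature count).
#' @param kernel `"linear"`, `"polynomial"` or `"rbf"`.
#' @param gamma polynomial dot-product scale (default 10, the pipeline
#'   default).
#' @param coef0 polynomial independent term `r` (default 0).
#' @param degree polynomial degree `d` (default 2).
#' @param sigma RBF kernel width (default 100).
#' @return `nrow(x)` x `nrow(z)` kernel matrix.
#' @export
kernel_matrix <- function(x, z, kernel = c("linear", "polynomial", "rbf"),
                          gamma = 10, coef0 = 0, degree = 2, sigma = 100) {
  kernel <- match.arg(kernel)
  x <- .check_design(x)
  z <- .check_design(z)
  switch(kernel,
         linear = tcrossprod(x, z),
         polynomial = (gamma * tcrossprod(x, z) + coef0)^degree,
         rbf = {
           d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
           exp(-pmax(d2, 0) / (2 * sigma^2))
         })
}

# Table-of-record soft-margin costs per kernel
.svm_default_C <- c(linear = 0.85, polynomial = 0.76, rbf = 1)

#' Soft-margin support vector machine fitted by SMO
#'
#' Solves the soft-margin dual by sequential minimal optimization
#' (pairwise coordinate ascent on the Lagrange multipliers, second index
#' chosen by maximal error difference) to KKT tolerance `tol`. The decision
#' function is `f(x) = sum_i alpha_i y_i K(x_i, x) + b`; its sign assigns
#' the class, with the first factor level mapped to +1. Kernel defaults
#' follow the pipeline's reference configuration: linear `C = 0.85`,
#' polynomial `C = 0.76, gamma = 10, r = 0, d = 2`, RBF `C = 1,
#' sigma = 100`.
#'
#' @param x samples x features design matrix.
#' @param y binary labels; first level maps to +1.
#' @param kernel kernel kind (see [kernel_matrix()]).
#' @param C box constraint; per-kernel default when `NULL`.
#' @param gamma,coef0,degree,sigma kernel parameters.
#' @param tol KKT violation tolerance (default 1e-3).
#' @param max_sweeps cap on full passes over the training set (default 500).
#' @return An `svm_model` with support vectors, dual coefficients
#'   (`alpha_i y_i`), bias `b`, the explicit weight vector for the linear
#'   kernel, and the kernel configuration.
#' @export
svm_fit <- function(x, y, kernel = c("linear", "polynomial", "rbf"), C = NULL,
                    gamma = 10, coef0 = 0, degree = 2, sigma = 100,
                    tol = 1e-3, max_sweeps = 500L) {
  kernel <- match.arg(kernel)
  x <- .check_design(x)
  y <- .as_binary_factor(y)
  if (is.null(C)) C <- unname(.svm_default_C[kernel])
  ysign <- ifelse(y == levels(y)[1L], 1, -1)
  n <- nrow(x)
  K <- kernel_matrix(x, x, kernel, gamma, coef0, degree, sigma)
  if (n <= 500L) {
    lam <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(lam) < -1e-6 * max(1, max(abs(lam)))) {
      stop(sprintf("kernel matrix for the %s kernel is not positive semidefinite;
  check the kernel parameters", kernel))
    }
  }

  alpha <- numeric(n)
  b <- 0
  f <- numeric(n)  # decision values at the training points

  # attempt one pairwise update; returns TRUE when the pair made progress
  take_step <- function(i, j) {
    if (i == j) return(FALSE)
    Ei <- f[i] - ysign[i]
    Ej <- f[j] - ysign[j]
    ai_old <- alpha[i]
    aj_old <- alpha[j]
    if (ysign[i] != ysign[j]) {
      L <- max(0, aj_old - ai_old)
      H <- min(C, C + aj_old - ai_old)
    } else {
      L <- max(0, ai_old + aj_old - C)
      H <- min(C, ai_old + aj_old)
    }
    if (L >= H) return(FALSE)
    eta <- 2 * K[i, j] - K[i, i] - K[j, j]
    if (eta >= -1e-12) return(FALSE)
    aj <- aj_old - ysign[j] * (Ei - Ej) / eta
    aj <- min(max(aj, L), H)
    if (abs(aj - aj_old) < 1e-10 * (aj + aj_old + 1e-10)) return(FALSE)
    ai <- ai_old + ysign[i] * ysign[j] * (aj_old - aj)
    b1 <- b - Ei - ysign[i] * (ai - ai_old) * K[i, i] -
      ysign[j] * (aj - aj_old) * K[i, j]
    b2 <- b - Ej - ysign[i] * (ai - ai_old) * K[i, j] -
      ysign[j] * (aj - aj_old) * K[j, j]
    b_new <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
    f <<- f + ysign[i] * (ai - ai_old) * K[, i] +
      ysign[j] * (aj - aj_old) * K[, j] + (b_new - b)
    alpha[i] <<- ai
    alpha[j] <<- aj
    b <<- b_new
    TRUE
  }

  for (sweep_i in seq_len(max_sweeps)) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- f[i] - ysign[i]
      r <- Ei * ysign[i]
      if (!((r < -tol && alpha[i] < C) || (r > tol && alpha[i] > 0))) next
      # second choice by largest error gap, falling back through the
      # remaining candidates when the best pair cannot make progress
      E <- f - ysign
      gap <- abs(Ei - E)
      gap[i] <- -Inf
      for (j in order(-gap, seq_len(n))) {
        if (take_step(i, j)) {
          changed <- changed + 1L
          break
        }
      }
    }
    if (changed == 0L) break
  }

  sv <- which(alpha > 1e-8)
  model <- list(kernel = kernel, C = C, gamma = gamma, coef0 = coef0,
                degree = degree, sigma = sigma, tol = tol,
                alpha = alpha[sv], coefs = (alpha * ysign)[sv],
                support = sv, sv_x = x[sv, , drop = FALSE],
                sv_y = ysign[sv], b = b, levels = levels(y),
                train_decision = f)
  if (kernel == "linear") {
    model$w <- as.numeric(crossprod(x[sv, , drop = FALSE], (alpha * ysign)[sv]))
  }
  class(model) <- "svm_model"
  model
}

#' Decision values of a fitted support vector machine
#'
#' @param model an `svm_model` from [svm_fit()].
#' @param x samples x features matrix.
#' @return Numeric decision values `f(x)`.
#' @export
svm_decision <- function(model, x) {
  x <- .check_design(x)
  if (length(model$support) == 0L) return(rep(model$b, nrow(x)))
  Kx <- kernel_matrix(x, model$sv_x, model$kernel, model$gamma, model$coef0,
                      model$degree, model$sigma)
  as.numeric(Kx %*% model$coefs + model$b)
}

#' Predict classes with a support vector machine
#'
#' Non-negative decision values map to the first (positive) class.
#'
#' @inheritParams svm_decision
#' @return Factor of predicted labels.
#' @export
svm_predict <- function(model, x) {
  f <- svm_decision(model, x)
  factor(ifelse(f >= 0, model$levels[1L], model$levels[2L]),
         levels = model$levels)
}
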