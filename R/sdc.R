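#' Softmax discriminant classifier trained by gradient descent
#'
#' Linear discriminant scores `z_k = w_k' x + b_k` are passed through the
#' softmax to class probabilities, and the weights are fitted by full-batch
#' gradient descent on the cross-entropy loss (optionally with an L2
#' penalty `gamma/2 ||W||^2 / N` on the weights). Features are standardized
#' internally. Training stops when the loss changes by less than `tol` or
#' after `epochs` iterations; if a step increases the loss the learning
#' rate is halved (up to five times) before an error is raised.
#'
#' @param x samples x features design matrix.
#' @param y binary labels; first level is the positive class.
#' @param alpha learning rate (default 0.5).
#' @param epochs iteration cap (default 1000).
#' @param tol loss-change stopping tolerance (default 1e-8).
#' @param gamma L2 penalty coefficient on the weights (default 0.5).
#' @param standardize centre/scale features before fitting (default TRUE).
#' @return An `sdc_model` with weights `W` (classes x features), biases `b`,
#'   the loss trace, and the standardization parameters.
#' @export
sdc_fit <- function(x, y, alpha = 0.5, epochs = 1000L, tol = 1e-8,
                    gamma = 0.5, standardize = TRUE) {
  x <- .check_design(x)
  y <- .as_binary_factor(y)
  n <- nrow(x)
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0] <- 1
  } else {
    center <- rep(0, ncol(x))
    scale <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  K <- nlevels(y)
  Y <- vapply(levels(y), function(lv) as.numeric(y == lv), numeric(n))
  Y <- matrix(Y, nrow = n)
  W <- matrix(0, nrow = K, ncol = ncol(x))
  b <- numeric(K)

  loss_of <- function(W, b) {
    P <- .softmax_rows(xs %*% t(W) + matrix(b, n, K, byrow = TRUE))
    -mean(base::log(pmax(rowSums(P * Y), 1e-300))) +
      gamma / (2 * n) * sum(W^2)
  }
  trace <- loss_of(W, b)
  halvings <- 0L
  it <- 0L
  while (it < epochs) {
    it <- it + 1L
    P <- .softmax_rows(xs %*% t(W) + matrix(b, n, K, byrow = TRUE))
    grad_W <- t(P - Y) %*% xs / n + gamma / n * W
    grad_b <- colMeans(P - Y)
    W_new <- W - alpha * grad_W
    b_new <- b - alpha * grad_b
    new_loss <- loss_of(W_new, b_new)
    if (!is.finite(new_loss) || new_loss > trace[length(trace)] + 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 5L) stop("softmax discriminant training diverged; reduce alpha")
      alpha <- alpha / 2
      it <- it - 1L
      next
    }
    W <- W_new
    b <- b_new
    trace <- c(trace, new_loss)
    if (abs(trace[length(trace)] - trace[length(trace) - 1L]) < tol) break
  }
  structure(list(W = W, b = b, levels = levels(y), loss_trace = trace,
                 center = center, scale = scale, alpha = alpha, gamma = gamma),
            class = "sdc_model")
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class probabilities from a softmax discriminant model
#'
#' @param model an `sdc_model` from [sdc_fit()].
#' @param x samples x features matrix on the training scale.
#' @return Matrix of class probabilities summing to 1 per sample.
#' @export
sdc_prob <- function(model, x) {
  x <- .check_design(x)
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  z <- xs %*% t(model$W) + matrix(model$b, nrow(xs), length(model$b),
                                  byrow = TRUE)
  p <- .softmax_rows(z)
  colnames(p) <- model$levels
  p
}

#' Predict classes with a softmax discriminant model
#'
#' Argmax of the class probabilities; exact ties go to the first (Adeno)
#' class.
#'
#' @inheritParams sdc_prob
#' @return Factor of predicted labels.
#' @export
sdc_predict <- function(model, x) {
  p <- sdc_prob(model, x)
  idx <- ifelse(p[, 2L] > p[, 1L], 2L, 1L)
  factor(model$levels[idx], levels = model$levels)
}
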