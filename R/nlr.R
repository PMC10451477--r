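#' Nonlinear regression classifier against class targets
#'
#' Each sample's features (expected on the unit interval) are collapsed to a
#' squared Euclidean distance from the Adeno target level,
#' `y_i = sum_j (T_Adeno - x_ij)^2`, which is then projected through the
#' cubic form `z = k1 y + k2^2 y^2 + k3^3 y^3` with `k1 > k2 > k3 > 0`,
#' `k2 = k1/10`, `k3 = k2/10`. The decision threshold is `g = f + d0` where
#' `f = min(z)` over the training samples and `d0` is the sum of squared
#' deviations of the training scores from their mean. `k1` is tuned by grid
#' search over `(0, 1]`, minimizing the training mean squared error between
#' the predicted-class target and the true-class target; the side of the
#' threshold assigned to Adeno is likewise chosen on the training data.
#'
#' @param x samples x features design matrix, normalized to `[0, 1]`.
#' @param y binary labels; the first factor level is the positive (Adeno)
#'   class.
#' @param targets a `target_map` (default targets 0.85 / 0.65).
#' @param k1_grid candidate `k1` values (default `seq(0.01, 1, 0.01)`).
#' @return An `nlr_model` with elements `k1`, `k2`, `k3`, `f`, `d0`, `g`,
#'   `orientation`, `train_mse`, `constraint_ok` and the class levels.
#' @export
nlr_fit <- function(x, y, targets = .default_targets(),
                    k1_grid = seq(0.01, 1, by = 0.01)) {
  x <- .check_design(x)
  y <- .as_binary_factor(y)
  if (min(table(y)) < 2L) stop("degenerate class: need at least 2 samples per class")
  ydist <- rowSums((targets$t_adeno - x)^2)
  truth_t <- .label_targets(y, targets)
  pos <- levels(y)[1L]
  neg <- levels(y)[2L]

  best <- NULL
  for (k1 in k1_grid) {
    k2 <- k1 / 10
    k3 <- k2 / 10
    z <- k1 * ydist + k2^2 * ydist^2 + k3^3 * ydist^3
    f <- min(z)
    d0 <- sum((z - mean(z))^2)
    g <- f + d0
    for (orientation in c("low_is_adeno", "high_is_adeno")) {
      pred <- if (orientation == "low_is_adeno") {
        ifelse(z <= g, pos, neg)
      } else {
        ifelse(z <= g, neg, pos)
      }
      pred_t <- ifelse(pred == pos, targets$t_adeno, targets$t_meso)
      m <- mean((pred_t - truth_t)^2)
      if (is.null(best) || m < best$train_mse - 1e-15) {
        best <- list(k1 = k1, k2 = k2, k3 = k3, f = f, d0 = d0, g = g,
                     orientation = orientation, train_mse = m)
      }
    }
  }
  best$targets <- targets
  best$levels <- levels(y)
  # printed constraint (k1 - k2^2)/2 < 0.5, read as an absolute bound
  best$constraint_ok <- abs(best$k1 - best$k2^2) / 2 < 0.5
  class(best) <- "nlr_model"
  best
}

#' Scores and class predictions from a fitted nonlinear regression model
#'
#' @param model an `nlr_model` from [nlr_fit()].
#' @param x samples x features matrix on the training scale.
#' @return Factor of predicted class labels.
#' @export
nlr_predict <- function(model, x) {
  x <- .check_design(x)
  ydist <- rowSums((model$targets$t_adeno - x)^2)
  z <- model$k1 * ydist + model$k2^2 * ydist^2 + model$k3^3 * ydist^3
  low <- z <= model$g
  pred <- if (model$orientation == "low_is_adeno") {
    ifelse(low, model$levels[1L], model$levels[2L])
  } else {
    ifelse(low, model$levels[2L], model$levels[1L])
  }
  factor(pred, levels = model$levels)
}

#' Cubic projection of squared target distances
#'
#' Exposes the score transform used by the nonlinear regression classifier:
#' `z = k1 y + k2^2 y^2 + k3^3 y^3`.
#'
#' @param y squared-distance value(s).
#' @param k1 leading coefficient in `(0, 1]`; `k2 = k1/10`, `k3 = k2/10`.
#' @return Score value(s) `z`.
#' @export
nlr_score <- function(y, k1) {
  k2 <- k1 / 10
  k3 <- k2 / 10
  k1 * y + k2^2 * y^2 + k3^3 * y^3
}
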