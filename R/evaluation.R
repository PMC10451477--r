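#' Mean squared error
#'
#' `MSE = mean((observed - target)^2)`, the quantity monitored during
#' classifier training and used as the wrapper-selection fitness.
#'
#' @param observed,targets numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
mse <- function(observed, targets) {
  if (length(observed) != length(targets)) stop("length mismatch")
  mean((observed - targets)^2)
}

#' Stratified k-fold assignment
#'
#' Deterministic given the seed. With stratification (the default — the
#' 150/31 imbalance otherwise risks folds without any Meso subject) each
#' class is shuffled and dealt round-robin, so per-fold class counts differ
#' by at most one from proportionality.
#'
#' @param labels per-subject class labels.
#' @param k number of folds (default 10).
#' @param stratified stratify by class (default TRUE).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`, one per subject.
#' @export
kfold_plan <- function(labels, k = 10L, stratified = TRUE, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must be between 2 and the number of subjects")
  set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    if (any(table(labels) < k)) {
      stop("a class has fewer members than k; use a smaller k")
    }
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

# stratified single train/test split; returns TRUE for test subjects
.split_plan <- function(labels, train_fraction = 0.85, seed = 1L) {
  labels <- as.factor(labels)
  set.seed(seed)
  test <- logical(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_test <- max(1L, length(idx) - round(length(idx) * train_fraction))
    test[sample(idx, n_test)] <- TRUE
  }
  test
}

#' Confusion matrix for the binary lung problem
#'
#' Adeno is the positive class: TP counts Adeno subjects predicted Adeno,
#' TN counts Meso subjects predicted Meso.
#'
#' @param truth,predicted label vectors of equal length.
#' @param positive the positive class label (default `"Adeno"`).
#' @return A `confusion_matrix` list with counts `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(truth, predicted, positive = "Adeno") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  is_pos <- truth == positive
  pred_pos <- predicted == positive
  structure(list(tp = sum(is_pos & pred_pos), fn = sum(is_pos & !pred_pos),
                 fp = sum(!is_pos & pred_pos), tn = sum(!is_pos & !pred_pos)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("Adeno", "Meso"), c("pred Adeno", "pred Meso")))
  print(m)
  invisible(x)
}

# add two confusion matrices
.cm_add <- function(a, b) {
  structure(list(tp = a$tp + b$tp, fn = a$fn + b$fn,
                 fp = a$fp + b$fp, tn = a$tn + b$tn),
            class = "confusion_matrix")
}

#' Classification metric suite from a confusion matrix
#'
#' Accuracy, precision, recall, F1 and error rate are reported as
#' percentages; the Matthews correlation coefficient and Cohen's kappa
#' (with its observed and chance agreement intermediates `p_o` and `p_e`)
#' on their natural scales. Any metric with a zero denominator is reported
#' as 0 and the report is flagged degenerate rather than raising an error.
#'
#' @param cm a [confusion()] result (or list with `tp`, `fn`, `fp`, `tn`).
#' @return A `metrics_report` list.
#' @export
metrics <- function(cm) {
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  n <- tp + fn + fp + tn
  if (n < 1L) stop("invalid argument: empty confusion matrix")
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else num / den
  }
  accuracy <- (tp + tn) / n
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    degenerate <- TRUE
    0
  } else (tp * tn - fp * fn) / mcc_den
  p_o <- accuracy
  p_e <- ((tp + fp) * (tp + fn) + (fp + tn) * (fn + tn)) / n^2
  kappa <- safe_div(p_o - p_e, 1 - p_e)
  structure(list(accuracy = 100 * accuracy, precision = 100 * precision,
                 recall = 100 * recall, f1 = 100 * f1, mcc = mcc,
                 error_rate = 100 * (1 - accuracy), kappa = kappa,
                 p_o = p_o, p_e = p_e, degenerate = degenerate,
                 confusion = list(tp = tp, fn = fn, fp = fp, tn = tn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.5f%%  precision %.5f%%  recall %.5f%%  ",
                     "F1 %.5f%%\nMCC %.5f  error rate %.5f%%  kappa %.5f%s\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$mcc, x$error_rate,
              x$kappa, if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Reconstruct a confusion matrix from printed summary rates
#'
#' Published tables often report only accuracy, precision and recall (as
#' percentages) together with the known class sizes. Because the counts are
#' integers, an exhaustive search over all matrices with `tp + fn = n_pos`
#' and `fp + tn = n_neg` recovers the underlying confusion matrix: the
#' candidate minimizing the squared mismatch to the printed rates is
#' returned, along with the achieved rates so the caller can verify the
#' reconstruction is consistent to printed rounding.
#'
#' @param accuracy,precision,recall printed percentages.
#' @param n_pos,n_neg class sizes (positives and negatives evaluated).
#' @return A `confusion_matrix` with attribute `"achieved"` (the rates of
#'   the reconstructed matrix) and `"mismatch"` (the residual).
#' @export
confusion_from_rates <- function(accuracy, precision, recall, n_pos, n_neg) {
  best <- NULL
  best_err <- Inf
  for (tp in 0:n_pos) {
    for (fp in 0:n_neg) {
      tn <- n_neg - fp
      fn <- n_pos - tp
      acc <- 100 * (tp + tn) / (n_pos + n_neg)
      prec <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
      rec <- 100 * tp / n_pos
      err <- (acc - accuracy)^2 + (prec - precision)^2 + (rec - recall)^2
      if (err < best_err) {
        best_err <- err
        best <- list(tp = tp, fn = fn, fp = fp, tn = tn,
                     achieved = c(accuracy = acc, precision = prec,
                                  recall = rec))
      }
    }
  }
  cm <- structure(best[c("tp", "fn", "fp", "tn")], class = "confusion_matrix")
  attr(cm, "achieved") <- best$achieved
  attr(cm, "mismatch") <- best_err
  cm
}
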