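# internal helpers shared by the classifiers

# coerce labels to a 2-level factor; first level is the positive class
# (Adeno for the lung cohort) and wins every deterministic tie-break
.as_binary_factor <- function(y) {
  if (is.factor(y)) {
    y <- droplevels(y)
  } else {
    y <- as.character(y)
    lev <- if (all(y %in% c("Adeno", "Meso"))) c("Adeno", "Meso") else sort(unique(y))
    y <- factor(y, levels = lev)
  }
  if (nlevels(y) != 2L) stop("need exactly two classes present for training")
  y
}

.check_design <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  storage.mode(x) <- "double"
  x
}

#' Min-max scale features to the unit interval
#'
#' Scales each feature (column) of a samples x features design matrix to
#' `[0, 1]` using per-feature ranges, optionally taken from a reference
#' (training) matrix so held-out samples are scaled consistently. Constant
#' features map to 0.
#'
#' @param x samples x features matrix to scale.
#' @param reference matrix supplying the ranges (default `x` itself).
#' @return Scaled matrix of the same shape.
#' @export
scale_unit <- function(x, reference = x) {
  x <- .check_design(x)
  reference <- .check_design(reference)
  lo <- apply(reference, 2L, min)
  hi <- apply(reference, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1
  sweep(sweep(x, 2L, lo), 2L, span, "/")
}

# per-sample target values (regression framing of the class labels)
.label_targets <- function(y, targets) {
  ifelse(y == levels(y)[1L], targets$t_adeno, targets$t_meso)
}
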