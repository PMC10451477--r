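#' Permutation entropy of a series
#'
#' Shannon entropy of the distribution of ordinal patterns of `order`
#' consecutive values (lag `lag`), in nats, normalized by `log(order!)` so
#' the result lies in `[0, 1]`. A strictly monotone series has a single
#' ordinal pattern and entropy 0. Ties are broken by position (first
#' occurrence ranks lower), the usual convention.
#'
#' @param x numeric vector.
#' @param order pattern length (default 3).
#' @param lag delay between pattern elements (default 1).
#' @return Normalized permutation entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(x, order = 3L, lag = 1L) {
  n <- length(x) - (order - 1L) * lag
  if (n < 1L) stop("series too short for the requested pattern order")
  patterns <- vapply(seq_len(n), function(i) {
    window <- x[i + (seq_len(order) - 1L) * lag]
    paste(order(window), collapse = "")
  }, character(1L))
  p <- table(patterns) / n
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

.moment_stats <- function(v) {
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 <= 0) {
    return(list(mean = m, variance = 0, skewness = 0, kurtosis = 0,
                degenerate = TRUE))
  }
  list(mean = m,
       variance = stats::var(v),
       skewness = mean((v - m)^3) / m2^1.5,
       kurtosis = mean((v - m)^4) / m2^2,
       degenerate = FALSE)
}

.mean_pairwise_cor <- function(values) {
  if (ncol(values) < 2L) return(NA_real_)
  cm <- suppressWarnings(stats::cor(values))
  off <- cm[upper.tri(cm)]
  if (all(is.na(off))) return(0)
  mean(off, na.rm = TRUE)
}

#' Statistical characterization of one class's spectral features
#'
#' Computes the descriptive battery used to judge whether the
#' dimensionality-reduced features still carry the character of the raw
#' intensities: pooled moments (mean, variance, skewness, Pearson kurtosis),
#' mean pairwise between-subject Pearson correlation (PCC), per-subject
#' permutation entropy (order 3, lag 1, normalized by `log 6`) and sample
#' entropy (`m = 2`, `r = 0.2 sd`) averaged over subjects, a two-sample
#' variance-ratio F test and Welch t test of this class's pooled feature
#' values against the other class, and the first canonical correlation
#' between the two classes' leading principal subspaces.
#'
#' @param features a [spectral_feature_set()] with labels for both classes.
#' @param class which class to summarize, `"Adeno"` or `"Meso"`.
#' @return A `stat_summary` list with fields `mean`, `variance`, `skewness`,
#'   `kurtosis`, `pcc`, `permutation_entropy`, `sample_entropy`,
#'   `f_statistic`, `t_statistic`, `p_value`, `cca`, `degenerate`.
#' @export
stat_summary <- function(features, class = c("Adeno", "Meso")) {
  class <- match.arg(class)
  stopifnot(inherits(features, "SpectralFeatures"))
  if (is.null(features$labels)) stop("features carry no class labels")
  in_class <- features$labels == class
  if (sum(in_class) < 2L) stop("need at least 2 subjects in the class")
  own <- features$values[, in_class, drop = FALSE]
  other <- features$values[, !in_class, drop = FALSE]
  pooled <- as.numeric(own)
  mom <- .moment_stats(pooled)
  degenerate <- mom$degenerate

  per_subject <- function(fn) {
    mean(apply(own, 2L, function(col) {
      if (stats::sd(col) == 0) return(0)
      fn(col)
    }))
  }
  pe <- per_subject(function(col) permutation_entropy(col, 3L, 1L))
  se <- per_subject(function(col) {
    pracma::sample_entropy(col, edim = 2, r = 0.2 * stats::sd(col), tau = 1)
  })

  f_stat <- t_stat <- p_val <- NA_real_
  cca <- NA_real_
  if (ncol(other) >= 2L) {
    pooled_other <- as.numeric(other)
    if (stats::sd(pooled) > 0 && stats::sd(pooled_other) > 0) {
      f_stat <- unname(stats::var.test(pooled, pooled_other)$statistic)
      tt <- stats::t.test(pooled, pooled_other)
      t_stat <- unname(tt$statistic)
      p_val <- tt$p.value
    } else {
      degenerate <- TRUE
    }
    cca <- first_canonical_correlation(own, other)
  }

  structure(list(class = class, mean = mom$mean, variance = mom$variance,
                 skewness = mom$skewness, kurtosis = mom$kurtosis,
                 pcc = .mean_pairwise_cor(own),
                 permutation_entropy = pe, sample_entropy = se,
                 f_statistic = f_stat, t_statistic = t_stat,
                 p_value = p_val, cca = cca, degenerate = degenerate),
            class = "stat_summary")
}

#' @export
print.stat_summary <- function(x, ...) {
  cat(sprintf("Feature statistics, %s class%s\n", x$class,
              if (x$degenerate) " (degenerate data)" else ""))
  flds <- c("mean", "variance", "skewness", "kurtosis", "pcc",
            "permutation_entropy", "sample_entropy",
            "f_statistic", "t_statistic", "p_value", "cca")
  for (f in flds) cat(sprintf("  %-20s %s\n", f, format(x[[f]], digits = 6)))
  invisible(x)
}

#' First canonical correlation between two classes' principal subspaces
#'
#' Each feature x subject matrix is column-centred, projected onto its
#' leading principal components (rank `min(n_A, n_B) - 1`, capped at
#' `rank_cap`), and the largest canonical correlation between the two score
#' matrices is returned. Covariances are ridge-regularized so rank-deficient
#' input never raises an error. A copy (or column permutation) of the same
#' matrix yields 1; independent matrices with many rows and few columns
#' yield small values.
#'
#' @param class_a,class_b numeric matrices with the same number of rows
#'   (features) and at least 2 columns each.
#' @param rank_cap maximum principal-subspace rank (default 10).
#' @param ridge ridge added to the score covariances (default 1e-8).
#' @return Largest canonical correlation, clamped to `[0, 1]`.
#' @export
first_canonical_correlation <- function(class_a, class_b, rank_cap = 10L,
                                        ridge = 1e-8) {
  class_a <- as.matrix(class_a)
  class_b <- as.matrix(class_b)
  if (nrow(class_a) != nrow(class_b)) {
    stop("feature dimensions (rows) must agree")
  }
  if (ncol(class_a) < 2L || ncol(class_b) < 2L) {
    stop("need at least 2 columns per class")
  }
  r <- max(1L, min(min(ncol(class_a), ncol(class_b)) - 1L, rank_cap))
  scores <- function(x) {
    x <- sweep(x, 2L, colMeans(x))
    s <- svd(x, nu = 0L, nv = min(r, ncol(x)))
    sc <- x %*% s$v
    sweep(sc, 2L, colMeans(sc))
  }
  sa <- scores(class_a)
  sb <- scores(class_b)
  whiten <- function(s) {
    cv <- crossprod(s) / (nrow(s) - 1L) + ridge * diag(ncol(s))
    e <- eigen(cv, symmetric = TRUE)
    vals <- pmax(e$values, ridge)
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  }
  m <- whiten(sa) %*% (crossprod(sa, sb) / (nrow(sa) - 1L)) %*% whiten(sb)
  rho <- svd(m)$d[1L]
  min(max(rho, 0), 1)
}
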