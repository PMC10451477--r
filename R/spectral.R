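#' Blackman window
#'
#' Symmetric Blackman taper
#' `w[n] = 0.42 - 0.5 cos(2 pi n / (M-1)) + 0.08 cos(4 pi n / (M-1))`,
#' `n = 0..M-1`. The endpoints vanish exactly (`0.42 - 0.5 + 0.08 = 0`) and
#' the centre of an odd-length window is exactly 1.
#'
#' @param M window length, at least 2.
#' @return Numeric vector of `M` weights.
#' @export
blackman_window <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || M < 2) {
    stop("invalid argument: window length M must be >= 2")
  }
  M <- as.integer(M)
  n <- seq_len(M) - 1L
  0.42 - 0.5 * cos(2 * pi * n / (M - 1)) + 0.08 * cos(4 * pi * n / (M - 1))
}

#' Window specification for the short-time Fourier transform
#'
#' Defaults are sized so that a 12,533-gene expression vector maps to
#' `4096/2 + 1 = 2049` one-sided spectral features: window and transform
#' length 4096, hop 2048.
#'
#' @param window_length window length `M` (Blackman taper).
#' @param hop frame advance, `0 < hop <= window_length`.
#' @param transform_size DFT length (even, `>= window_length`); the one-sided
#'   output has `transform_size/2 + 1` bins.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_length = 4096L, hop = 2048L,
                        transform_size = 4096L) {
  spec <- list(window_length = as.integer(window_length),
               hop = as.integer(hop),
               transform_size = as.integer(transform_size))
  if (spec$hop < 1L || spec$hop > spec$window_length) {
    stop("invalid window spec: need 0 < hop <= window_length")
  }
  if (spec$window_length > spec$transform_size) {
    stop("invalid window spec: window_length must not exceed transform_size")
  }
  if (spec$transform_size %% 2L != 0L) {
    stop("invalid window spec: transform_size must be even")
  }
  class(spec) <- "window_spec"
  spec
}

#' Short-time Fourier transform (one-sided)
#'
#' Frames the signal at multiples of `hop`, applies the Blackman window,
#' zero-pads each frame to `transform_size` and returns the one-sided DFT
#' `X[f, k] = sum_n x[n] w[n - f hop] exp(-j 2 pi k n / transform_size)`
#' for bins `k = 0..transform_size/2`. The signal is zero-padded so the
#' last frame is complete; the frame count is `ceiling(N / hop)`.
#'
#' @param signal real vector, length at least 1.
#' @param spec a [window_spec()].
#' @return Complex matrix, `transform_size/2 + 1` bins x `ceiling(N/hop)`
#'   frames, with the window weights attached as attribute `"window"`.
#' @export
stft <- function(signal, spec = window_spec()) {
  if (length(signal) < 1L) stop("invalid argument: empty signal")
  if (!is.numeric(signal)) stop("invalid argument: signal must be numeric")
  M <- spec$window_length
  hop <- spec$hop
  nfft <- spec$transform_size
  n_frames <- as.integer(ceiling(length(signal) / hop))
  padded_len <- (n_frames - 1L) * hop + M
  x <- c(signal, numeric(padded_len - length(signal)))
  w <- blackman_window(M)
  frames <- matrix(0, nrow = nfft, ncol = n_frames)
  for (f in seq_len(n_frames)) {
    start <- (f - 1L) * hop
    frames[seq_len(M), f] <- x[start + seq_len(M)] * w
  }
  spectrum <- stats::mvfft(frames)[seq_len(nfft / 2L + 1L), , drop = FALSE]
  attr(spectrum, "window") <- w
  spectrum
}

#' Spectral feature container
#'
#' @param values non-negative feature x subject magnitude matrix.
#' @param labels per-subject class labels (levels Adeno, Meso) or NULL.
#' @param spec the [window_spec()] that produced the features.
#' @return A `SpectralFeatures` list with `values`, `labels`,
#'   `feature_count`, `spec`.
#' @export
spectral_feature_set <- function(values, labels = NULL, spec = window_spec()) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("spectral features are magnitudes; must be >= 0")
  if (!is.null(labels)) {
    labels <- factor(as.character(labels), levels = c("Adeno", "Meso"))
    if (length(labels) != ncol(values)) stop("label/subject count mismatch")
  }
  structure(list(values = values, labels = labels,
                 feature_count = nrow(values), spec = spec),
            class = "SpectralFeatures")
}

#' @export
print.SpectralFeatures <- function(x, ...) {
  cat(sprintf("SpectralFeatures: %d features x %d subjects\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' STFT dimensionality reduction of an expression matrix
#'
#' Each subject's gene vector (array-native gene ordering treated as the
#' signal axis) is short-time Fourier transformed; the magnitude of each
#' one-sided bin is aggregated across frames, yielding
#' `transform_size/2 + 1` features per subject. With the default 4096-point
#' transform a 12,533-gene subject yields 2049 features, so the full
#' cohort maps to a 2049 x 181 matrix (2049 x 150 Adeno, 2049 x 31 Meso).
#'
#' @param data an [expression_matrix()] (or plain matrix, genes x subjects).
#' @param spec a [window_spec()].
#' @param aggregate frame aggregation, `"mean"` (default) or `"max"` of the
#'   per-frame magnitudes.
#' @return A [spectral_feature_set()] carrying the labels of `data`.
#' @export
spectral_features <- function(data, spec = window_spec(),
                              aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (inherits(data, "ExpressionMatrix")) {
    values <- data$values
    labels <- data$labels
  } else {
    values <- as.matrix(data)
    labels <- NULL
  }
  if (nrow(values) < spec$window_length) {
    stop(sprintf(paste0("gene count (%d) is smaller than the window length (%d);",
                        " use a smaller window"),
                 nrow(values), spec$window_length))
  }
  agg <- if (aggregate == "mean") rowMeans else function(m) apply(m, 1L, max)
  feats <- vapply(seq_len(ncol(values)), function(s) {
    agg(Mod(stft(values[, s], spec)))
  }, numeric(spec$transform_size / 2L + 1L))
  feats <- matrix(feats, nrow = spec$transform_size / 2L + 1L)
  spectral_feature_set(feats, labels, spec)
}
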