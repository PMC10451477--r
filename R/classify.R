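#' Train any of the seven pipeline classifiers by name
#'
#' Thin dispatcher used by the wrapper-selection fitness and the
#' cross-validation driver. Recognised kinds: `"nlr"`, `"gmm"`, `"sdc"`,
#' `"nbc"`, `"svm-linear"`, `"svm-poly"`, `"svm-rbf"`.
#'
#' @param kind classifier name.
#' @param x samples x features design matrix.
#' @param y binary labels.
#' @param params named list of extra arguments passed to the `*_fit`
#'   function.
#' @return A fitted model whose class carries a `classifier_predict` method.
#' @export
train_classifier <- function(kind, x, y, params = list()) {
  fitter <- switch(kind,
                   "nlr" = nlr_fit,
                   "gmm" = gmm_fit,
                   "sdc" = sdc_fit,
                   "nbc" = nbc_fit,
                   "svm-linear" = function(x, y, ...) svm_fit(x, y, kernel = "linear", ...),
                   "svm-poly" = function(x, y, ...) svm_fit(x, y, kernel = "polynomial", ...),
                   "svm-rbf" = function(x, y, ...) svm_fit(x, y, kernel = "rbf", ...),
                   stop("unknown classifier kind: ", kind))
  model <- do.call(fitter, c(list(x, y), params))
  attr(model, "kind") <- kind
  model
}

#' Predict with a model trained by [train_classifier()]
#'
#' @param model fitted model.
#' @param x samples x features matrix.
#' @return Factor of predicted labels.
#' @export
classifier_predict <- function(model, x) {
  switch(class(model)[1L],
         nlr_model = nlr_predict(model, x),
         gmm_model = gmm_predict(model, x),
         sdc_model = sdc_predict(model, x),
         nbc_model = nbc_predict(model, x),
         svm_model = svm_predict(model, x),
         stop("unknown model class: ", class(model)[1L]))
}
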