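Package: lungSTFT
Title: STFT Dimensionality Reduction and Metaheuristic Feature Selection
    for Lung Cancer Microarray Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-level pipeline for classifying adenocarcinoma versus
    mesothelioma from bulk microarray gene expression. Each subject's gene
    expression vector is reduced to a fixed-length magnitude spectrum by a
    short-time Fourier transform with a Blackman window, a subset of the
    spectral features (or of subject columns) is chosen by particle swarm
    optimization or harmony search driven by training mean squared error,
    and seven classifiers (nonlinear regression against class targets,
    Gaussian mixture models fitted by expectation-maximization, a softmax
    discriminant trained by gradient descent, Gaussian naive Bayes, and
    support vector machines with linear, polynomial and radial basis
    kernels) are evaluated under stratified cross-validation with a full
    confusion-matrix metric suite (accuracy, precision, recall, F1,
    Matthews correlation, error rate, Cohen's kappa) and a Friedman rank
    test for comparing selectors. A synthetic data generator emulating the
    shape and class imbalance of the Lung Harvard 2 cohort makes the whole
    pipeline testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
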