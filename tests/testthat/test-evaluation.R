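test_that("mse matches hand arithmetic and a loop oracle", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, 0), c(0, 0)), 0.5)
  set.seed(19)
  o <- stats::rnorm(50)
  t <- stats::rnorm(50)
  acc <- 0
  for (i in seq_along(o)) acc <- acc + (o[i] - t[i])^2
  expect_equal(mse(o, t), acc / 50, tolerance = 1e-12)
  expect_error(mse(1:3, 1:2), "mismatch")
})

test_that("stratified folds cover the cohort with balanced class counts", {
  labels <- rep(c("Adeno", "Meso"), c(150, 31))
  folds <- kfold_plan(labels, k = 10L, seed = 3)
  expect_setequal(unique(folds), 1:10)
  expect_equal(length(folds), 181L)
  meso_per_fold <- table(folds[labels == "Meso"])
  expect_true(all(meso_per_fold %in% c(3, 4)))
  adeno_per_fold <- table(folds[labels == "Adeno"])
  expect_true(all(adeno_per_fold == 15))
  expect_identical(folds, kfold_plan(labels, k = 10L, seed = 3))
  expect_false(identical(folds, kfold_plan(labels, k = 10L, seed = 4)))
  expect_error(kfold_plan(rep(c("Adeno", "Meso"), c(20, 5)), k = 10L),
               "smaller k")
})

test_that("confusion counts follow the Adeno-positive convention", {
  truth <- c("Adeno", "Adeno", "Meso", "Meso", "Adeno")
  cm <- confusion(truth, truth)
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 3L, fn = 0L, fp = 0L, tn = 2L))
  all_adeno <- confusion(truth, rep("Adeno", 5))
  expect_equal(all_adeno$tn, 0L)
  expect_equal(all_adeno$fp, 2L)
  with(unclass(all_adeno), expect_equal(tp + fn + fp + tn, 5L))
})

test_that("the metric suite agrees with an independent formula oracle", {
  oracle <- function(tp, fn, fp, tn) {
    n <- tp + fn + fp + tn
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fp + tn) * (fn + tn)) / n^2
    list(accuracy = 100 * po,
         precision = if (tp + fp > 0) 100 * tp / (tp + fp) else 0,
         recall = if (tp + fn > 0) 100 * tp / (tp + fn) else 0,
         f1 = if (2 * tp + fp + fn > 0) 100 * 2 * tp / (2 * tp + fp + fn) else 0,
         mcc = {
           den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
           if (den == 0) 0 else (tp * tn - fp * fn) / den
         },
         error_rate = 100 * (1 - po),
         kappa = if (pe < 1) (po - pe) / (1 - pe) else 0)
  }
  set.seed(23)
  for (i in 1:1000) {
    cnt <- stats::rpois(4, lambda = c(40, 5, 5, 10))
    if (sum(cnt) == 0) cnt <- c(1, 0, 0, 0)
    cm <- list(tp = cnt[1], fn = cnt[2], fp = cnt[3], tn = cnt[4])
    got <- metrics(cm)
    want <- oracle(cnt[1], cnt[2], cnt[3], cnt[4])
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10, label = f)
    }
    # MCC and kappa share the sign of TP*TN - FP*FN
    if (got$mcc != 0 && got$kappa != 0) {
      expect_equal(sign(got$mcc), sign(got$kappa))
    }
  }
})

test_that("perfect and degenerate matrices behave as documented", {
  perfect <- metrics(list(tp = 10L, fn = 0L, fp = 0L, tn = 5L))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$accuracy + perfect$error_rate, 100)

  # kappa is 1 exactly when there are no errors and both classes appear
  imperfect <- metrics(list(tp = 10L, fn = 1L, fp = 0L, tn = 5L))
  expect_lt(imperfect$kappa, 1)
  one_class <- metrics(list(tp = 10L, fn = 0L, fp = 0L, tn = 0L))
  expect_true(one_class$degenerate)

  expect_error(metrics(list(tp = 0L, fn = 0L, fp = 0L, tn = 0L)), "empty")
})

test_that("F1 is the harmonic mean of precision and recall", {
  m <- metrics(list(tp = 30L, fn = 10L, fp = 5L, tn = 20L))
  harmonic <- 2 / (1 / m$precision + 1 / m$recall)
  expect_equal(m$f1, harmonic, tolerance = 1e-10)
  expect_equal(m$kappa, (m$p_o - m$p_e) / (1 - m$p_e), tolerance = 1e-12)
})

test_that("published-rate reconstruction inverts known confusion matrices", {
  cm0 <- list(tp = 143L, fn = 7L, fp = 3L, tn = 28L)
  m0 <- metrics(cm0)
  back <- confusion_from_rates(round(m0$accuracy, 5), round(m0$precision, 2),
                               round(m0$recall, 2), 150L, 31L)
  expect_equal(unclass(back)[c("tp", "fn", "fp", "tn")],
               cm0, ignore_attr = TRUE)
})
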