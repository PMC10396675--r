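# Classifier bank, CV harness, confusion metrics and reporting.

# two well-separated Gaussian blobs whose means also point in different
# directions (so cosine distance separates them too)
make_blobs <- function(n_per = 30, p = 6, sep = 8, seed = 1) {
  set.seed(seed)
  mu1 <- rep(c(sep, 0), length.out = p)
  mu2 <- rep(c(0, sep), length.out = p)
  X <- rbind(sweep(matrix(rnorm(n_per * p), n_per, p), 2, mu1, "+"),
             sweep(matrix(rnorm(n_per * p), n_per, p), 2, mu2, "+"))
  labs <- rep(c("benign", "malignant"), each = n_per)
  list(X = X, labs = labs)
}

test_that("presets cover the bank and unknown names fail loudly", {
  presets <- classifier_presets()
  bank <- default_classifier_bank()
  expect_length(bank, 17L)
  expect_true(all(bank %in% names(presets)))
  expect_equal(classifier_presets()$quadratic_svm$kern$degree, 2)
  expect_equal(classifier_presets()$fine_knn$k, 1L)
  expect_equal(classifier_presets()$coarse_tree$max_splits, 4L)
  expect_error(build_classifier("no_such"), "valid names")
})

test_that("every SVM and KNN preset separates two disjoint Gaussian blobs", {
  b <- make_blobs()
  svm_knn <- grep("svm|knn", default_classifier_bank(), value = TRUE)
  rep <- cross_validate(b$X, b$labs, specs = svm_knn, k_folds = 5L, seed = 2L)
  expect_equal(rep$accuracy_pct, rep(100, length(svm_knn)))
  expect_equal(rep$sensitivity, rep(1, length(svm_knn)))
  expect_equal(rep$specificity, rep(1, length(svm_knn)))
})

test_that("trees and ensembles also solve the separable case", {
  b <- make_blobs(seed = 3)
  rep <- cross_validate(b$X, b$labs,
                        specs = c("fine_tree", "bagged_ensemble", "rusboost",
                                  "subspace_discriminant", "subspace_knn"),
                        k_folds = 5L, seed = 2L)
  expect_true(all(rep$accuracy_pct >= 95))
})

test_that("permuted labels give chance-level pooled accuracy", {
  b <- make_blobs(n_per = 30, seed = 4)
  set.seed(5)
  labs <- sample(b$labs)   # break the feature-label association
  rep <- cross_validate(b$X, labs, specs = "fine_knn", k_folds = 5L, seed = 6L)
  n <- length(labs)
  # 99% binomial interval around the majority-class rate (here 0.5)
  lo <- 100 * qbinom(0.005, n, 0.5) / n
  hi <- 100 * qbinom(0.995, n, 0.5) / n
  expect_gte(rep$accuracy_pct, lo)
  expect_lte(rep$accuracy_pct, hi)
})

test_that("cross-validation is deterministic and covers every sample once", {
  b <- make_blobs(n_per = 15, seed = 7)
  r1 <- cross_validate(b$X, b$labs, specs = c("rusboost", "quadratic_svm"),
                       k_folds = 5L, seed = 9L)
  r2 <- cross_validate(b$X, b$labs, specs = c("rusboost", "quadratic_svm"),
                       k_folds = 5L, seed = 9L)
  expect_identical(attr(r1, "folds"), attr(r2, "folds"))
  expect_identical(attr(r1, "oof"), attr(r2, "oof"))
  expect_identical(attr(r1, "confusions"), attr(r2, "confusions"))
  folds <- attr(r1, "folds")
  expect_identical(sort(unique(folds)), 1:5)
  expect_length(attr(r1, "oof")$rusboost, length(b$labs))
  # stratification: each fold holds both classes
  for (f in 1:5) expect_length(unique(b$labs[folds == f]), 2L)
})

test_that("fold construction fails when a class is smaller than k", {
  expect_error(make_folds(c(rep("a", 30), rep("b", 4)), k_folds = 10L),
               "smaller k")
})

test_that("confusion metrics: arithmetic, degenerate flags, identities", {
  m <- confusion_metrics(TP = 49, FP = 7, TN = 96, FN = 0)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 96 / 103, tolerance = 1e-12)
  expect_equal(m$false_positive_rate, 7 / 103, tolerance = 1e-12)
  expect_equal(m$accuracy, 145 / 152, tolerance = 1e-12)
  d <- confusion_metrics(0, 0, 10, 0)
  expect_true(is.na(d$sensitivity))
  expect_true("sensitivity" %in% d$undefined)
  expect_equal(d$specificity, 1)
  expect_error(confusion_metrics(-1, 0, 1, 0), "non-negative")
  expect_error(confusion_metrics(0, 0, 0, 0), "positive")
  set.seed(10)
  for (trial in 1:50) {
    cnt <- rpois(4, 20)
    if (sum(cnt) == 0 || cnt[2] + cnt[3] == 0) next
    m <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(m$false_positive_rate + m$specificity, 1)
    expect_equal(m$accuracy + m$error_rate, 1)
  }
})

test_that("appending a constant column does not change pooled accuracy", {
  b <- make_blobs(n_per = 20, seed = 11)
  r1 <- cross_validate(b$X, b$labs, "quadratic_svm", k_folds = 5L, seed = 3L)
  r2 <- cross_validate(cbind(b$X, 5), b$labs, "quadratic_svm", k_folds = 5L,
                       seed = 3L)
  expect_equal(r1$accuracy_pct, r2$accuracy_pct)
})

test_that("rank_and_report orders by accuracy with time as tie-breaker", {
  td <- withr::local_tempdir()
  rep <- structure(
    data.frame(method = c("a", "b", "c"),
               prediction_speed_obs_per_sec = c(10, 20, 30),
               training_time_sec = c(5, 1, 2),
               accuracy_pct = c(90, 95, 95),
               sensitivity = c(0.9, 0.95, 0.95),
               specificity = c(0.9, 0.95, 0.95),
               false_positive_rate = c(0.1, 0.05, 0.05),
               error_rate_pct = c(10, 5, 5),
               tp = c(9, 9, 9), fp = c(1, 1, 1), tn = c(9, 9, 9),
               fn = c(1, 1, 1)),
    class = c("eval_report", "data.frame"),
    confusions = list(a = c(TP = 9, FP = 1, TN = 9, FN = 1)),
    k_folds = 10L, positive_class = "malignant")
  out <- rank_and_report(rep, td)
  expect_identical(out$ranked$method, c("b", "c", "a"))  # tie: b is faster
  hdr <- readLines(file.path(td, "results.csv"), n = 1)
  expect_match(hdr, "^\"method\",\"prediction_speed_obs_per_sec\",\"training_time_sec\",\"accuracy_pct\"")
  js <- jsonlite::read_json(file.path(td, "summary.json"))
  expect_identical(js$best$method, "b")
  expect_error(rank_and_report(rep[0, ], td), "non-empty")
})
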