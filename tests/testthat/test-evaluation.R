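# LOOCV harness and pooled metrics.

test_that("leave-one-out splits partition the cohort", {
  folds <- loocv_splits(8L)
  expect_length(folds, 8L)
  for (k in seq_along(folds)) {
    expect_length(folds[[k]]$train, 7L)
    expect_equal(sort(c(folds[[k]]$train, folds[[k]]$test)), 1:8)
  }
  expect_equal(sort(vapply(folds, function(f) f$test, integer(1))), 1:8)

  two <- loocv_splits(2L)
  expect_equal(two[[1]]$train, 2L)
  expect_equal(two[[1]]$test, 1L)
  expect_equal(two[[2]]$train, 1L)
  expect_equal(two[[2]]$test, 2L)

  expect_error(loocv_splits(1L), "at least 2")
})

test_that("pooled metrics handle the canonical hand cases", {
  m <- compute_metrics(c(1L, 0L), c(0.9, 0.1))
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$roc_auc, 1)
  expect_equal(m$pr_auc, 1)

  # constant score: exchangeable ranking
  expect_equal(compute_metrics(c(1L, 0L, 1L, 0L), rep(0.4, 4))$roc_auc, 0.5)

  # degenerate single-class truth: areas undefined
  d <- compute_metrics(c(1L, 1L), c(0.6, 0.7))
  expect_true(is.na(d$roc_auc) && is.na(d$pr_auc))
  expect_equal(d$accuracy, 1)

  expect_error(compute_metrics(c(1L, 0L), 0.5), "equal length")
})

test_that("rank ROC-AUC equals the brute-force pairwise count with half ties", {
  cases <- eamreg:::with_seed(12L, lapply(1:100, function(i) {
    n <- sample(4:12, 1)
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    p <- round(runif(n), 2)  # rounding forces occasional ties
    list(y = y, p = p)
  }))
  for (cs in cases) {
    pos <- which(cs$y == 1L)
    neg <- which(cs$y == 0L)
    brute <- mean(outer(cs$p[pos], cs$p[neg],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(compute_metrics(cs$y, cs$p)$roc_auc, brute, tolerance = 1e-9)
  }
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  cases <- eamreg:::with_seed(13L, lapply(1:50, function(i) {
    n <- sample(6:20, 1)
    list(y = c(0L, 1L, sample(0:1, n - 2, replace = TRUE)), p = runif(n))
  }))
  for (cs in cases) {
    ref <- suppressMessages(pROC::auc(pROC::roc(
      cs$y, cs$p, quiet = TRUE, direction = "<", levels = c(0, 1))))
    expect_equal(compute_metrics(cs$y, cs$p)$roc_auc, as.numeric(ref),
                 tolerance = 1e-9)
  }
})

test_that("average precision matches step-integration on small instances", {
  # hand case: truth (1,0,1), scores ranked (0.9, 0.8, 0.4)
  # thresholds desc: P=(1, 1/2, 2/3), R=(1/2, 1/2, 1) -> AP = 1/2 + 1/3
  expect_equal(compute_metrics(c(1L, 0L, 1L), c(0.9, 0.8, 0.4))$pr_auc,
               1 / 2 + 1 / 3, tolerance = 1e-12)
  # perfect ranking gives area 1
  expect_equal(compute_metrics(c(0L, 1L), c(0.1, 0.9))$pr_auc, 1)
})

test_that("scenario evaluation pools one held-out prediction per map", {
  cohort <- small_cohort(seed = 19L, n = 6L)
  w <- encoder_init(1L)
  cfg <- mlp_config(epochs = 20L, seed = 2L, balanced_bagging = FALSE)
  s <- run_scenario(cohort, template_index = 1L, channel = "bipolar",
                    label = "af_type", encoder_weights = w, config = cfg,
                    seed = 3L, max_iter = 2L)
  expect_s3_class(s, "scenario_result")
  expect_length(s$per_fold_predictions, 6L)
  expect_true(all(vapply(s$per_fold_predictions, function(p) {
    abs(sum(p$probabilities) - 1) < 1e-9
  }, logical(1))))
  expect_true(s$accuracy >= 0 && s$accuracy <= 1)
  expect_error(run_scenario(cohort, template_index = 9L, channel = "bipolar",
                            label = "af_type", encoder_weights = w,
                            config = cfg),
               "out of range")
})

test_that("the full report has six tables and ensemble rows collapse correctly", {
  cohort <- small_cohort(seed = 23L, n = 4L)
  w <- encoder_init(1L)
  cfg <- mlp_config(epochs = 15L, seed = 2L, balanced_bagging = FALSE)
  rep1 <- full_report(cohort, w, cfg, seed = 5L, max_iter = 2L)
  expect_length(rep1$tables, 6L)
  expect_setequal(names(rep1$tables),
                  c("unipolar_af_type", "bipolar_af_type", "ensemble_af_type",
                    "unipolar_recurrence_1y", "bipolar_recurrence_1y",
                    "ensemble_recurrence_1y"))
  for (tb in rep1$tables) {
    expect_equal(nrow(tb), 4L)
    expect_setequal(setdiff(names(tb), "template"),
                    c("accuracy", "f1", "roc_auc", "pr_auc"))
  }
  # determinism under the master seed
  rep2 <- full_report(cohort, w, cfg, seed = 5L, max_iter = 2L)
  expect_identical(rep1$tables, rep2$tables)

  # an ensemble of two identical predictions equals the single channel:
  # force it by using the bipolar features for both channels
  cohort_same <- lapply(cohort, function(m) {
    m$unipolar <- m$bipolar
    m
  })
  rep3 <- full_report(cohort_same, w, cfg, seed = 5L, max_iter = 2L)
  expect_equal(rep3$tables$ensemble_af_type, rep3$tables$bipolar_af_type)
})

test_that("reports can be written to disk with a JSON summary", {
  cohort <- small_cohort(seed = 29L, n = 4L)
  rep1 <- full_report(cohort, encoder_init(1L),
                      mlp_config(epochs = 10L, seed = 2L, balanced_bagging = FALSE),
                      seed = 5L, max_iter = 1L)
  dir <- withr::local_tempdir()
  write_report(rep1, dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 6L)
  expect_true(file.exists(file.path(dir, "summary.json")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_length(js, 6L)
})
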