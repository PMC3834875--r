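test_that("confusion counts behave at degenerate and hand-checked thresholds", {
  pr <- make_preds(prob = c(0.9, 0.7, 0.55, 0.5, 0.3, 0.1),
                   label = c(1, 0, 1, 0, 1, 0))
  c0 <- confusion_at_threshold(pr, 0)
  expect_equal(c(c0$tp, c0$fp, c0$tn, c0$fn), c(3, 3, 0, 0))
  c1 <- confusion_at_threshold(pr, 1)
  expect_equal(c(c1$tp, c1$fp), c(0, 0))
  # hand tally at 0.5 (tie at the threshold classifies positive)
  c5 <- confusion_at_threshold(pr, 0.5)
  expect_equal(c(c5$tp, c5$fp, c5$tn, c5$fn), c(2, 2, 1, 1))
  expect_equal(c5$tp + c5$fp + c5$tn + c5$fn, nrow(pr))
})

test_that("threshold metrics satisfy their identities on known counts", {
  # counts engineered to sens 0.647, spec 0.601
  m <- basic_metrics(list(tp = 647, fn = 353, tn = 601, fp = 399))
  expect_equal(m[["sensitivity"]], 0.647)
  expect_equal(m[["specificity"]], 0.601)
  expect_equal(m[["youden"]], 0.248)

  # an all-negative classifier: sens 0, spec 1, youden 0, PPV undefined
  pr <- make_preds(c(0.1, 0.2, 0.3), c(1, 0, 0))
  m2 <- basic_metrics(confusion_at_threshold(pr, 0.9))
  expect_equal(unname(m2[c("sensitivity", "specificity", "youden")]),
               c(0, 1, 0))
  expect_true(is.na(m2[["ppv"]]))

  # perfection
  prf <- make_preds(c(0.9, 0.8, 0.1), c(1, 1, 0))
  m3 <- basic_metrics(confusion_at_threshold(prf, 0.5))
  expect_equal(unname(m3), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Brier score matches direct arithmetic and the prevalence bound", {
  labs <- rep(c(1, 0), c(30, 70))
  expect_equal(brier_score(make_preds(rep(0.3, 100), labs)), 0.21)
  expect_equal(brier_score(make_preds(labs, labs)), 0)
  expect_equal(brier_score(make_preds(c(0.8, 0.2), c(1, 0))), 0.04)
  # pi (1 - pi) for several prevalences
  for (pi in c(0.1, 0.25, 0.5)) {
    n <- 200
    labs <- rep(c(1, 0), c(pi * n, (1 - pi) * n))
    expect_equal(brier_score(make_preds(rep(pi, n), labs)), pi * (1 - pi),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals exhaustive pairwise counting on random instances", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(8:50, 1)
    prob <- round(runif(n), 2)  # rounding forces ties
    label <- rbinom(n, 1, 0.4)
    if (length(unique(label)) < 2) next
    pr <- make_preds(prob, label)
    expect_equal(auc(pr), auc_pairwise_oracle(prob, label),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  pr <- make_preds(runif(200), rbinom(200, 1, 0.3))
  ref <- as.numeric(pROC::auc(pROC::roc(pr$label, pr$prob, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(pr), ref, tolerance = 1e-12)
})

test_that("AUC degenerate cases and rank invariance hold", {
  expect_equal(auc(make_preds(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))), 1)
  expect_equal(auc(make_preds(rep(0.4, 10), rep(c(1, 0), 5))), 0.5)
  expect_error(auc(make_preds(c(0.3, 0.4), c(1, 1))), "both outcome classes")
  set.seed(10)
  prob <- runif(80); label <- rbinom(80, 1, 0.4)
  a0 <- auc(make_preds(prob, label))
  expect_equal(auc(make_preds(plogis(5 * prob - 2), label)), a0)
  expect_equal(auc(make_preds(prob^3, label)), a0)
})

test_that("sensitivity falls and specificity rises along a threshold sweep", {
  set.seed(7)
  pr <- make_preds(runif(300), rbinom(300, 1, 0.3))
  grid <- seq(0, 1, by = 0.01)
  sens <- spec <- numeric(length(grid))
  for (i in seq_along(grid)) {
    m <- basic_metrics(confusion_at_threshold(pr, grid[i]))
    sens[i] <- m[["sensitivity"]]; spec[i] <- m[["specificity"]]
  }
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("the discrimination report is internally consistent", {
  co <- planted_cohort(n = 500, seed = 41)
  pr <- cross_validated_predictions(co, model_spec("LOGISTIC"),
                                    assign_folds(co, 5, 4))
  rep <- discrimination_report(pr)
  expect_equal(rep$youden, rep$sensitivity + rep$specificity - 1)
  expect_equal(rep$auc, auc_pairwise_oracle(pr$prob, pr$label),
               tolerance = 1e-12)
  # the chosen threshold maximizes Youden over observed probabilities
  youdens <- vapply(unique(pr$prob), function(t)
    basic_metrics(confusion_at_threshold(pr, t))[["youden"]], numeric(1))
  expect_equal(basic_metrics(confusion_at_threshold(pr, rep$threshold))[["youden"]],
               max(youdens))
  # alternative threshold rules
  expect_equal(discrimination_report(pr, "fixed", fixed = 0.5)$threshold, 0.5)
  expect_equal(discrimination_report(pr, "prevalence")$threshold,
               mean(pr$label))
})

test_that("ties in the Youden criterion break to the smallest threshold", {
  pr <- make_preds(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))
  # thresholds 0.4 and 0.8 both give youden 0.5; the smaller must win
  t <- choose_threshold(pr, "youden")
  expect_equal(t, 0.4)
})
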