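test_that("fold assignment is balanced, exhaustive and reproducible", {
  co <- sample_cohort(default_params(n = 603, seed = 1))
  f <- assign_folds(co, k = 5, seed = 42)
  expect_setequal(f$id, co$id)
  expect_equal(sort(as.integer(table(f$fold))), c(120, 120, 121, 121, 121))
  expect_identical(assign_folds(co, 5, 42), f)
  expect_false(identical(assign_folds(co, 5, 43)$fold, f$fold))

  tiny <- co[1:5, ]
  expect_equal(sort(as.integer(table(assign_folds(tiny, 5, 1)$fold))),
               rep(1L, 5))
  expect_error(assign_folds(co, k = 1), "at least 2")
  expect_error(assign_folds(tiny[1:3, ], k = 5), "at least k")
})

test_that("feature encoding uses fixed reference coding", {
  co <- sample_cohort(default_params(n = 50, seed = 2))
  X <- encode_features(co)
  expect_equal(ncol(X), 1 + 2 + 5)
  expect_equal(colnames(X)[1], "psa")
  # reference-level patient: T1c and GS <=5 encode to all-zero indicators
  ref <- co[1, ]
  ref$clinical_stage <- factor("T1c", CLINICAL_STAGE_LEVELS)
  ref$biopsy_gs <- factor("<=5", GS_LEVELS)
  x <- encode_features(ref)
  expect_equal(unname(x[1, -1]), rep(0, 7))
  # deterministic for identical patients
  expect_identical(encode_features(co), encode_features(co))
  expect_equal(ncol(encode_features(co, "clinical_stage")), 2)
})

test_that("out-of-fold predictions partition the cohort with valid probabilities", {
  co <- planted_cohort(n = 300, seed = 21)
  folds <- assign_folds(co, 5, seed = 7)
  for (fam in c("LOGISTIC", "RANDOM_FOREST", "KNN")) {
    pr <- cross_validated_predictions(co, model_spec(fam), folds)
    expect_setequal(pr$id, co$id)
    expect_equal(nrow(pr), nrow(co))
    expect_false(anyDuplicated(pr$id) > 0)
    expect_true(all(pr$prob >= 0 & pr$prob <= 1))
    # every prediction comes from the patient's own held-out fold
    expect_equal(pr$fold, folds$fold[match(pr$id, folds$id)])
  }
})

test_that("the whole CV run is deterministic given cohort, spec and folds", {
  co <- planted_cohort(n = 250, seed = 33)
  folds <- assign_folds(co, 5, seed = 3)
  for (fam in c("LOGISTIC", "RANDOM_FOREST", "KNN")) {
    a <- cross_validated_predictions(co, model_spec(fam), folds)
    b <- cross_validated_predictions(co, model_spec(fam), folds)
    expect_identical(a, b)
  }
})

test_that("a planted PSA effect is detected and a null signal is not", {
  co <- planted_cohort(n = 600, seed = 55)
  folds <- assign_folds(co, 5, seed = 5)
  pr <- cross_validated_predictions(co, model_spec("LOGISTIC"), folds)
  expect_gt(auc(pr), 0.6)

  # outcome independent of all predictors: pooled AUC near 1/2
  null_co <- co
  set.seed(99)
  null_noc <- runif(nrow(co)) < 0.3
  null_co$path_stage <- factor(ifelse(null_noc, "ECE", "OC"),
                               PATH_STAGE_LEVELS)
  null_co$noc <- null_noc
  pr0 <- cross_validated_predictions(null_co, model_spec("LOGISTIC"),
                                     assign_folds(null_co, 5, 6))
  expect_lt(abs(auc(pr0) - 0.5), 0.08)
})

test_that("training folds with a single outcome class abort clearly", {
  co <- sample_cohort(default_params(n = 100, seed = 14))
  co$path_stage <- factor("OC", PATH_STAGE_LEVELS)
  co$noc <- FALSE
  co$noc[1] <- TRUE
  co$path_stage[1] <- "ECE"
  folds <- assign_folds(co, 5, seed = 2)
  expect_error(cross_validated_predictions(co, model_spec("LOGISTIC"), folds),
               "single outcome class")
})

test_that("univariate clinical-stage predictions collapse to a narrow band", {
  co <- sample_cohort(default_params(n = 1000, seed = 18))
  folds <- assign_folds(co, 5, seed = 8)
  pr <- univariate_predictions(co, "clinical_stage", folds)
  # at most 3 distinct values per fold's model
  for (f in unique(pr$fold))
    expect_lte(length(unique(pr$prob[pr$fold == f])), 3)
  # stage alone carries almost no signal: probabilities hug the prevalence
  expect_true(all(pr$prob > 0.15 & pr$prob < 0.45))
  expect_lt(diff(range(pr$prob)), 0.2)

  pr_psa <- univariate_predictions(planted_cohort(500, 61), "psa",
                                   assign_folds(planted_cohort(500, 61), 5, 9))
  expect_gt(auc(pr_psa), 0.6)
})

test_that("prediction sets round-trip through CSV", {
  co <- planted_cohort(n = 120, seed = 71)
  pr <- cross_validated_predictions(co, model_spec("LOGISTIC"),
                                    assign_folds(co, 4, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_predictions(pr, f)
  back <- read_predictions(f)
  expect_equal(back$prob, pr$prob, tolerance = 1e-12)
  expect_identical(back$id, pr$id)
  expect_identical(back$label, pr$label)
})
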