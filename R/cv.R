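#' Model families available for staging prediction
#' @export
MODEL_FAMILIES <- c("LOGISTIC", "RANDOM_FOREST", "KNN", "UNIVARIATE")

#' Specify a staging classifier
#'
#' The three full models (logistic regression, random forests, k nearest
#' neighbours) use all three routine clinical predictors — PSA, clinical
#' stage and biopsy Gleason score. A `UNIVARIATE` spec is a single-covariate
#' logistic fit, used to evaluate each clinical variable in isolation.
#'
#' @param family one of [MODEL_FAMILIES].
#' @param predictors subset of `c("psa", "clinical_stage", "biopsy_gs")`;
#'   defaults to all three (exactly one required for `UNIVARIATE`).
#' @param ntree random-forest tree count (default 500).
#' @param knn_k neighbour count for kNN (default 25); the predicted
#'   probability is the fraction of NOC neighbours, distances computed on
#'   standardized features.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("LOGISTIC", "RANDOM_FOREST", "KNN",
                                  "UNIVARIATE"),
                       predictors = c("psa", "clinical_stage", "biopsy_gs"),
                       ntree = 500L, knn_k = 25L) {
  family <- match.arg(family)
  allowed <- c("psa", "clinical_stage", "biopsy_gs")
  if (!length(predictors) || !all(predictors %in% allowed))
    stop("predictors must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if (family == "UNIVARIATE" && length(predictors) != 1)
    stop("a UNIVARIATE spec uses exactly one predictor", call. = FALSE)
  structure(list(family = family, predictors = predictors,
                 ntree = as.integer(ntree), knn_k = as.integer(knn_k)),
            class = "model_spec")
}

model_label <- function(spec) {
  if (spec$family == "UNIVARIATE") spec$predictors else spec$family
}

#' Assign patients to cross-validation folds
#'
#' Uniform random partition into `k` folds whose sizes differ by at most one,
#' reproducible from `seed`.
#'
#' @param cohort cohort `data.frame`.
#' @param k fold count (default 5).
#' @param seed integer seed.
#' @return An object of class `fold_assignment`: data.frame with columns
#'   `id`, `fold`, and attributes `k` and `seed`.
#' @export
assign_folds <- function(cohort, k = 5L, seed = 1L) {
  n <- nrow(cohort)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("cohort size must be at least k", call. = FALSE)
  fold <- with_seed(derived_seed(seed, "folds"),
                    sample(rep_len(seq_len(k), n)))
  structure(data.frame(id = cohort$id, fold = fold,
                       stringsAsFactors = FALSE),
            k = as.integer(k), seed = as.integer(seed),
            class = c("fold_assignment", "data.frame"))
}

#' Encode patient covariates as a numeric feature matrix
#'
#' PSA enters as a single continuous value. Clinical stage is
#' reference-coded with T1c as reference ("NOT_REPORTED" is a level of its
#' own, not missingness), giving indicators `clinical_stageT2a` and
#' `clinical_stageNOT_REPORTED`. Biopsy Gleason score is reference-coded on
#' its six ordered categories with "<=5" as reference, giving five
#' indicators in the category order. Column order is fixed: psa, then
#' clinical stage indicators, then Gleason indicators.
#'
#' @param cohort cohort `data.frame` (one or more rows).
#' @param predictors which predictors to encode, in any subset of
#'   `c("psa", "clinical_stage", "biopsy_gs")`.
#' @return A numeric matrix with one row per patient.
#' @export
encode_features <- function(cohort,
                            predictors = c("psa", "clinical_stage",
                                           "biopsy_gs")) {
  stopifnot(all(predictors %in% c("psa", "clinical_stage", "biopsy_gs")))
  blocks <- list()
  if ("psa" %in% predictors)
    blocks$psa <- matrix(cohort$psa, ncol = 1,
                         dimnames = list(NULL, "psa"))
  if ("clinical_stage" %in% predictors) {
    lev <- CLINICAL_STAGE_LEVELS[-1]
    m <- sapply(lev, function(l) as.numeric(cohort$clinical_stage == l))
    m <- matrix(m, ncol = length(lev),
                dimnames = list(NULL, paste0("clinical_stage", lev)))
    blocks$clinical_stage <- m
  }
  if ("biopsy_gs" %in% predictors) {
    lev <- GS_LEVELS[-1]
    m <- sapply(lev, function(l) as.numeric(cohort$biopsy_gs == l))
    m <- matrix(m, ncol = length(lev),
                dimnames = list(NULL, paste0("biopsy_gs", lev)))
    blocks$biopsy_gs <- m
  }
  do.call(cbind, blocks[intersect(c("psa", "clinical_stage", "biopsy_gs"),
                                  predictors)])
}

#' Pooled out-of-fold predictions under k-fold cross-validation
#'
#' For each fold, the model is trained on all patients outside it and emits
#' NOC probabilities for the held-out patients; predictions are pooled over
#' folds so every patient receives exactly one probability from a model that
#' never saw them in training. Model-internal randomness (forest bootstrap,
#' kNN distance tie-breaking) is seeded deterministically from
#' `derived_seed(folds seed, "model:<family>:fold<f>")`.
#'
#' @param cohort cohort `data.frame`.
#' @param spec a [model_spec()].
#' @param folds a [assign_folds()] result covering the cohort.
#' @return An object of class `prediction_set`: data.frame with columns
#'   `id`, `prob`, `label` (1 = NOC), `fold`, `model`.
#' @export
cross_validated_predictions <- function(cohort, spec, folds) {
  stopifnot(inherits(spec, "model_spec"), inherits(folds, "fold_assignment"))
  if (!setequal(folds$id, cohort$id))
    stop("fold assignment does not cover the cohort", call. = FALSE)
  fold <- folds$fold[match(cohort$id, folds$id)]
  y <- as.integer(cohort$noc)
  X <- encode_features(cohort, spec$predictors)
  seed0 <- attr(folds, "seed")

  out <- vector("list", attr(folds, "k"))
  for (f in sort(unique(fold))) {
    test <- fold == f
    y_tr <- y[!test]
    if (length(unique(y_tr)) < 2)
      stop(sprintf("training data for fold %d contains a single outcome %s",
                   f, "class; cannot fit a classifier"), call. = FALSE)
    seed_f <- derived_seed(seed0, sprintf("model:%s:fold%d", spec$family, f))
    prob <- with_seed(seed_f,
      fit_and_predict(spec, X[!test, , drop = FALSE], y_tr,
                      X[test, , drop = FALSE]))
    out[[f]] <- data.frame(id = cohort$id[test], prob = prob,
                           label = y[test], fold = f,
                           model = model_label(spec),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[match(cohort$id, res$id), ]
  rownames(res) <- NULL
  structure(res, class = c("prediction_set", "data.frame"))
}

fit_and_predict <- function(spec, X_tr, y_tr, X_te) {
  fam <- if (spec$family == "UNIVARIATE") "LOGISTIC" else spec$family
  if (fam == "LOGISTIC") {
    d_tr <- as.data.frame(X_tr); d_te <- as.data.frame(X_te)
    d_tr$.y <- y_tr
    fit <- suppressWarnings(stats::glm(.y ~ ., data = d_tr,
                                       family = stats::binomial()))
    p <- suppressWarnings(stats::predict(fit, newdata = d_te,
                                         type = "response"))
    as.numeric(p)
  } else if (fam == "RANDOM_FOREST") {
    fit <- randomForest::randomForest(x = X_tr, y = factor(y_tr, c(0, 1)),
                                      ntree = spec$ntree)
    as.numeric(stats::predict(fit, X_te, type = "prob")[, "1"])
  } else if (fam == "KNN") {
    # standardize on training statistics; constant columns left unscaled
    mu <- colMeans(X_tr)
    sd <- apply(X_tr, 2, stats::sd)
    sd[sd == 0] <- 1
    Z_tr <- scale(X_tr, mu, sd); Z_te <- scale(X_te, mu, sd)
    k <- min(spec$knn_k, nrow(Z_tr))
    pred <- class::knn(Z_tr, Z_te, cl = factor(y_tr, c(0, 1)), k = k,
                       prob = TRUE)
    win <- attr(pred, "prob")
    ifelse(pred == "1", win, 1 - win)
  } else stop("unknown model family: ", fam, call. = FALSE)
}

#' Out-of-fold predictions from a single clinical variable
#'
#' Convenience wrapper: a univariate logistic model on one predictor under
#' the same fold assignment as the full models.
#'
#' @param cohort cohort `data.frame`.
#' @param predictor one of `"psa"`, `"clinical_stage"`, `"biopsy_gs"`.
#' @param folds a [assign_folds()] result.
#' @return A `prediction_set` whose `model` column names the predictor.
#' @export
univariate_predictions <- function(cohort, predictor, folds) {
  cross_validated_predictions(
    cohort, model_spec("UNIVARIATE", predictors = predictor), folds)
}

#' Write / read a prediction set as CSV
#' @param preds a `prediction_set`.
#' @param path CSV path.
#' @return `path` (write) or the `prediction_set` (read).
#' @export
write_predictions <- function(preds, path) {
  utils::write.csv(as.data.frame(preds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "prob", "label", "fold", "model") %in% names(d)))
  if (any(d$prob < 0 | d$prob > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(d, class = c("prediction_set", "data.frame"))
}
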