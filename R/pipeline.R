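#' Default pipeline configuration
#'
#' Returns the full study configuration as a nested list: a `generator`
#' section (either generator parameters or a `cohort_path`), a `models`
#' section (families and hyperparameters), an `evaluation` section
#' (threshold rule, Loess settings, calibration bin count, decision-curve
#' grid), an optional `partin` section (`table_path`, outcome,
#' label scheme), an output directory and a master seed. One master seed
#' fans out via [derived_seed()] to the generator, the fold assignment and
#' each model's internal randomness.
#'
#' @param out_dir output directory.
#' @param n cohort size when generating.
#' @param seed master seed.
#' @return A named list accepted by [run_pipeline()].
#' @export
default_config <- function(out_dir = "stageval_run", n = 603L,
                           seed = 20260101L) {
  list(
    generator = list(params = default_params(n = n, seed = seed),
                     cohort_path = NULL),
    models = list(families = c("LOGISTIC", "RANDOM_FOREST", "KNN"),
                  univariate = c("psa", "clinical_stage", "biopsy_gs"),
                  ntree = 500L, knn_k = 25L, k_folds = 5L),
    evaluation = list(threshold_rule = "youden", fixed_threshold = 0.5,
                      loess_span = 0.75, loess_degree = 2,
                      calibration_bins = 10L,
                      pt_grid = default_pt_grid()),
    partin = list(table_path = NULL, outcome = "ECE",
                  label_scheme = "outcome"),
    out_dir = out_dir,
    plots = FALSE,
    seed = as.integer(seed)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat-key YAML mirroring [default_config()]; unspecified keys keep their
#' defaults. The `generator` section may give either a `params` mapping
#' (overriding individual generator parameters) or a `cohort_path`.
#'
#' @param path YAML file.
#' @return A config list for [run_pipeline()].
#' @export
read_config <- function(path) {
  # keep y/n-like scalars literal: "n" is a parameter name, not a boolean
  y <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (x %in% c("true", "True", "TRUE")) TRUE else x,
    "bool#no" = function(x) if (x %in% c("false", "False", "FALSE")) FALSE else x))
  cfg <- default_config(out_dir = y$out_dir %||% "stageval_run",
                        n = y$generator$params$n %||% 603L,
                        seed = y$seed %||% 20260101L)
  if (!is.null(y$generator$cohort_path)) {
    cfg$generator$cohort_path <- y$generator$cohort_path
    cfg$generator$params <- NULL
  } else if (!is.null(y$generator$params)) {
    for (k in names(y$generator$params))
      cfg$generator$params[[k]] <- y$generator$params[[k]]
  }
  for (sec in c("models", "evaluation", "partin"))
    for (k in names(y[[sec]])) cfg[[sec]][[k]] <- y[[sec]][[k]]
  if (!is.null(y$plots)) cfg$plots <- isTRUE(y$plots)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full staging-model evaluation study
#'
#' Orchestrates every stage: generate (or load) the cohort, write its CSV,
#' produce the descriptive summary and Gleason transition tables, fit the
#' configured models under k-fold cross-validation, and write the
#' discrimination report, calibration curves and bins, decision curves, the
#' optional Partin-table evaluation, and a machine-readable manifest with a
#' content hash of every output. A second run with the same configuration
#' reproduces every numeric output byte-for-byte.
#'
#' @param config a [default_config()]-style list (or a YAML path, read via
#'   [read_config()]).
#' @return The manifest, invisibly: list of stages with output paths and
#'   MD5 hashes.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  has_params <- !is.null(config$generator$params)
  has_path <- !is.null(config$generator$cohort_path)
  if (has_params == has_path)
    stop("exactly one of generator$params / generator$cohort_path required",
         call. = FALSE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config_echo(config), seed = config$seed,
                   r_version = as.character(getRversion()),
                   outputs = list(), stages = list())
  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    message(sprintf("[stageval] %-14s %6.2fs", name,
                    manifest$stages[[name]]$seconds))
    res
  }

  cohort <- stage("cohort", {
    cohort <- if (has_params) sample_cohort(config$generator$params)
    else read_cohort(config$generator$cohort_path)
    if (has_params) write_cohort(cohort, file.path(out, "cohort.csv"))
    cohort
  })

  stage("descriptives", {
    write_summary(summarize_cohort(cohort), out)
    write_transition(gleason_transition(cohort),
                     file.path(out, "table2_transition.csv"))
  })

  preds_list <- stage("cv_models", {
    folds <- assign_folds(cohort, k = config$models$k_folds,
                          seed = derived_seed(config$seed, "folds"))
    specs <- c(
      lapply(config$models$families, function(fam)
        model_spec(fam, ntree = config$models$ntree,
                   knn_k = config$models$knn_k)),
      lapply(config$models$univariate, function(v)
        model_spec("UNIVARIATE", predictors = v)))
    preds_list <- lapply(specs, function(sp)
      cross_validated_predictions(cohort, sp, folds))
    names(preds_list) <- vapply(preds_list, function(p) p$model[1],
                                character(1))
    for (nm in names(preds_list))
      write_predictions(preds_list[[nm]],
                        file.path(out, sprintf("predictions_%s.csv", nm)))
    preds_list
  })

  stage("discrimination", {
    rep <- do.call(rbind, lapply(preds_list, function(p)
      discrimination_report(p, config$evaluation$threshold_rule,
                            config$evaluation$fixed_threshold)))
    utils::write.csv(rep, file.path(out, "discrimination.csv"),
                     row.names = FALSE)
  })

  stage("calibration", {
    for (nm in names(preds_list)) {
      curve <- withCallingHandlers(
        loess_calibration(preds_list[[nm]],
                          span = config$evaluation$loess_span,
                          degree = config$evaluation$loess_degree),
        warning = function(w) {
          message(sprintf("[stageval] calibration (%s): %s", nm,
                          conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      if (!is.null(curve))
        utils::write.csv(as.data.frame(curve),
                         file.path(out, sprintf("calibration_curve_%s.csv", nm)),
                         row.names = FALSE)
      bins <- suppressMessages(
        binned_calibration(preds_list[[nm]],
                           n_bins = config$evaluation$calibration_bins))
      utils::write.csv(bins,
                       file.path(out, sprintf("calibration_bins_%s.csv", nm)),
                       row.names = FALSE)
      if (isTRUE(config$plots)) {
        grDevices::png(file.path(out, sprintf("calibration_%s.png", nm)),
                       width = 600, height = 600)
        plot_calibration(curve, bins, main = nm)
        grDevices::dev.off()
      }
    }
  })

  stage("decision_curves", {
    curves <- lapply(preds_list, decision_curve,
                     grid = config$evaluation$pt_grid)
    utils::write.csv(decision_curves_long(curves),
                     file.path(out, "decision_curves.csv"), row.names = FALSE)
    if (isTRUE(config$plots)) {
      grDevices::png(file.path(out, "decision_curves.png"),
                     width = 700, height = 600)
      plot_decision_curves(curves)
      grDevices::dev.off()
    }
  })

  if (!is.null(config$partin$table_path)) {
    stage("partin", {
      tab <- load_partin_table(config$partin$table_path)
      rows <- list()
      for (st in intersect(unique(tab$clinical_stage),
                           as.character(unique(cohort$clinical_stage)))) {
        pp <- partin_predict(cohort[cohort$clinical_stage == st, ], tab,
                             outcome = config$partin$outcome,
                             label_scheme = config$partin$label_scheme)
        write_predictions(pp, file.path(out,
                                        sprintf("partin_predictions_%s.csv", st)))
        if (length(unique(pp$label)) == 2)
          rows[[st]] <- data.frame(clinical_stage = st, n = nrow(pp),
                                   auc = auc(pp))
      }
      if (length(rows))
        utils::write.csv(do.call(rbind, rows),
                         file.path(out, "partin_auc.csv"), row.names = FALSE)
    })
  } else {
    manifest$stages$partin <- list(status = "skipped",
                                   reason = "no Partin table configured")
  }

  files <- sort(list.files(out, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest$outputs <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

# config copy safe for JSON echo (drops non-scalar classes cleanly)
config_echo <- function(config) {
  cfg <- config
  if (!is.null(cfg$generator$params))
    cfg$generator$params <- lapply(unclass(cfg$generator$params), function(x)
      if (is.matrix(x)) as.data.frame(x) else x)
  cfg
}
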