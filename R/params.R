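#' Category levels used throughout the package
#'
#' Fixed level sets for the clinical covariates: clinical stage from digital
#' rectal exam (with "NOT_REPORTED" as a legitimate sampled level, not
#' missingness), the six-category biopsy/prostatectomy Gleason score scale,
#' family history, and pathological stage at radical prostatectomy.
#'
#' @format Character vectors of level labels.
#' @name stage_levels
NULL

#' @rdname stage_levels
#' @export
CLINICAL_STAGE_LEVELS <- c("T1c", "T2a", "NOT_REPORTED")

#' @rdname stage_levels
#' @export
GS_LEVELS <- c("<=5", "6", "3+4", "4+3", "8", "9")

#' @rdname stage_levels
#' @export
FAMILY_HISTORY_LEVELS <- c("NONE", "CANCER", "PCA")

#' @rdname stage_levels
#' @export
PATH_STAGE_LEVELS <- c("OC", "ECE", "SVI", "LNI")

#' Default generator parameters for a synthetic prostatectomy cohort
#'
#' Returns the parameter set whose implied population moments match a large
#' European radical-prostatectomy series: 30% non-organ-confined (NOC)
#' prevalence split 63/27/10 over ECE/SVI/LNI; stage-conditional log-normal
#' PSA with means 7.6 (OC) and 8.6 (NOC) ng/ml and medians 6.7 and 7.5
#' (log-scale parameters are solved from the mean/median pairs, so
#' `meanlog = log(median)` and `sdlog = sqrt(2 log(mean/median))`); ages
#' truncated-normal with means 60.7 / 62.2 years; clinical stage frequencies
#' 44.3 / 23.9 / 31.8% for T1c / T2a / not reported; stage-conditional biopsy
#' Gleason distributions; and a per-category biopsy-to-prostatectomy Gleason
#' transition whose marginal (decrease, no change, increase) triple is about
#' (0.13, 0.53, 0.34).
#'
#' @param n cohort size (default 603).
#' @param seed master seed; every random draw in [sample_cohort()] derives
#'   from it.
#' @return An object of class `generator_params`: a named list, see fields in
#'   the source. Validate with [validate_params()].
#' @examples
#' p <- default_params(n = 100, seed = 1)
#' p$noc_prevalence
#' @export
default_params <- function(n = 603L, seed = 20260101L) {
  # log-normal parameters solved from (mean, median): sdlog^2 = 2 log(m/med)
  lnorm_from <- function(mean, median) {
    list(meanlog = log(median), sdlog = sqrt(2 * log(mean / median)))
  }
  oc <- lnorm_from(7.6, 6.7)
  noc <- lnorm_from(8.6, 7.5)
  p <- list(
    n = as.integer(n),
    noc_prevalence = 0.30,
    noc_split = c(ECE = 0.63, SVI = 0.27, LNI = 0.10),
    psa_logmean_oc = oc$meanlog, psa_logsd_oc = oc$sdlog,
    psa_logmean_noc = noc$meanlog, psa_logsd_noc = noc$sdlog,
    psa_clip = c(0.7, 40),
    age_mean_oc = 60.7, age_mean_noc = 62.2, age_sd = 7.5,
    age_range = c(40L, 80L),
    # stage-conditional biopsy GS probabilities over the six categories,
    # renormalised printed percentages
    biopsy_gs_probs_oc = stats::setNames(
      c(19.7, 41.7, 26.3, 5.7, 4.6, 2.0) / 100, GS_LEVELS),
    biopsy_gs_probs_noc = stats::setNames(
      c(11.8, 26.1, 31.1, 14.9, 9.9, 6.2) / 100, GS_LEVELS),
    clinical_stage_probs = stats::setNames(
      c(0.443, 0.239, 0.318), CLINICAL_STAGE_LEVELS),
    family_history_probs = stats::setNames(
      c(0.549, 0.201, 0.250), FAMILY_HISTORY_LEVELS),
    # per-biopsy-GS (decrease, no change, increase) at prostatectomy;
    # the two lowest categories form one reporting group, so a decrease
    # within it is unobservable and carries probability zero
    gs_transition = matrix(
      c(0.000, 0.565, 0.435,
        0.000, 0.565, 0.435,
        0.151, 0.601, 0.248,
        0.326, 0.348, 0.326,
        0.735, 0.147, 0.118,
        0.500, 0.500, 0.000),
      nrow = 6, byrow = TRUE,
      dimnames = list(GS_LEVELS, c("decrease", "no_change", "increase"))),
    seed = as.integer(seed)
  )
  # renormalise to machine precision so probability invariants hold exactly
  p$noc_split <- p$noc_split / sum(p$noc_split)
  p$biopsy_gs_probs_oc <- p$biopsy_gs_probs_oc / sum(p$biopsy_gs_probs_oc)
  p$biopsy_gs_probs_noc <- p$biopsy_gs_probs_noc / sum(p$biopsy_gs_probs_noc)
  p$clinical_stage_probs <- p$clinical_stage_probs / sum(p$clinical_stage_probs)
  p$family_history_probs <- p$family_history_probs / sum(p$family_history_probs)
  structure(p, class = "generator_params")
}

#' Validate a generator parameter set
#'
#' Checks the probability-vector, prevalence and clipping invariants and
#' stops with an informative message on the first violation.
#'
#' @param params a `generator_params` object or compatible named list.
#' @param tol tolerance for probability-vector sums (default 1e-9).
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params, tol = 1e-9) {
  stopifnot(is.list(params))
  chk_prob <- function(x, what) {
    if (any(x < 0) || abs(sum(x) - 1) > tol)
      stop(sprintf("%s must be non-negative and sum to 1 (got sum %.12f)",
                   what, sum(x)), call. = FALSE)
  }
  if (!is.numeric(params$n) || params$n < 0)
    stop("n must be a non-negative integer", call. = FALSE)
  if (params$noc_prevalence <= 0 || params$noc_prevalence >= 1)
    stop("noc_prevalence must lie in (0, 1)", call. = FALSE)
  chk_prob(params$noc_split, "noc_split")
  chk_prob(params$biopsy_gs_probs_oc, "biopsy_gs_probs_oc")
  chk_prob(params$biopsy_gs_probs_noc, "biopsy_gs_probs_noc")
  chk_prob(params$clinical_stage_probs, "clinical_stage_probs")
  chk_prob(params$family_history_probs, "family_history_probs")
  for (i in seq_len(nrow(params$gs_transition)))
    chk_prob(params$gs_transition[i, ],
             sprintf("gs_transition row '%s'", rownames(params$gs_transition)[i]))
  if (params$psa_clip[1] >= params$psa_clip[2])
    stop("psa_clip must satisfy min < max", call. = FALSE)
  if (params$psa_clip[1] <= 0)
    stop("psa_clip minimum must be positive", call. = FALSE)
  invisible(params)
}

#' Derive a stream-specific seed from a master seed
#'
#' Deterministic fan-out of one master seed to named random streams
#' (generator, fold assignment, per-fold model randomness). Uses a small
#' polynomial string hash folded with the master seed modulo 2^31 - 1, so the
#' result is always a valid 32-bit R seed.
#'
#' @param master integer master seed.
#' @param stream character tag naming the consumer, e.g. "folds" or
#'   "model:RANDOM_FOREST:fold3".
#' @return A single integer seed.
#' @export
derived_seed <- function(master, stream) {
  m <- 2147483647
  h <- as.double(master %% m)
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

# evaluate `code` under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
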