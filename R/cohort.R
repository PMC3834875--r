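#' Sample a synthetic radical-prostatectomy cohort
#'
#' Draws `params$n` patient records. Pathological stage is drawn first
#' (Bernoulli NOC at `noc_prevalence`, then the ECE/SVI/LNI split within
#' NOC); PSA, age and biopsy Gleason score are then drawn from their
#' stage-conditional distributions, clinical stage and family history from
#' stage-independent frequencies, and the prostatectomy Gleason score from
#' the biopsy score through the per-category transition triple. A decrease
#' or increase moves the score exactly one *reporting group* down or up on
#' the [GS_GROUPS] scale (clamped at the boundary groups), so grouped
#' tabulation recovers the configured triples; an unchanged score keeps the
#' exact biopsy category. PSA is clamped to `psa_clip`; ages are truncated-normal on
#' `age_range` and rounded to whole years.
#'
#' Fully reproducible: all randomness derives from `params$seed` and the
#' caller's RNG state is left untouched.
#'
#' @param params a [default_params()]-style `generator_params` object;
#'   validated before any sampling.
#' @return A `data.frame` with one row per patient and columns `id`, `age`,
#'   `psa`, `clinical_stage`, `biopsy_gs`, `prostatectomy_gs`,
#'   `family_history`, `path_stage` (all categories as factors with the
#'   package level sets) plus the derived logical column `noc`
#'   (`path_stage != "OC"`).
#' @examples
#' cohort <- sample_cohort(default_params(n = 50, seed = 7))
#' table(cohort$path_stage)
#' @export
sample_cohort <- function(params) {
  validate_params(params)
  n <- as.integer(params$n)
  empty <- data.frame(
    id = character(), age = integer(), psa = numeric(),
    clinical_stage = factor(character(), CLINICAL_STAGE_LEVELS),
    biopsy_gs = factor(character(), GS_LEVELS),
    prostatectomy_gs = factor(character(), GS_LEVELS),
    family_history = factor(character(), FAMILY_HISTORY_LEVELS),
    path_stage = factor(character(), PATH_STAGE_LEVELS),
    noc = logical(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  with_seed(derived_seed(params$seed, "cohort"), {
    noc <- stats::runif(n) < params$noc_prevalence
    path_stage <- rep("OC", n)
    n_noc <- sum(noc)
    if (n_noc > 0)
      path_stage[noc] <- sample(names(params$noc_split), n_noc,
                                replace = TRUE, prob = params$noc_split)

    psa <- numeric(n)
    psa[!noc] <- stats::rlnorm(n - n_noc, params$psa_logmean_oc,
                               params$psa_logsd_oc)
    psa[noc] <- stats::rlnorm(n_noc, params$psa_logmean_noc,
                              params$psa_logsd_noc)
    psa <- pmin(pmax(psa, params$psa_clip[1]), params$psa_clip[2])

    age_mean <- ifelse(noc, params$age_mean_noc, params$age_mean_oc)
    age <- as.integer(round(rtruncnorm(n, age_mean, params$age_sd,
                                       params$age_range[1],
                                       params$age_range[2])))

    biopsy_gs <- character(n)
    biopsy_gs[!noc] <- sample(GS_LEVELS, n - n_noc, replace = TRUE,
                              prob = params$biopsy_gs_probs_oc)
    biopsy_gs[noc] <- sample(GS_LEVELS, n_noc, replace = TRUE,
                             prob = params$biopsy_gs_probs_noc)

    clinical_stage <- sample(CLINICAL_STAGE_LEVELS, n, replace = TRUE,
                             prob = params$clinical_stage_probs)
    family_history <- sample(FAMILY_HISTORY_LEVELS, n, replace = TRUE,
                             prob = params$family_history_probs)

    # transitions act on the five reporting groups: a decrease/increase is an
    # observable move of one group, so grouped tabulation recovers the
    # configured triples exactly
    bidx <- match(biopsy_gs, GS_LEVELS)
    move <- integer(n)
    for (g in seq_along(GS_LEVELS)) {
      sel <- bidx == g
      if (!any(sel)) next
      move[sel] <- sample(c(-1L, 0L, 1L), sum(sel), replace = TRUE,
                          prob = params$gs_transition[g, ])
    }
    gidx <- as.integer(map_gs_group(biopsy_gs))
    new_group <- pmin(pmax(gidx + move, 1L), length(GS_GROUPS))
    # representative six-level category of each group for moved patients;
    # unmoved patients keep their exact biopsy category
    group_rep <- c("6", "3+4", "4+3", "8", "9")
    prost_gs <- ifelse(move == 0L, biopsy_gs, group_rep[new_group])

    data.frame(
      id = sprintf("P%05d", seq_len(n)),
      age = age,
      psa = psa,
      clinical_stage = factor(clinical_stage, CLINICAL_STAGE_LEVELS),
      biopsy_gs = factor(biopsy_gs, GS_LEVELS),
      prostatectomy_gs = factor(prost_gs, GS_LEVELS),
      family_history = factor(family_history, FAMILY_HISTORY_LEVELS),
      path_stage = factor(path_stage, PATH_STAGE_LEVELS),
      noc = path_stage != "OC",
      stringsAsFactors = FALSE)
  })
}

# truncated normal via inverse-CDF; exact, no rejection loop
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Write a cohort to CSV
#'
#' One header row; columns `id, age, psa, clinical_stage, biopsy_gs,
#' prostatectomy_gs, family_history, path_stage`; category labels exactly as
#' in the package level sets; UTF-8, comma-separated. The derived `noc`
#' column is not written (it is recomputed on read).
#'
#' @param cohort a cohort `data.frame` as returned by [sample_cohort()].
#' @param destination path to write.
#' @return `destination`, invisibly.
#' @export
write_cohort <- function(cohort, destination) {
  cols <- c("id", "age", "psa", "clinical_stage", "biopsy_gs",
            "prostatectomy_gs", "family_history", "path_stage")
  stopifnot(all(cols %in% names(cohort)))
  utils::write.csv(cohort[, cols], destination, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(destination)
}

#' Read a cohort from CSV
#'
#' Parses the dialect written by [write_cohort()] and enforces the record
#' invariants: positive PSA, ages within `age_range`, and category labels
#' drawn from the package level sets. Violations are rejected with a message
#' naming the offending row and column.
#'
#' @param source CSV path.
#' @param age_range plausible age bounds (default 40-80 years).
#' @return A cohort `data.frame` with the derived `noc` column, suitable for
#'   every downstream operation.
#' @export
read_cohort <- function(source, age_range = c(40L, 80L)) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  cols <- c("id", "age", "psa", "clinical_stage", "biopsy_gs",
            "prostatectomy_gs", "family_history", "path_stage")
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols))
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  fail <- function(col, rows, why)
    stop(sprintf("invalid cohort CSV: column '%s', row(s) %s: %s",
                 col, paste(utils::head(rows, 5), collapse = ", "), why),
         call. = FALSE)
  chk_levels <- function(col, levels) {
    bad <- which(!(raw[[col]] %in% levels))
    if (length(bad))
      fail(col, bad, sprintf("unrecognized label '%s' (allowed: %s)",
                             raw[[col]][bad[1]], paste(levels, collapse = ", ")))
  }
  bad_psa <- which(!is.finite(raw$psa) | raw$psa <= 0)
  if (length(bad_psa)) fail("psa", bad_psa, "PSA must be a positive number")
  bad_age <- which(!is.finite(raw$age) | raw$age < age_range[1] |
                     raw$age > age_range[2])
  if (length(bad_age))
    fail("age", bad_age, sprintf("age must lie in [%d, %d]",
                                 age_range[1], age_range[2]))
  chk_levels("clinical_stage", CLINICAL_STAGE_LEVELS)
  chk_levels("biopsy_gs", GS_LEVELS)
  chk_levels("prostatectomy_gs", GS_LEVELS)
  chk_levels("family_history", FAMILY_HISTORY_LEVELS)
  chk_levels("path_stage", PATH_STAGE_LEVELS)
  if (anyDuplicated(raw$id))
    fail("id", which(duplicated(raw$id)), "duplicate patient id")

  data.frame(
    id = as.character(raw$id),
    age = as.integer(raw$age),
    psa = as.numeric(raw$psa),
    clinical_stage = factor(raw$clinical_stage, CLINICAL_STAGE_LEVELS),
    biopsy_gs = factor(raw$biopsy_gs, GS_LEVELS),
    prostatectomy_gs = factor(raw$prostatectomy_gs, GS_LEVELS),
    family_history = factor(raw$family_history, FAMILY_HISTORY_LEVELS),
    path_stage = factor(raw$path_stage, PATH_STAGE_LEVELS),
    noc = raw$path_stage != "OC",
    stringsAsFactors = FALSE)
}
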