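#' Load a Partin-style staging lookup table
#'
#' Reads the CSV layout `clinical_stage, psa_low, psa_high, gs_category,
#' p_oc, p_ece, p_svi, p_lni` (probabilities on the percent scale;
#' `psa_high` may be `Inf` for the open top band). PSA bands are half-open
#' intervals `(psa_low, psa_high]`; within every (clinical stage, Gleason
#' category) combination the bands must tile `(0, Inf)` without gaps or
#' overlaps. Cells whose four probabilities sum outside `100 +/- sum_tol`
#' (published tables round each entry) are flagged with a warning.
#'
#' The published 2007 probability values are not shipped with the package;
#' transcribe them into this layout to reproduce a real-table comparison.
#' A small synthetic toy table is included for tests and examples
#' (`system.file("extdata", "partin_toy_synthetic.csv", package =
#' "stageval")`).
#'
#' @param source CSV path.
#' @param sum_tol tolerance, in percentage points, for each cell's
#'   probability sum (default 3).
#' @return An object of class `partin_table`: the validated data.frame.
#' @export
load_partin_table <- function(source, sum_tol = 3) {
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("clinical_stage", "psa_low", "psa_high", "gs_category",
            "p_oc", "p_ece", "p_svi", "p_lni")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("Partin table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$psa_high <- as.numeric(tab$psa_high)  # "Inf" parses to Inf
  probs <- as.matrix(tab[, c("p_oc", "p_ece", "p_svi", "p_lni")])
  if (any(probs < 0 | probs > 100))
    stop("cell probabilities must lie in [0, 100] percent", call. = FALSE)
  off <- abs(rowSums(probs) - 100) > sum_tol
  if (any(off))
    warning(sprintf("%d Partin cell(s) have probabilities summing outside %s",
                    sum(off), sprintf("100 +/- %g", sum_tol)), call. = FALSE)
  # band tiling per (stage, GS) combination
  for (key in split(tab, interaction(tab$clinical_stage, tab$gs_category,
                                     drop = TRUE))) {
    key <- key[order(key$psa_low), ]
    lab <- sprintf("stage %s / GS %s", key$clinical_stage[1],
                   key$gs_category[1])
    if (key$psa_low[1] != 0)
      stop(sprintf("PSA bands for %s must start at 0", lab), call. = FALSE)
    if (!is.infinite(key$psa_high[nrow(key)]))
      stop(sprintf("top PSA band for %s must be open (psa_high = Inf)", lab),
           call. = FALSE)
    if (nrow(key) > 1 &&
        any(key$psa_high[-nrow(key)] != key$psa_low[-1]))
      stop(sprintf("PSA bands for %s have a gap or overlap", lab),
           call. = FALSE)
  }
  structure(tab, class = c("partin_table", "data.frame"))
}

#' Apply a Partin-style table to a cohort
#'
#' Each patient whose clinical stage is covered by the table receives the
#' probability of the requested pathological outcome from their
#' (clinical stage, PSA band, biopsy Gleason group) cell, divided by 100.
#' Patients whose stage the table does not cover (typically NOT_REPORTED)
#' are excluded; the exclusion count is attached as attribute
#' `n_excluded`. Lookup is a pure function of the cell, so patients in the
#' same cell always receive identical predictions.
#'
#' @param cohort cohort `data.frame`; biopsy Gleason scores are mapped to
#'   the five reporting groups ([GS_GROUPS]) before lookup, which must match
#'   the table's `gs_category` labels.
#' @param table a `partin_table`.
#' @param outcome which pathological stage to predict: `"OC"`, `"ECE"`,
#'   `"SVI"` or `"LNI"`.
#' @param label_scheme how evaluation labels are formed: `"outcome"`
#'   (default) labels outcome-vs-rest (e.g. ECE vs not-ECE); `"noc"` labels
#'   non-organ-confined vs organ-confined regardless of `outcome`.
#' @return A `prediction_set` restricted to covered patients, with the
#'   `model` column `"partin_<outcome>"` and attribute `n_excluded`.
#' @export
partin_predict <- function(cohort, table, outcome = c("ECE", "OC", "SVI",
                                                      "LNI"),
                           label_scheme = c("outcome", "noc")) {
  outcome <- match.arg(outcome)
  label_scheme <- match.arg(label_scheme)
  stopifnot(inherits(table, "partin_table"))
  covered <- as.character(cohort$clinical_stage) %in%
    unique(table$clinical_stage)
  n_excluded <- sum(!covered)
  sub <- cohort[covered, , drop = FALSE]
  pcol <- paste0("p_", tolower(outcome))
  gs_group <- as.character(map_gs_group(sub$biopsy_gs))
  prob <- vapply(seq_len(nrow(sub)), function(i) {
    hit <- table$clinical_stage == as.character(sub$clinical_stage[i]) &
      table$gs_category == gs_group[i] &
      table$psa_low < sub$psa[i] & sub$psa[i] <= table$psa_high
    if (sum(hit) != 1)
      stop(sprintf("no unique Partin cell for patient %s (stage %s, PSA %.2f, GS %s)",
                   sub$id[i], sub$clinical_stage[i], sub$psa[i], gs_group[i]),
           call. = FALSE)
    table[[pcol]][hit] / 100
  }, numeric(1))
  label <- if (label_scheme == "outcome")
    as.integer(as.character(sub$path_stage) == outcome)
  else as.integer(sub$noc)
  structure(data.frame(id = sub$id, prob = prob, label = label,
                       fold = rep(NA_integer_, nrow(sub)),
                       model = rep(paste0("partin_", outcome), nrow(sub)),
                       stringsAsFactors = FALSE),
            n_excluded = n_excluded,
            class = c("prediction_set", "data.frame"))
}
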