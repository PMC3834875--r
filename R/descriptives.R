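#' Summarize a cohort, split by organ-confined status
#'
#' Builds the standard cohort-characteristics table: for the continuous
#' variables (age, PSA) the mean, median, range and normal-approximation 95%
#' CI of the mean, overall and within the OC / NOC groups; for the
#' categorical variables counts and percentages by the same split; and a
#' group-comparison p-value per variable. Continuous comparisons use the
#' two-sample t-test when both groups pass a Shapiro-Wilk normality check at
#' `normality_alpha`, and the Mann-Whitney U test otherwise; categorical
#' comparisons use the chi-square test without continuity correction
#' (expected counts below 5 trigger a warning, not an exact test).
#'
#' @param cohort cohort `data.frame` (see [sample_cohort()]).
#' @param normality_alpha significance level of the per-group Shapiro-Wilk
#'   check that selects t-test vs Mann-Whitney (default 0.05).
#' @return An object of class `cohort_summary`: a list with data frames
#'   `continuous` (variable, group, n, mean, median, min, max, ci_lo, ci_hi),
#'   `categorical` (variable, level, group, count, pct) and `tests`
#'   (variable, test, p_value, note). Groups with fewer than 2 members get
#'   no test; the `note` column flags this.
#' @export
summarize_cohort <- function(cohort, normality_alpha = 0.05) {
  stopifnot(nrow(cohort) > 0)
  groups <- list(overall = rep(TRUE, nrow(cohort)),
                 OC = !cohort$noc, NOC = cohort$noc)

  cont_row <- function(variable, x, group) {
    n <- length(x)
    if (n == 0)
      return(data.frame(variable = variable, group = group, n = 0L,
                        mean = NA_real_, median = NA_real_, min = NA_real_,
                        max = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_))
    m <- mean(x)
    se <- if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
    data.frame(variable = variable, group = group, n = n, mean = m,
               median = stats::median(x), min = min(x), max = max(x),
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
  }
  continuous <- do.call(rbind, lapply(c("age", "psa"), function(v) {
    do.call(rbind, lapply(names(groups), function(g)
      cont_row(v, as.numeric(cohort[[v]][groups[[g]]]), g)))
  }))

  cat_vars <- c("family_history", "clinical_stage", "biopsy_gs",
                "prostatectomy_gs", "path_stage")
  categorical <- do.call(rbind, lapply(cat_vars, function(v) {
    do.call(rbind, lapply(names(groups), function(g) {
      x <- cohort[[v]][groups[[g]]]
      tab <- table(x)
      data.frame(variable = v, level = names(tab), group = g,
                 count = as.integer(tab),
                 pct = if (length(x)) 100 * as.integer(tab) / length(x)
                       else NA_real_)
    }))
  }))

  # group comparisons OC vs NOC
  n_oc <- sum(!cohort$noc); n_noc <- sum(cohort$noc)
  degenerate <- n_oc < 2 || n_noc < 2
  tests <- do.call(rbind, lapply(c("age", "psa", cat_vars), function(v) {
    if (v == "path_stage")  # defines the split, no comparison
      return(NULL)
    if (degenerate)
      return(data.frame(variable = v, test = NA_character_,
                        p_value = NA_real_,
                        note = "group with fewer than 2 members; no test"))
    if (v %in% c("age", "psa")) {
      x <- as.numeric(cohort[[v]][!cohort$noc])
      y <- as.numeric(cohort[[v]][cohort$noc])
      if (both_normal(x, y, normality_alpha)) {
        p <- stats::t.test(x, y)$p.value
        data.frame(variable = v, test = "t-test", p_value = p, note = "")
      } else {
        p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
        data.frame(variable = v, test = "Mann-Whitney U", p_value = p,
                   note = "")
      }
    } else {
      tab <- table(cohort[[v]], cohort$noc)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2)
        return(data.frame(variable = v, test = NA_character_,
                          p_value = NA_real_, note = "single level; no test"))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      note <- if (any(ct$expected < 5))
        "expected count < 5 in some cells" else ""
      data.frame(variable = v, test = "chi-square", p_value = ct$p.value,
                 note = note)
    }
  }))
  structure(list(continuous = continuous, categorical = categorical,
                 tests = tests), class = "cohort_summary")
}

# Shapiro-Wilk per group; the test caps n at 5000, so larger groups are
# checked on a seeded subsample
both_normal <- function(x, y, alpha) {
  shap <- function(z) {
    if (length(z) < 3 || stats::sd(z) == 0) return(FALSE)
    if (length(z) > 5000)
      z <- with_seed(909090L, sample(z, 5000))
    stats::shapiro.test(z)$p.value > alpha
  }
  shap(x) && shap(y)
}

#' Gleason score groups used for transition reporting
#'
#' The six sampling categories collapse to five reporting groups: the two
#' lowest merge into "<=6", and the top category is labelled "9-10".
#' @export
GS_GROUPS <- c("<=6", "3+4", "4+3", "8", "9-10")

#' Map six-category Gleason levels to the five reporting groups
#' @param gs factor or character vector on the [GS_LEVELS] scale.
#' @return Factor on the [GS_GROUPS] scale.
#' @export
map_gs_group <- function(gs) {
  map <- c("<=5" = "<=6", "6" = "<=6", "3+4" = "3+4", "4+3" = "4+3",
           "8" = "8", "9" = "9-10")
  factor(unname(map[as.character(gs)]), GS_GROUPS)
}

#' Build a Gleason transition table from per-group counts
#'
#' Constructor for the biopsy-vs-prostatectomy concordance layout: one column
#' per biopsy group, rows for the column total and the decrease / no change /
#' increase counts, plus overall totals and percentages (one decimal, half
#' away from zero). Used both by [gleason_transition()] and directly on
#' externally tabulated counts.
#'
#' @param decrease,no_change,increase integer count vectors, one entry per
#'   [GS_GROUPS] column.
#' @param n_excluded number of records excluded for a missing Gleason score.
#' @return An object of class `gleason_transition`: list with the count
#'   matrix `counts` (rows N, decrease, no_change, increase; columns the five
#'   groups plus Total), the percentage matrix `pct` (of each column's N),
#'   `overall` (named percentages decrease / no_change / increase of the
#'   grand total) and `n_excluded`.
#' @export
transition_table <- function(decrease, no_change, increase, n_excluded = 0L) {
  k <- length(GS_GROUPS)
  stopifnot(length(decrease) == k, length(no_change) == k,
            length(increase) == k)
  if (decrease[1] != 0)
    stop("lowest Gleason group cannot decrease", call. = FALSE)
  if (increase[k] != 0)
    stop("highest Gleason group cannot increase", call. = FALSE)
  counts <- rbind(N = decrease + no_change + increase,
                  decrease = decrease, no_change = no_change,
                  increase = increase)
  colnames(counts) <- GS_GROUPS
  counts <- cbind(counts, Total = rowSums(counts))
  pct <- sweep(counts[-1, , drop = FALSE], 2, counts["N", ], "/") * 100
  overall <- round_half_up(pct[, "Total"], 1)
  structure(list(counts = counts, pct = pct, overall = overall,
                 n_excluded = as.integer(n_excluded)),
            class = "gleason_transition")
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tabulate Gleason upgrading and downgrading in a cohort
#'
#' Compares each patient's biopsy Gleason score with the score assigned at
#' radical prostatectomy. Both scores are mapped to the five reporting groups
#' ([GS_GROUPS]); each record is classified by the sign of the group-index
#' difference (prostatectomy minus biopsy). Records missing either score are
#' excluded and counted.
#'
#' @param cohort cohort `data.frame`.
#' @return A `gleason_transition` object (see [transition_table()]).
#' @export
gleason_transition <- function(cohort) {
  b <- map_gs_group(cohort$biopsy_gs)
  p <- map_gs_group(cohort$prostatectomy_gs)
  keep <- !is.na(b) & !is.na(p)
  n_excluded <- sum(!keep)
  b <- b[keep]; p <- p[keep]
  d <- sign(as.integer(p) - as.integer(b))
  tab <- function(s) as.integer(table(factor(b[d == s], GS_GROUPS)))
  transition_table(decrease = tab(-1), no_change = tab(0),
                   increase = tab(1), n_excluded = n_excluded)
}

#' @export
print.gleason_transition <- function(x, ...) {
  cat("Gleason biopsy-vs-prostatectomy transition",
      sprintf("(n = %d, %d excluded)\n", x$counts["N", "Total"],
              x$n_excluded))
  print(x$counts)
  cat("Overall %: decrease", x$overall["decrease"],
      "| no change", x$overall["no_change"],
      "| increase", x$overall["increase"], "\n")
  invisible(x)
}

#' Write a cohort summary to CSV files
#' @param summary a `cohort_summary` object.
#' @param dir output directory; files `table1_continuous.csv`,
#'   `table1_categorical.csv`, `table1_tests.csv` are created.
#' @return Written paths, invisibly.
#' @export
write_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  paths <- file.path(dir, c("table1_continuous.csv", "table1_categorical.csv",
                            "table1_tests.csv"))
  utils::write.csv(summary$continuous, paths[1], row.names = FALSE)
  utils::write.csv(summary$categorical, paths[2], row.names = FALSE)
  utils::write.csv(summary$tests, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write a Gleason transition table to CSV
#' @param x a `gleason_transition` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition <- function(x, path) {
  stopifnot(inherits(x, "gleason_transition"))
  out <- as.data.frame(x$counts)
  out <- cbind(row = rownames(out), out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
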