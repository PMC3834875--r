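#' Net benefit of a classifier at a threshold probability
#'
#' The decision-analytic net benefit
#' \deqn{NB(P_t) = \frac{TP}{n} - \frac{FP}{n} \cdot \frac{P_t}{1 - P_t}}
#' where patients are classified positive iff their predicted probability is
#' at least the threshold probability Pt — the probability at which a
#' clinician would advise treatment, encoding the relative weight of false
#' positives against false negatives.
#'
#' @param preds a `prediction_set`.
#' @param pt threshold probability, strictly inside (0, 1).
#' @return Net benefit per patient (a single number).
#' @examples
#' # tp = 30, fp = 20 of n = 100 at pt = 0.2: 0.30 - 0.20 * 0.25 = 0.25
#' @export
net_benefit <- function(preds, pt) {
  if (pt <= 0 || pt >= 1)
    stop("pt must lie strictly inside (0, 1)", call. = FALSE)
  n <- nrow(preds)
  cc <- confusion_at_threshold(preds, pt)
  cc$tp / n - cc$fp / n * pt / (1 - pt)
}

#' Default threshold-probability grid for decision curves
#'
#' From 1% to 50% in 0.5% steps — the range over which a staging model is
#' plausibly decision-relevant.
#' @export
default_pt_grid <- function() seq(0.01, 0.50, by = 0.005)

#' Decision curve of a model with treat-all / treat-none references
#'
#' Net benefit of the model across the threshold grid, alongside the two
#' reference strategies: treat-all (classify every patient positive; its net
#' benefit declines with Pt and crosses zero exactly at the outcome
#' prevalence) and treat-none (identically zero). The model with the highest
#' net benefit at the clinically relevant Pt should be chosen.
#'
#' @param preds a `prediction_set`.
#' @param grid strictly increasing thresholds inside (0, 1)
#'   (default [default_pt_grid()]).
#' @return An object of class `decision_curve`: data.frame with columns
#'   `pt`, `nb_model`, `nb_all`, `nb_none`; attributes `model`, `n`,
#'   `prevalence`.
#' @export
decision_curve <- function(preds, grid = default_pt_grid()) {
  stopifnot(all(grid > 0), all(grid < 1), all(diff(grid) > 0))
  n <- nrow(preds)
  pos <- sum(preds$label == 1)
  prev <- pos / n
  nb_model <- vapply(grid, function(pt) net_benefit(preds, pt), numeric(1))
  nb_all <- prev - (1 - prev) * grid / (1 - grid)
  structure(data.frame(pt = grid, nb_model = nb_model, nb_all = nb_all,
                       nb_none = 0),
            model = unique(preds$model)[1], n = n, prevalence = prev,
            class = c("decision_curve", "data.frame"))
}

#' Best strategy at a threshold probability
#'
#' Compares the models' decision curves together with the treat-all and
#' treat-none reference strategies at one Pt, and names the strategy with
#' the highest net benefit. Ties break deterministically by the order the
#' curves were supplied, with `treat_all` and `treat_none` considered last.
#'
#' @param curves list of `decision_curve` objects sharing the same grid.
#' @param pt threshold probability; if off-grid, the nearest grid point is
#'   used and a message logged.
#' @return The winning model identifier (or `"treat_all"` / `"treat_none"`).
#' @export
best_model_at <- function(curves, pt) {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]$pt
  for (cv in curves)
    if (!isTRUE(all.equal(cv$pt, grid)))
      stop("all curves must share the same threshold grid", call. = FALSE)
  i <- which.min(abs(grid - pt))
  if (abs(grid[i] - pt) > 1e-9)
    message(sprintf("pt = %.4f is off-grid; using nearest grid point %.4f",
                    pt, grid[i]))
  names <- vapply(curves, function(cv) as.character(attr(cv, "model")),
                  character(1))
  nb <- c(vapply(curves, function(cv) cv$nb_model[i], numeric(1)),
          treat_all = curves[[1]]$nb_all[i], treat_none = 0)
  names(nb)[seq_along(curves)] <- names
  names(nb)[which.max(nb)]  # first maximum: supplied order wins ties
}

#' Bind decision curves into long form for export
#' @param curves list of `decision_curve` objects.
#' @return data.frame with columns `model`, `pt`, `net_benefit`, including
#'   `treat_all` and `treat_none` rows.
#' @export
decision_curves_long <- function(curves) {
  stopifnot(length(curves) >= 1)
  rows <- lapply(curves, function(cv)
    data.frame(model = as.character(attr(cv, "model")), pt = cv$pt,
               net_benefit = cv$nb_model, stringsAsFactors = FALSE))
  ref <- curves[[1]]
  rows <- c(rows, list(
    data.frame(model = "treat_all", pt = ref$pt, net_benefit = ref$nb_all,
               stringsAsFactors = FALSE),
    data.frame(model = "treat_none", pt = ref$pt, net_benefit = 0,
               stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Plot decision curves
#' @param curves list of `decision_curve` objects.
#' @param main plot title.
#' @return `NULL`, invisibly.
#' @export
plot_decision_curves <- function(curves, main = "Decision curve analysis") {
  ref <- curves[[1]]
  ylim <- range(0, ref$nb_all,
                vapply(curves, function(cv) range(cv$nb_model), numeric(2)))
  plot(ref$pt, ref$nb_all, type = "l", lty = 2, col = "grey40",
       ylim = ylim, xlab = "Threshold probability",
       ylab = "Net benefit", main = main)
  graphics::abline(h = 0, lty = 3, col = "grey60")
  cols <- seq_along(curves) + 1
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$pt, curves[[i]]$nb_model, col = cols[i],
                    lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c(vapply(curves, function(cv)
                     as.character(attr(cv, "model")), character(1)),
                     "treat all", "treat none"),
                   col = c(cols, "grey40", "grey60"),
                   lty = c(rep(1, length(curves)), 2, 3), lwd = 2)
  invisible(NULL)
}
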