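#' Loess-smoothed calibration curve
#'
#' Locally weighted polynomial regression (tricube weights) of the binary
#' outcome on the predicted probability, evaluated on an even grid spanning
#' the observed prediction range and clamped to \[0, 1\]. A perfectly
#' calibrated model tracks the 45-degree diagonal. Models whose predictions
#' collapse onto too few distinct values (e.g. a classifier driven by a
#' 3-level factor alone) cannot support a local fit: the curve is omitted
#' and a diagnostic warning raised.
#'
#' @param preds a `prediction_set`.
#' @param span Loess span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param min_distinct minimum number of distinct predicted values required
#'   (default 10).
#' @param grid_n number of evaluation points (default 101).
#' @return An object of class `calibration_curve` — data.frame with columns
#'   `pred` (grid) and `observed` (smoothed outcome frequency), attributes
#'   `span`, `degree`, `model` — or `NULL` with a warning when the
#'   prediction range is too degenerate to smooth.
#' @export
loess_calibration <- function(preds, span = 0.75, degree = 2,
                              min_distinct = 10, grid_n = 101) {
  distinct <- length(unique(preds$prob))
  if (distinct < min_distinct) {
    warning(sprintf(paste0("calibration curve omitted: only %d distinct ",
                           "predicted values (minimum %d); the prediction ",
                           "band is too narrow to smooth"),
                    distinct, min_distinct), call. = FALSE)
    return(NULL)
  }
  fit <- stats::loess(label ~ prob, data = preds, span = span,
                      degree = degree,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(preds$prob), max(preds$prob), length.out = grid_n)
  obs <- pmin(pmax(stats::predict(fit, newdata = data.frame(prob = grid)),
                   0), 1)
  structure(data.frame(pred = grid, observed = obs),
            span = span, degree = degree,
            model = unique(preds$model)[1],
            class = c("calibration_curve", "data.frame"))
}

#' Binned calibration with Wilson 95% intervals
#'
#' Quantile bins of the predicted probability; per bin, the mean prediction,
#' the observed outcome fraction and its Wilson score 95% confidence
#' interval. Bins emptied by ties in the quantiles are merged with their
#' neighbours (a message reports the final bin count).
#'
#' @param preds a `prediction_set`.
#' @param n_bins requested number of quantile bins (default 10).
#' @return A data.frame with one row per bin: `bin`, `lo`, `hi` (bin range),
#'   `n`, `mean_pred`, `obs_frac`, `ci_lo`, `ci_hi`.
#' @export
binned_calibration <- function(preds, n_bins = 10) {
  n <- nrow(preds)
  stopifnot(n >= n_bins, n_bins >= 1)
  edges <- unique(stats::quantile(preds$prob, probs = seq(0, 1,
                                                          length.out = n_bins + 1)))
  if (length(edges) < 2)  # all predictions identical: one bin
    edges <- c(min(preds$prob) - 1e-12, max(preds$prob))
  if (length(edges) < n_bins + 1)
    message(sprintf("binned_calibration: %d empty bins merged; using %d bins",
                    n_bins + 1 - length(edges), length(edges) - 1))
  bin <- cut(preds$prob, breaks = edges, include.lowest = TRUE,
             labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    k <- sum(preds$label[sel]); m <- sum(sel)
    ci <- wilson_ci(k, m)
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1], n = m,
               mean_pred = mean(preds$prob[sel]), obs_frac = k / m,
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  rownames(out) <- NULL
  out
}

# Wilson score interval via prop.test without continuity correction
wilson_ci <- function(k, m, conf = 0.95) {
  if (m == 0) return(c(NA_real_, NA_real_))
  as.numeric(suppressWarnings(
    stats::prop.test(k, m, conf.level = conf, correct = FALSE)$conf.int))
}

#' Plot a calibration panel
#'
#' Diagonal reference, Loess curve and binned error bars on one panel,
#' base-graphics style.
#'
#' @param curve a `calibration_curve` (may be `NULL`).
#' @param bins output of [binned_calibration()] (optional).
#' @param main plot title.
#' @return `NULL`, invisibly.
#' @export
plot_calibration <- function(curve, bins = NULL, main = "Calibration") {
  plot(c(0, 1), c(0, 1), type = "n", xlab = "Predicted probability",
       ylab = "Observed frequency", main = main)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  if (!is.null(curve))
    graphics::lines(curve$pred, curve$observed, col = "blue", lwd = 2)
  if (!is.null(bins)) {
    graphics::points(bins$mean_pred, bins$obs_frac, pch = 19)
    graphics::arrows(bins$mean_pred, bins$ci_lo, bins$mean_pred, bins$ci_hi,
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(NULL)
}
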