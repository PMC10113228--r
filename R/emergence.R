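#' Predicted daily activity totals
#'
#' Full-model response-scale predictions on the frame's site-hours, summed
#' per day of year: the model-predicted daily activity distribution from
#' which timing and synchronization metrics are computed.
#'
#' @param fit A fitted [fit_gapm()] model.
#' @param frame The model frame to predict on (typically the training frame).
#' @return Data frame (`doy`, `activity`), non-negative, ordered by day.
#' @export
daily_predicted_activity <- function(fit, frame) {
  mu <- predict(fit, frame, type = "response")
  agg <- stats::aggregate(list(activity = mu), by = list(doy = frame$DOY), sum)
  agg[order(agg$doy), , drop = FALSE]
}

#' Weighted quantile of a discrete day distribution
#'
#' Linear interpolation on the cumulative normalized weight function using
#' the midpoint convention (`(cumsum(w) - w/2) / sum(w)`), so that the
#' median of symmetric weights is the centre of symmetry. A single positive
#' weight yields that day for every quantile.
#'
#' @param days Integer (or numeric) day values, ordered or not.
#' @param weights Non-negative weights with positive sum.
#' @param q Quantile(s) in (0, 1).
#' @return Interpolated day value(s).
#' @export
weighted_quantiles <- function(days, weights, q) {
  stop_if_not(length(days) == length(weights), "length mismatch")
  stop_if_not(all(weights >= 0) && sum(weights) > 0,
              "weights must be non-negative with positive sum")
  stop_if_not(all(q > 0 & q < 1), "q must be in (0, 1)")
  ord <- order(days)
  days <- days[ord]; weights <- weights[ord]
  pos <- weights > 0
  days <- days[pos]; weights <- weights[pos]
  if (length(days) == 1L) return(rep(days, length(q)))
  p <- (cumsum(weights) - weights / 2) / sum(weights)
  stats::approx(p, days, xout = q, rule = 2, ties = "ordered")$y
}

#' Emergence timing and synchronization summary
#'
#' Activity-weighted median day of emergence and the interquartile range
#' (IQR): the number of days containing the central 50% of the (predicted)
#' spring activity, a proxy for within-species synchronization (smaller =
#' more synchronized). Also reports the mean (signed) and mean absolute
#' residual activity when a residual curve is supplied.
#'
#' @param daily Data frame (`doy`, `activity`) from
#'   [daily_predicted_activity()].
#' @param curve Optional [residual_activity()] curve for the same species.
#' @param species Species label; defaults to the curve's.
#' @return Object of class `emergence_summary`: one-row data frame with
#'   `species`, `median_doy`, `mean_doy`, `q1`, `q3`, `iqr`,
#'   `mean_residual`, `mean_abs_residual`.
#' @export
emergence_summary <- function(daily, curve = NULL, species = NULL) {
  qs <- weighted_quantiles(daily$doy, daily$activity, c(0.25, 0.5, 0.75))
  species <- species %||% (if (!is.null(curve)) as.character(curve$species[1])
                           else "species")
  out <- data.frame(
    species = species,
    median_doy = qs[2],
    mean_doy = sum(daily$doy * daily$activity) / sum(daily$activity),
    q1 = qs[1], q3 = qs[3], iqr = qs[3] - qs[1],
    mean_residual = if (!is.null(curve)) mean(curve$value) else NA_real_,
    mean_abs_residual = if (!is.null(curve)) mean(abs(curve$value)) else NA_real_,
    row.names = NULL
  )
  structure(out, class = c("emergence_summary", "data.frame"))
}

#' Cross-species regressions among residual activity, timing and IQR
#'
#' Ordinary least-squares regressions across species summaries:
#' `median_doy ~ mean_residual` (does residual motivation shift timing?) and
#' `iqr ~ median_doy` (do later emergers synchronize more?). Reports slope,
#' intercept, R-squared and the two-sided p-value of the slope.
#'
#' @param summaries List of [emergence_summary()] rows or a stacked data
#'   frame with >= 3 species.
#' @param residual Which residual statistic to use as predictor:
#'   `"signed"` (`mean_residual`, default) or `"absolute"`
#'   (`mean_abs_residual`).
#' @return Data frame with one row per regression (`response`, `predictor`,
#'   `slope`, `intercept`, `r_squared`, `p`).
#' @export
cross_species_regression <- function(summaries,
                                     residual = c("signed", "absolute")) {
  residual <- match.arg(residual)
  if (!is.data.frame(summaries)) summaries <- do.call(rbind, summaries)
  stop_if_not(nrow(summaries) >= 3L,
              "need at least 3 species for cross-species regression")
  pred <- if (residual == "signed") "mean_residual" else "mean_abs_residual"
  one <- function(yv, xv, yn, xn) {
    fit <- stats::lm(yv ~ xv)
    sm <- summary(fit)
    p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
    data.frame(response = yn, predictor = xn,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = sm$r.squared, p = p)
  }
  out <- rbind(
    one(summaries$median_doy, summaries[[pred]], "median_doy", pred),
    one(summaries$iqr, summaries$median_doy, "iqr", "median_doy")
  )
  rownames(out) <- NULL
  out
}
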