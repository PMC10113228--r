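#' Simulate a model frame directly at the model level
#'
#' Draws hourly Poisson counts straight from the generative rate on the
#' covariates of a weather table, bypassing the event stream and the
#' moving-average/minimum response construction. This is the frame the
#' fitted model assumes verbatim (independent Poisson counts given the
#' covariates), which makes it the right input for parameter-recovery and
#' calibration studies of the fitter itself; the event-level pipeline is
#' exercised separately.
#'
#' @param truth A [true_model()].
#' @param weather Hourly weather table (as from [simulate_weather()]).
#' @param sites List of [site_config()] objects covering the weather sites.
#' @param seed Integer seed.
#' @param day_max Last day of year retained (default 136).
#' @param species Species label stamped on the frame.
#' @return A model frame with the same columns as
#'   [assemble_model_frame()] output, with `y` an integer Poisson draw.
#' @export
simulate_frame <- function(truth, weather, sites, seed = 1, day_max = 136,
                           species = "species") {
  stop_if_not(inherits(truth, "true_model"), "`truth` must be a true_model")
  if (inherits(sites, "site_config")) sites <- list(sites)
  covars <- with_covariates(weather, sites)
  ok <- stats::complete.cases(covars[, c("T_S", "T_A", "AP", "APT", "WS",
                                         "PR", "CC", "ST", "DOY")])
  covars <- covars[ok & covars$DOY <= day_max, , drop = FALSE]
  with_seed(seed, {
    mu <- activity_rate(truth, covars)
    y <- stats::rpois(nrow(covars), mu)
    out <- data.frame(site_id = covars$site_id, species = species,
                      hour = covars$timestamp, n_in = NA_integer_,
                      n_out = NA_integer_, y = as.numeric(y),
                      covars[, c("T_S", "T_A", "AP", "APT", "WS", "PR",
                                 "CC", "ST", "DOY")])
    rownames(out) <- NULL
    structure(out, class = c("model_frame", class(out)))
  })
}
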