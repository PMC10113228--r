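#' Default parameters of the synthetic weather generator
#'
#' The generator is structural, not climatological: each covariate is a
#' seasonal/diel deterministic component plus autoregressive noise, with
#' amplitudes chosen so that pairwise covariate correlations stay low
#' (well under 0.5), matching the weakly collinear regime the activity
#' model assumes.
#'
#' @param ta_mean Annual mean air temperature (deg C).
#' @param ta_seasonal_amp Amplitude of the annual air-temperature cycle (deg C).
#' @param ta_diel_amp Amplitude of the day/night air-temperature cycle (deg C).
#' @param ta_ar,ta_sd AR(1) coefficient and innovation SD of air-temperature
#'   noise (per hour).
#' @param ts_mean,ts_seasonal_amp,ts_lag_days Mean, annual amplitude and phase
#'   lag (days) of soil temperature at 20 cm; the soil cycle is damped and
#'   delayed relative to the air cycle (thermal inertia).
#' @param ts_couple Fraction of the low-pass-filtered air-temperature anomaly
#'   fed into soil temperature.
#' @param ts_ar,ts_sd AR(1) coefficient and innovation SD of the slow soil
#'   noise.
#' @param ap_mean Mean sea-level pressure (hPa).
#' @param ap_ar,ap_sd AR(1) coefficient and innovation SD of the pressure
#'   process (mean-reverting random walk).
#' @param ws_mean,ws_ar,ws_sd Mean, AR(1) coefficient and innovation SD of
#'   wind speed (m/s, truncated at 0).
#' @param pr_wet_wet,pr_dry_wet Markov-chain persistence of rain spells:
#'   probability an hour is wet given the previous hour was wet / dry.
#' @param pr_mean_mm Mean rainfall in a wet hour (mm, exponential).
#' @param cc_ar,cc_sd AR(1) coefficient and innovation SD of the latent
#'   cloudiness process mapped to eighths 0-8.
#' @param noise_scale Global multiplier on every innovation SD; 0 gives the
#'   purely deterministic seasonal + diel component.
#'
#' @return A named list of generator parameters.
#' @export
weather_config <- function(ta_mean = 9, ta_seasonal_amp = 9, ta_diel_amp = 4,
                           ta_ar = 0.95, ta_sd = 0.8,
                           ts_mean = 8, ts_seasonal_amp = 2.5, ts_lag_days = 45,
                           ts_couple = 0.15, ts_ar = 0.995, ts_sd = 0.25,
                           ap_mean = 1013, ap_ar = 0.997, ap_sd = 0.5,
                           ws_mean = 3, ws_ar = 0.9, ws_sd = 0.7,
                           pr_wet_wet = 0.65, pr_dry_wet = 0.04,
                           pr_mean_mm = 0.8,
                           cc_ar = 0.97, cc_sd = 0.35,
                           noise_scale = 1) {
  as.list(environment())
}

#' Simulate hourly weather for a set of sites
#'
#' Generates an hourly weather table with one row per site per hour over
#' `n_days` days. Air temperature is an annual + diel harmonic plus AR(1)
#' noise; soil temperature at 20 cm is a damped, phase-lagged annual cycle
#' plus a low-pass filter of the air anomaly (soil thermal inertia); air
#' pressure is a slow mean-reverting walk around 1013 hPa; precipitation is
#' zero-inflated with Markov rain spells; cloud cover is an integer 0-8 from
#' a latent AR(1) process. Fully deterministic given `seed`.
#'
#' @param sites List of [site_config()] objects.
#' @param start_date First day (Date or string), default January 1st.
#' @param n_days Number of days (>= 2; the pressure-trend covariate needs
#'   neighbouring hours).
#' @param seed Integer seed.
#' @param config Generator parameters from [weather_config()].
#'
#' @return A data frame with columns `site_id`, `timestamp` (POSIXct UTC),
#'   `T_S`, `T_A`, `AP`, `WS`, `PR`, `CC`.
#' @examples
#' w <- simulate_weather(list(site_config("A", 50.3, 7.2)), "2015-01-01",
#'                       n_days = 3, seed = 1)
#' head(w)
#' @export
simulate_weather <- function(sites, start_date = "2015-01-01", n_days,
                             seed = 1, config = weather_config()) {
  stop_if_not(is.numeric(n_days) && length(n_days) == 1L && n_days >= 2,
              "`n_days` must be >= 2 (the pressure trend needs neighbouring hours)")
  if (inherits(sites, "site_config")) sites <- list(sites)
  stop_if_not(length(sites) >= 1L, "need at least one site")
  start <- as.Date(start_date)
  n_hours <- as.integer(n_days) * 24L
  hours <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC") +
    3600 * (seq_len(n_hours) - 1L)
  cfg <- config

  with_seed(seed, {
    out <- lapply(sites, function(site) {
      doy <- doy0(hours)
      hod <- as.POSIXlt(hours, tz = "UTC")$hour

      ## deterministic components
      ta_det <- cfg$ta_mean -
        cfg$ta_seasonal_amp * cos(2 * pi * (doy - 15) / 365) -
        cfg$ta_diel_amp * cos(2 * pi * (hod - 14) / 24)
      ts_det <- cfg$ts_mean -
        cfg$ts_seasonal_amp * cos(2 * pi * (doy - 15 - cfg$ts_lag_days) / 365)

      ar1 <- function(n, phi, sd) {
        sd <- sd * cfg$noise_scale
        if (sd == 0) return(numeric(n))
        e <- stats::rnorm(n, 0, sd)
        x <- numeric(n)
        x[1] <- e[1] / sqrt(max(1 - phi^2, 1e-12))
        for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
        x
      }

      ta_noise <- ar1(n_hours, cfg$ta_ar, cfg$ta_sd)
      T_A <- ta_det + ta_noise

      ## soil: damped lagged seasonal + low-pass of the air anomaly + slow noise
      lp <- numeric(n_hours)
      k <- 0.01                      # per-hour relaxation, ~4 day time constant
      for (i in 2:n_hours) lp[i] <- lp[i - 1] + k * (ta_noise[i] - lp[i - 1])
      T_S <- ts_det + cfg$ts_couple * lp + ar1(n_hours, cfg$ts_ar, cfg$ts_sd)

      AP <- cfg$ap_mean + ar1(n_hours, cfg$ap_ar, cfg$ap_sd)
      WS <- pmax(0, cfg$ws_mean + ar1(n_hours, cfg$ws_ar, cfg$ws_sd))

      ## rain: two-state Markov chain, exponential amounts in wet hours
      PR <- numeric(n_hours)
      if (cfg$noise_scale > 0) {
        wet <- logical(n_hours)
        u <- stats::runif(n_hours)
        wet[1] <- u[1] < cfg$pr_dry_wet
        for (i in 2:n_hours) {
          p <- if (wet[i - 1]) cfg$pr_wet_wet else cfg$pr_dry_wet
          wet[i] <- u[i] < p
        }
        PR[wet] <- stats::rexp(sum(wet), rate = 1 / cfg$pr_mean_mm)
      }

      cc_lat <- ar1(n_hours, cfg$cc_ar, cfg$cc_sd)
      CC <- as.integer(round(8 * stats::pnorm(cc_lat, sd = max(
        cfg$cc_sd * cfg$noise_scale / sqrt(max(1 - cfg$cc_ar^2, 1e-12)), 1e-9))))
      CC <- pmin(8L, pmax(0L, CC))

      data.frame(site_id = site$site_id, timestamp = hours,
                 T_S = T_S, T_A = T_A, AP = AP, WS = WS, PR = PR, CC = CC)
    })
    do.call(rbind, out)
  })
}
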