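#' Site description for a hibernaculum
#'
#' Bundles a site identifier with geographic coordinates (used for
#' sunrise/sunset computation) and a site-level activity offset on the log
#' scale, mirroring the site factor of the activity model.
#'
#' @param site_id Character scalar naming the site.
#' @param latitude Latitude in decimal degrees, in \[-90, 90\].
#' @param longitude Longitude in decimal degrees, in \[-180, 180\].
#' @param activity_scale Log-scale intercept offset of the site relative to
#'   the model's reference site. Default 0.
#'
#' @return An object of class `site_config`.
#' @examples
#' site_config("Mayen", 50.33, 7.22)
#' @export
site_config <- function(site_id, latitude, longitude, activity_scale = 0) {
  stop_if_not(is_string(site_id), "`site_id` must be a single string")
  stop_if_not(is.numeric(latitude) && length(latitude) == 1L &&
                latitude >= -90 && latitude <= 90,
              "`latitude` must be a number in [-90, 90]")
  stop_if_not(is.numeric(longitude) && length(longitude) == 1L &&
                longitude >= -180 && longitude <= 180,
              "`longitude` must be a number in [-180, 180]")
  stop_if_not(is.numeric(activity_scale) && length(activity_scale) == 1L &&
                is.finite(activity_scale),
              "`activity_scale` must be a finite number")
  structure(list(site_id = site_id, latitude = latitude,
                 longitude = longitude, activity_scale = activity_scale),
            class = "site_config")
}

#' @export
print.site_config <- function(x, ...) {
  cat(sprintf("<site_config> %s (%.3f deg N, %.3f deg E), log-offset %+.3f\n",
              x$site_id, x$latitude, x$longitude, x$activity_scale))
  invisible(x)
}

#' Sunrise and sunset for a site and date
#'
#' Computes sunrise and sunset times (UTC) from the NOAA solar-position
#' equations: fractional year, equation of time and solar declination from
#' low-order trigonometric series, then the sunrise hour angle at a solar
#' zenith of 90.833 degrees (accounting for refraction and the solar disc).
#' Accuracy is within a few minutes of almanac values, ample for assigning
#' hourly observations to the day/night cycle.
#'
#' @param site A [site_config()] object (or any list with `latitude`,
#'   `longitude`).
#' @param date A `Date` (or string coercible to one). Vectorised over `date`.
#'
#' @return A data frame with columns `date`, `sunrise`, `sunset` (`POSIXct`,
#'   UTC).
#' @examples
#' solar_events(site_config("Mayen", 50.33, 7.22), as.Date("2015-03-21"))
#' @export
solar_events <- function(site, date) {
  date <- as.Date(date)
  stop_if_not(!anyNA(date), "`date` must be a valid Date")
  lat <- site$latitude
  lon <- site$longitude
  stop_if_not(is.numeric(lat) && is.numeric(lon), "site must carry coordinates")

  yday <- as.POSIXlt(date)$yday            # 0-based
  nyear <- ifelse(as.POSIXlt(date)$year %% 4 == 0, 366, 365)
  gamma <- 2 * pi / nyear * (yday + 0.5)   # fractional year, radians

  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma)
                      - 0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- (0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma)
           - 0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma)
           - 0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma))

  latr <- lat * pi / 180
  zen <- 90.833 * pi / 180
  cosha <- cos(zen) / (cos(latr) * cos(decl)) - tan(latr) * tan(decl)
  if (any(abs(cosha) >= 1)) {
    stop("polar day or night at latitude ", lat,
         ": sunrise/sunset undefined for this date", call. = FALSE)
  }
  ha <- acos(cosha) * 180 / pi             # degrees

  sunrise_min <- 720 - 4 * (lon + ha) - eqtime   # minutes after 00:00 UTC
  sunset_min <- 720 - 4 * (lon - ha) - eqtime
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  data.frame(
    date = date,
    sunrise = midnight + 60 * sunrise_min,
    sunset = midnight + 60 * sunset_min
  )
}

#' Solar-event table over a date range
#'
#' Convenience wrapper computing [solar_events()] for every date in
#' `[start_date, end_date]` for one site.
#'
#' @inheritParams solar_events
#' @param start_date,end_date First and last civil date, inclusive.
#' @return A data frame with one row per date (`date`, `sunrise`, `sunset`).
#' @export
solar_table <- function(site, start_date, end_date) {
  dates <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  solar_events(site, dates)
}
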