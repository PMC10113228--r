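#' Aggregate raw events into hourly entry/exit counts
#'
#' Counts entries and exits per species, site and clock hour. Hours with no
#' events are present with zero counts over the covered span, so that the
#' downstream moving average sees a complete series.
#'
#' @param events Data frame with columns `timestamp` (POSIXct or parseable),
#'   `site_id`, `species`, `direction` (`"in"` or `"out"`).
#' @param span Optional `c(start, end)` POSIXct pair: the hourly span to
#'   cover for every site/species. Default: each site's own event range.
#' @return Data frame (`site_id`, `species`, `hour`, `n_in`, `n_out`), one
#'   row per covered hour, ordered by site, species, hour. Records with an
#'   unknown direction are rejected with a counted warning.
#' @export
aggregate_hourly <- function(events, span = NULL) {
  empty <- data.frame(site_id = character(), species = character(),
                      hour = as.POSIXct(character(), tz = "UTC"),
                      n_in = integer(), n_out = integer())
  if (is.null(events) || nrow(events) == 0L) return(empty)
  ts <- as.POSIXct(events$timestamp, tz = "UTC")
  bad <- !(events$direction %in% c("in", "out")) | is.na(ts)
  if (any(bad)) {
    warning(sum(bad), " event record(s) rejected (bad direction or timestamp)",
            call. = FALSE)
    events <- events[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  if (nrow(events) == 0L) return(empty)
  hour <- trunc(ts, "hours")

  pieces <- lapply(split(seq_len(nrow(events)),
                         list(events$site_id, events$species), drop = TRUE),
                   function(idx) {
    si <- events$site_id[idx[1]]
    sp <- events$species[idx[1]]
    h <- hour[idx]
    if (is.null(span)) {
      site_hours <- hour[events$site_id == si]
      rng <- range(site_hours)
    } else {
      rng <- trunc(as.POSIXct(span, tz = "UTC"), "hours")
    }
    grid <- seq(rng[1], rng[2], by = "hour")
    key <- match(as.numeric(h), as.numeric(grid))
    n_in <- tabulate(key[events$direction[idx] == "in"], length(grid))
    n_out <- tabulate(key[events$direction[idx] == "out"], length(grid))
    data.frame(site_id = si, species = sp, hour = grid,
               n_in = n_in, n_out = n_out)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$site_id, out$species, out$hour), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-hour moving average of an hourly count series
#'
#' Interior values are the mean of the hour and its two neighbours; the first
#' and last value of a series use the available (shrunken) two-term window,
#' so output length equals input length.
#'
#' @param series Numeric vector ordered by hour, no duplicate hours.
#' @return Numeric vector of the same length.
#' @examples
#' smooth_counts(c(0, 3, 6, 3, 0))  # 1.5 3 4 3 1.5
#' @export
smooth_counts <- function(series) {
  if (length(series) == 0L) return(numeric())
  if (length(series) == 1L) return(as.numeric(series))
  as.numeric(zoo::rollapply(as.numeric(series), 3, mean,
                            partial = TRUE, align = "center"))
}

#' Hourly response: the smaller of the smoothed entry and exit aggregates
#'
#' Taking the minimum of the smoothed in- and out-flows damps one-way bulk
#' movements (e.g. the final departure wave) and retains the back-and-forth
#' activity signal.
#'
#' @param s_in,s_out Smoothed entry/exit aggregates (non-negative reals).
#' @return `pmin(s_in, s_out)`.
#' @export
build_response <- function(s_in, s_out) {
  pmin(s_in, s_out)
}

#' Air-pressure trend
#'
#' `APT[t] = AP[t+1] - AP[t-1]`, the pressure difference between the
#' subsequent and the preceding hour. The first and last hour of the series
#' have no trend and are returned as `NA` (those rows are later excluded).
#'
#' @param ap Ordered hourly air-pressure series (hPa).
#' @return Numeric vector of the same length with `NA` at both ends.
#' @export
compute_apt <- function(ap) {
  n <- length(ap)
  if (n < 3L) return(rep(NA_real_, n))
  c(NA_real_, ap[3:n] - ap[1:(n - 2L)], NA_real_)
}

#' Sun time of a timestamp
#'
#' Maps clock time onto the diel cycle anchored at solar events: sunset is 0,
#' sunrise is -1/+1, night hours (sunset to next sunrise) run linearly from 0
#' to +1, day hours (sunrise to next sunset) from -1 to 0. The result is
#' continuous and periodic with period 2 at the sunrise seam.
#'
#' @param t POSIXct timestamps.
#' @param solar Data frame with `sunrise` and `sunset` POSIXct columns (as
#'   from [solar_table()]) covering at least one event before and after every
#'   `t`.
#' @return Numeric sun times in `[-1, 1]`; `NA` where `t` falls outside the
#'   covered solar range.
#' @export
compute_sun_time <- function(t, solar) {
  ev <- data.frame(
    time = c(as.numeric(solar$sunrise), as.numeric(solar$sunset)),
    is_sunrise = rep(c(TRUE, FALSE), each = nrow(solar))
  )
  ev <- ev[order(ev$time), , drop = FALSE]
  stop_if_not(all(diff(ev$is_sunrise) != 0),
              "solar events must alternate sunrise/sunset")
  ## unwrapped phase: sunset = even integers, sunrise = odd integers
  phase <- seq_len(nrow(ev)) - 1L + ifelse(ev$is_sunrise[1], 1L, 0L)
  phi <- stats::approx(ev$time, phase, xout = as.numeric(t),
                       method = "linear", rule = 1)$y
  st <- (phi + 1) %% 2 - 1
  ## map the day-segment branch to [-1, 0]: phases in (odd, even) intervals
  st
}

#' Assemble the hourly model frame
#'
#' Joins hourly activity with same-site same-hour weather, smooths the
#' entry/exit counts by a three-hour moving average per contiguous recording
#' block (gaps do not bleed across), forms the response `y = min(s_in,
#' s_out)`, and adds the derived covariates `APT`, `ST` and `DOY` (January
#' 1st = day 0). Rows beyond `day_max` or with any missing covariate are
#' dropped, with per-reason counts in the `drops` attribute.
#'
#' @param hourly Hourly activity table from [aggregate_hourly()].
#' @param weather Hourly weather table covering every site in `hourly`.
#' @param sites List of [site_config()] objects (coordinates drive the solar
#'   events behind `ST`).
#' @param day_max Last day of year retained (default 136, mid-May).
#' @return The model frame: columns `y`, `T_S`, `T_A`, `AP`, `APT`, `WS`,
#'   `PR`, `CC`, `ST`, `DOY`, `site_id`, `species`, `hour`, plus `n_in`,
#'   `n_out`, with zero missing values; attribute `drops` accounts for every
#'   dropped row.
#' @export
assemble_model_frame <- function(hourly, weather, sites, day_max = 136) {
  stop_if_not(nrow(hourly) > 0L, "`hourly` is empty")
  miss <- setdiff(unique(hourly$site_id), unique(weather$site_id))
  if (length(miss)) {
    stop("site(s) in activity data but not in weather: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  ## smooth per site x species x contiguous block of recorded hours
  pieces <- lapply(split(hourly, list(hourly$site_id, hourly$species),
                         drop = TRUE), function(h) {
    h <- h[order(h$hour), , drop = FALSE]
    block <- cumsum(c(1, diff(as.numeric(h$hour)) != 3600))
    h$s_in <- unlist(lapply(split(h$n_in, block), smooth_counts),
                     use.names = FALSE)
    h$s_out <- unlist(lapply(split(h$n_out, block), smooth_counts),
                      use.names = FALSE)
    h
  })
  act <- do.call(rbind, pieces)
  act$y <- build_response(act$s_in, act$s_out)

  wx <- with_covariates(weather, sites)
  wx_key <- paste(wx$site_id, as.numeric(wx$timestamp))
  idx <- match(paste(act$site_id, as.numeric(act$hour)), wx_key)
  covars <- c("T_S", "T_A", "AP", "APT", "WS", "PR", "CC", "ST", "DOY")
  frame <- cbind(act[, c("site_id", "species", "hour", "n_in", "n_out", "y")],
                 wx[idx, covars])

  n0 <- nrow(frame)
  keep_doy <- !is.na(frame$DOY) & frame$DOY <= day_max
  ## unmatched weather hours count as missing covariates
  keep_doy[is.na(frame$DOY)] <- TRUE
  dropped_doy <- sum(!keep_doy)
  frame <- frame[keep_doy, , drop = FALSE]
  cc_ok <- stats::complete.cases(frame[, covars])
  dropped_na <- sum(!cc_ok)
  frame <- frame[cc_ok, , drop = FALSE]
  rownames(frame) <- NULL
  attr(frame, "drops") <- c(day_beyond_max = dropped_doy,
                            missing_covariate = dropped_na)
  structure(frame, class = c("model_frame", class(frame)))
}
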