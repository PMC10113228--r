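mk_events <- function(times, site = "S1", species = "sp", direction = "in") {
  if (!length(times)) {
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      site_id = character(), species = character(),
                      direction = character()))
  }
  data.frame(timestamp = as.POSIXct(times, tz = "UTC"), site_id = site,
             species = species, direction = direction)
}

test_that("events are aggregated into the right clock hour", {
  ev <- mk_events(c("2015-02-01 02:10:00", "2015-02-01 02:50:00",
                    "2015-02-01 02:59:59"))
  h <- aggregate_hourly(ev)
  expect_equal(nrow(h), 1L)
  expect_equal(h$hour, as.POSIXct("2015-02-01 02:00:00", tz = "UTC"))
  expect_equal(h$n_in, 3L)
  expect_equal(h$n_out, 0L)
})

test_that("empty input aggregates to an empty table", {
  expect_equal(nrow(aggregate_hourly(NULL)), 0L)
  expect_equal(nrow(aggregate_hourly(mk_events(character(0)))), 0L)
})

test_that("aggregation fills uncovered hours with zeros and conserves counts", {
  ev <- rbind(mk_events(c("2015-02-01 02:10:00", "2015-02-01 05:30:00")),
              mk_events("2015-02-01 03:30:00", direction = "out"))
  h <- aggregate_hourly(ev)
  expect_equal(nrow(h), 4L)                      # 02:00 .. 05:00 inclusive
  expect_equal(sum(h$n_in), 2L)
  expect_equal(sum(h$n_out), 1L)
  expect_equal(h$n_in[h$hour == as.POSIXct("2015-02-01 04:00:00", tz = "UTC")], 0L)
})

test_that("aggregation conserves totals per site and species on a large stream", {
  sites <- quick_sites(3)
  truth <- true_model(alpha = 0.5, beta = null_beta, f1 = diel_f1)
  w <- simulate_weather(sites, "2015-01-01", 60, seed = 8)
  ev <- simulate_activity(truth, w, sites, seed = 9, species = "spA")
  h <- aggregate_hourly(ev)
  in_by_site <- tapply(h$n_in, h$site_id, sum)
  ev_in <- table(ev$site_id[ev$direction == "in"])
  expect_equal(as.numeric(in_by_site[names(ev_in)]), as.numeric(ev_in))
  expect_equal(sum(h$n_in) + sum(h$n_out), nrow(ev))
})

test_that("unknown directions are rejected with a counted warning", {
  ev <- rbind(mk_events("2015-02-01 02:10:00"),
              mk_events("2015-02-01 02:20:00", direction = "sideways"))
  expect_warning(h <- aggregate_hourly(ev), "1 event record")
  expect_equal(sum(h$n_in) + sum(h$n_out), 1L)
})

test_that("three-hour moving average matches hand-computed values", {
  expect_equal(smooth_counts(c(0, 3, 6, 3, 0)), c(1.5, 3, 4, 3, 1.5))
  expect_equal(smooth_counts(rep(7, 20)), rep(7, 20))
  expect_equal(smooth_counts(numeric(0)), numeric(0))
  expect_equal(smooth_counts(5), 5)
  expect_equal(smooth_counts(c(2, 4)), c(3, 3))
})

test_that("moving-average interior equals the convolution oracle", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rpois(50, 4)
    sm <- smooth_counts(x)
    oracle <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
    expect_equal(sm[2:49], oracle[2:49], tolerance = 1e-12)
    expect_length(sm, 50)
  }
})

test_that("the response is the smaller smoothed aggregate", {
  expect_equal(build_response(2.3, 1.7), 1.7)
  expect_equal(build_response(0, 5), 0)
  expect_equal(build_response(3.3, 3.3), 3.3)
  expect_equal(build_response(c(1, 5), c(2, 4)), c(1, 4))
})

test_that("air-pressure trend is the centered two-hour difference", {
  expect_equal(compute_apt(c(1000, 1005, 1010)), c(NA, 10, NA))
  expect_equal(compute_apt(rep(1013, 6)), c(NA, 0, 0, 0, 0, NA))
  x <- c(1000, 1003, 1001, 998, 1002, 1005)
  expect_equal(compute_apt(rev(x))[2:5], -rev(compute_apt(x)[2:5]))
  expect_equal(compute_apt(c(1000, 1001)), c(NA_real_, NA_real_))
})

test_that("sun time anchors sunset at 0 and interpolates linearly", {
  solar <- data.frame(
    date = as.Date(c("2015-03-01", "2015-03-02")),
    sunrise = as.POSIXct(c("2015-03-01 06:00:00", "2015-03-02 06:00:00"), tz = "UTC"),
    sunset = as.POSIXct(c("2015-03-01 18:00:00", "2015-03-02 18:00:00"), tz = "UTC")
  )
  t_sunset <- as.POSIXct("2015-03-01 18:00:00", tz = "UTC")
  t_midnight <- as.POSIXct("2015-03-02 00:00:00", tz = "UTC")
  t_noon <- as.POSIXct("2015-03-01 12:00:00", tz = "UTC")
  st <- compute_sun_time(c(t_sunset, t_midnight, t_noon), solar)
  expect_equal(st, c(0, 0.5, -0.5), tolerance = 1e-9)
})

test_that("sun time is periodic and continuous at the sunrise seam", {
  site <- site_config("x", 50.3, 7.2)
  solar <- solar_table(site, "2015-03-01", "2015-03-03")
  sr <- solar$sunrise[2]
  st <- compute_sun_time(c(sr - 60, sr + 60), solar)
  expect_gt(st[1], 0.99)                        # end of night -> +1
  expect_lt(st[2], -0.99)                       # start of day -> -1
  hours <- seq(solar$sunrise[1], solar$sunset[3], by = "hour")
  stv <- compute_sun_time(hours, solar)
  expect_true(all(stv >= -1 & stv <= 1))
})

test_that("the model frame truncates at day_max and drops missing covariates", {
  sites <- quick_sites(1)
  truth <- true_model(alpha = 1.2, beta = null_beta, f1 = diel_f1)
  w <- simulate_weather(sites, "2015-05-10", 20, seed = 12)  # spans day 136
  ev <- simulate_activity(truth, w, sites, seed = 13)
  h <- aggregate_hourly(ev, span = range(w$timestamp))
  fr <- assemble_model_frame(h, w, sites, day_max = 136)
  expect_true(all(fr$DOY <= 136))
  expect_true(all(doy0(fr$hour) <= 136))
  drops <- attr(fr, "drops")
  expect_equal(nrow(h), nrow(fr) + sum(drops))
  expect_false(anyNA(fr[, c("y", "T_S", "T_A", "AP", "APT", "WS", "PR",
                            "CC", "ST", "DOY")]))
})

test_that("blanking covariate hours removes exactly those rows downstream", {
  sites <- quick_sites(1)
  truth <- true_model(alpha = 1, beta = null_beta)
  w <- simulate_weather(sites, "2015-02-01", 30, seed = 14)
  ev <- simulate_activity(truth, w, sites, seed = 15)
  h <- aggregate_hourly(ev, span = range(w$timestamp))
  fr0 <- assemble_model_frame(h, w, sites)
  blank <- list(list(site = "S1", field = "T_A",
                     start = "2015-02-10 00:00:00",
                     end = "2015-02-10 09:00:00"))
  gi <- inject_gaps(ev, list(), w, blank)
  expect_equal(gi$log[["blanked_hours"]], 10L)
  fr1 <- assemble_model_frame(h, gi$weather, sites)
  expect_equal(nrow(fr0) - nrow(fr1), 10L)
})

test_that("full-coverage input yields sites x hours minus APT boundary rows", {
  sites <- quick_sites(2)
  truth <- true_model(alpha = 1, beta = null_beta)
  w <- simulate_weather(sites, "2015-02-01", 15, seed = 16)
  ev <- simulate_activity(truth, w, sites, seed = 17)
  h <- aggregate_hourly(ev, span = range(w$timestamp))
  fr <- assemble_model_frame(h, w, sites)
  expect_equal(nrow(fr), 2 * (15 * 24 - 2))
})

test_that("a site without weather is a hard error naming the site", {
  ev <- mk_events("2015-02-01 02:10:00", site = "Orphan")
  h <- aggregate_hourly(ev)
  w <- simulate_weather(quick_sites(1), "2015-02-01", 3, seed = 1)
  expect_error(assemble_model_frame(h, w, quick_sites(1)), "Orphan")
})

test_that("smoothing does not bleed across recording gaps", {
  # two separated blocks: constant 6 in block 1, constant 0 in block 2
  t1 <- as.POSIXct("2015-02-01 00:00:00", tz = "UTC") + 3600 * (0:5)
  t2 <- as.POSIXct("2015-02-03 00:00:00", tz = "UTC") + 3600 * (0:5)
  ev <- do.call(rbind, lapply(t1, function(tt) {
    rbind(mk_events(format(tt + 60 * (1:6)), direction = "in"),
          mk_events(format(tt + 60 * (7:12)), direction = "out"))
  }))
  h1 <- aggregate_hourly(ev)
  h2 <- data.frame(site_id = "S1", species = "sp", hour = t2,
                   n_in = 0L, n_out = 0L)
  h <- rbind(h1, h2)
  sites <- quick_sites(1)
  w <- simulate_weather(sites, "2015-01-31", 5, seed = 18)
  fr <- assemble_model_frame(h, w, sites)
  # block 1 is constant 6-in/6-out, so y = 6 everywhere in it; block 2 stays 0
  expect_true(all(fr$y[fr$hour %in% t1] == 6))
  expect_true(all(fr$y[fr$hour %in% t2] == 0))
})
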