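# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

null_beta <- c(T_S = 0, T_A = 0, AP = 0, APT = 0, WS = 0, PR = 0, CC = 0)

# Linear coefficients of the M. myotis preset, used as simulation truth.
myotis_beta <- c(T_S = -0.055, T_A = 0.173, AP = 0.011, APT = 0.015,
                 WS = -0.126, PR = -0.367, CC = -0.005)

diel_f1 <- function(st) 1.5 * cos(pi * (st - 0.5))

quick_sites <- function(n = 2) {
  lapply(seq_len(n), function(i) {
    site_config(paste0("S", i), 49 + i / 3, 7 + i / 2)
  })
}

# Weather + model-level Poisson frame in one call.
quick_frame <- function(truth, n_sites = 2, n_days = 110, seed = 1,
                        weather_seed = seed + 10000) {
  sites <- quick_sites(n_sites)
  w <- simulate_weather(sites, "2015-01-01", n_days, seed = weather_seed)
  simulate_frame(truth, w, sites, seed = seed)
}

# One-sided derivative estimates at x0 from an exact local cubic fit
# (the spline is piecewise cubic, so these carry no truncation error).
cubic_side_derivs <- function(f, x0, e, dir = 1) {
  xs <- x0 + dir * e * (0:3)
  A <- outer(xs - x0, 0:3, "^")
  cf <- solve(A, f(xs))
  c(value = cf[1], d1 = cf[2], d2 = 2 * cf[3])
}
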