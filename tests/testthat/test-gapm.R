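test_that("intercept-only fit recovers the log mean in closed form", {
  y <- rep(3.7, 50)
  X <- matrix(1, 50, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- penalized_irls(X, y)
  expect_equal(unname(fit$coefficients), log(3.7), tolerance = 1e-9)
  expect_equal(fit$deviance, fit$null_deviance, tolerance = 1e-9)
})

test_that("unpenalized linear fit matches the independent GLM optimizer", {
  truth <- true_model(alpha = -10, site_effects = c(S2 = -0.6),
                      beta = myotis_beta, f1 = diel_f1)
  fr <- quick_frame(truth, n_sites = 2, n_days = 45, seed = 21)
  X <- cbind("(Intercept)" = 1, "site:S2" = as.numeric(fr$site_id == "S2"),
             as.matrix(fr[, names(myotis_beta)]))
  ours <- penalized_irls(X, fr$y)
  oracle <- glm(fr$y ~ X - 1, family = poisson())
  expect_lt(max(abs(ours$coefficients - coef(oracle))), 1e-6)
  expect_equal(ours$deviance, deviance(oracle), tolerance = 1e-8)
})

test_that("an overwhelming penalty shrinks a smooth to the constant log mean", {
  set.seed(22)
  st <- runif(800, -1, 1)
  b <- cyclic_basis(st, 8, c(-1, 1))
  ctr <- apply_sum_to_zero(cyclic_design(b, st))
  y <- rpois(800, exp(0.5 + 0.8 * sin(pi * st)))
  X <- cbind("(Intercept)" = 1, ctr$X)
  Sc <- crossprod(ctr$Z, b$S %*% ctr$Z)
  fit <- penalized_irls(X, y, list(list(cols = 2:8, S = Sc, lambda = 1e9)))
  eta <- X %*% fit$coefficients
  expect_lt(max(abs(eta - log(mean(y)))), 1e-3)
})

test_that("rank deficiency is reported with the offending column", {
  X <- cbind("(Intercept)" = 1, a = rnorm(50), dup = 0)
  X[, "dup"] <- X[, "a"]
  y <- rpois(50, 2)
  expect_error(penalized_irls(X, y), "rank deficient")
})

test_that("fixed-lambda mode bypasses the GCV search", {
  truth <- true_model(alpha = 0, beta = null_beta, f1 = diel_f1)
  fr <- quick_frame(truth, n_sites = 1, n_days = 30, seed = 23)
  fit <- suppressWarnings(
    fit_gapm(fr, gapm_spec(method = "fixed", lambda = c(2, 3, 4, 5),
                           use_f3 = TRUE)))
  expect_equal(unname(fit$lambda), c(2, 3, 4, 5))
})

test_that("the selected smoothing parameter minimizes the recorded GCV scores", {
  set.seed(24)
  st <- runif(1500, -1, 1)
  b <- cyclic_basis(st, 10, c(-1, 1))
  ctr <- apply_sum_to_zero(cyclic_design(b, st))
  y <- rpois(1500, exp(0.3 + 1.2 * sin(pi * st)))
  X <- cbind("(Intercept)" = 1, ctr$X)
  Sc <- crossprod(ctr$Z, b$S %*% ctr$Z)
  pen <- suppressWarnings(
    select_smoothing(X, y, list(list(cols = 2:10, S = Sc, lambda = 1)),
                     criterion = "GCV"))
  scores <- attr(pen, "gcv")[, 1]
  grid <- 10^seq(-4, 10, by = 1)
  expect_equal(pen[[1]]$lambda, grid[which.min(scores)])
})

test_that("wigglier truth selects a smaller smoothing parameter", {
  set.seed(25)
  st <- runif(2000, -1, 1)
  b <- cyclic_basis(st, 10, c(-1, 1))
  ctr <- apply_sum_to_zero(cyclic_design(b, st))
  X <- cbind("(Intercept)" = 1, ctr$X)
  Sc <- crossprod(ctr$Z, b$S %*% ctr$Z)
  pen0 <- list(list(cols = 2:10, S = Sc, lambda = 1))
  y_wiggly <- rpois(2000, exp(1 + 1.5 * sin(3 * pi * st)))
  y_flat <- rpois(2000, exp(1 + 0.01 * sin(pi * st)))
  lam_w <- suppressWarnings(select_smoothing(X, y_wiggly, pen0))[[1]]$lambda
  lam_f <- suppressWarnings(select_smoothing(X, y_flat, pen0))[[1]]$lambda
  expect_lt(lam_w, lam_f)
})

test_that("a preset-anchored air-temperature effect is recovered within 2 SEs", {
  truth <- true_model(alpha = -12, site_effects = c(S2 = -0.5),
                      beta = myotis_beta, f1 = diel_f1,
                      f2 = doy_bump(100, 12, 2.5))
  fr <- quick_frame(truth, n_sites = 2, n_days = 110, seed = 26)
  fit <- suppressWarnings(fit_gapm(fr, gapm_spec(reference_site = "S1")))
  wt <- wald_tests(fit)
  est <- wt$estimate[wt$term == "T_A"]
  se <- wt$se[wt$term == "T_A"]
  expect_lt(abs(est - 0.173), 2 * se)
  expect_equal(wt$stars[wt$term == "T_A"], "***")
})

test_that("refitting a frame simulated from a fit reproduces its deviance explained", {
  truth <- true_model(alpha = -1, site_effects = c(S2 = -0.5),
                      beta = myotis_beta, f1 = diel_f1,
                      f2 = doy_bump(95, 14, 2))
  fr <- quick_frame(truth, n_sites = 2, n_days = 80, seed = 27)
  spec <- gapm_spec(reference_site = "S1")
  fit1 <- suppressWarnings(fit_gapm(fr, spec))
  fr2 <- fr
  fr2$y <- with_seed(28, rpois(nrow(fr), fit1$fitted))
  fit2 <- suppressWarnings(fit_gapm(fr2, spec))
  expect_lt(abs(deviance_explained(fit1) - deviance_explained(fit2)), 0.05)
})

test_that("identical frame and spec give bit-identical fits", {
  truth <- true_model(alpha = 0, beta = null_beta, f1 = diel_f1)
  fr <- quick_frame(truth, n_sites = 1, n_days = 40, seed = 29)
  spec <- gapm_spec()
  f1 <- suppressWarnings(fit_gapm(fr, spec))
  f2 <- suppressWarnings(fit_gapm(fr, spec))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$lambda, f2$lambda)
})

test_that("an all-zero response is a documented boundary error", {
  truth <- true_model(alpha = 0, beta = null_beta)
  fr <- quick_frame(truth, n_sites = 1, n_days = 20, seed = 30)
  fr$y <- 0
  expect_error(fit_gapm(fr), "boundary")
})

test_that("a single site drops the site factor with a warning", {
  truth <- true_model(alpha = 0, beta = null_beta)
  fr <- quick_frame(truth, n_sites = 1, n_days = 30, seed = 31)
  w <- capture_warnings(fit <- fit_gapm(fr))
  expect_true(any(grepl("site factor dropped", w)))
  expect_length(fit$site_coefficients, 0)
})

test_that("non-integer responses from the smoothed-minimum pipeline are accepted", {
  sites <- quick_sites(1)
  truth <- true_model(alpha = 1.3, beta = null_beta, f1 = diel_f1)
  w <- simulate_weather(sites, "2015-01-01", 60, seed = 32)
  ev <- simulate_activity(truth, w, sites, seed = 33)
  fr <- assemble_model_frame(aggregate_hourly(ev, span = range(w$timestamp)),
                             w, sites)
  expect_gt(sum(fr$y %% 1 != 0), 0)
  fit <- suppressWarnings(fit_gapm(fr))
  expect_true(is.finite(fit$deviance))
})

test_that("significance stars follow the printed thresholds", {
  expect_equal(batgapm:::p_stars(c(1, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
  wt <- data.frame(est = c(0, 1.96), se = c(1, 1))
  p <- 2 * pnorm(-abs(wt$est / wt$se))
  expect_equal(p[1], 1)
  expect_equal(p[2], 0.05, tolerance = 1e-3)
})

test_that("a zeroed smooth block has statistic 0 and p = 1", {
  truth <- true_model(alpha = 0, beta = null_beta, f1 = diel_f1)
  fr <- quick_frame(truth, n_sites = 1, n_days = 30, seed = 34)
  fit <- suppressWarnings(fit_gapm(fr))
  fit$coefficients[fit$blocks$f2] <- 0
  sig <- smooth_significance(fit)
  expect_equal(sig$statistic[sig$smooth == "f2"], 0)
  expect_equal(sig$p[sig$smooth == "f2"], 1)
})

test_that("a strongly simulated seasonal smooth is highly significant", {
  rej <- vapply(1:5, function(r) {
    truth <- true_model(alpha = 0, beta = null_beta, f1 = diel_f1,
                        f2 = doy_bump(100, 12, 2.5))
    fr <- quick_frame(truth, n_sites = 1, n_days = 110, seed = 40 + r)
    fit <- suppressWarnings(fit_gapm(fr))
    sig <- smooth_significance(fit)
    sig$p[sig$smooth == "f2"]
  }, 0)
  expect_true(all(rej < 0.001))
})

test_that("deviance explained is 0 for the null fit, 1 for a perfect fit, monotone in covariates", {
  y <- c(rpois(100, 4), 0)
  expect_equal(batgapm:::poisson_deviance(y, y + (y == 0) * 1e-12), 0,
               tolerance = 1e-6)
  truth <- true_model(alpha = -8, beta = myotis_beta, f1 = diel_f1)
  fr <- quick_frame(truth, n_sites = 1, n_days = 60, seed = 35)
  spec_small <- gapm_spec(linear = c("T_S", "WS"), method = "fixed",
                          lambda = 1, use_f3 = FALSE)
  spec_big <- gapm_spec(linear = c("T_S", "WS", "T_A"), method = "fixed",
                        lambda = 1, use_f3 = FALSE)
  de_small <- deviance_explained(suppressWarnings(fit_gapm(fr, spec_small)))
  de_big <- deviance_explained(suppressWarnings(fit_gapm(fr, spec_big)))
  expect_gte(de_big, de_small)
  expect_gte(de_small, 0)
  expect_lte(de_big, 1)
})

test_that("component predictions add up on the link scale and f2 ignores weather", {
  truth <- true_model(alpha = -10, site_effects = c(S2 = -0.4),
                      beta = myotis_beta, f1 = diel_f1,
                      f2 = doy_bump(90, 15, 1.5))
  fr <- quick_frame(truth, n_sites = 2, n_days = 90, seed = 36)
  fit <- suppressWarnings(fit_gapm(fr, gapm_spec(reference_site = "S1")))
  nd <- fr[1:50, ]
  total <- predict(fit, nd, type = "link")
  parts <- sapply(c("intercept", "site", "linear", "f1", "f2", "f3"),
                  function(cm) predict(fit, nd, components = cm, type = "link"))
  expect_equal(total, rowSums(parts), tolerance = 1e-10)
  expect_equal(exp(total), predict(fit, nd, type = "response"),
               tolerance = 1e-12)
  nd_shift <- nd
  nd_shift[, names(myotis_beta)] <- nd_shift[, names(myotis_beta)] + 3
  expect_equal(predict(fit, nd, components = "f2"),
               predict(fit, nd_shift, components = "f2"))
})

test_that("response-scale predictions on the training frame match the observed total", {
  truth <- true_model(alpha = -9, beta = myotis_beta, f1 = diel_f1,
                      f2 = doy_bump(100, 12, 2))
  fr <- quick_frame(truth, n_sites = 1, n_days = 100, seed = 37)
  fit <- suppressWarnings(fit_gapm(fr))
  mu <- predict(fit, fr, type = "response")
  expect_lt(abs(sum(mu) - sum(fr$y)) / sum(fr$y), 0.005)
})

test_that("prediction warns when extrapolating and errors on unknown sites", {
  truth <- true_model(alpha = 0, site_effects = c(S2 = -0.3),
                      beta = null_beta, f1 = diel_f1)
  fr <- quick_frame(truth, n_sites = 2, n_days = 40, seed = 38)
  fit <- suppressWarnings(fit_gapm(fr, gapm_spec(reference_site = "S1")))
  nd <- fr[1, ]
  nd$T_A <- max(fr$T_A) + 50
  expect_warning(predict(fit, nd), "extrapolating")
  nd2 <- fr[1, ]
  nd2$site_id <- "Atlantis"
  expect_error(predict(fit, nd2), "Atlantis")
})

test_that("the report table carries all sections for each species", {
  truth <- true_model(alpha = 0, beta = null_beta, f1 = diel_f1)
  fr <- quick_frame(truth, n_sites = 1, n_days = 40, seed = 39)
  fit <- suppressWarnings(fit_gapm(fr))
  rep <- gapm_report(list(spA = fit))
  expect_setequal(unique(rep$section), c("site", "weather", "smooth", "fit"))
  expect_equal(rep$estimate[rep$term == "n_obs"], fit$n_obs)
  expect_true(all(names(myotis_beta) %in% rep$term[rep$section == "weather"]))
})
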