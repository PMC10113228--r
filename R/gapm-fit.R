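#' Model specification for the activity GAPM
#'
#' Describes the right-hand side of the hourly activity model: the seven
#' linear weather covariates, the site factor (with a declared reference
#' level), and the three smooths — a cyclic smooth of sun time `f1(ST)`
#' (period 2), a cyclic smooth of day of year `f2(DOY)`, and optionally the
#' interaction tensor `f3(ST, DOY)` — together with smoothing-selection
#' settings.
#'
#' @param linear Character vector of linear covariates (default the seven
#'   weather variables).
#' @param reference_site Reference level of the site factor; default
#'   `"Mayen-Mauerstollen"`, falling back to the first observed site when
#'   absent from the data.
#' @param k_st,k_doy Basis dimensions of `f1` and `f2` (defaults 10 and 20).
#' @param k_tensor Marginal basis dimension of the interaction (default 5;
#'   the interaction has `(k_tensor-1)^2` coefficients).
#' @param use_f3 Include the `f3(ST, DOY)` interaction (default TRUE).
#' @param doy_period Period range of the DOY smooth; default `c(0, 366)`,
#'   wrapping at the year boundary.
#' @param knot_placement Knot placement rule for the cyclic bases.
#' @param method Smoothing-parameter selection: `"UBRE"` (default; an
#'   AIC-type unbiased-risk score `deviance + 2*edf` at Poisson scale 1,
#'   minimized by grid coordinate descent), `"GCV"` (generalized
#'   cross-validation of the working penalized least-squares problem), or
#'   `"fixed"`. UBRE is the default because its additive degrees-of-freedom
#'   cost resists the interpolation pathology GCV exhibits on sparse count
#'   series with long all-zero stretches.
#' @param lambda Fixed smoothing parameters (recycled over penalties) used
#'   when `method = "fixed"` and as the GCV starting point.
#' @param lambda_grid Log-spaced candidate grid for GCV.
#' @param tol,maxit Convergence tolerance (relative deviance change) and
#'   iteration cap of the penalized IRLS.
#' @return An object of class `gapm_spec`.
#' @export
gapm_spec <- function(linear = c("T_S", "T_A", "AP", "APT", "WS", "PR", "CC"),
                      reference_site = "Mayen-Mauerstollen",
                      k_st = 10, k_doy = 20, k_tensor = 5, use_f3 = TRUE,
                      doy_period = c(0, 366),
                      knot_placement = c("quantile", "uniform"),
                      method = c("UBRE", "GCV", "fixed"), lambda = 1,
                      lambda_grid = 10^seq(-4, 10, by = 1),
                      tol = 1e-8, maxit = 100) {
  stop_if_not(length(linear) >= 1L, "`linear` must name at least one covariate")
  structure(list(linear = linear, reference_site = reference_site,
                 k_st = k_st, k_doy = k_doy, k_tensor = k_tensor,
                 use_f3 = isTRUE(use_f3), doy_period = doy_period,
                 knot_placement = match.arg(knot_placement),
                 method = match.arg(method), lambda = lambda,
                 lambda_grid = lambda_grid, tol = tol, maxit = maxit),
            class = "gapm_spec")
}

## Poisson deviance valid for real-valued non-negative y (y*log(y) := 0 at 0).
poisson_deviance <- function(y, mu) {
  ylogy <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(ylogy - (y - mu))
}

#' Penalized IRLS for the Poisson log-link model
#'
#' Maximizes the penalized Poisson log-likelihood
#' `l(beta) - 0.5 * sum_j lambda_j beta' S_j beta` by iteratively reweighted
#' least squares. The response may be any non-negative real vector (the
#' activity response is a minimum of moving averages and is generally
#' non-integer); the deviance uses the continuous extension of the Poisson
#' deviance. Convergence is declared when the relative deviance change falls
#' below `tol`.
#'
#' @param X Design matrix (full column rank).
#' @param y Non-negative response vector.
#' @param penalties List of `list(cols, S, lambda)` blocks: column indices
#'   into `X`, a PSD penalty matrix of matching dimension, and its smoothing
#'   parameter. May be empty (unpenalized GLM).
#' @param tol,maxit Convergence control.
#' @return List with `coefficients`, `vcov` (penalized-information inverse),
#'   `XtWX`, `deviance`, `null_deviance`, `edf` (per-coefficient effective
#'   degrees of freedom), `fitted`, `iter`.
#' @export
penalized_irls <- function(X, y, penalties = list(), tol = 1e-8, maxit = 100) {
  stop_if_not(all(y >= 0), "`y` must be non-negative")
  p <- ncol(X)
  Slam <- matrix(0, p, p)
  for (pen in penalties) {
    idx <- pen$cols
    Slam[idx, idx] <- Slam[idx, idx] + pen$lambda * pen$S
  }
  fit <- pirls_engine(X, y, Slam, tol = tol, maxit = maxit)
  ybar <- mean(y)
  fit$null_deviance <- if (ybar > 0) poisson_deviance(y, rep(ybar, length(y))) else 0
  fit
}

## Core IRLS loop for a fixed total penalty matrix, with step halving on
## the penalized deviance (the standard safeguard against Newton overshoot
## on sparse or spiky count data).
pirls_engine <- function(X, y, Slam, tol = 1e-8, maxit = 100, start = NULL) {
  n <- nrow(X); p <- ncol(X)
  clamp <- function(e) pmin(pmax(e, -30), 30)
  if (is.null(start)) {
    beta <- numeric(p)
    if (all(X[, 1] == 1)) beta[1] <- log(mean(y) + 1e-4)
  } else {
    beta <- as.numeric(start)
  }
  pdev_of <- function(b) {
    mu <- exp(clamp(as.numeric(X %*% b)))
    poisson_deviance(y, mu) + drop(b %*% Slam %*% b)
  }
  eta <- clamp(as.numeric(X %*% beta))
  mu <- exp(eta)
  dev <- poisson_deviance(y, mu)
  pdev <- dev + drop(beta %*% Slam %*% beta)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    w <- mu
    z <- eta + (y - mu) / mu
    XtWX <- crossprod(X * w, X)
    XtWz <- crossprod(X, w * z)
    A <- XtWX + Slam
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) {
      qx <- qr(X)
      bad <- if (qx$rank < p) {
        colnames(X)[qx$pivot[(qx$rank + 1):p]]
      } else {
        ## numerically degenerate under the current weights (e.g. a factor
        ## level whose fitted rate collapsed to zero: quasi-separation)
        d <- diag(XtWX)
        colnames(X)[d < 1e-10 * max(d)]
      }
      stop("design is rank deficient or degenerate; offending column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    beta_new <- as.numeric(backsolve(R, forwardsolve(t(R), XtWz)))
    pdev_new <- pdev_of(beta_new)
    halvings <- 0L
    while ((!is.finite(pdev_new) || pdev_new > pdev + 1e-7 * (abs(pdev) + 1))
           && halvings < 30L) {
      beta_new <- (beta_new + beta) / 2
      pdev_new <- pdev_of(beta_new)
      halvings <- halvings + 1L
    }
    if (halvings == 30L && pdev_new > pdev) {
      converged <- TRUE                      # no further descent possible
      break
    }
    beta <- beta_new
    eta <- clamp(as.numeric(X %*% beta))
    mu <- exp(eta)
    dev_new <- poisson_deviance(y, mu)
    trace <- c(trace, dev_new)
    done <- abs(pdev_new - pdev) < tol * (abs(pdev_new) + 0.1)
    pdev <- pdev_new
    dev <- dev_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf(paste0("penalized IRLS did not converge in %d iterations; ",
                        "deviance trace tail: %s"), maxit,
                 paste(signif(utils::tail(trace, 5), 8), collapse = ", ")),
         call. = FALSE)
  }
  w <- mu
  XtWX <- crossprod(X * w, X)
  Vb <- chol2inv(chol(XtWX + Slam))
  edf <- rowSums(Vb * t(XtWX))              # diag(Vb %*% XtWX)
  list(coefficients = stats::setNames(beta, colnames(X)),
       vcov = Vb, XtWX = XtWX, deviance = dev, edf = edf,
       fitted = mu, linear_predictor = eta, iter = iter)
}

#' Data-driven smoothing-parameter selection
#'
#' Selects one smoothing parameter per penalty block by minimizing a
#' prediction-error score over a log-spaced grid, by coordinate descent
#' (two sweeps per outer step). Two criteria are available: `"UBRE"`
#' (default), the AIC-type unbiased-risk score `deviance + 2 * edf` of the
#' actual Poisson fit implied by the working coefficients, and `"GCV"`,
#' generalized cross-validation `n * RSS_w / (n - edf)^2` of the working
#' penalized least-squares problem. The IRLS weights are frozen at the
#' current fit between sweeps (performance iteration) and the model is
#' refitted at the selected parameters, which makes the search
#' deterministic and cheap: each candidate costs one p x p Cholesky solve.
#'
#' @param X Design matrix.
#' @param y Non-negative response.
#' @param penalties List of `list(cols, S, lambda)` blocks (`lambda` is the
#'   starting value).
#' @param grid Candidate smoothing parameters (log-spaced).
#' @param criterion `"UBRE"` or `"GCV"`.
#' @param sweeps Coordinate-descent sweeps per outer step.
#' @param outer Outer IRLS/selection alternations.
#' @param tol,maxit IRLS control.
#' @return The input `penalties` with selected `lambda` values; attributes
#'   `gcv` (score of the final sweep per block, a matrix grid x block) and
#'   `edge` (TRUE where the optimum sat on the grid boundary, also warned).
#' @export
select_smoothing <- function(X, y, penalties, grid = 10^seq(-4, 10, by = 1),
                             criterion = c("UBRE", "GCV"),
                             sweeps = 2, outer = 2, tol = 1e-8, maxit = 100) {
  if (!length(penalties)) return(penalties)
  criterion <- match.arg(criterion)
  p <- ncol(X)
  nb <- length(penalties)
  lam <- vapply(penalties, `[[`, 0, "lambda")
  Sfull <- lapply(penalties, function(pen) {
    S <- matrix(0, p, p)
    S[pen$cols, pen$cols] <- pen$S
    S
  })
  scores <- matrix(NA_real_, length(grid), nb)
  start <- NULL
  n <- length(y)
  for (step in seq_len(outer)) {
    Slam <- Reduce(`+`, Map(`*`, Sfull, lam))
    fit <- pirls_engine(X, y, Slam, tol = tol, maxit = maxit, start = start)
    start <- fit$coefficients
    mu <- fit$fitted
    w <- mu
    z <- fit$linear_predictor + (y - mu) / mu
    XtWX <- crossprod(X * w, X)
    XtWz <- crossprod(X, w * z)
    zWz <- sum(w * z^2)
    score_at <- function(lam_try) {
      A <- XtWX + Reduce(`+`, Map(`*`, Sfull, lam_try))
      R <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(R)) return(Inf)
      beta <- backsolve(R, forwardsolve(t(R), XtWz))
      Ainv <- chol2inv(R)
      edf <- sum(Ainv * t(XtWX))
      if (criterion == "GCV") {
        rss <- zWz - 2 * sum(beta * XtWz) + sum(beta * (XtWX %*% beta))
        n * rss / (n - edf)^2
      } else {
        eta <- pmin(pmax(as.numeric(X %*% beta), -30), 30)
        poisson_deviance(y, exp(eta)) + 2 * edf
      }
    }
    for (sweep in seq_len(sweeps)) {
      for (j in seq_len(nb)) {
        for (g in seq_along(grid)) {
          lam_try <- lam
          lam_try[j] <- grid[g]
          scores[g, j] <- score_at(lam_try)
        }
        lam[j] <- grid[which.min(scores[, j])]
      }
    }
  }
  edge <- lam %in% range(grid)
  if (any(edge)) {
    warning("smoothing criterion optimum at grid edge for penalty block(s) ",
            paste(which(edge), collapse = ", "), call. = FALSE)
  }
  for (j in seq_len(nb)) penalties[[j]]$lambda <- lam[j]
  attr(penalties, "gcv") <- scores
  attr(penalties, "edge") <- edge
  penalties
}

## Build the full design matrix and penalty blocks for a model frame.
gapm_design <- function(frame, spec) {
  n <- nrow(frame)
  stop_if_not(n > 0L, "model frame is empty")
  miss <- setdiff(spec$linear, names(frame))
  stop_if_not(length(miss) == 0L,
              paste("covariate(s) missing from frame:",
                    paste(miss, collapse = ", ")))

  sites <- sort(unique(as.character(frame$site_id)))
  ref <- if (spec$reference_site %in% sites) spec$reference_site else sites[1]
  others <- setdiff(sites, ref)
  Xs <- NULL
  if (length(sites) >= 2L) {
    Xs <- sapply(others, function(s) as.numeric(frame$site_id == s))
    colnames(Xs) <- paste0("site:", others)
  } else if (length(sites) == 1L && !is.null(frame$site_id)) {
    others <- character()
  }

  Xl <- as.matrix(frame[, spec$linear, drop = FALSE])
  colnames(Xl) <- spec$linear

  b1 <- cyclic_basis(frame$ST, spec$k_st, c(-1, 1), spec$knot_placement)
  c1 <- apply_sum_to_zero(cyclic_design(b1, frame$ST))
  b2 <- cyclic_basis(frame$DOY, spec$k_doy, spec$doy_period,
                     spec$knot_placement)
  c2 <- apply_sum_to_zero(cyclic_design(b2, frame$DOY))

  blocks <- list(intercept = 1L)
  X <- cbind("(Intercept)" = rep(1, n))
  if (!is.null(Xs)) {
    blocks$site <- ncol(X) + seq_len(ncol(Xs)); X <- cbind(X, Xs)
  }
  blocks$linear <- ncol(X) + seq_len(ncol(Xl)); X <- cbind(X, Xl)
  X1 <- c1$X; colnames(X1) <- paste0("f1.", seq_len(ncol(X1)))
  blocks$f1 <- ncol(X) + seq_len(ncol(X1)); X <- cbind(X, X1)
  X2 <- c2$X; colnames(X2) <- paste0("f2.", seq_len(ncol(X2)))
  blocks$f2 <- ncol(X) + seq_len(ncol(X2)); X <- cbind(X, X2)

  ## normalize each penalty to unit Frobenius norm so one lambda grid serves
  ## smooths whose raw second-derivative penalties differ by orders of magnitude
  normS <- function(S) S / sqrt(sum(S^2))
  penalties <- list(
    list(cols = blocks$f1, S = normS(crossprod(c1$Z, b1$S %*% c1$Z)),
         lambda = spec$lambda[1]),
    list(cols = blocks$f2, S = normS(crossprod(c2$Z, b2$S %*% c2$Z)),
         lambda = spec$lambda[min(2, length(spec$lambda))])
  )
  names(penalties) <- c("f1", "f2")

  tb <- NULL
  if (spec$use_f3) {
    bt1 <- cyclic_basis(frame$ST, spec$k_tensor, c(-1, 1), spec$knot_placement)
    bt2 <- cyclic_basis(frame$DOY, spec$k_tensor, spec$doy_period,
                        spec$knot_placement)
    tb <- build_tensor_basis(bt1, bt2, frame$ST, frame$DOY)
    Xt <- tb$X; colnames(Xt) <- paste0("f3.", seq_len(ncol(Xt)))
    blocks$f3 <- ncol(X) + seq_len(ncol(Xt)); X <- cbind(X, Xt)
    lam3 <- spec$lambda[min(3, length(spec$lambda))]
    lam4 <- spec$lambda[min(4, length(spec$lambda))]
    penalties$f3_st <- list(cols = blocks$f3, S = normS(tb$S1), lambda = lam3)
    penalties$f3_doy <- list(cols = blocks$f3, S = normS(tb$S2), lambda = lam4)
  }

  list(X = X, blocks = blocks, penalties = penalties,
       bases = list(b1 = b1, Z1 = c1$Z, b2 = b2, Z2 = c2$Z, tensor = tb),
       sites = sites, reference = ref, site_cols = others)
}

#' Fit the generalized additive Poisson activity model
#'
#' Fits the hourly activity model
#' `log(mu) = alpha + site + beta' x + f1(ST) + f2(DOY) + f3(ST, DOY)`
#' to a model frame by penalized IRLS, selecting smoothing parameters by GCV
#' (or using fixed values). Refitting the same frame with the same spec is
#' bit-stable.
#'
#' @param frame Model frame from [assemble_model_frame()] (any data frame
#'   with `y`, the linear covariates, `ST`, `DOY` and `site_id` works).
#' @param spec A [gapm_spec()].
#' @return Object of class `gapm` with coefficients, covariance, smoothing
#'   parameters, deviances, effective degrees of freedom and the basis
#'   objects needed for prediction.
#' @seealso [predict.gapm()], [wald_tests()], [smooth_significance()],
#'   [deviance_explained()]
#' @export
fit_gapm <- function(frame, spec = gapm_spec()) {
  stop_if_not(inherits(spec, "gapm_spec"), "`spec` must be a gapm_spec")
  stop_if_not(nrow(frame) > 0L, "model frame is empty")
  y <- frame$y
  stop_if_not(all(y >= 0), "response must be non-negative")
  if (sum(y) == 0) {
    stop("response is identically zero: the Poisson mean lies on the ",
         "boundary (intercept at -Inf); no model fitted", call. = FALSE)
  }
  n_sites <- length(unique(as.character(frame$site_id)))
  if (n_sites < 2L) {
    warning("fewer than 2 sites: site factor dropped", call. = FALSE)
  }
  des <- gapm_design(frame, spec)

  penalties <- des$penalties
  if (spec$method %in% c("UBRE", "GCV") && length(penalties)) {
    penalties <- select_smoothing(des$X, y, penalties,
                                  grid = spec$lambda_grid,
                                  criterion = spec$method,
                                  tol = spec$tol, maxit = spec$maxit)
  }
  fit <- penalized_irls(des$X, y, penalties, tol = spec$tol,
                        maxit = spec$maxit)

  coefs <- fit$coefficients
  blocks <- des$blocks
  edf_smooth <- vapply(intersect(c("f1", "f2", "f3"), names(blocks)),
                       function(b) sum(fit$edf[blocks[[b]]]), 0)
  cov_ranges <- lapply(frame[, c(spec$linear, "ST", "DOY"), drop = FALSE],
                       range)

  structure(list(
    coefficients = coefs,
    alpha = unname(coefs[1]),
    site_coefficients = if (!is.null(blocks$site)) coefs[blocks$site] else numeric(),
    beta = coefs[blocks$linear],
    vcov = fit$vcov,
    blocks = blocks,
    lambda = vapply(penalties, `[[`, 0, "lambda"),
    gcv = attr(penalties, "gcv"),
    deviance = fit$deviance,
    null_deviance = fit$null_deviance,
    edf = fit$edf,
    edf_smooth = edf_smooth,
    n_obs = nrow(frame),
    iter = fit$iter,
    spec = spec,
    bases = des$bases,
    sites = des$sites,
    reference = des$reference,
    site_cols = des$site_cols,
    cov_ranges = cov_ranges,
    fitted = fit$fitted,
    y = y,
    species = if (!is.null(frame$species)) as.character(frame$species[1]) else "species"
  ), class = "gapm")
}

#' @export
print.gapm <- function(x, ...) {
  cat("Generalized additive Poisson activity model\n")
  cat(sprintf("  n = %d site-hours over %d site(s), reference %s\n",
              x$n_obs, length(x$sites), x$reference))
  cat(sprintf("  deviance explained: %.3f  (deviance %.1f, null %.1f)\n",
              deviance_explained(x), x$deviance, x$null_deviance))
  cat("  smoothing parameters:",
      paste(sprintf("%s=%.3g", names(x$lambda), x$lambda), collapse = ", "),
      "\n")
  invisible(x)
}

#' Wald tests of the parametric coefficients
#'
#' Per-coefficient estimate, standard error, z value, two-sided normal
#' p-value and significance stars at the conventional 0.05 / 0.01 / 0.001
#' thresholds, for the intercept, site and linear weather terms.
#'
#' @param fit A fitted [fit_gapm()] model.
#' @return Data frame with one row per parametric coefficient.
#' @export
wald_tests <- function(fit) {
  stop_if_not(inherits(fit, "gapm"), "`fit` must be a gapm")
  idx <- c(fit$blocks$intercept, fit$blocks$site, fit$blocks$linear)
  est <- fit$coefficients[idx]
  se <- sqrt(diag(fit$vcov)[idx])
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(p), stars = p_stars(p),
             row.names = NULL)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Approximate significance of the smooth terms
#'
#' Wald-type chi-squared test per smooth: the quadratic form of the smooth's
#' coefficient block against a rank-truncated pseudo-inverse of its
#' covariance block, referred to a chi-squared distribution with rank equal
#' to the rounded effective degrees of freedom (at least 1). This is the
#' plain Wald reading of the smooth test; more refined randomized-df
#' corrections are deliberately not applied.
#'
#' @param fit A fitted [fit_gapm()] model.
#' @return Data frame with columns `smooth`, `statistic`, `df`, `p`, `stars`.
#' @export
smooth_significance <- function(fit) {
  stop_if_not(inherits(fit, "gapm"), "`fit` must be a gapm")
  smooths <- intersect(c("f1", "f2", "f3"), names(fit$blocks))
  rows <- lapply(smooths, function(s) {
    idx <- fit$blocks[[s]]
    b <- fit$coefficients[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    edf <- sum(fit$edf[idx])
    r <- min(length(idx), max(1L, round(edf)))
    eg <- eigen(V, symmetric = TRUE)
    keep <- seq_len(r)
    stat <- sum((crossprod(eg$vectors[, keep, drop = FALSE], b))^2 /
                  pmax(eg$values[keep], 1e-12))
    p <- stats::pchisq(stat, df = r, lower.tail = FALSE)
    data.frame(smooth = s, statistic = stat, df = r, edf = edf, p = p,
               stars = p_stars(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportion of deviance explained
#'
#' `1 - deviance / null deviance`: the share of the deviation from the
#' constant-mean model captured by the fit.
#'
#' @param fit A fitted [fit_gapm()] model.
#' @return A number in `[0, 1]` for intercept-containing fits.
#' @export
deviance_explained <- function(fit) {
  stop_if_not(inherits(fit, "gapm"), "`fit` must be a gapm")
  1 - fit$deviance / fit$null_deviance
}

#' Predict from a fitted activity model
#'
#' Component-selective prediction: any subset of the intercept, site,
#' linear, `f1`, `f2` and `f3` components can be summed on the link scale,
#' or exponentiated to the response scale. With all components on the
#' response scale this is the predicted hourly movement rate.
#'
#' @param object A fitted [fit_gapm()] model.
#' @param newdata Data frame with the covariates the requested components
#'   need (`site_id`, linear covariates, `ST`, `DOY`). Defaults to refitting
#'   covariate columns are not stored, so `newdata` is required.
#' @param components Subset of `c("intercept", "site", "linear", "f1", "f2",
#'   "f3")`; default all fitted components.
#' @param type `"link"` (sum of selected components) or `"response"`
#'   (its exponential).
#' @param ... Unused.
#' @return Numeric vector of predictions. Covariates outside the fitted
#'   range trigger an extrapolation warning.
#' @export
predict.gapm <- function(object, newdata,
                         components = c("intercept", "site", "linear",
                                        "f1", "f2", "f3"),
                         type = c("link", "response"), ...) {
  type <- match.arg(type)
  components <- match.arg(components, several.ok = TRUE)
  components <- intersect(components, c(names(object$blocks)))
  n <- nrow(newdata)
  eta <- numeric(n)
  cf <- object$coefficients
  bl <- object$blocks

  used <- intersect(components, c("linear", "f1", "f2", "f3"))
  if (length(used)) {
    vars <- c(if ("linear" %in% used) object$spec$linear,
              if (any(c("f1", "f3") %in% used)) "ST",
              if (any(c("f2", "f3") %in% used)) "DOY")
    for (v in intersect(vars, names(object$cov_ranges))) {
      r <- object$cov_ranges[[v]]
      if (any(newdata[[v]] < r[1] - 1e-9 | newdata[[v]] > r[2] + 1e-9, na.rm = TRUE))
        warning("extrapolating beyond the fitted range of ", v, call. = FALSE)
    }
  }

  if ("intercept" %in% components) eta <- eta + cf[bl$intercept]
  if ("site" %in% components && !is.null(bl$site)) {
    site <- as.character(newdata$site_id)
    unknown <- setdiff(unique(site), object$sites)
    stop_if_not(length(unknown) == 0L,
                paste("unknown site(s):", paste(unknown, collapse = ", ")))
    sc <- c(stats::setNames(0, object$reference),
            stats::setNames(cf[bl$site], object$site_cols))
    eta <- eta + sc[site]
  }
  if ("linear" %in% components) {
    Xl <- as.matrix(newdata[, object$spec$linear, drop = FALSE])
    eta <- eta + as.numeric(Xl %*% cf[bl$linear])
  }
  if ("f1" %in% components) {
    X1 <- cyclic_design(object$bases$b1, newdata$ST) %*% object$bases$Z1
    eta <- eta + as.numeric(X1 %*% cf[bl$f1])
  }
  if ("f2" %in% components) {
    X2 <- cyclic_design(object$bases$b2, newdata$DOY) %*% object$bases$Z2
    eta <- eta + as.numeric(X2 %*% cf[bl$f2])
  }
  if ("f3" %in% components && !is.null(bl$f3)) {
    Xt <- tensor_design(object$bases$tensor, newdata$ST, newdata$DOY)
    eta <- eta + as.numeric(Xt %*% cf[bl$f3])
  }
  eta <- unname(eta)
  if (type == "response") exp(eta) else eta
}

#' Coefficient table in the style of the published six-model report
#'
#' Renders one or more fitted models as a long-format report: site
#' coefficients, weather coefficients with standard errors and significance
#' stars, approximate smooth-term significances, deviance explained and the
#' number of observations.
#'
#' @param fits A named list of fitted [fit_gapm()] models (one per species).
#' @return Data frame with columns `species`, `section`, `term`, `estimate`,
#'   `se`, `stars`.
#' @export
gapm_report <- function(fits) {
  if (inherits(fits, "gapm")) fits <- list(model = fits)
  rows <- lapply(names(fits), function(sp) {
    fit <- fits[[sp]]
    wt <- wald_tests(fit)
    sig <- smooth_significance(fit)
    is_site <- grepl("^site:", wt$term)
    rbind(
      data.frame(species = sp,
                 section = ifelse(is_site | wt$term == "(Intercept)",
                                  "site", "weather"),
                 term = wt$term, estimate = wt$estimate, se = wt$se,
                 stars = wt$stars),
      data.frame(species = sp, section = "smooth", term = sig$smooth,
                 estimate = sig$statistic, se = NA_real_, stars = sig$stars),
      data.frame(species = sp, section = "fit",
                 term = c("deviance_explained", "n_obs"),
                 estimate = c(deviance_explained(fit), fit$n_obs),
                 se = NA_real_, stars = "")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
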