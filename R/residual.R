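#' Weather-independent ("residual") activity curve
#'
#' Extracts the partial effect of the day-of-year smooth from a fitted
#' model: the predicted activity attributable to `DOY` alone, regardless of
#' the weather covariates, on the link scale and sum-to-zero centred so that
#' zero means "fully explained by the other terms". Positive values mark
#' days with more activity than the weather accounts for; negative values
#' mark days when even favourable weather produces little activity.
#'
#' @param fit A fitted [fit_gapm()] model.
#' @param doy_grid Integer day grid (default 0:136).
#' @param include_f3 Also add the interaction smooth marginalized over an
#'   even grid of sun times (default FALSE: `f2` only, since the interaction
#'   involves sun time and is not a function of DOY alone).
#' @return Object of class `residual_activity_curve`: data frame with
#'   columns `species`, `doy`, `value`.
#' @export
residual_activity <- function(fit, doy_grid = 0:136, include_f3 = FALSE) {
  stop_if_not(inherits(fit, "gapm"), "`fit` must be a gapm")
  nd <- data.frame(DOY = doy_grid)
  val <- predict(fit, nd, components = "f2", type = "link")
  if (include_f3 && !is.null(fit$blocks$f3)) {
    st_grid <- seq(-1, 1, length.out = 41)[-41]
    f3m <- vapply(doy_grid, function(d) {
      mean(predict(fit, data.frame(ST = st_grid, DOY = d),
                   components = "f3", type = "link"))
    }, 0)
    val <- val + f3m
  }
  val <- val - mean(val)
  species <- fit$species %||% "species"
  structure(data.frame(species = species, doy = doy_grid, value = val),
            class = c("residual_activity_curve", "data.frame"))
}

#' Median absolute residual activity
#'
#' The median over the day grid of the absolute residual activity: the
#' headline statistic by which species are ranked (larger = activity less
#' dependent on the measured weather).
#'
#' @param curve A [residual_activity()] curve.
#' @return A single non-negative number.
#' @export
median_abs_residual <- function(curve) {
  stats::median(abs(curve$value))
}

#' Classify species into residual-activity functional groups
#'
#' Ranks species by decreasing median absolute residual activity, runs a
#' Kruskal-Wallis omnibus test on the per-day absolute values followed by
#' all pairwise Mann-Whitney tests with Bonferroni correction (p times the
#' number of pairs, capped at 1), builds a compact letter display greedily
#' from the non-significant pairs, and labels species tiers as
#' high/medium/low residual activity (HRA/MRA/LRA) by rank thirds of the
#' letter groups.
#'
#' @param curves Named list of [residual_activity()] curves (>= 2 species),
#'   or a single long data frame with `species`, `doy`, `value`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param labels Tier labels from highest to lowest residual activity.
#' @return Object of class `group_assignment`: list with `ranking` (data
#'   frame: species, median_abs, letters, label), `p_adjusted` (pairwise
#'   matrix), `p_raw`, `kruskal_p`.
#' @export
classify_groups <- function(curves, alpha = 0.05,
                            labels = c("HRA", "MRA", "LRA")) {
  if (is.data.frame(curves)) {
    curves <- split(curves, curves$species)
  }
  stop_if_not(length(curves) >= 2L, "need at least 2 species to classify")
  vals <- lapply(curves, function(cv) abs(cv$value))
  if (is.null(names(vals)) || any(names(vals) == "")) {
    names(vals) <- vapply(curves, function(cv) as.character(cv$species[1]), "")
  }
  med <- vapply(vals, stats::median, 0)
  ord <- order(-med)
  vals <- vals[ord]; med <- med[ord]
  k <- length(vals)

  kw <- stats::kruskal.test(vals)
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  p_raw <- matrix(NA_real_, k, k, dimnames = list(names(vals), names(vals)))
  for (j in seq_len(n_pairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    p <- suppressWarnings(stats::wilcox.test(vals[[a]], vals[[b]],
                                             exact = FALSE)$p.value)
    p_raw[a, b] <- p_raw[b, a] <- p
  }
  p_adj <- pmin(p_raw * n_pairs, 1)

  ## compact letter display: greedy placement in rank order
  nonsig <- function(a, b) p_adj[a, b] >= alpha
  groups <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(vapply(groups[[g]], function(j) nonsig(i, j), TRUE))) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  letters_per_sp <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(groups, function(g) i %in% g, TRUE))],
          collapse = "")
  }, "")

  ## tier labels by rank thirds of the letter groups
  group_rank <- vapply(groups, function(g) mean(match(g, seq_len(k))), 0)
  tier_of_group <- ceiling(rank(group_rank, ties.method = "first") /
                             length(groups) * 3)
  tier_of_group <- pmin(pmax(tier_of_group, 1L), 3L)
  sp_tier <- vapply(seq_len(k), function(i) {
    min(tier_of_group[vapply(groups, function(g) i %in% g, TRUE)])
  }, 0)

  ranking <- data.frame(species = names(vals), median_abs = unname(med),
                        letters = letters_per_sp,
                        label = labels[sp_tier], row.names = NULL)
  structure(list(ranking = ranking, p_adjusted = p_adj, p_raw = p_raw,
                 kruskal_p = kw$p.value, alpha = alpha),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Residual-activity functional groups",
      sprintf("(Kruskal-Wallis p = %.3g, alpha = %g)\n", x$kruskal_p, x$alpha))
  print(x$ranking)
  invisible(x)
}
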