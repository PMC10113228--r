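#' Pipeline configuration
#'
#' Loads (from a YAML file) or validates (from a list) the configuration of
#' the end-to-end pipeline: input paths or simulation settings, site
#' coordinates, species, analysis window, model settings, seeds and the
#' group-test level.
#'
#' @param x Path to a YAML file, or a named list with the same structure.
#' @return Object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(system.file("extdata", "demo_config.yaml",
#'                                    package = "batgapm"))
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) {
    stop_if_not(file.exists(x), paste("no such config file:", x))
    yaml::read_yaml(x)
  } else {
    stop_if_not(is.list(x), "`x` must be a path or a list")
    x
  }
  stop_if_not(!is.null(cfg$output_dir), "config needs `output_dir`")
  stop_if_not(!is.null(cfg$sites) && length(cfg$sites) >= 1L,
              "config needs at least one site")
  cfg$day_max <- cfg$day_max %||% 136
  stop_if_not(cfg$day_max >= 2 && cfg$day_max <= 366,
              "`day_max` must be in [2, 366]")
  cfg$seed <- cfg$seed %||% 1L
  cfg$min_rows <- cfg$min_rows %||% 100L
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$model <- cfg$model %||% list()
  if (is.null(cfg$simulate)) {
    stop_if_not(!is.null(cfg$events) && !is.null(cfg$weather),
                "config needs `events` and `weather` paths (or a `simulate` block)")
  }
  cfg$site_configs <- lapply(cfg$sites, function(s) {
    site_config(s$site_id, s$latitude, s$longitude, s$activity_scale %||% 0)
  })
  structure(cfg, class = c("pipeline_config", "list"))
}

config_spec <- function(cfg) {
  m <- cfg$model
  gapm_spec(
    reference_site = m$reference_site %||% "Mayen-Mauerstollen",
    k_st = m$k_st %||% 10, k_doy = m$k_doy %||% 20,
    k_tensor = m$k_tensor %||% 5,
    use_f3 = m$use_f3 %||% TRUE,
    method = m$method %||% "UBRE",
    lambda = unlist(m$lambda %||% 1)
  )
}

#' Run the full emergence-analysis pipeline
#'
#' Executes (optionally) simulation, then preprocessing, per-species model
#' fitting, residual-activity analysis and emergence summaries, writing all
#' artifacts to the configured output directory: `events.csv` /
#' `weather.csv` (when simulating), `model_frame.csv`, `report.csv`
#' (coefficient table across species), `<species>_model.json` bundles,
#' `curves.csv`, `groups.csv`, `emergence.csv`, `regressions.csv` and
#' `log.txt` with row-drop accounting. Fully deterministic given the
#' configured seed.
#'
#' Species whose model frame has fewer than `min_rows` rows (or an all-zero
#' response) are skipped with a logged reason. Group classification needs at
#' least two fitted species; cross-species regressions at least three.
#'
#' @param config A [pipeline_config()], YAML path, or list.
#' @param stages Subset of `c("simulate", "preprocess", "fit", "residuals",
#'   "emergence")`; later stages reuse intermediates in `output_dir` when an
#'   earlier stage is not rerun.
#' @return Invisibly, the output directory, with attributes `fits`,
#'   `curves`, `groups`, `emergence`, `regressions`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "fit",
                                    "residuals", "emergence")) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$output_dir, "log.txt")
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  sites <- cfg$site_configs
  site_ids <- vapply(sites, `[[`, "", "site_id")

  events_path <- cfg$events %||% file.path(cfg$output_dir, "events.csv")
  weather_path <- cfg$weather %||% file.path(cfg$output_dir, "weather.csv")

  if ("simulate" %in% stages && !is.null(cfg$simulate)) {
    sim <- cfg$simulate
    presets <- species_presets(sim$species)
    weather <- simulate_weather(sites, sim$start_date %||% "2015-01-01",
                                n_days = sim$n_days %||% 136,
                                seed = cfg$seed)
    events <- do.call(rbind, lapply(names(presets), function(sp) {
      tm <- presets[[sp]]
      occupied <- intersect(site_ids, attr(tm, "sites") %||% site_ids)
      if (!length(occupied)) return(NULL)
      simulate_activity(tm, weather[weather$site_id %in% occupied, ,
                                    drop = FALSE],
                        sites[site_ids %in% occupied],
                        seed = cfg$seed + match(sp, names(presets)),
                        species = sp)
    }))
    if (length(cfg$gaps %||% list())) {
      gi <- inject_gaps(events, cfg$gaps, weather, cfg$missing %||% list())
      events <- gi$events; weather <- gi$weather
      say("gap injection: removed %d events, blanked %d site-hours",
          gi$log["removed_events"], gi$log["blanked_hours"])
    }
    write_events(events, events_path)
    write_weather(weather, weather_path)
    say("simulated %d events over %d sites", nrow(events), length(sites))
  }

  result <- structure(cfg$output_dir, fits = NULL)
  if (any(c("preprocess", "fit", "residuals", "emergence") %in% stages)) {
    events <- read_events(events_path)
    weather <- read_weather(weather_path, cfg$weather_dialect %||% "package")
    hourly <- aggregate_hourly(events)
    frames <- lapply(split(hourly, hourly$species), function(h) {
      ## per-species models only include sites where the species occurs
      occupied <- unique(h$site_id[h$n_in + h$n_out > 0])
      absent <- setdiff(unique(h$site_id), occupied)
      if (length(absent)) {
        say("%s: excluded site(s) without any activity: %s", h$species[1],
            paste(absent, collapse = ", "))
        h <- h[h$site_id %in% occupied, , drop = FALSE]
      }
      fr <- assemble_model_frame(h, weather, sites, day_max = cfg$day_max)
      d <- attr(fr, "drops")
      say("%s: %d hourly rows -> %d frame rows (dropped: %d beyond day %d, %d missing covariates)",
          h$species[1], nrow(h), nrow(fr), d["day_beyond_max"], cfg$day_max,
          d["missing_covariate"])
      fr
    })
    frame_all <- do.call(rbind, frames)
    utils::write.csv(format_frame(frame_all),
                     file.path(cfg$output_dir, "model_frame.csv"),
                     row.names = FALSE, quote = FALSE)

    if (any(c("fit", "residuals", "emergence") %in% stages)) {
      spec <- config_spec(cfg)
      fits <- list(); curves <- list(); summaries <- list()
      for (sp in names(frames)) {
        fr <- frames[[sp]]
        if (nrow(fr) < cfg$min_rows) {
          say("%s: skipped (%d rows < min_rows %d)", sp, nrow(fr), cfg$min_rows)
          next
        }
        if (sum(fr$y) == 0) {
          say("%s: skipped (all-zero response)", sp)
          next
        }
        fit <- fit_gapm(fr, spec)
        fits[[sp]] <- fit
        gapm_save(fit, file.path(cfg$output_dir,
                                 paste0(gsub("[^A-Za-z0-9._-]", "_", sp),
                                        "_model.json")))
        say("%s: fitted on %d rows, deviance explained %.3f", sp,
            fit$n_obs, deviance_explained(fit))
        if (any(c("residuals", "emergence") %in% stages)) {
          curves[[sp]] <- residual_activity(fit, 0:min(cfg$day_max, max(fr$DOY)))
        }
        if ("emergence" %in% stages) {
          daily <- daily_predicted_activity(fit, fr)
          summaries[[sp]] <- emergence_summary(daily, curves[[sp]])
        }
      }
      report <- gapm_report(fits)
      utils::write.csv(format_num(report),
                       file.path(cfg$output_dir, "report.csv"),
                       row.names = FALSE, quote = FALSE)
      attr(result, "fits") <- fits

      if ("residuals" %in% stages && length(curves)) {
        utils::write.csv(format_num(do.call(rbind, curves)),
                         file.path(cfg$output_dir, "curves.csv"),
                         row.names = FALSE, quote = FALSE)
        if (length(curves) >= 2L) {
          groups <- classify_groups(curves, alpha = cfg$alpha)
          utils::write.csv(format_num(groups$ranking),
                           file.path(cfg$output_dir, "groups.csv"),
                           row.names = FALSE, quote = FALSE)
          pmat <- as.data.frame(groups$p_adjusted)
          pmat <- cbind(species = rownames(groups$p_adjusted), pmat)
          utils::write.csv(format_num(pmat),
                           file.path(cfg$output_dir, "groups_pmatrix.csv"),
                           row.names = FALSE, quote = FALSE)
          attr(result, "groups") <- groups
        } else say("fewer than 2 fitted species: no group classification")
        attr(result, "curves") <- curves
      }
      if ("emergence" %in% stages && length(summaries)) {
        em <- do.call(rbind, summaries)
        utils::write.csv(format_num(em),
                         file.path(cfg$output_dir, "emergence.csv"),
                         row.names = FALSE, quote = FALSE)
        attr(result, "emergence") <- em
        if (nrow(em) >= 3L) {
          reg <- cross_species_regression(em)
          utils::write.csv(format_num(reg),
                           file.path(cfg$output_dir, "regressions.csv"),
                           row.names = FALSE, quote = FALSE)
          attr(result, "regressions") <- reg
        } else say("fewer than 3 fitted species: no cross-species regression")
      }
    }
  }
  writeLines(log_lines, logf)
  invisible(result)
}

## Stable numeric formatting so reruns are byte-identical.
format_num <- function(df) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  df
}

format_frame <- function(fr) {
  fr$hour <- format(fr$hour, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  format_num(fr)
}
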