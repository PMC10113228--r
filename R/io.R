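## Tolerant timestamp parser: ISO-8601 with T or space separator, bare dates,
## and the compact YYYYMMDDHH hour stamp; unparseable entries become NA.
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y%m%d%H",
                "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = fmt)
  }
  out
}

#' Read and write event streams
#'
#' Events are CSV with columns `timestamp` (ISO-8601), `site_id`, `species`,
#' `direction` (`"in"`/`"out"`). Malformed rows (unparseable timestamp or
#' unknown direction) are rejected with a counted warning.
#'
#' @param path CSV file path.
#' @return `read_events`: data frame of events with POSIXct timestamps (UTC).
#' @export
read_events <- function(path) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "site_id", "species", "direction")
  miss <- setdiff(need, names(raw))
  stop_if_not(length(miss) == 0L,
              paste("event file lacks column(s):", paste(miss, collapse = ", ")))
  ts <- parse_timestamp(raw$timestamp)
  bad <- is.na(ts) | !(raw$direction %in% c("in", "out"))
  if (any(bad)) {
    warning(sum(bad), " malformed event row(s) rejected", call. = FALSE)
  }
  out <- data.frame(timestamp = ts[!bad], site_id = raw$site_id[!bad],
                    species = raw$species[!bad], direction = raw$direction[!bad])
  out
}

#' @rdname read_events
#' @param events Event data frame.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    timestamp = format(events$timestamp, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
    site_id = events$site_id, species = events$species,
    direction = events$direction
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write hourly weather tables
#'
#' The package dialect is CSV with columns `site_id`, `timestamp`, `T_S`,
#' `T_A`, `AP`, `WS`, `PR`, `CC`. The `"dwd-like"` dialect accepts the
#' column names of German Meteorological Service hourly products
#' (`STATIONS_ID`, `MESS_DATUM`, `TT_TU` air temperature, `V_TE020` soil
#' temperature at 20 cm, `P` pressure, `F` wind, `R1` precipitation, `V_N`
#' cloud cover) and normalizes the -999 missing sentinel to `NA`.
#'
#' @param path CSV file path.
#' @param dialect `"package"` or `"dwd-like"`.
#' @return `read_weather`: weather data frame in package schema.
#' @export
read_weather <- function(path, dialect = "package") {
  if (!dialect %in% c("package", "dwd-like")) {
    stop("unknown weather dialect '", dialect,
         "'; supported: package, dwd-like", call. = FALSE)
  }
  stop_if_not(file.exists(path), paste("no such file:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "dwd-like") {
    map <- c(STATIONS_ID = "site_id", MESS_DATUM = "timestamp",
             V_TE020 = "T_S", TT_TU = "T_A", P = "AP", F = "WS",
             R1 = "PR", V_N = "CC")
    hit <- names(raw) %in% names(map)
    names(raw)[hit] <- map[names(raw)[hit]]
    for (v in c("T_S", "T_A", "AP", "WS", "PR", "CC")) {
      if (v %in% names(raw)) raw[[v]][raw[[v]] <= -999] <- NA
    }
  }
  need <- c("site_id", "timestamp", "T_S", "T_A", "AP", "WS", "PR", "CC")
  miss <- setdiff(need, names(raw))
  stop_if_not(length(miss) == 0L,
              paste("weather file lacks column(s):", paste(miss, collapse = ", ")))
  raw$timestamp <- parse_timestamp(raw$timestamp)
  raw$site_id <- as.character(raw$site_id)
  raw[, need]
}

#' @rdname read_weather
#' @param weather Weather data frame in package schema.
#' @export
write_weather <- function(weather, path) {
  out <- weather
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) round(x, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save and load a fitted model bundle
#'
#' Serializes a fitted model to a single versioned JSON bundle (header plus
#' numeric arrays) holding everything [predict.gapm()] needs; the training
#' response and fitted values are not stored.
#'
#' @param fit A fitted [fit_gapm()] model.
#' @param path Bundle file path.
#' @export
gapm_save <- function(fit, path) {
  stop_if_not(inherits(fit, "gapm"), "`fit` must be a gapm")
  strip_basis <- function(b) b[c("knots", "lo", "hi", "period", "n_basis",
                                 "h", "F", "S")]
  tb <- fit$bases$tensor
  bundle <- list(
    format = "batgapm-bundle", version = 1L,
    species = fit$species,
    coefficients = as.list(fit$coefficients),   # lists keep names in JSON
    vcov = fit$vcov,
    blocks = fit$blocks,
    lambda = as.list(fit$lambda),
    deviance = fit$deviance, null_deviance = fit$null_deviance,
    edf = fit$edf, edf_smooth = fit$edf_smooth,
    n_obs = fit$n_obs, iter = fit$iter,
    spec = unclass(fit$spec),
    sites = fit$sites, reference = fit$reference, site_cols = fit$site_cols,
    cov_ranges = fit$cov_ranges,
    b1 = strip_basis(fit$bases$b1), Z1 = fit$bases$Z1,
    b2 = strip_basis(fit$bases$b2), Z2 = fit$bases$Z2,
    tensor = if (!is.null(tb)) list(b1 = strip_basis(tb$b1),
                                    b2 = strip_basis(tb$b2),
                                    Z1 = tb$Z1, Z2 = tb$Z2) else NULL
  )
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname gapm_save
#' @return `gapm_load`: the reconstructed `gapm` object (without training
#'   data).
#' @export
gapm_load <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if_not(identical(b$format, "batgapm-bundle"),
              "not a batgapm model bundle")
  as_basis <- function(x) {
    x$F <- as.matrix(x$F); x$S <- as.matrix(x$S)
    structure(x, class = "cyclic_basis")
  }
  blocks <- lapply(b$blocks, as.integer)
  tensor <- NULL
  if (!is.null(b$tensor)) {
    tensor <- structure(list(b1 = as_basis(b$tensor$b1),
                             b2 = as_basis(b$tensor$b2),
                             Z1 = as.matrix(b$tensor$Z1),
                             Z2 = as.matrix(b$tensor$Z2)),
                        class = "tensor_basis")
  }
  structure(list(
    coefficients = unlist(b$coefficients),
    alpha = unname(unlist(b$coefficients)[1]),
    site_coefficients = if (!is.null(blocks$site))
      unlist(b$coefficients)[blocks$site] else numeric(),
    beta = unlist(b$coefficients)[blocks$linear],
    vcov = as.matrix(b$vcov),
    blocks = blocks,
    lambda = unlist(b$lambda),
    deviance = b$deviance, null_deviance = b$null_deviance,
    edf = unlist(b$edf), edf_smooth = unlist(b$edf_smooth),
    n_obs = b$n_obs, iter = b$iter,
    spec = structure(b$spec, class = "gapm_spec"),
    bases = list(b1 = as_basis(b$b1), Z1 = as.matrix(b$Z1),
                 b2 = as_basis(b$b2), Z2 = as.matrix(b$Z2),
                 tensor = tensor),
    sites = b$sites, reference = b$reference, site_cols = b$site_cols,
    cov_ranges = b$cov_ranges,
    species = b$species
  ), class = "gapm")
}
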