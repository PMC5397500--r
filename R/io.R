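#' Read per-fruit observation series from CSV
#'
#' Accepts either direct `mass_g` / `hue_deg` columns or the raw
#' measurement columns (`diameter_m`, converted through
#' [mass_from_diameter()]; `a` and `b` chromaticity, converted through
#' [hue_from_lab()]). Expected columns: `fruit_id`, optionally `season`,
#' `t_exp_d`, and one of each measurement pair.
#'
#' @param path CSV file path.
#' @param density Fruit density (kg/m^3) for the diameter conversion.
#' @return A [fruit_observations()] data frame.
#' @export
read_observations <- function(path, density = 873) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"fruit_id" %in% names(d)) stop("missing column: fruit_id")
  if (!"t_exp_d" %in% names(d)) stop("missing column: t_exp_d")
  mass <- if ("mass_g" %in% names(d)) d$mass_g
    else if ("diameter_m" %in% names(d))
      mass_from_diameter(d$diameter_m, density) * 1000
    else stop("need mass_g or diameter_m")
  hue <- if ("hue_deg" %in% names(d)) d$hue_deg
    else if (all(c("a", "b") %in% names(d))) hue_from_lab(d$a, d$b)
    else stop("need hue_deg or a/b chromaticity")
  fruit_observations(d$fruit_id, d$t_exp_d, mass, hue,
                     season = if ("season" %in% names(d)) d$season
                              else NA_character_)
}

#' Write observation series to CSV
#' @param obs A `fruit_observations` data frame.
#' @param path Output CSV path.
#' @export
write_observations <- function(obs, path) {
  write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize growth parameters as JSON
#'
#' Parameter sets are stored as flat JSON objects keyed by symbol name
#' (`C`, `km`, `kh_max`, `H0`, `Hmin`, `s`, plus optional `Mmax`,
#' `delta_t` for a fruit-specific record).
#'
#' @param params A [growth_params()] object.
#' @param path JSON file path.
#' @return `read_growth_params()` returns a [growth_params()] object.
#' @export
write_growth_params <- function(params, path) {
  validate_growth_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_growth_params
#' @export
read_growth_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  growth_params(p$C, p$km, p$kh_max, p$H0, p$Hmin, p$s)
}

#' Write a calibration fit to disk
#'
#' The shared parameters, their approximate standard errors and the fit
#' statistics go to a JSON file; the per-fruit `(Mmax, delta_t)` estimates
#' go to a CSV next to it.
#'
#' @param fit A `calibration_fit`.
#' @param json_path Path for the JSON summary.
#' @param per_fruit_path Path for the per-fruit CSV (default: alongside).
#' @export
write_calibration <- function(fit, json_path,
                              per_fruit_path = sub("\\.json$", "_per_fruit.csv",
                                                   json_path)) {
  stopifnot(inherits(fit, "calibration_fit"))
  jsonlite::write_json(list(
    shared = unclass(fit$shared), shared_se = as.list(fit$shared_se),
    rss = fit$rss, r_squared = fit$r_squared, converged = fit$converged,
    n_outer = fit$n_outer, normalization = fit$normalization,
    excluded = fit$excluded), json_path, auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(fit$per_fruit), per_fruit_path, row.names = FALSE)
  invisible(json_path)
}

#' Serialize / deserialize a population distribution as JSON
#' @param dist A [population_distribution()].
#' @param path JSON file path.
#' @export
write_population_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "population_distribution"))
  jsonlite::write_json(unclass(dist), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population_distribution
#' @export
read_population_distribution <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  population_distribution(d$Mmax_mean, d$Mmax_sd, d$delta_t_mean,
                          d$delta_t_sd, d$Mmax_family, d$correlation,
                          d$provenance)
}

#' Write a population simulation state to long-format CSV
#'
#' One row per fruit per time point: `fruit_id`, `t_d`, `mass_g`,
#' `hue_deg`, `stage`.
#'
#' @param sim A [simulate_population()] result.
#' @param path Output CSV path.
#' @param scheme A [ripening_scheme()] for the stage column.
#' @export
write_population_state <- function(sim, path, scheme = ripening_scheme()) {
  long <- data.frame(
    fruit_id = rep(sim$pop$fruit_id, times = length(sim$t_exp_d)),
    t_d = rep(sim$t_exp_d, each = nrow(sim$mass_g)),
    mass_g = as.vector(sim$mass_g),
    hue_deg = as.vector(sim$hue_deg))
  long$stage <- classify_stage(long$hue_deg, scheme)
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read harvest strategies from a config file
#'
#' The config is a JSON (or YAML, when the `yaml` package is available)
#' list of strategy definitions, each an object with fields `mode`,
#' `target_stages`, `interval`, `schedule`, `window`, `label` as understood
#' by [harvest_strategy()].
#'
#' @param path Config file path (`.json`, `.yml` or `.yaml`).
#' @return A list of [harvest_strategy()] objects.
#' @export
read_strategies <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  lapply(raw, function(sd) {
    harvest_strategy(mode = sd$mode,
                     target_stages = if (!is.null(sd$target_stages))
                       unlist(sd$target_stages) else c("RS5", "RS6"),
                     interval = sd$interval,
                     schedule = if (!is.null(sd$schedule)) unlist(sd$schedule),
                     window = if (!is.null(sd$window)) unlist(sd$window),
                     label = sd$label)
  })
}

#' Write a strategy comparison table and its per-event breakdown
#'
#' @param comparison A [compare_strategies()] result.
#' @param path CSV path for the ranked table.
#' @param events_path CSV path for the per-event breakdown (one row per
#'   strategy per harvest date; default alongside `path`).
#' @export
write_comparison <- function(comparison, path,
                             events_path = sub("\\.csv$", "_events.csv", path)) {
  write.csv(comparison, path, row.names = FALSE)
  outcomes <- attr(comparison, "outcomes")
  ev <- do.call(rbind, lapply(outcomes, function(o)
    cbind(label = o$strategy$label, o$events)))
  write.csv(ev, events_path, row.names = FALSE)
  invisible(path)
}
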