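#' Season-level kinetic growth and colour-change parameters
#'
#' Bundles the six parameters shared by all fruit of a season/cultivar in the
#' coupled growth--ripening model: the Gompertz displacement factor `C` and
#' growth rate `km` (1/d), the maximum colour-change rate `kh_max` (1/d), the
#' initial and minimum hue angles `H0` and `Hmin` (degrees), and the
#' dimensionless steepness `s` of the mass-triggered ripening switch.
#'
#' Internally all masses are expressed in grams and all times in days.
#'
#' @param C Dimensionless Gompertz displacement factor, `> 0`. The initial
#'   relative mass is `exp(-C)`.
#' @param km Growth rate in 1/d, `> 0`.
#' @param kh_max Maximum colour-change rate in 1/d once the switch is fully
#'   triggered, `> 0`.
#' @param H0 Initial hue angle in degrees (green fruit, around 105).
#' @param Hmin Minimum (fully ripe) hue angle in degrees; must be below `H0`.
#' @param s Dimensionless steepness of the biological switch, `> 0`.
#'
#' @return An object of class `growth_params` (a named list).
#' @seealso [savior_growth_params()] for reference estimates,
#'   [simulate_fruit()] for the model they parameterize.
#' @export
#' @examples
#' growth_params(C = 4.87, km = 0.0702, kh_max = 26.02,
#'               H0 = 105.74, Hmin = 52.55, s = 54.30)
growth_params <- function(C, km, kh_max, H0, Hmin, s) {
  p <- list(C = as.numeric(C), km = as.numeric(km),
            kh_max = as.numeric(kh_max), H0 = as.numeric(H0),
            Hmin = as.numeric(Hmin), s = as.numeric(s))
  validate_growth_params(p)
  structure(p, class = "growth_params")
}

validate_growth_params <- function(p) {
  stopifnot(is.list(p))
  need <- c("C", "km", "kh_max", "H0", "Hmin", "s")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("growth_params is missing: ", paste(missing, collapse = ", "))
  vals <- unlist(p[need])
  if (any(!is.finite(vals)))
    stop("growth_params must be finite numbers")
  if (p$km <= 0) stop("km must be positive")
  if (p$kh_max <= 0) stop("kh_max must be positive")
  if (p$s <= 0) stop("s must be positive")
  if (p$C <= 0) stop("C must be positive")
  if (p$H0 <= p$Hmin) stop("H0 must exceed Hmin")
  invisible(p)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Season-level kinetic parameters (g, d units):\n")
  cat(sprintf("  C      = %.4g   (Gompertz displacement)\n", x$C))
  cat(sprintf("  km     = %.4g 1/d (growth rate)\n", x$km))
  cat(sprintf("  kh_max = %.4g 1/d (max colour-change rate)\n", x$kh_max))
  cat(sprintf("  H0     = %.4g deg (initial hue)\n", x$H0))
  cat(sprintf("  Hmin   = %.4g deg (minimum hue)\n", x$Hmin))
  cat(sprintf("  s      = %.4g   (switch steepness)\n", x$s))
  invisible(x)
}

#' Fruit-specific parameters
#'
#' Each fruit is described by its own maximum mass `Mmax` (g) and a
#' biological-age shift `delta_t` (d) translating the shared experimental
#' clock into the fruit's developmental clock (`t_age = t_exp + delta_t`).
#' A collection of fruit is represented as a data frame with one row per
#' fruit.
#'
#' @param Mmax Numeric vector of maximum fruit masses in grams, all `> 0`.
#' @param delta_t Numeric vector of biological shifts in days (finite,
#'   recycled against `Mmax`).
#' @param fruit_id Optional identifiers; defaults to `1:n`.
#'
#' @return A data frame of class `fruit_params` with columns `fruit_id`,
#'   `Mmax_g`, `delta_t_d`.
#' @export
#' @examples
#' fruit_params(Mmax = c(107.1, 95.2), delta_t = c(7.0, 5.5))
fruit_params <- function(Mmax, delta_t, fruit_id = NULL) {
  n <- max(length(Mmax), length(delta_t))
  Mmax <- rep_len(as.numeric(Mmax), n)
  delta_t <- rep_len(as.numeric(delta_t), n)
  if (is.null(fruit_id)) fruit_id <- seq_len(n)
  if (any(!is.finite(Mmax)) || any(Mmax <= 0))
    stop("Mmax must be finite and positive")
  if (any(!is.finite(delta_t)))
    stop("delta_t must be finite")
  structure(data.frame(fruit_id = fruit_id, Mmax_g = Mmax,
                       delta_t_d = delta_t),
            class = c("fruit_params", "data.frame"))
}

#' Reference kinetic parameter estimates for field tomato cv. 'Savior'
#'
#' Season-specific estimates of the shared kinetic parameters obtained by
#' calibrating the integrated growth--ripening model to on-plant mass and
#' colour time series of field-grown plum tomato (cv. 'Savior') in the
#' Vietnamese winter and summer growing seasons.
#'
#' @param season `"winter"` or `"summer"`.
#' @return A [growth_params()] object.
#' @export
#' @examples
#' savior_growth_params("winter")
savior_growth_params <- function(season = c("winter", "summer")) {
  season <- match.arg(season)
  switch(season,
    winter = growth_params(C = 4.87, km = 0.0702, kh_max = 26.02,
                           H0 = 105.74, Hmin = 52.55, s = 54.30),
    summer = growth_params(C = 9.76, km = 0.11, kh_max = 14.83,
                           H0 = 106.63, Hmin = 51.37, s = 33.39))
}

#' Reference fruit-to-fruit variation for cv. 'Savior'
#'
#' Moments of the per-fruit parameter distributions estimated for the two
#' seasonal cohorts (342 winter fruit, 370 summer fruit): maximum fruit mass
#' `Mmax` and biological shift `delta_t`. Estimated `Mmax` and `delta_t`
#' showed no correlation between fruit, so the marginals are treated as
#' independent.
#'
#' @param season `"winter"` or `"summer"`.
#' @return A [population_distribution()] object.
#' @export
#' @examples
#' savior_population("winter")
savior_population <- function(season = c("winter", "summer")) {
  season <- match.arg(season)
  switch(season,
    winter = population_distribution(
      Mmax_mean = 107.1, Mmax_sd = 36.9,
      delta_t_mean = 7.01, delta_t_sd = 2.82,
      provenance = "reference (cv. Savior, winter, n = 342)"),
    summer = population_distribution(
      Mmax_mean = 99.03, Mmax_sd = 28.39,
      delta_t_mean = 5.39, delta_t_sd = 2.12,
      provenance = "reference (cv. Savior, summer, n = 370)"))
}

#' Cohort size of the reference field campaigns
#'
#' Number of fruit successfully monitored on the plant in each seasonal
#' cohort of the reference 'Savior' campaigns.
#'
#' @param season `"winter"` or `"summer"`.
#' @return Integer count of fruit.
#' @export
savior_cohort_size <- function(season = c("winter", "summer")) {
  season <- match.arg(season)
  switch(season, winter = 342L, summer = 370L)
}
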