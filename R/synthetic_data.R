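#' Specification of a synthetic monitoring campaign
#'
#' Describes the field campaign the observation generator emulates: fruit
#' are labelled at anthesis in a few flowering cohorts a fixed number of
#' days apart, then measured on the plant at a coarse cadence during growth
#' and a finer cadence during ripening, until the fruit is fully ripe.
#' Fruit-specific parameters are drawn from a [population_distribution()];
#' independent Gaussian measurement noise is added to mass and hue.
#'
#' @param n_fruit Number of fruit to generate.
#' @param growth A [growth_params()] object (season-level truth).
#' @param population A [population_distribution()] for `(Mmax, delta_t)`.
#' @param cohorts Number of flowering cohorts (default 3).
#' @param cohort_spacing_d Days between successive cohorts (default 5).
#' @param growth_interval_d Measurement cadence during growth, d (default 3).
#' @param ripening_interval_d Cadence during ripening, d (default 2).
#' @param mass_noise_sd_g Gaussian mass noise, g (default 2).
#' @param hue_noise_sd_deg Gaussian hue noise, degrees (default 1).
#' @param monitor_until_deg Per-fruit monitoring stops once the noise-free
#'   hue drops below this angle (default 56, i.e. 2 degrees above the
#'   54-degree overripe threshold, emulating on-vine monitoring through
#'   full ripeness).
#' @return A list of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(20, savior_growth_params("winter"), savior_population("winter"))
cohort_spec <- function(n_fruit, growth, population,
                        cohorts = 3, cohort_spacing_d = 5,
                        growth_interval_d = 3, ripening_interval_d = 2,
                        mass_noise_sd_g = 2, hue_noise_sd_deg = 1,
                        monitor_until_deg = 56) {
  validate_growth_params(growth)
  stopifnot(inherits(population, "population_distribution"),
            n_fruit >= 1, cohorts >= 1, cohort_spacing_d > 0,
            growth_interval_d > 0, ripening_interval_d > 0,
            mass_noise_sd_g >= 0, hue_noise_sd_deg >= 0)
  structure(list(n_fruit = as.integer(n_fruit), growth = growth,
                 population = population, cohorts = as.integer(cohorts),
                 cohort_spacing_d = cohort_spacing_d,
                 growth_interval_d = growth_interval_d,
                 ripening_interval_d = ripening_interval_d,
                 mass_noise_sd_g = mass_noise_sd_g,
                 hue_noise_sd_deg = hue_noise_sd_deg,
                 monitor_until_deg = monitor_until_deg),
            class = "cohort_spec")
}

#' Generate synthetic per-fruit observation series
#'
#' Draws `(Mmax, delta_t)` for every fruit, evaluates the noise-free model
#' on each fruit's shifted clock, samples it at the campaign cadence (the
#' growth-phase interval until the fruit's colour break, then the ripening
#' interval until the fruit is fully ripe) and adds independent Gaussian
#' noise. A fruit's colour break is the first day its noise-free hue falls
#' more than 1 degree below the initial hue. Fruit belong to flowering
#' cohorts whose labelling dates are spaced `cohort_spacing_d` apart, so
#' observation series start at different experimental times. The generating
#' truth is returned for recovery testing; the whole draw is a pure
#' function of `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (RNG state is restored on exit).
#' @return A list: `obs` (a [fruit_observations()] table) and `truth`
#'   (list with the generating `growth` parameters and `per_fruit` table).
#' @export
#' @examples
#' d <- gen_fruit_observations(
#'   cohort_spec(5, savior_growth_params("winter"), savior_population("winter")),
#'   seed = 1)
#' head(d$obs)
gen_fruit_observations <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  g <- spec$growth
  per <- sample_population(spec$population, spec$n_fruit, seed = seed + 1L)
  cohort <- sample.int(spec$cohorts, spec$n_fruit, replace = TRUE) - 1L
  start_d <- cohort * spec$cohort_spacing_d

  # shared fine grid for break/stop detection (noise-free model)
  age_hi <- max(per$delta_t_d) + 200
  Kf <- .ripening_integral(g, min(per$delta_t_d) - 1, age_hi)

  series <- vector("list", spec$n_fruit)
  for (i in seq_len(spec$n_fruit)) {
    dt_i <- per$delta_t_d[i]
    probe <- seq(start_d[i], start_d[i] + 200, by = 0.5)
    hue_probe <- .hue_at_age(probe + dt_i, g, Kf)
    brk <- probe[which(hue_probe < g$H0 - 1)[1]]
    stop_t <- probe[which(hue_probe < spec$monitor_until_deg)[1]]
    if (is.na(stop_t)) stop_t <- max(probe)
    if (is.na(brk)) brk <- stop_t
    te <- sort(unique(c(seq(start_d[i], brk, by = spec$growth_interval_d),
                        seq(brk, stop_t, by = spec$ripening_interval_d),
                        stop_t)))
    m <- gompertz_mass(te + dt_i, per$Mmax_g[i], g$C, g$km) +
      rnorm(length(te), 0, spec$mass_noise_sd_g)
    h <- .hue_at_age(te + dt_i, g, Kf) +
      rnorm(length(te), 0, spec$hue_noise_sd_deg)
    series[[i]] <- data.frame(fruit_id = per$fruit_id[i], t_exp_d = te,
                              mass_g = m, hue_deg = pmin(pmax(h, 1e-6), 180))
  }
  all <- do.call(rbind, series)
  obs <- fruit_observations(all$fruit_id, all$t_exp_d, all$mass_g,
                            all$hue_deg)
  list(obs = obs, truth = list(growth = g, per_fruit = per,
                               cohort_start_d = start_d, seed = seed))
}

#' Specification of a synthetic wholesale price survey
#'
#' @param n_raters Number of wholesalers on the panel (default 30).
#' @param coefficients True `price_coefficients` generating the prices.
#' @param design Mixture design (data frame with `rs1..rs6`); defaults to
#'   the 13-mixture reference design of [savior_price_survey()].
#' @param noise_sd Rater noise standard deviation on the raw price scale.
#' @return A list of class `survey_spec`.
#' @export
survey_spec <- function(n_raters = 30,
                        coefficients = savior_price_coefficients("winter"),
                        design = savior_price_survey()[paste0("rs", 1:6)],
                        noise_sd = 0.1) {
  stopifnot(n_raters >= 1, inherits(coefficients, "price_coefficients"),
            noise_sd >= 0)
  .as_composition_matrix(design)  # validates
  structure(list(n_raters = as.integer(n_raters),
                 coefficients = coefficients,
                 design = as.data.frame(design), noise_sd = noise_sd),
            class = "survey_spec")
}

#' Generate a synthetic wholesale price survey
#'
#' Each rater prices every mixture of the design at the model value plus
#' independent Gaussian rater noise; each rater's prices are then min-max
#' normalized per rater (one season per survey). Reproducible by seed.
#'
#' @param spec A [survey_spec()].
#' @param seed Integer seed.
#' @param season Season label attached to the observations.
#' @return A list: `prices` (data frame with `rater_id`, `season`,
#'   `rs1..rs6`, `raw_price`, `normalized_price`) and `truth` (the
#'   generating coefficients and seed).
#' @export
gen_price_survey <- function(spec, seed, season = "winter") {
  stopifnot(inherits(spec, "survey_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  base <- predict_price(spec$coefficients, spec$design)
  n_mix <- nrow(spec$design)
  out <- do.call(rbind, lapply(seq_len(spec$n_raters), function(r) {
    raw <- base + rnorm(n_mix, 0, spec$noise_sd)
    cbind(data.frame(rater_id = r, season = season), spec$design,
          raw_price = raw)
  }))
  out <- normalize_prices(out)
  list(prices = out, truth = list(coefficients = spec$coefficients,
                                  seed = seed))
}
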