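#' Distribution of fruit-specific parameters over a population
#'
#' Describes how maximum fruit mass `Mmax` (g) and biological shift
#' `delta_t` (d) vary fruit-to-fruit. Marginals are specified by family and
#' moments; the `Mmax` marginal is truncated at zero on sampling. The two
#' components are linked by a Gaussian copula with the given correlation
#' (default 0: estimated `Mmax` and `delta_t` show no correlation in the
#' reference cohorts, so independence is the default).
#'
#' @param Mmax_mean,Mmax_sd Mean and standard deviation of `Mmax`, g.
#' @param delta_t_mean,delta_t_sd Mean and standard deviation of `delta_t`, d.
#' @param Mmax_family `"normal"` (truncated at zero on sampling) or
#'   `"lognormal"` (moment-matched; reproduces the right skew seen in
#'   estimated `Mmax` histograms).
#' @param correlation Correlation between the two components in `[-1, 1]`.
#' @param provenance Free-text note on where the moments come from.
#' @return A list of class `population_distribution`.
#' @export
#' @examples
#' population_distribution(107.1, 36.9, 7.01, 2.82)
population_distribution <- function(Mmax_mean, Mmax_sd,
                                    delta_t_mean, delta_t_sd,
                                    Mmax_family = c("normal", "lognormal"),
                                    correlation = 0,
                                    provenance = "specified") {
  Mmax_family <- match.arg(Mmax_family)
  if (Mmax_mean <= 0 || Mmax_sd <= 0 || delta_t_sd <= 0)
    stop("Mmax_mean, Mmax_sd and delta_t_sd must be positive")
  if (abs(correlation) > 1) stop("correlation must lie in [-1, 1]")
  structure(list(Mmax_mean = Mmax_mean, Mmax_sd = Mmax_sd,
                 delta_t_mean = delta_t_mean, delta_t_sd = delta_t_sd,
                 Mmax_family = Mmax_family, correlation = correlation,
                 provenance = provenance),
            class = "population_distribution")
}

#' Fit a population distribution to calibrated per-fruit parameters
#'
#' Matches the marginal moments (mean, sd) of the estimated `Mmax` and
#' `delta_t` and records their sample correlation, so that virtual
#' populations preserve the average, variation, shape and correlation of
#' the calibrated cohort.
#'
#' @param per_fruit A [fruit_params()] data frame with at least 10 fruit.
#' @param Mmax_family Marginal family for `Mmax`, see
#'   [population_distribution()].
#' @param independent If `TRUE` (default) the recorded correlation is kept
#'   as metadata but sampling treats the components as independent, matching
#'   the empirical absence of correlation; set `FALSE` to sample with the
#'   fitted correlation.
#' @return A `population_distribution`.
#' @export
fit_population_distribution <- function(per_fruit,
                                        Mmax_family = c("normal", "lognormal"),
                                        independent = TRUE) {
  Mmax_family <- match.arg(Mmax_family)
  if (nrow(per_fruit) < 10)
    stop("need at least 10 fruit to fit a population distribution")
  if (sd(per_fruit$Mmax_g) == 0 || sd(per_fruit$delta_t_d) == 0)
    stop("degenerate per-fruit parameters: zero variance")
  rho <- cor(per_fruit$Mmax_g, per_fruit$delta_t_d)
  population_distribution(
    Mmax_mean = mean(per_fruit$Mmax_g), Mmax_sd = sd(per_fruit$Mmax_g),
    delta_t_mean = mean(per_fruit$delta_t_d), delta_t_sd = sd(per_fruit$delta_t_d),
    Mmax_family = Mmax_family,
    correlation = if (independent) 0 else rho,
    provenance = sprintf("fitted from %d calibrated fruit (sample cor %.3f)",
                         nrow(per_fruit), rho))
}

#' Draw a virtual fruit population
#'
#' Samples `N` fruit-specific parameter pairs from a
#' [population_distribution()] via a Gaussian copula: correlated standard
#' normals are transformed to the requested marginals. `Mmax` draws are
#' rejected and redrawn while non-positive (normal family) so all virtual
#' fruit have positive maximum mass. Reproducible for a given `seed`.
#'
#' @param dist A `population_distribution`.
#' @param N Number of virtual fruit, `> 0`.
#' @param seed Integer seed; the sampler restores the caller's RNG state.
#' @return A [fruit_params()] data frame with attributes `seed` and `dist`.
#' @export
#' @examples
#' pop <- sample_population(savior_population("winter"), 1000, seed = 1)
#' c(mean(pop$Mmax_g), sd(pop$Mmax_g))
sample_population <- function(dist, N, seed) {
  stopifnot(inherits(dist, "population_distribution"))
  if (N <= 0) stop("N must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  draw <- function(n) {
    z1 <- rnorm(n)
    z2 <- dist$correlation * z1 + sqrt(1 - dist$correlation^2) * rnorm(n)
    M <- if (dist$Mmax_family == "lognormal") {
      s2 <- log(1 + (dist$Mmax_sd / dist$Mmax_mean)^2)
      exp(log(dist$Mmax_mean) - s2 / 2 + sqrt(s2) * z1)
    } else {
      dist$Mmax_mean + dist$Mmax_sd * z1
    }
    data.frame(M = M, dt = dist$delta_t_mean + dist$delta_t_sd * z2)
  }
  d <- draw(N)
  while (any(bad <- d$M <= 0)) d[bad, ] <- draw(sum(bad))
  out <- fruit_params(d$M, d$dt)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "dist") <- dist
  out
}

#' Simulate a whole population on the experimental clock
#'
#' Evaluates every virtual fruit's mass and hue trajectory on a common
#' experimental-time grid, each fruit's dynamics shifted by its own
#' `delta_t` (`t_age = t_exp + delta_t`). Mass uses the Gompertz closed
#' form; hue the exact solution of the linear colour equation with a single
#' shared quadrature of the switch rate, so simulating 10,000 fruit is a
#' vectorized lookup.
#'
#' @param growth A [growth_params()] object.
#' @param pop A [fruit_params()] data frame (e.g. from
#'   [sample_population()]).
#' @param t_grid Strictly increasing experimental-time grid, d.
#' @return A list of class `population_sim`: `t_exp_d`, matrices `mass_g`
#'   and `hue_deg` (`N x length(t_grid)`), `pop`, `growth`.
#' @export
simulate_population <- function(growth, pop, t_grid) {
  validate_growth_params(growth)
  t_grid <- as.numeric(t_grid)
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  t_age <- outer(pop$delta_t_d, t_grid, `+`)   # N x T
  Kf <- .ripening_integral(growth, min(t_age), max(t_age))
  shape <- exp(-growth$C * exp(-growth$km * t_age))
  mass <- pop$Mmax_g * shape                   # recycles by row
  hue <- growth$Hmin + (growth$H0 - growth$Hmin) * exp(-Kf(t_age))
  dim(hue) <- dim(t_age)
  structure(list(t_exp_d = t_grid, mass_g = mass, hue_deg = hue,
                 pop = pop, growth = growth),
            class = "population_sim")
}

#' @export
print.population_sim <- function(x, ...) {
  cat(sprintf("Population simulation: %d fruit on t = [%g, %g] d (%d points)\n",
              nrow(x$mass_g), min(x$t_exp_d), max(x$t_exp_d),
              length(x$t_exp_d)))
  invisible(x)
}

#' Ripening-stage classification scheme
#'
#' Ordered hue-angle boundaries defining the six commercial ripening stages,
#' from mature green (RS1) through breaker (RS2), light orange (RS3),
#' orange (RS4) and red (RS5) to red ripe (RS6), plus the overripe waste
#' threshold. Intervals are half-open and lower-bound inclusive: a fruit at
#' exactly a stage's lower edge belongs to that stage, and fruit with hue
#' below the waste threshold are overripe waste with zero sale value.
#'
#' Only the 54-degree waste edge is an established reference value; the
#' stage boundaries above it are package defaults chosen to span the
#' green-to-red hue range and should be adapted to local grading charts.
#'
#' @param edges Named, strictly decreasing numeric vector of lower hue
#'   bounds for RS1..RS6, degrees.
#' @param waste Hue threshold (degrees) below which fruit are overripe
#'   waste; must not exceed the RS6 lower bound.
#' @return A list of class `ripening_scheme`.
#' @export
#' @examples
#' ripening_scheme()
ripening_scheme <- function(edges = c(RS1 = 95, RS2 = 85, RS3 = 75,
                                      RS4 = 65, RS5 = 58, RS6 = 54),
                            waste = 54) {
  if (!identical(names(edges), paste0("RS", 1:6)))
    stop("edges must be named RS1..RS6")
  if (any(diff(edges) >= 0))
    stop("edges must be strictly decreasing from RS1 to RS6")
  if (waste > edges[["RS6"]])
    stop("waste threshold must not exceed the RS6 lower bound")
  structure(list(edges = edges, waste = waste), class = "ripening_scheme")
}

#' Stage labels used throughout the package
#' @return Character vector `RS1..RS6, WASTE` (riper stages last).
#' @export
stage_levels <- function() c(paste0("RS", 1:6), "WASTE")

#' Classify hue angles into ripening stages
#'
#' @param hue Hue angles in degrees, in `(0, 180]`.
#' @param scheme A [ripening_scheme()].
#' @return Factor with levels `RS1..RS6, WASTE`.
#' @export
#' @examples
#' classify_stage(c(105, 60, 53.9))
classify_stage <- function(hue, scheme = ripening_scheme()) {
  if (any(!is.finite(hue)) || any(hue <= 0 | hue > 180))
    stop("hue must lie in (0, 180]")
  # breaks ascending: waste | RS6 | RS5 | ... | RS1
  breaks <- c(scheme$waste, rev(scheme$edges[-6]))
  k <- findInterval(hue, breaks)  # 0 = waste, 1 = RS6, ..., 6 = RS1
  lab <- c("WASTE", paste0("RS", 6:1))[k + 1]
  factor(lab, levels = stage_levels())
}

#' Tally a population's ripening stages at one time point
#'
#' Counts fruit and sums fruit mass per ripening stage (including waste)
#' at experimental time `t`. Counts always partition the population and
#' stage masses sum to the total population mass at `t`.
#'
#' @param sim A [simulate_population()] result.
#' @param t Experimental time, must be one of the simulated grid points.
#' @param scheme A [ripening_scheme()].
#' @param alive Optional logical vector marking the fruit still on the vine
#'   (defaults to all).
#' @return A data frame with columns `stage`, `count`, `mass_g`.
#' @export
stage_tally <- function(sim, t, scheme = ripening_scheme(), alive = NULL) {
  j <- match(t, sim$t_exp_d)
  if (is.na(j)) stop("t = ", t, " is not on the simulated grid")
  if (is.null(alive)) alive <- rep(TRUE, nrow(sim$mass_g))
  st <- classify_stage(sim$hue_deg[alive, j], scheme)
  data.frame(stage = factor(stage_levels(), levels = stage_levels()),
             count = as.integer(table(st)),
             mass_g = as.numeric(tapply(sim$mass_g[alive, j], st, sum,
                                        default = 0)))
}
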