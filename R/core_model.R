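#' Fruit mass from diameter
#'
#' Converts a caliper diameter measurement to fruit mass assuming a spherical
#' fruit of constant density. The default density of 873 kg/m^3 was found to
#' be constant over the whole mass range of field tomato in a preliminary
#' diameter--mass survey.
#'
#' @param diameter Fruit diameter in metres, `>= 0`.
#' @param density Fruit density in kg/m^3, `> 0` (default 873).
#' @return Fruit mass in kilograms: `(4/3) * pi * (diameter/2)^3 * density`.
#' @export
#' @examples
#' mass_from_diameter(0.05)          # ~0.0571 kg
#' mass_from_diameter(0.05) * 1000   # in grams
mass_from_diameter <- function(diameter, density = 873) {
  if (any(!is.finite(diameter)) || any(diameter < 0))
    stop("diameter must be finite and non-negative")
  if (!is.finite(density) || density <= 0)
    stop("density must be positive")
  (4 / 3) * pi * (diameter / 2)^3 * density
}

#' Hue angle from CIELAB chromaticity
#'
#' Computes the hue angle from the `a*` (green--red) and `b*` (blue--yellow)
#' coordinates. A plain `arctan(b*/a*)` is ambiguous for green fruit
#' (`a* < 0`), so the two-argument arctangent is used and mapped to
#' `(0, 180]` degrees: green fruit yield hue angles above 90 degrees, ripe
#' red fruit angles near 50 degrees.
#'
#' @param a_star,b_star CIELAB chromaticity coordinates (unitless vectors,
#'   recycled). Both zero is an undefined hue and raises an error.
#' @return Hue angle in degrees in `[0, 180]`: 0 on the red axis
#'   (`a* > 0, b* = 0`), above 90 for green fruit (`a* < 0`).
#' @export
#' @examples
#' hue_from_lab(10, 10)   # 45
#' hue_from_lab(-5, 20)   # ~104, a green fruit
hue_from_lab <- function(a_star, b_star) {
  n <- max(length(a_star), length(b_star))
  a_star <- rep_len(as.numeric(a_star), n)
  b_star <- rep_len(as.numeric(b_star), n)
  if (any(a_star == 0 & b_star == 0))
    stop("hue is undefined when both a* and b* are zero")
  h <- atan2(b_star, a_star) * 180 / pi
  # fold onto [0, 180]: hue is a ripeness scale with period 180, so (a, b)
  # and (-a, -b) are equivalent, as in arctan(b*/a*)
  h <- ifelse(h < 0, h + 180, h)
  h
}

#' Gompertz fruit mass (closed form)
#'
#' Closed-form solution of the Gompertz growth law
#' `dM/dt = km * M * ln(Mmax / M)` with initial condition
#' `M(0) = Mmax * exp(-C)`:
#' `M(t) = Mmax * exp(-C * exp(-km * t))`.
#'
#' @param t Biological age in days (vector).
#' @param Mmax Maximum fruit mass (g).
#' @param C Dimensionless displacement factor, `> 0`.
#' @param km Growth rate (1/d), `> 0`.
#' @return Fruit mass in the units of `Mmax`.
#' @export
#' @examples
#' gompertz_mass(0, Mmax = 107.1, C = 4.87, km = 0.0702)  # Mmax * exp(-C)
gompertz_mass <- function(t, Mmax, C, km) {
  if (Mmax <= 0 || C <= 0 || km <= 0)
    stop("Mmax, C and km must be positive")
  Mmax * exp(-C * exp(-km * t))
}

#' Mass-triggered colour-change rate (biological switch)
#'
#' The rate of hue decay is modulated by how close the fruit is to its
#' maximum mass: `kh = kh_max / (1 + (Mmax - M)/Mmax)^s`. For large `s` the
#' rate is negligible while the fruit is still growing and rises steeply to
#' `kh_max` as `M` approaches `Mmax`, emulating the climacteric onset of
#' ripening without modelling it mechanistically.
#'
#' @param M Current fruit mass (g), in `[0, Mmax]`.
#' @param Mmax Maximum fruit mass (g).
#' @param kh_max Maximum colour-change rate (1/d).
#' @param s Dimensionless switch steepness.
#' @return Colour-change rate `kh` in 1/d, in `(0, kh_max]`.
#' @export
#' @examples
#' switch_rate(0.99 * 107.1, 107.1, kh_max = 26.02, s = 54.30)  # ~15 1/d
switch_rate <- function(M, Mmax, kh_max, s) {
  if (any(!is.finite(M)) || any(M < 0))
    stop("M must be finite and non-negative")
  if (any(M > Mmax))
    stop("invalid state: M exceeds Mmax")
  kh_max / (1 + (Mmax - M) / Mmax)^s
}

#' Biological age from experimental time
#'
#' `t_age = t_exp + delta_t`: fruit observed on a common experimental clock
#' differ in developmental stage; the fruit-specific shift `delta_t` aligns
#' them on a biological-age clock.
#'
#' @param t_exp Experimental time (d since flower labelling).
#' @param delta_t Fruit-specific biological shift (d).
#' @return Biological age in days.
#' @export
shift_time <- function(t_exp, delta_t) t_exp + delta_t

## ---- internal fast evaluation of the coupled model -------------------------

## The colour ODE dH/dt = -(H - Hmin) * kh(M(t)) is linear in H, and
## kh depends on M only through the relative mass M/Mmax =
## exp(-C * exp(-km * t)), which is the same function of biological age for
## every fruit. Its exact solution is
##   H(t) = Hmin + (H0 - Hmin) * exp(-K(t)),  K(t) = int_0^t kh(u) du,
## so one quadrature of kh serves a whole cohort. Used by the calibration
## and population code; cross-checked against the ODE integration in tests.

# kh as a function of biological age (shared across fruit)
.kh_of_age <- function(t, p) {
  p$kh_max / (2 - exp(-p$C * exp(-p$km * t)))^p$s
}

# cumulative colour impulse K(t) on [t_min, t_max], returned as approxfun;
# the grid always covers age 0, where K is anchored to zero
.ripening_integral <- function(p, t_min, t_max, dt = 0.05) {
  grid <- seq(min(t_min, 0) - 1, max(t_max, 0) + 1, by = dt)
  kh <- .kh_of_age(grid, p)
  K <- c(0, cumsum((kh[-1] + kh[-length(kh)]) / 2 * diff(grid)))
  K <- K - approx(grid, K, xout = 0)$y  # anchor K(0) = 0
  approxfun(grid, K, rule = 2)
}

# hue at biological ages t given a precomputed ripening integral
.hue_at_age <- function(t, p, Kfun) {
  p$Hmin + (p$H0 - p$Hmin) * exp(-Kfun(t))
}

## ---- trajectory simulation -------------------------------------------------

#' Simulate one fruit's mass and hue trajectory
#'
#' Integrates the coupled two-state system (Gompertz mass growth and hue
#' decay gated by the mass-triggered switch) on a biological-age grid.
#' The default integrator is an adaptive explicit Runge--Kutta
#' (`deSolve::ode` method `"ode45"`, rtol 1e-8 / atol 1e-10, max step
#' 0.1 d, which resolves the short hue time constant of roughly
#' `1/kh_max` days once the switch is triggered). `method = "analytic"`
#' evaluates the closed-form mass solution and the exact solution of the
#' linear hue equation via quadrature of the switch rate; the two paths
#' agree to solver tolerance and the closed form doubles as a test oracle.
#'
#' @param growth A [growth_params()] object.
#' @param fruit A single-row [fruit_params()] object (or a list with
#'   `Mmax_g` and `delta_t_d`).
#' @param t_grid Strictly increasing biological-age grid in days; must start
#'   at or after age 0.
#' @param method `"ode45"` (default) or `"analytic"`.
#' @param rtol,atol,hmax Solver tolerances and maximum step for the ODE path.
#' @return A data frame of class `fruit_trajectory` with columns `t_age_d`,
#'   `mass_g`, `hue_deg`.
#' @export
#' @examples
#' tr <- simulate_fruit(savior_growth_params("winter"),
#'                      fruit_params(107.1, 0), t_grid = seq(0, 90, by = 1))
#' head(tr)
simulate_fruit <- function(growth, fruit, t_grid,
                           method = c("ode45", "analytic"),
                           rtol = 1e-8, atol = 1e-10, hmax = 0.1) {
  method <- match.arg(method)
  validate_growth_params(growth)
  Mmax <- if (is.data.frame(fruit)) fruit$Mmax_g[1] else fruit$Mmax_g
  if (is.null(Mmax)) stop("fruit must carry Mmax_g")
  if (!is.finite(Mmax) || Mmax <= 0) stop("Mmax must be positive")
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least two points")
  if (t_grid[1] < 0)
    stop("t_grid must start at or after biological age 0")

  if (method == "analytic") {
    Kf <- .ripening_integral(growth, min(t_grid), max(t_grid))
    out <- data.frame(t_age_d = t_grid,
                      mass_g = gompertz_mass(t_grid, Mmax, growth$C, growth$km),
                      hue_deg = .hue_at_age(t_grid, growth, Kf))
  } else {
    rhs <- function(t, y, parms) {
      M <- y[[1]]; H <- y[[2]]
      dM <- growth$km * M * log(Mmax / M)
      kh <- growth$kh_max / (1 + (Mmax - M) / Mmax)^growth$s
      list(c(dM, -(H - growth$Hmin) * kh))
    }
    y0 <- c(M = gompertz_mass(t_grid[1], Mmax, growth$C, growth$km),
            H = .hue_at_age(t_grid[1], growth,
                            .ripening_integral(growth, 0, max(t_grid[1], 1))))
    sol <- deSolve::ode(y0, t_grid, rhs, parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol, hmax = hmax)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed to converge for Mmax = ", Mmax)
    out <- data.frame(t_age_d = sol[, 1], mass_g = sol[, 2], hue_deg = sol[, 3])
  }
  class(out) <- c("fruit_trajectory", "data.frame")
  out
}

#' Check trajectory invariants
#'
#' Verifies that a simulated trajectory is physically admissible: strictly
#' increasing time, non-decreasing mass bounded by `Mmax`, non-increasing
#' hue bounded by `[Hmin, H0]` (up to a numerical tolerance).
#'
#' @param traj A `fruit_trajectory`.
#' @param growth The [growth_params()] used to generate it.
#' @param Mmax The fruit's maximum mass (g).
#' @param tol Numerical slack (default 1e-6 relative).
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_trajectory <- function(traj, growth, Mmax, tol = 1e-6) {
  if (any(diff(traj$t_age_d) <= 0)) stop("times must be strictly increasing")
  if (any(diff(traj$mass_g) < -tol * Mmax)) stop("mass must be non-decreasing")
  if (any(traj$mass_g <= 0) || any(traj$mass_g > Mmax * (1 + tol)))
    stop("mass must lie in (0, Mmax]")
  if (any(diff(traj$hue_deg) > tol * growth$H0)) stop("hue must be non-increasing")
  if (any(traj$hue_deg < growth$Hmin - tol * growth$H0) ||
      any(traj$hue_deg > growth$H0 + tol * growth$H0))
    stop("hue must lie in [Hmin, H0]")
  invisible(TRUE)
}
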