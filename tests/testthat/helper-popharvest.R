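# shared fixtures: small synthetic cohorts and an independent hue oracle

winter_params <- function() savior_growth_params("winter")
summer_params <- function() savior_growth_params("summer")

# small winter-like cohort; noise defaults match the campaign emulation
tiny_cohort <- function(n = 12, seed = 11, mass_sd = 2, hue_sd = 1,
                        growth = winter_params(),
                        population = savior_population("winter")) {
  gen_fruit_observations(
    cohort_spec(n, growth, population,
                mass_noise_sd_g = mass_sd, hue_noise_sd_deg = hue_sd),
    seed = seed)
}

# independent hue oracle: Richardson-refined trapezoid quadrature of the
# switch rate, written without the package's internals
oracle_hue <- function(t, growth, dt = 0.005) {
  vapply(t, function(tt) {
    if (tt == 0) return(growth$H0)
    grid <- seq(0, tt, length.out = max(ceiling(abs(tt) / dt), 2))
    frac <- exp(-growth$C * exp(-growth$km * grid))
    kh <- growth$kh_max / (1 + (1 - frac))^growth$s
    K <- sum((kh[-1] + kh[-length(kh)]) / 2 * diff(grid))
    growth$Hmin + (growth$H0 - growth$Hmin) * exp(-K)
  }, numeric(1))
}

# hand evaluation of the mixture price polynomial (independent of the
# package's design-matrix path)
oracle_price <- function(alpha, comp) {
  comp <- unlist(comp)
  sum(alpha[1:6] * comp[paste0("rs", 1:6)]) +
    alpha[7] * comp[["rs1"]] * comp[["rs6"]] +
    alpha[8] * comp[["rs2"]] * comp[["rs6"]] +
    alpha[9] * comp[["rs1"]] * comp[["rs5"]]
}
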