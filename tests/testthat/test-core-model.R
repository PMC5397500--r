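test_that("mass_from_diameter implements the constant-density sphere", {
  # hand evaluation: (4/3) * pi * 0.025^3 * 873 = 0.05714 kg
  expect_equal(mass_from_diameter(0.05), 0.0571377, tolerance = 1e-5)
  expect_equal(mass_from_diameter(0), 0)
  # default density is 873 kg/m^3
  expect_equal(mass_from_diameter(0.04), mass_from_diameter(0.04, 873))
  # mass scales linearly in density, cubically in diameter
  expect_equal(mass_from_diameter(0.05, 1746), 2 * mass_from_diameter(0.05))
  expect_equal(mass_from_diameter(0.1), 8 * mass_from_diameter(0.05))
  expect_error(mass_from_diameter(-0.01), "non-negative")
  expect_error(mass_from_diameter(0.05, 0), "positive")
})

test_that("hue_from_lab is quadrant-corrected onto a 0-180 ripeness scale", {
  expect_equal(hue_from_lab(10, 10), 45)
  expect_equal(hue_from_lab(20, 0), 0)
  # green fruit (a* < 0) land above 90 degrees
  expect_equal(hue_from_lab(-5, 20), atan2(20, -5) * 180 / pi,
               tolerance = 1e-10)
  expect_gt(hue_from_lab(-5, 20), 90)
  expect_equal(hue_from_lab(-5, 20), 104.036, tolerance = 1e-3)
  # period-180 equivalence of (a, b) and (-a, -b), as for arctan(b/a)
  expect_equal(hue_from_lab(-3, -7), hue_from_lab(3, 7))
  expect_error(hue_from_lab(0, 0), "undefined")
})

test_that("gompertz_mass matches the stated initial condition and limits", {
  w <- winter_params()
  expect_equal(gompertz_mass(0, 107.1, w$C, w$km), 107.1 * exp(-w$C))
  expect_equal(gompertz_mass(1e4, 107.1, w$C, w$km), 107.1)
  # inflection point: M(ln(C)/km) = Mmax / e
  expect_equal(gompertz_mass(log(w$C) / w$km, 107.1, w$C, w$km),
               107.1 / exp(1), tolerance = 1e-12)
  expect_equal(log(w$C) / w$km, 22.57, tolerance = 1e-3)
  # monotone non-decreasing
  tt <- seq(0, 120, by = 0.5)
  expect_true(all(diff(gompertz_mass(tt, 107.1, w$C, w$km)) >= 0))
})

test_that("switch_rate rises monotonically to kh_max at full mass", {
  w <- winter_params()
  expect_equal(switch_rate(107.1, 107.1, w$kh_max, w$s), w$kh_max)
  expect_equal(switch_rate(0, 107.1, w$kh_max, w$s), w$kh_max * 2^(-w$s))
  # direct evaluation near full mass
  expect_equal(switch_rate(0.99 * 107.1, 107.1, 26.02, 54.30), 15.159,
               tolerance = 1e-3)
  M <- seq(0, 107.1, length.out = 200)
  kh <- switch_rate(M, 107.1, w$kh_max, w$s)
  expect_true(all(diff(kh) > 0))
  expect_true(all(kh > 0 & kh <= w$kh_max))
  expect_error(switch_rate(108, 107.1, w$kh_max, w$s), "invalid state")
})

test_that("shift_time maps the experimental clock to biological age", {
  expect_equal(shift_time(10, 7.01), 17.01)
  expect_equal(shift_time(3.5, 0), 3.5)
  expect_equal(shift_time(-7.01, 7.01), 0)
})

test_that("numeric ODE mass agrees with the Gompertz closed form to 1e-6", {
  tg <- seq(0, 100, by = 1)
  for (p in list(winter_params(), summer_params())) {
    for (Mmax in c(50, 107.1, 250)) {
      tr <- simulate_fruit(p, fruit_params(Mmax, 0), tg)
      expect_lt(max(abs(tr$mass_g - gompertz_mass(tg, Mmax, p$C, p$km))),
                1e-6 * Mmax)
    }
  }
})

test_that("ODE and analytic trajectory paths agree and honour invariants", {
  tg <- seq(0, 100, by = 0.5)
  for (p in list(winter_params(), summer_params())) {
    ode <- simulate_fruit(p, fruit_params(107.1, 0), tg)
    ana <- simulate_fruit(p, fruit_params(107.1, 0), tg, method = "analytic")
    expect_lt(max(abs(ode$hue_deg - ana$hue_deg)), 1e-3)
    expect_lt(max(abs(ode$mass_g - ana$mass_g)), 1e-6 * 107.1)
    expect_true(validate_trajectory(ode, p, 107.1))
    expect_true(validate_trajectory(ana, p, 107.1))
    # hue settles at Hmin once ripening completes
    expect_equal(ode$hue_deg[length(tg)], p$Hmin, tolerance = 1e-6)
    # hue stays put while the switch is off
    off <- growth_params(p$C, p$km, 1e-10, p$H0, p$Hmin, p$s)
    flat <- simulate_fruit(off, fruit_params(107.1, 0), tg)
    expect_equal(flat$hue_deg, rep(p$H0, length(tg)), tolerance = 1e-7)
  }
})

test_that("hue trajectory matches an independent quadrature oracle", {
  w <- winter_params()
  tt <- c(10, 40, 55, 60, 62, 70, 90)
  ana <- simulate_fruit(w, fruit_params(107.1, 0), seq(0, 90, by = 0.5),
                        method = "analytic")
  expect_equal(ana$hue_deg[match(tt, ana$t_age_d)], oracle_hue(tt, w),
               tolerance = 1e-4)
})

test_that("the model is covariant under the time-translation gauge", {
  # shifting the clock by delta while rescaling C by exp(km * delta)
  # reproduces the same trajectory
  w <- winter_params()
  delta <- 4
  tg <- seq(0, 80, by = 1)
  base <- simulate_fruit(w, fruit_params(107.1, 0), tg, method = "analytic")
  shifted_p <- growth_params(w$C * exp(w$km * delta), w$km, w$kh_max,
                             w$H0, w$Hmin, w$s)
  shifted <- simulate_fruit(shifted_p, fruit_params(107.1, 0), tg + delta,
                            method = "analytic")
  expect_equal(shifted$mass_g, base$mass_g, tolerance = 1e-9)
  expect_equal(shifted$hue_deg, base$hue_deg, tolerance = 1e-4)
})

test_that("simulate_fruit rejects inadmissible grids", {
  w <- winter_params()
  expect_error(simulate_fruit(w, fruit_params(100, 0), c(0, 0, 1)),
               "strictly increasing")
  expect_error(simulate_fruit(w, fruit_params(100, 0), c(-5, 0, 5)),
               "age 0")
})
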