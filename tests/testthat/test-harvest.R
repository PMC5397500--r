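# small winter-like population shared across harvest tests
harvest_fixture <- function(N = 300, seed = 17) {
  pop <- sample_population(savior_population("winter"), N, seed = seed)
  sim <- simulate_population(winter_params(), pop, seq(20, 100, by = 1))
  list(sim = sim, coeffs = savior_price_coefficients("winter"))
}

# independent replay: per fruit, find its removal date and mass by scanning
# the schedule directly on the trajectory matrices
replay_accounting <- function(sim, strategy, scheme = ripening_scheme()) {
  N <- nrow(sim$mass_g)
  jdx <- match(strategy$schedule, sim$t_exp_d)
  removed_mass <- 0; end_mass <- 0
  for (i in seq_len(N)) {
    gone <- FALSE
    for (j in jdx) {
      st <- as.character(classify_stage(sim$hue_deg[i, j], scheme))
      if (st %in% strategy$target_stages || st == "WASTE") {
        removed_mass <- removed_mass + sim$mass_g[i, j]
        gone <- TRUE
        break
      }
    }
    if (!gone) end_mass <- end_mass + sim$mass_g[i, jdx[length(jdx)]]
  }
  c(removed = removed_mass, left = end_mass)
}

test_that("a single harvest long after ripening yields only waste", {
  f <- harvest_fixture(N = 150)
  out <- apply_harvest_strategy(f$sim,
    harvest_strategy("single", schedule = 100), coeffs = f$coeffs)
  expect_equal(out$total_value, 0)
  expect_equal(out$total_saleable_g, 0)
  expect_equal(out$total_waste_g, sum(f$sim$mass_g[, ncol(f$sim$mass_g)]))
  expect_equal(out$unharvested_n, 0L)
})

test_that("strategies whose targets never occur harvest nothing", {
  f <- harvest_fixture(N = 100)
  # RS2 band is crossed between grid days sometimes, but at t 20-25 no
  # fruit has left RS1 yet
  st <- harvest_strategy("dynamic", target_stages = "RS6",
                         schedule = c(21, 23, 25))
  out <- apply_harvest_strategy(f$sim, st, coeffs = f$coeffs)
  expect_equal(out$total_value, 0)
  expect_equal(out$n_events, 0L)
  expect_equal(out$unharvested_n, 100L)
})

test_that("a two-fruit toy harvest reproduces hand accounting", {
  w <- winter_params()
  pop <- fruit_params(c(120, 80), c(10, 0))   # fruit 1 is 10 d older
  sim <- simulate_population(w, pop, seq(30, 90, by = 1))
  cf <- savior_price_coefficients("winter")
  # pick a date where fruit 1 is ripe (RS5/RS6) and fruit 2 still green
  hue1 <- sim$hue_deg[1, ]; hue2 <- sim$hue_deg[2, ]
  d <- sim$t_exp_d[which(hue1 < 58 & hue1 >= 54 & hue2 > 95)[1]]
  expect_false(is.na(d))
  out <- apply_harvest_strategy(sim, harvest_strategy("single", schedule = d),
                                coeffs = cf)
  j <- match(d, sim$t_exp_d)
  m1 <- sim$mass_g[1, j]; m2 <- sim$mass_g[2, j]
  comp <- setNames(c(m2, 0, 0, 0, 0, m1) / (m1 + m2), paste0("rs", 1:6))
  expect_equal(out$events$saleable_g, m1 + m2)
  expect_equal(out$events$price_per_kg,
               oracle_price(unname(cf$coef), as.list(comp)))
  expect_equal(out$total_value,
               oracle_price(unname(cf$coef), as.list(comp)) * (m1 + m2) / 1000)
})

test_that("mass is conserved across harvest scenarios", {
  f <- harvest_fixture(N = 120)
  strategies <- list(
    harvest_strategy("single", schedule = 55),
    harvest_strategy("fixed_interval", c("RS5", "RS6"), interval = 2,
                     window = c(45, 85)),
    harvest_strategy("fixed_interval", c("RS4", "RS5", "RS6"), interval = 3,
                     window = c(45, 85)),
    harvest_strategy("dynamic", c("RS5", "RS6"),
                     schedule = c(48, 51, 56, 63, 71, 80)))
  for (st in strategies) {
    out <- apply_harvest_strategy(f$sim, st, coeffs = f$coeffs)
    oracle <- replay_accounting(f$sim, st)
    lhs <- out$total_saleable_g + out$total_waste_g + out$unharvested_g
    expect_equal(lhs, sum(oracle), tolerance = 1e-9)
    expect_equal(out$total_saleable_g + out$total_waste_g,
                 oracle[["removed"]], tolerance = 1e-9)
    # no fruit harvested twice
    expect_equal(sum(out$events$n_harvested) + sum(out$events$n_wasted) +
                   out$unharvested_n, 120L)
    # cumulative value is the plain sum of event values
    expect_equal(out$total_value, sum(out$events$value))
  }
})

test_that("a dense early all-stage schedule leaves essentially no waste", {
  f <- harvest_fixture(N = 120)
  st <- harvest_strategy("fixed_interval", paste0("RS", 1:6), interval = 1,
                         window = c(25, 95))
  out <- apply_harvest_strategy(f$sim, st, coeffs = f$coeffs)
  expect_equal(out$total_waste_g, 0)
  expect_equal(out$unharvested_n, 0L)
})

test_that("single-harvest sweep has the expected shape", {
  f <- harvest_fixture(N = 400)
  sw <- single_harvest_sweep(f$sim, c(25, 95), coeffs = f$coeffs)
  expect_true(all(diff(sw$waste_g) >= -1e-9))        # waste never shrinks
  expect_lt(sw$value[nrow(sw)], 1e-6)                # terminal value ~ 0
  best <- attr(sw, "best_date")
  expect_gt(best, sw$date_d[which.max(sw$saleable_g)])  # value peaks later
  expect_error(single_harvest_sweep(f$sim, c(500, 600), coeffs = f$coeffs),
               "outside")
})

test_that("strategy comparison is deterministic and complete", {
  f <- harvest_fixture(N = 150)
  st <- harvest_strategy("fixed_interval", c("RS5", "RS6"), interval = 2,
                         window = c(45, 80))
  cmp <- compare_strategies(f$sim, list(st, st), coeffs = f$coeffs)
  expect_equal(cmp$total_value[1], cmp$total_value[2])
  expect_equal(cmp$value_rel[1], 1)
  expect_length(attr(cmp, "outcomes"), 2)
})

test_that("strategy construction validates its schedule", {
  expect_error(harvest_strategy("single", schedule = c(1, 2)), "exactly one")
  expect_error(harvest_strategy("fixed_interval", interval = 0.5,
                                window = c(0, 10)), "interval")
  expect_error(harvest_strategy("dynamic", schedule = c(5, 4)),
               "strictly increasing")
  expect_error(harvest_strategy("fixed_interval", "RS9", interval = 2,
                                window = c(0, 10)), "subset")
  f <- harvest_fixture(N = 10)
  expect_error(apply_harvest_strategy(
    f$sim, harvest_strategy("single", schedule = 999), coeffs = f$coeffs),
    "not on the simulated grid")
})
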