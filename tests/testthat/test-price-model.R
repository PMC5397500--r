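test_that("price normalization is min-max within rater and season", {
  p <- normalize_prices(data.frame(rater_id = 1, season = "winter",
                                   raw_price = c(5000, 9000, 13000)))
  expect_equal(p$normalized_price, c(0, 0.5, 1))
  # groups are independent
  two <- normalize_prices(data.frame(
    rater_id = c(1, 1, 2, 2), season = "winter",
    raw_price = c(10, 20, 100, 300)))
  expect_equal(two$normalized_price, c(0, 1, 0, 1))
  # already-normalized group with min 0 and max 1 is unchanged
  u <- normalize_prices(data.frame(rater_id = 1, season = "s",
                                   raw_price = c(0, 0.25, 1)))
  expect_equal(u$normalized_price, c(0, 0.25, 1))
  expect_error(normalize_prices(data.frame(rater_id = 1, season = "w",
                                           raw_price = c(2, 2, 2))),
               "degenerate")
})

test_that("the design matrix has the documented columns and full rank", {
  pure6 <- c(rs1 = 0, rs2 = 0, rs3 = 0, rs4 = 0, rs5 = 0, rs6 = 1)
  expect_equal(as.numeric(build_design_matrix(pure6)),
               c(0, 0, 0, 0, 0, 1, 0, 0, 0))
  sv <- savior_price_survey()
  X <- build_design_matrix(sv)
  expect_equal(dim(X), c(13L, 9L))
  expect_equal(colnames(X), c(paste0("rs", 1:6), "rs1_rs6", "rs2_rs6",
                              "rs1_rs5"))
  expect_equal(qr(X)$rank, 9L)
  # mixture 11: 0.2 RS1 x 0.1 RS6
  expect_equal(unname(X[11, "rs1_rs6"]), 0.02)
  bad <- pure6; bad["rs6"] <- 0.9
  expect_error(build_design_matrix(bad), "sum to 1")
})

test_that("no-intercept OLS matches the normal-equations oracle", {
  sv <- savior_price_survey()
  sv$normalized_price <- sv$price_winter
  fit <- fit_price_model(sv)
  X <- build_design_matrix(sv)
  beta <- solve(crossprod(X), crossprod(X, sv$price_winter))  # oracle
  expect_equal(unname(fit$coef), as.numeric(beta), tolerance = 1e-10)
  expect_true(all(is.finite(fit$se)))
  expect_gt(fit$r_squared, fit$r_squared_centered)
})

test_that("noise-free synthetic prices are recovered exactly", {
  truth <- price_coefficients(c(alpha1 = 0.05, alpha2 = 0.3, alpha3 = 0.5,
                                alpha4 = 0.7, alpha5 = 0.85, alpha6 = 0.95,
                                alpha7 = -1, alpha8 = -2, alpha9 = -0.5))
  sv <- savior_price_survey()
  sv$normalized_price <- predict_price(truth, sv)
  fit <- fit_price_model(sv)
  expect_equal(fit$coef, truth$coef, tolerance = 1e-9)
})

test_that("balanced replicated surveys equal the fit to per-mixture means", {
  spec <- survey_spec(n_raters = 12, noise_sd = 0.08)
  sv <- gen_price_survey(spec, seed = 6)$prices
  full <- fit_price_model(sv)
  means <- aggregate(normalized_price ~ rs1 + rs2 + rs3 + rs4 + rs5 + rs6,
                     sv, mean)
  by_mean <- fit_price_model(means)
  expect_equal(full$coef, by_mean$coef, tolerance = 1e-9)
})

test_that("synthetic surveys recover the generating coefficients", {
  truth <- savior_price_coefficients("winter")
  sv <- gen_price_survey(survey_spec(n_raters = 30, coefficients = truth,
                                     noise_sd = 0.03), seed = 14)$prices
  fit <- fit_price_model(sv)
  # per-rater min-max renormalization leaves a small affine imprint, so
  # compare within 2 standard errors (plus that imprint for alpha6/alpha1)
  for (i in 1:9)
    expect_lt(abs(fit$coef[i] - truth$coef[i]),
              2 * fit$se[i] + 0.06)
})

test_that("per-rater fits are supported and behave like the pooled fit", {
  sv <- gen_price_survey(survey_spec(n_raters = 4, noise_sd = 0.03),
                         seed = 20)$prices
  fits <- fit_price_model(sv, by_rater = TRUE)
  expect_length(fits, 4)
  expect_true(all(vapply(fits, inherits, logical(1), "price_coefficients")))
})

test_that("predicted prices match hand arithmetic on reference coefficients", {
  wcf <- savior_price_coefficients("winter")
  pure <- function(k) setNames(as.numeric(seq_len(6) == k), paste0("rs", 1:6))
  expect_equal(predict_price(wcf, pure(6)), 0.94)
  expect_equal(predict_price(wcf, pure(1)), 0.00)
  mixed <- c(rs1 = 0, rs2 = 0, rs3 = 0, rs4 = 0.4, rs5 = 0.5, rs6 = 0.1)
  expect_equal(predict_price(wcf, mixed), 0.1 * 0.94 + 0.5 * 0.84 + 0.4 * 0.81)
  expect_equal(predict_price(savior_price_coefficients("summer"), pure(5)),
               0.85)
  # agreement with the polynomial oracle on every design mixture
  sv <- savior_price_survey()
  for (r in seq_len(nrow(sv))) {
    comp <- unlist(sv[r, paste0("rs", 1:6)])
    expect_equal(predict_price(wcf, comp),
                 oracle_price(unname(wcf$coef), comp), tolerance = 1e-12)
  }
})

test_that("adding green fruit to realistic batches never raises the price", {
  wcf <- savior_price_coefficients("winter")
  sv <- savior_price_survey()
  for (r in which(sv$rs6 >= 0.05)) {
    comp <- unlist(sv[r, paste0("rs", 1:6)])
    shifted <- comp
    shifted["rs6"] <- comp["rs6"] - 0.05
    shifted["rs1"] <- comp["rs1"] + 0.05
    # the negative interactions almost exactly offset the main-effect loss
    # for mixtures rich in RS2; allow curvature-level slack
    expect_lte(predict_price(wcf, shifted), predict_price(wcf, comp) + 1e-4)
  }
})
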