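#' Reference wholesale price survey for cv. 'Savior'
#'
#' The 13-mixture design used to elicit wholesale prices for batches of
#' tomato of varying ripening-stage composition, together with the mean
#' normalized price per kg given by a panel of 30 wholesalers for winter and
#' summer fruit. Fractions `rs1..rs6` are the proportions of each ripening
#' stage in the batch and sum to 1; prices are min-max normalized to
#' `[0, 1]` per wholesaler and season, so a pure mature-green batch scores 0
#' and the dearest batch 1.
#'
#' @return A data frame with columns `mixture`, `rs1..rs6`,
#'   `price_winter`, `price_summer`.
#' @export
#' @examples
#' savior_price_survey()
savior_price_survey <- function() {
  d <- data.frame(
    mixture = 1:13,
    rs6 = c(1, 0, 0, 0, 0, 0, 0.25, 0.2, 0, 0.1, 0.1, 0.1, 0.1),
    rs5 = c(0, 1, 0, 0, 0, 0, 0.25, 0.2, 0.2, 0.3, 0.3, 0.5, 0.2),
    rs4 = c(0, 0, 1, 0, 0, 0, 0.25, 0.2, 0.2, 0.3, 0.2, 0.4, 0.2),
    rs3 = c(0, 0, 0, 1, 0, 0, 0.25, 0.2, 0.2, 0.15, 0.1, 0, 0.2),
    rs2 = c(0, 0, 0, 0, 1, 0, 0, 0.2, 0.2, 0.1, 0.1, 0, 0.2),
    rs1 = c(0, 0, 0, 0, 0, 1, 0, 0, 0.2, 0.05, 0.2, 0, 0.1),
    price_winter = c(1.00, 0.98, 0.93, 0.51, 0.36, 0, 0.63, 0.54, 0.49,
                     0.54, 0.50, 0.66, 0.47),
    price_summer = c(1.00, 0.97, 0.73, 0.61, 0.30, 0, 0.62, 0.52, 0.47,
                     0.50, 0.50, 0.62, 0.48))
  d[, c("mixture", paste0("rs", 1:6), "price_winter", "price_summer")]
}

#' Reference price-model coefficients for cv. 'Savior'
#'
#' Published estimates of the nine mixture-model coefficients (six main
#' ripening-stage effects plus the RS1xRS6, RS2xRS6 and RS1xRS5
#' interactions) fitted to the combined responses of 30 wholesalers.
#'
#' @param season `"winter"` or `"summer"`.
#' @return A `price_coefficients` object (see [price_coefficients()]).
#' @export
savior_price_coefficients <- function(season = c("winter", "summer")) {
  season <- match.arg(season)
  cf <- switch(season,
    winter = c(alpha1 = 0.00, alpha2 = 0.35, alpha3 = 0.47, alpha4 = 0.81,
               alpha5 = 0.84, alpha6 = 0.94, alpha7 = -3.21, alpha8 = -4.11,
               alpha9 = -0.21),
    summer = c(alpha1 = 0.00, alpha2 = 0.29, alpha3 = 0.57, alpha4 = 0.62,
               alpha5 = 0.85, alpha6 = 0.95, alpha7 = -2.33, alpha8 = -3.66,
               alpha9 = -0.10))
  price_coefficients(cf)
}

#' Price-model coefficient container
#'
#' @param coef Named numeric vector `alpha1..alpha9`: main effects for
#'   RS1..RS6 and the RS1xRS6 (`alpha7`), RS2xRS6 (`alpha8`), RS1xRS5
#'   (`alpha9`) interactions. The model has no intercept.
#' @param se,p_value Optional standard errors and p-values (same names).
#' @param r_squared,r_squared_centered Optional fit statistics.
#' @return A list of class `price_coefficients`.
#' @export
price_coefficients <- function(coef, se = NULL, p_value = NULL,
                               r_squared = NA_real_,
                               r_squared_centered = NA_real_) {
  nm <- paste0("alpha", 1:9)
  if (!all(nm %in% names(coef)))
    stop("coef must be named alpha1..alpha9")
  coef <- coef[nm]
  if (any(!is.finite(coef))) stop("coefficients must be finite")
  structure(list(coef = coef, se = se, p_value = p_value,
                 r_squared = r_squared,
                 r_squared_centered = r_squared_centered),
            class = "price_coefficients")
}

#' @export
print.price_coefficients <- function(x, ...) {
  terms <- c(paste0("RS", 1:6), "RS1xRS6", "RS2xRS6", "RS1xRS5")
  cat("Mixture price model (no intercept), normalized price/kg:\n")
  for (i in 1:9)
    cat(sprintf("  %-8s alpha%-2d %8.3f%s\n", terms[i], i, x$coef[i],
                if (!is.null(x$se)) sprintf("  (se %.3f)", x$se[i]) else ""))
  if (is.finite(x$r_squared))
    cat(sprintf("  R^2 (uncentered) %.3f   R^2 (centered) %.3f\n",
                x$r_squared, x$r_squared_centered))
  invisible(x)
}

#' Min-max normalize raw prices within rater and season
#'
#' Each wholesaler's raw prices are rescaled to `[0, 1]` separately per
#' season (cheapest batch to 0, dearest to 1) so that raters using
#' different absolute price levels become comparable.
#'
#' @param prices Data frame with columns `rater_id`, `season`, `raw_price`.
#' @return The input with a `normalized_price` column added.
#' @export
#' @examples
#' normalize_prices(data.frame(rater_id = 1, season = "winter",
#'                             raw_price = c(5000, 9000, 13000)))
normalize_prices <- function(prices) {
  stopifnot(all(c("rater_id", "season", "raw_price") %in% names(prices)))
  grp <- interaction(prices$rater_id, prices$season, drop = TRUE)
  out <- unsplit(lapply(split(prices$raw_price, grp), function(p) {
    rng <- range(p)
    if (diff(rng) == 0)
      stop("degenerate group: a rater/season has constant prices")
    (p - rng[1]) / diff(rng)
  }), grp)
  prices$normalized_price <- out
  prices
}

#' Build the 9-column mixture design matrix
#'
#' Columns, in fixed order: the six stage fractions `RS1..RS6` followed by
#' the interaction products `RS1*RS6`, `RS2*RS6`, `RS1*RS5`. No intercept
#' column: the stage fractions sum to 1, so an intercept would be collinear.
#'
#' @param compositions Matrix or data frame with columns `rs1..rs6` (rows
#'   summing to 1 within 1e-9), or a single composition vector.
#' @return Numeric matrix with 9 named columns.
#' @export
#' @examples
#' build_design_matrix(c(rs1 = 0, rs2 = 0, rs3 = 0, rs4 = 0, rs5 = 0, rs6 = 1))
build_design_matrix <- function(compositions) {
  m <- .as_composition_matrix(compositions)
  X <- cbind(m, m[, "rs1"] * m[, "rs6"], m[, "rs2"] * m[, "rs6"],
             m[, "rs1"] * m[, "rs5"])
  colnames(X) <- c(paste0("rs", 1:6), "rs1_rs6", "rs2_rs6", "rs1_rs5")
  X
}

.as_composition_matrix <- function(compositions) {
  if (is.null(dim(compositions)))
    compositions <- matrix(compositions, nrow = 1,
                           dimnames = list(NULL, names(compositions)))
  m <- as.matrix(as.data.frame(compositions)[, paste0("rs", 1:6)])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < -1e-12))
    stop("stage fractions must be finite and non-negative")
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("invalid composition: stage fractions must sum to 1")
  m
}

#' Fit the no-intercept mixture price model
#'
#' Ordinary least squares of normalized price on the nine mixture terms
#' without an intercept. Standard errors and p-values follow the usual
#' linear-model theory. Because the model has no intercept the headline
#' `R^2` is uncentered (`1 - RSS / sum(y^2)`); the centered value is also
#' reported. With a balanced replicated design (every rater prices every
#' mixture) the point estimates equal those of a fit to per-mixture mean
#' prices.
#'
#' @param observations Data frame with columns `rs1..rs6` and
#'   `normalized_price` (one row per priced batch). Optionally `rater_id`
#'   with `by_rater = TRUE` for per-wholesaler fits.
#' @param by_rater Fit one model per rater instead of the combined model.
#' @return A `price_coefficients` object, or a named list of them when
#'   `by_rater = TRUE`.
#' @export
#' @examples
#' sv <- savior_price_survey()
#' sv$normalized_price <- sv$price_winter
#' fit_price_model(sv)
fit_price_model <- function(observations, by_rater = FALSE) {
  stopifnot("normalized_price" %in% names(observations))
  if (by_rater) {
    stopifnot("rater_id" %in% names(observations))
    return(lapply(split(observations, observations$rater_id),
                  fit_price_model))
  }
  X <- build_design_matrix(observations)
  y <- observations$normalized_price
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm(y ~ X - 1)
  cf <- setNames(coef(fit), paste0("alpha", 1:9))
  sm <- summary(fit)
  se <- setNames(sm$coefficients[, 2], names(cf))
  pv <- setNames(sm$coefficients[, 4], names(cf))
  rss <- sum(fit$residuals^2)
  price_coefficients(cf, se = se, p_value = pv,
                     r_squared = 1 - rss / sum(y^2),
                     r_squared_centered = 1 - rss / sum((y - mean(y))^2))
}

#' Predict the normalized price of a batch
#'
#' Evaluates the mixture model on one or more stage compositions. Values
#' are not clipped to `[0, 1]`; predictions outside that range are reported
#' via a warning.
#'
#' @param coeffs A `price_coefficients` object.
#' @param composition Composition vector (`rs1..rs6` summing to 1) or a
#'   matrix/data frame of compositions.
#' @return Numeric vector of normalized prices per kg.
#' @export
#' @examples
#' predict_price(savior_price_coefficients("winter"),
#'               c(rs1 = 0, rs2 = 0, rs3 = 0, rs4 = 0.4, rs5 = 0.5, rs6 = 0.1))
predict_price <- function(coeffs, composition) {
  stopifnot(inherits(coeffs, "price_coefficients"))
  X <- build_design_matrix(composition)
  y <- drop(X %*% coeffs$coef)
  if (any(y < -1e-9 | y > 1 + 1e-9))
    warning("predicted price outside [0, 1] for ",
            sum(y < -1e-9 | y > 1 + 1e-9), " composition(s)")
  unname(y)
}
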