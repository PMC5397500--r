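#' Assemble per-fruit observation series
#'
#' On-plant monitoring data: per fruit, measurement times on the
#' experimental clock (days since flower labelling) with fruit mass (g) and
#' hue angle (degrees). Fruit with fewer than four observations cannot be
#' calibrated and are flagged by [validate_observations()].
#'
#' @param fruit_id Fruit identifier vector.
#' @param t_exp Observation times, d since labelling.
#' @param mass_g Observed fruit mass, g.
#' @param hue_deg Observed hue angle, degrees in `(0, 180]`.
#' @param season Optional season label (recycled).
#' @return A data frame of class `fruit_observations`.
#' @export
fruit_observations <- function(fruit_id, t_exp, mass_g, hue_deg,
                               season = NA_character_) {
  obs <- data.frame(fruit_id = fruit_id, season = season,
                    t_exp_d = as.numeric(t_exp),
                    mass_g = as.numeric(mass_g),
                    hue_deg = as.numeric(hue_deg))
  obs <- obs[order(obs$fruit_id, obs$t_exp_d), , drop = FALSE]
  rownames(obs) <- NULL
  class(obs) <- c("fruit_observations", "data.frame")
  validate_observations(obs)
  obs
}

#' Validate an observation table
#'
#' Checks column presence, strictly increasing times within fruit, and hue
#' range. Returns (invisibly) the ids of fruit with fewer than four
#' observations, which calibration will exclude.
#'
#' @param obs A `fruit_observations` data frame.
#' @return Invisibly, a character vector of under-observed fruit ids.
#' @export
validate_observations <- function(obs) {
  need <- c("fruit_id", "t_exp_d", "mass_g", "hue_deg")
  missing <- setdiff(need, names(obs))
  if (length(missing))
    stop("observations are missing columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(obs$t_exp_d)) || any(!is.finite(obs$mass_g)) ||
      any(!is.finite(obs$hue_deg)))
    stop("observations contain non-finite values")
  if (any(obs$hue_deg <= 0 | obs$hue_deg > 180))
    stop("hue_deg must lie in (0, 180]")
  bad_t <- vapply(split(obs$t_exp_d, obs$fruit_id),
                  function(t) any(diff(t) <= 0), logical(1))
  if (any(bad_t))
    stop("t_exp_d must be strictly increasing within fruit: ",
         paste(names(bad_t)[bad_t], collapse = ", "))
  counts <- table(obs$fruit_id)
  invisible(names(counts)[counts < 4])
}

#' Pooled z-score normalization of mass and hue
#'
#' Mass (g) and hue (degrees) live on very different scales; to weight both
#' channels equally in the combined residual sum of squares each is pooled
#' over all fruit and standardized by subtracting its mean and dividing by
#' its standard deviation.
#'
#' @param obs A `fruit_observations` data frame.
#' @return A list with `obs` (normalized copy, columns `mass_norm`,
#'   `hue_norm` added) and `constants` (`mass_mean`, `mass_sd`, `hue_mean`,
#'   `hue_sd`) for the inverse transform.
#' @export
normalize_observations <- function(obs) {
  validate_observations(obs)
  cst <- list(mass_mean = mean(obs$mass_g), mass_sd = sd(obs$mass_g),
              hue_mean = mean(obs$hue_deg), hue_sd = sd(obs$hue_deg))
  if (!is.finite(cst$mass_sd) || cst$mass_sd <= 0 ||
      !is.finite(cst$hue_sd) || cst$hue_sd <= 0)
    stop("degenerate data: pooled mass or hue has zero variance")
  obs$mass_norm <- (obs$mass_g - cst$mass_mean) / cst$mass_sd
  obs$hue_norm <- (obs$hue_deg - cst$hue_mean) / cst$hue_sd
  list(obs = obs, constants = cst)
}

#' Combined normalized model residuals
#'
#' For every observation, simulates the fruit on its shifted clock
#' (`t_age = t_exp + delta_t`) and returns the stacked normalized residuals
#' (mass channel first, then hue), each channel scaled by the pooled
#' standard deviation so both contribute with equal weight.
#'
#' @param shared A [growth_params()] object.
#' @param per_fruit A [fruit_params()] data frame covering every fruit id in
#'   `obs`.
#' @param obs A `fruit_observations` data frame.
#' @param constants Optional normalization constants as returned by
#'   [normalize_observations()]; recomputed from `obs` when omitted.
#' @return Numeric vector of length `2 * nrow(obs)`.
#' @export
combined_residuals <- function(shared, per_fruit, obs, constants = NULL) {
  validate_growth_params(shared)
  if (is.null(constants)) constants <- normalize_observations(obs)$constants
  idx <- match(obs$fruit_id, per_fruit$fruit_id)
  if (any(is.na(idx)))
    stop("per_fruit parameters missing for fruit: ",
         paste(unique(obs$fruit_id[is.na(idx)]), collapse = ", "))
  t_age <- obs$t_exp_d + per_fruit$delta_t_d[idx]
  Kf <- .ripening_integral(shared, min(t_age), max(t_age))
  m_hat <- gompertz_mass(t_age, 1, shared$C, shared$km) * per_fruit$Mmax_g[idx]
  h_hat <- .hue_at_age(t_age, shared, Kf)
  c((m_hat - obs$mass_g) / constants$mass_sd,
    (h_hat - obs$hue_deg) / constants$hue_sd)
}

#' Calibration settings
#'
#' @param fix Named numeric vector of shared parameters to hold fixed during
#'   estimation (any of `C`, `km`, `kh_max`, `H0`, `Hmin`, `s`). The model
#'   has a gauge degeneracy -- it is invariant under `C -> C * exp(km * d)`
#'   with all `delta_t -> delta_t - d` -- so `C` is always frozen: either at
#'   the value supplied here, or at its value from an initial pooled fit
#'   (all fruit, `delta_t = 0`) when not supplied. Fixing all six shared
#'   parameters reduces calibration to the per-fruit subproblems.
#' @param max_outer Maximum number of outer (alternating) iterations.
#' @param rel_tol Relative improvement of the combined RSS below which the
#'   alternation stops.
#' @param delta_t_bounds Bounds for the per-fruit biological shift, d.
#' @param quad_dt Step (d) of the quadrature grid for the ripening integral.
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(fix = NULL, max_outer = 50, rel_tol = 1e-8,
                               delta_t_bounds = c(-30, 30), quad_dt = 0.05) {
  if (!is.null(fix)) {
    bad <- setdiff(names(fix), c("C", "km", "kh_max", "H0", "Hmin", "s"))
    if (length(bad)) stop("unknown shared parameters in fix: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(fix = fix, max_outer = max_outer, rel_tol = rel_tol,
                 delta_t_bounds = delta_t_bounds, quad_dt = quad_dt),
            class = "calibration_config")
}

## per-fruit (Mmax, delta_t) weighted least squares, shared params fixed
.fit_fruit <- function(oi, shared, Kf, start, wm, wh, dt_bounds) {
  fn <- function(th) {
    t_age <- oi$t_exp_d + th[2]
    c((gompertz_mass(t_age, th[1], shared$C, shared$km) - oi$mass_g) / wm,
      (.hue_at_age(t_age, shared, Kf) - oi$hue_deg) / wh)
  }
  minpack.lm::nls.lm(start, lower = c(1e-3, dt_bounds[1]),
                     upper = c(1e5, dt_bounds[2]), fn = fn,
                     control = minpack.lm::nls.lm.control(maxiter = 60))
}

## hue-aligned delta_t start: shift such that the fruit's observed colour
## break (first drop 5 degrees below H0) meets the model's break age. Fruit
## whose mass data are uninformative (tiny or noisy masses) would otherwise
## let delta_t wander; the colour break pins it. NA when no break observed.
.hue_break_shift <- function(oi, shared, Kf, dt_bounds) {
  thr <- shared$H0 - 5
  k <- which(oi$hue_deg < thr)[1]
  if (is.na(k) || k == 1) return(NA_real_)
  # linear interpolation of the observed crossing time
  h1 <- oi$hue_deg[k - 1]; h2 <- oi$hue_deg[k]
  t_obs <- oi$t_exp_d[k - 1] +
    (h1 - thr) / max(h1 - h2, 1e-9) * (oi$t_exp_d[k] - oi$t_exp_d[k - 1])
  K_target <- log((shared$H0 - shared$Hmin) / (thr - shared$Hmin))
  age <- tryCatch(stats::uniroot(function(t) Kf(t) - K_target,
                                 interval = c(-50, 300))$root,
                  error = function(e) NA_real_)
  dt <- age - t_obs
  if (is.na(dt)) return(NA_real_)
  min(max(dt, dt_bounds[1]), dt_bounds[2])
}

## mass-only per-fruit fit (used for initialization; hue ignored)
.fit_fruit_mass <- function(oi, C, km, start, dt_bounds) {
  fn <- function(th)
    gompertz_mass(oi$t_exp_d + th[2], th[1], C, km) - oi$mass_g
  minpack.lm::nls.lm(start, lower = c(1e-3, dt_bounds[1]),
                     upper = c(1e5, dt_bounds[2]), fn = fn,
                     control = minpack.lm::nls.lm.control(maxiter = 60))
}

## age range that any admissible delta_t can reach, for the quadrature grid
.age_range <- function(obs, dt_bounds) {
  c(min(obs$t_exp_d) + dt_bounds[1], max(obs$t_exp_d) + dt_bounds[2])
}

#' Joint calibration of shared and fruit-specific parameters
#'
#' Estimates the six season-level kinetic parameters together with each
#' fruit's `(Mmax, delta_t)` by minimizing the combined normalized residual
#' sum of squares over all observations (mass and hue channels weighted
#' equally via pooled standardization).
#'
#' The optimization exploits the separable structure of the problem with an
#' alternating scheme: an inner step solves every fruit's two-parameter
#' subproblem independently (Levenberg--Marquardt), an outer step updates
#' the free shared parameters with the per-fruit estimates held fixed, until
#' the combined RSS improves by less than `rel_tol` (relative) or
#' `max_outer` iterations are reached. The alternation is warm-started in
#' three stages to avoid poor local optima: (i) `km` and the per-fruit
#' parameters from the mass channel alone (profiled one-dimensional search
#' over `km`); (ii) the four colour parameters from the hue channel with the
#' per-fruit parameters held fixed; (iii) the full alternation.
#'
#' The displacement factor `C` is never free alongside the shifts (gauge
#' degeneracy, see [calibration_config()]): it is frozen at the supplied
#' value or at an initial pooled estimate, and `delta_t` absorbs per-fruit
#' timing, which makes the mean biological shift well defined.
#'
#' Approximate standard errors for the free shared parameters are computed
#' from the Jacobian of the normalized residuals at the optimum with the
#' per-fruit estimates treated as known.
#'
#' @param obs A `fruit_observations` data frame (at least 2 fruit; fruit
#'   with fewer than 4 observations are excluded and reported).
#' @param config A [calibration_config()].
#' @return A list of class `calibration_fit`: `shared` ([growth_params()]),
#'   `shared_se` (named vector, `NA` for fixed parameters), `per_fruit`
#'   ([fruit_params()]), `rss`, `r_squared` (1 - RSS/TSS on the combined
#'   normalized response), `converged`, `n_outer`, `normalization`,
#'   `excluded` (fruit ids dropped for lack of data).
#' @export
calibrate <- function(obs, config = calibration_config()) {
  excluded <- validate_observations(obs)
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " fruit with fewer than 4 observations: ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ...")
    obs <- obs[!(obs$fruit_id %in% excluded), , drop = FALSE]
  }
  ids <- unique(obs$fruit_id)
  if (length(ids) < 2) stop("calibration needs at least 2 fruit")
  norm <- normalize_observations(obs)
  cst <- norm$constants
  obs_by <- split(obs, factor(obs$fruit_id, levels = ids))
  dtb <- config$delta_t_bounds
  fix <- config$fix

  ## --- initial per-fruit and shared values ---------------------------------
  per <- data.frame(fruit_id = ids,
                    Mmax_g = vapply(obs_by, function(o)
                      max(1.05 * max(o$mass_g), 1), numeric(1)),
                    delta_t_d = 0)
  C0 <- if (!is.null(fix) && "C" %in% names(fix)) unname(fix[["C"]]) else NA

  mass_profile <- function(km, C, per0) {
    sum(vapply(seq_along(obs_by), function(i)
      .fit_fruit_mass(obs_by[[i]], C, km,
                      c(per0$Mmax_g[i], per0$delta_t_d[i]), dtb)$deviance,
      numeric(1)))
  }

  if (is.na(C0)) {
    ## pooled fit with all delta_t = 0 to freeze C (gauge constraint):
    ## profile the mass RSS over (C, km) with per-fruit Mmax only
    pooled <- function(th) {
      C <- th[1]; km <- th[2]
      shape <- lapply(obs_by, function(o) gompertz_mass(o$t_exp_d, 1, C, km))
      unlist(lapply(seq_along(obs_by), function(i) {
        sh <- shape[[i]]; m <- obs_by[[i]]$mass_g
        sh * sum(sh * m) / max(sum(sh^2), 1e-12) - m  # Mmax profiled out
      }))
    }
    pf <- minpack.lm::nls.lm(c(5, 0.08), lower = c(0.1, 1e-3),
                             upper = c(50, 2), fn = pooled,
                             control = minpack.lm::nls.lm.control(maxiter = 100))
    C0 <- pf$par[1]
  }

  ## --- stage i: mass-only, profiled search over km -------------------------
  if (is.null(fix) || !("km" %in% names(fix))) {
    km0 <- optimize(mass_profile, c(0.01, 0.5), C = C0, per0 = per,
                    tol = 1e-5)$minimum
  } else km0 <- unname(fix[["km"]])
  for (i in seq_along(obs_by)) {
    f <- .fit_fruit_mass(obs_by[[i]], C0, km0,
                         c(per$Mmax_g[i], per$delta_t_d[i]), dtb)
    per$Mmax_g[i] <- f$par[1]; per$delta_t_d[i] <- f$par[2]
  }

  shared <- list(C = C0, km = km0, kh_max = 10,
                 H0 = max(obs$hue_deg), Hmin = min(obs$hue_deg), s = 40)
  if (!is.null(fix)) shared[names(fix)] <- as.list(unname(fix))

  lower_all <- c(C = 0.1, km = 1e-3, kh_max = 0.05, H0 = 60, Hmin = 5, s = 0.5)
  upper_all <- c(C = 50, km = 2, kh_max = 1e3, H0 = 180, Hmin = 95, s = 1e3)
  free <- setdiff(c("km", "kh_max", "H0", "Hmin", "s"),
                  names(fix))  # C is always frozen
  arange <- .age_range(obs, dtb)

  ## --- stage ii: colour parameters from the hue channel --------------------
  ## Fit the colour parameters with the per-fruit shifts held fixed, then
  ## realign each fruit's shift on its observed colour break (robust against
  ## fruit whose mass channel is uninformative) and refit once.
  col_free <- intersect(c("kh_max", "H0", "Hmin", "s"), free)
  if (length(col_free)) {
    hue_fn <- function(th) {
      sh <- shared; sh[col_free] <- as.list(th)
      Kf <- .ripening_integral(sh, arange[1], arange[2], config$quad_dt)
      idx <- match(obs$fruit_id, per$fruit_id)
      .hue_at_age(obs$t_exp_d + per$delta_t_d[idx], sh, Kf) - obs$hue_deg
    }
    for (pass in 1:2) {
      fB <- minpack.lm::nls.lm(unlist(shared[col_free]),
                               lower = lower_all[col_free],
                               upper = upper_all[col_free], fn = hue_fn,
                               control = minpack.lm::nls.lm.control(maxiter = 100))
      shared[col_free] <- as.list(fB$par)
      if (pass == 1) {
        Kf <- .ripening_integral(shared, arange[1], arange[2], config$quad_dt)
        dt_hue <- vapply(obs_by, .hue_break_shift, numeric(1),
                         shared = shared, Kf = Kf, dt_bounds = dtb)
        # adopt the realigned shift only where it fits the fruit's hue
        # series better than the mass-based one
        for (i in seq_along(obs_by)) {
          if (is.na(dt_hue[i])) next
          oi <- obs_by[[i]]
          rss_dt <- function(dt)
            sum((.hue_at_age(oi$t_exp_d + dt, shared, Kf) - oi$hue_deg)^2)
          if (rss_dt(dt_hue[i]) < rss_dt(per$delta_t_d[i]))
            per$delta_t_d[i] <- dt_hue[i]
        }
      }
    }
  }

  ## --- stage iii: full alternation -----------------------------------------
  idx <- match(obs$fruit_id, per$fruit_id)
  all_resid <- function(sh, per) {
    Kf <- .ripening_integral(sh, arange[1], arange[2], config$quad_dt)
    t_age <- obs$t_exp_d + per$delta_t_d[idx]
    c((gompertz_mass(t_age, 1, sh$C, sh$km) * per$Mmax_g[idx] - obs$mass_g) /
        cst$mass_sd,
      (.hue_at_age(t_age, sh, Kf) - obs$hue_deg) / cst$hue_sd)
  }
  outer_fn <- function(th, per) {
    sh <- shared; sh[free] <- as.list(th)
    all_resid(sh, per)
  }

  rss_prev <- Inf
  converged <- FALSE
  n_outer <- 0
  rss <- sum(all_resid(shared, per)^2)
  for (it in seq_len(config$max_outer)) {
    n_outer <- it
    Kf <- .ripening_integral(shared, arange[1], arange[2], config$quad_dt)
    for (i in seq_along(obs_by)) {
      f <- .fit_fruit(obs_by[[i]], shared, Kf,
                      c(per$Mmax_g[i], per$delta_t_d[i]),
                      cst$mass_sd, cst$hue_sd, dtb)
      if (it == 1) {
        # second start with the shift aligned on the observed colour break;
        # keeps fruit with uninformative mass data out of spurious optima
        dt2 <- .hue_break_shift(obs_by[[i]], shared, Kf, dtb)
        if (!is.na(dt2) && abs(dt2 - f$par[2]) > 0.5) {
          f2 <- .fit_fruit(obs_by[[i]], shared, Kf, c(per$Mmax_g[i], dt2),
                           cst$mass_sd, cst$hue_sd, dtb)
          if (f2$deviance < f$deviance) f <- f2
        }
      }
      per$Mmax_g[i] <- f$par[1]; per$delta_t_d[i] <- f$par[2]
    }
    if (length(free)) {
      fo <- minpack.lm::nls.lm(unlist(shared[free]), lower = lower_all[free],
                               upper = upper_all[free], fn = outer_fn,
                               per = per,
                               control = minpack.lm::nls.lm.control(maxiter = 60))
      shared[free] <- as.list(fo$par)
      rss <- fo$deviance
    } else {
      rss <- sum(all_resid(shared, per)^2)
    }
    if (rss > rss_prev + 1e-12)
      warning("combined RSS increased across an outer iteration")
    if (is.finite(rss_prev) &&
        abs(rss_prev - rss) < config$rel_tol * max(rss, 1)) {
      converged <- TRUE
      break
    }
    rss_prev <- rss
  }
  if (!length(free)) converged <- TRUE

  ## --- uncertainty and fit quality -----------------------------------------
  shared_se <- setNames(rep(NA_real_, 6),
                        c("C", "km", "kh_max", "H0", "Hmin", "s"))
  if (length(free)) {
    th <- unlist(shared[free])
    r0 <- outer_fn(th, per)
    J <- vapply(seq_along(th), function(j) {
      h <- pmax(1e-6 * abs(th[j]), 1e-8)
      tp <- th; tp[j] <- tp[j] + h
      (outer_fn(tp, per) - r0) / h
    }, numeric(length(r0)))
    dof <- length(r0) - length(th) - 2 * length(ids)
    sigma2 <- rss / max(dof, 1)
    covm <- tryCatch(solve(crossprod(J)) * sigma2,
                     error = function(e) matrix(NA, length(th), length(th)))
    shared_se[free] <- sqrt(pmax(diag(covm), 0))
  }
  z <- c(obs$mass_g - cst$mass_mean, obs$hue_deg - cst$hue_mean) /
    rep(c(cst$mass_sd, cst$hue_sd), each = nrow(obs))
  r2 <- 1 - rss / sum(z^2)

  structure(list(
    shared = growth_params(shared$C, shared$km, shared$kh_max,
                           shared$H0, shared$Hmin, shared$s),
    shared_se = shared_se,
    per_fruit = fruit_params(per$Mmax_g, per$delta_t_d, per$fruit_id),
    rss = rss, r_squared = r2, converged = converged, n_outer = n_outer,
    normalization = cst, excluded = excluded),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Joint calibration fit\n")
  cat(sprintf("  fruit: %d (excluded: %d)   outer iterations: %d (%s)\n",
              nrow(x$per_fruit), length(x$excluded), x$n_outer,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  combined normalized RSS: %.6g   R^2: %.4f\n",
              x$rss, x$r_squared))
  est <- unlist(unclass(x$shared))
  for (nm in names(est))
    cat(sprintf("  %-7s %10.4g  (se %s)\n", nm, est[[nm]],
                ifelse(is.na(x$shared_se[[nm]]), "fixed/approx NA",
                       sprintf("%.3g", x$shared_se[[nm]]))))
  cat(sprintf("  per-fruit Mmax: mean %.4g g   delta_t: mean %.4g d\n",
              mean(x$per_fruit$Mmax_g), mean(x$per_fruit$delta_t_d)))
  invisible(x)
}
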