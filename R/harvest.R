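#' Define a harvest strategy
#'
#' Three modes are supported. `"single"`: the whole crop (every non-waste
#' fruit) is picked on one date. `"fixed_interval"`: fruit in the target
#' stages are picked every `interval` days across the window.
#' `"dynamic"`: fruit in the target stages are picked on an explicit,
#' strictly increasing list of dates (flexible intervals adapted to crop
#' development).
#'
#' @param mode `"single"`, `"fixed_interval"` or `"dynamic"`.
#' @param target_stages Subset of `RS1..RS6` eligible for picking
#'   (ignored for `"single"`, which takes every non-waste stage).
#' @param interval Days between harvests (`fixed_interval`), `>= 1`.
#' @param schedule Explicit harvest dates, d (`dynamic`), or the single
#'   harvest date (`single`).
#' @param window Length-2 numeric `(start, end)` of the harvest window, d.
#' @param label Optional label used in comparison tables.
#' @return A list of class `harvest_strategy`.
#' @export
#' @examples
#' harvest_strategy("fixed_interval", target_stages = c("RS5", "RS6"),
#'                  interval = 3, window = c(40, 70))
harvest_strategy <- function(mode = c("single", "fixed_interval", "dynamic"),
                             target_stages = c("RS5", "RS6"),
                             interval = NULL, schedule = NULL,
                             window = NULL, label = NULL) {
  mode <- match.arg(mode)
  if (mode == "single") {
    if (length(schedule) != 1)
      stop("single mode needs exactly one harvest date in schedule")
    target_stages <- paste0("RS", 1:6)
  } else {
    if (!length(target_stages) || !all(target_stages %in% paste0("RS", 1:6)))
      stop("target_stages must be a non-empty subset of RS1..RS6")
  }
  if (mode == "fixed_interval") {
    if (is.null(interval) || interval < 1)
      stop("fixed_interval mode needs interval >= 1 d")
    if (is.null(window)) stop("fixed_interval mode needs a window")
    schedule <- seq(window[1], window[2], by = interval)
  }
  if (mode == "dynamic") {
    if (is.null(schedule) || length(schedule) < 1 || any(diff(schedule) <= 0))
      stop("dynamic mode needs a strictly increasing schedule")
    if (!is.null(window) &&
        (min(schedule) < window[1] || max(schedule) > window[2]))
      stop("schedule must lie within the window")
  }
  if (is.null(label))
    label <- switch(mode,
      single = sprintf("single @ %g d", schedule),
      fixed_interval = sprintf("%s every %g d",
                               paste(target_stages, collapse = "+"), interval),
      dynamic = sprintf("dynamic %s (%d harvests)",
                        paste(target_stages, collapse = "+"), length(schedule)))
  structure(list(mode = mode, target_stages = target_stages,
                 interval = interval, schedule = as.numeric(schedule),
                 window = window, label = label),
            class = "harvest_strategy")
}

#' Apply a harvest strategy to a simulated population
#'
#' Walks the strategy's harvest dates in order. On each date, fruit still on
#' the vine whose current stage is in the target set are removed at their
#' current mass and valued; overripe fruit (hue below the waste threshold)
#' are removed as waste with zero value, keeping the vine state consistent
#' with the waste accounting (set `remove_waste = FALSE` to leave overripe
#' fruit hanging). Remaining fruit continue to develop unmodified. The
#' batch composition of each event is the mass fraction of each ripening
#' stage over the saleable (non-waste) harvested mass, and the event value
#' is the predicted normalized price per kg times the saleable mass in kg.
#'
#' @param sim A [simulate_population()] result covering all harvest dates.
#' @param strategy A [harvest_strategy()].
#' @param scheme A [ripening_scheme()].
#' @param coeffs A `price_coefficients` object.
#' @param remove_waste Remove overripe fruit from the vine on harvest dates
#'   (default `TRUE`).
#' @return A list of class `harvest_outcome`: `events` (data frame with one
#'   row per harvest date: counts, per-stage masses, composition, price,
#'   value), `total_value` (normalized price x kg, summed over events),
#'   `total_saleable_g`, `total_waste_g`, `unharvested_g` (mass of fruit
#'   left on the vine at the window end), `n_events` (harvests with
#'   non-zero saleable mass), `strategy`.
#' @export
apply_harvest_strategy <- function(sim, strategy, scheme = ripening_scheme(),
                                   coeffs, remove_waste = TRUE) {
  stopifnot(inherits(sim, "population_sim"),
            inherits(strategy, "harvest_strategy"))
  dates <- strategy$schedule
  jdx <- vapply(dates, function(d) {
    j <- which(abs(sim$t_exp_d - d) < 1e-9)
    if (!length(j)) stop("harvest date ", d, " is not on the simulated grid")
    j[1]
  }, integer(1))
  N <- nrow(sim$mass_g)
  alive <- rep(TRUE, N)
  stages <- paste0("RS", 1:6)
  ev <- vector("list", length(dates))
  for (k in seq_along(dates)) {
    j <- jdx[k]
    st <- classify_stage(sim$hue_deg[, j], scheme)
    pick <- alive & (st %in% strategy$target_stages)
    waste <- alive & (st == "WASTE")
    stage_mass <- vapply(stages, function(sg)
      sum(sim$mass_g[pick & st == sg, j]), numeric(1))
    saleable <- sum(stage_mass)
    waste_mass <- if (remove_waste) sum(sim$mass_g[waste, j]) else 0
    if (saleable > 0) {
      comp <- setNames(stage_mass / saleable, paste0("rs", 1:6))
      price <- predict_price(coeffs, comp)
    } else {
      comp <- setNames(rep(0, 6), paste0("rs", 1:6))
      price <- 0
    }
    value <- price * saleable / 1000  # normalized price/kg x kg
    alive[pick] <- FALSE
    if (remove_waste) alive[waste] <- FALSE
    ev[[k]] <- data.frame(date_d = dates[k], n_harvested = sum(pick),
                          n_wasted = if (remove_waste) sum(waste) else 0L,
                          t(stage_mass), saleable_g = saleable,
                          waste_g = waste_mass, t(comp),
                          price_per_kg = price, value = value)
  }
  events <- do.call(rbind, ev)
  names(events)[match(stages, names(events))] <- paste0("mass_", tolower(stages), "_g")
  jend <- jdx[length(jdx)]
  structure(list(events = events,
                 total_value = sum(events$value),
                 total_saleable_g = sum(events$saleable_g),
                 total_waste_g = sum(events$waste_g),
                 unharvested_g = sum(sim$mass_g[alive, jend]),
                 unharvested_n = sum(alive),
                 n_events = sum(events$saleable_g > 0),
                 strategy = strategy),
            class = "harvest_outcome")
}

#' @export
print.harvest_outcome <- function(x, ...) {
  cat(sprintf("Harvest outcome [%s]\n", x$strategy$label))
  cat(sprintf("  harvests with yield: %d of %d dates\n", x$n_events,
              nrow(x$events)))
  cat(sprintf("  saleable %.1f kg, waste %.1f kg, left on vine %.1f kg\n",
              x$total_saleable_g / 1000, x$total_waste_g / 1000,
              x$unharvested_g / 1000))
  cat(sprintf("  cumulative value: %.2f (normalized price x kg)\n",
              x$total_value))
  invisible(x)
}

#' Single-harvest sweep over candidate dates
#'
#' For every grid date in the window, evaluates a one-off harvest of the
#' whole crop: overripe fruit is waste, everything else is sold unsorted at
#' the price of its stage composition. Returns the value, saleable-mass and
#' waste-mass series together with the date maximizing value.
#'
#' @param sim A [simulate_population()] result.
#' @param window Length-2 `(start, end)` within the simulated grid.
#' @param scheme A [ripening_scheme()].
#' @param coeffs A `price_coefficients` object.
#' @return A data frame of class `harvest_sweep` (columns `date_d`, `value`,
#'   `saleable_g`, `waste_g`) with attribute `best_date`.
#' @export
single_harvest_sweep <- function(sim, window, scheme = ripening_scheme(),
                                 coeffs) {
  sel <- sim$t_exp_d >= window[1] & sim$t_exp_d <= window[2]
  if (!any(sel)) stop("window lies outside the simulated grid")
  dates <- sim$t_exp_d[sel]
  rows <- lapply(dates, function(d) {
    out <- apply_harvest_strategy(sim,
      harvest_strategy("single", schedule = d), scheme, coeffs)
    data.frame(date_d = d, value = out$total_value,
               saleable_g = out$total_saleable_g,
               waste_g = out$total_waste_g)
  })
  res <- do.call(rbind, rows)
  attr(res, "best_date") <- res$date_d[which.max(res$value)]
  class(res) <- c("harvest_sweep", "data.frame")
  res
}

#' Compare harvest strategies on a common population
#'
#' Evaluates each strategy against the same simulated population and ranks
#' them by cumulative economic value. The per-event value breakdown (the
#' stacked contributions of successive harvest days) is kept alongside.
#'
#' @param sim A [simulate_population()] result.
#' @param strategies List of [harvest_strategy()] objects.
#' @param scheme A [ripening_scheme()].
#' @param coeffs A `price_coefficients` object.
#' @return A data frame with one row per strategy (`label`, `mode`,
#'   `n_events`, `total_value`, `value_rel` normalized to the best,
#'   `saleable_kg`, `waste_kg`), ordered by decreasing value, with the full
#'   [apply_harvest_strategy()] outcomes in attribute `outcomes`.
#' @export
compare_strategies <- function(sim, strategies, scheme = ripening_scheme(),
                               coeffs) {
  outcomes <- lapply(strategies, apply_harvest_strategy, sim = sim,
                     scheme = scheme, coeffs = coeffs)
  tab <- do.call(rbind, lapply(outcomes, function(o)
    data.frame(label = o$strategy$label, mode = o$strategy$mode,
               n_events = o$n_events, total_value = o$total_value,
               saleable_kg = o$total_saleable_g / 1000,
               waste_kg = o$total_waste_g / 1000)))
  tab$value_rel <- tab$total_value / max(tab$total_value)
  ord <- order(-tab$total_value)
  tab <- tab[ord, c("label", "mode", "n_events", "total_value", "value_rel",
                    "saleable_kg", "waste_kg")]
  rownames(tab) <- NULL
  attr(tab, "outcomes") <- outcomes[ord]
  tab
}
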