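#' Simulation configuration for the synthetic feeder-visit generator
#'
#' Bundles every knob of the synthetic RFID study into a single validated
#' list. The defaults emulate the design of a two-site winter feeding
#' experiment: a 12-day baseline with a single familiar-food feeder per site,
#' followed by two 4-day trials in which a novel-food feeder (dyed red or
#' green, colours swapped between trials) sits next to the familiar one.
#' Individuals carry a latent gregariousness that drives both flock joining
#' and (configurably) novel-food preference, so the generator produces data
#' in which sociality and dietary adventurousness are linked by a known,
#' recoverable effect size.
#'
#' @param n_individuals_per_site Number of tagged birds at each site.
#' @param n_sites Number of study sites (default 2).
#' @param baseline_days Days of baseline recording with familiar food only.
#' @param trial_days Days per experimental trial.
#' @param events_per_site_day Poisson mean of the number of flocking events
#'   at one site on one day.
#' @param within_event_sd Standard deviation (seconds) of detection times
#'   around an event's centre.
#' @param between_event_gap_min Minimum separation (seconds) between
#'   consecutive event centres within a site-day. Must exceed
#'   `6 * within_event_sd` so that bursts are separable by construction.
#' @param detections_per_member Poisson mean of the number of extra antenna
#'   reads a member emits per event (every member emits at least one read).
#' @param gregariousness_sd Standard deviation of the latent gregariousness.
#' @param join_intercept,join_slope Logit-scale intercept and per-SD slope of
#'   the probability that an individual joins an event at its site. The
#'   default intercept is calibrated so the typical group size is about 6.8.
#' @param diet_intercept Logit-scale intercept of the probability that a
#'   trial-period read lands on the novel (rather than familiar) feeder.
#' @param diet_slope_sociality Logit units per gregariousness SD added to the
#'   novel-feeder probability: the true sociality-on-diet effect.
#' @param neophobia_slope_sociality Logit units per gregariousness SD applied
#'   only to each bird's chronologically first trial read. The default 0
#'   makes the first-arrival choice independent of sociality, so usage and
#'   neophobia effects can be dissociated.
#' @param site_colour_effect Logit units added to the novel-feeder
#'   probability when the site's novel food is green (negative values encode
#'   a red-over-green preference).
#' @param covariate_effects Named list of logit effects for binary traits:
#'   `sex_M`, `age_adult`, `immigrant`. Defaults are all zero.
#' @param day_length Length (seconds) of the foraging day, dawn to dusk.
#' @param dawn Clock time ("HH:MM:SS") at which the foraging day starts.
#' @param start_date Date of the first baseline day (ISO string or Date).
#' @param seed Integer seed; identical configurations yield identical data.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [simulate_population()], [simulate_period()], [simulate_study()]
#' @export
#' @examples
#' cfg <- sim_config(n_individuals_per_site = 10, seed = 42)
#' cfg$baseline_days
sim_config <- function(n_individuals_per_site = 40,
                       n_sites = 2,
                       baseline_days = 12,
                       trial_days = 4,
                       events_per_site_day = 30,
                       within_event_sd = 15,
                       between_event_gap_min = 300,
                       detections_per_member = 6,
                       gregariousness_sd = 1,
                       join_intercept = -2.05,
                       join_slope = 1,
                       diet_intercept = -0.4,
                       diet_slope_sociality = 0.5,
                       neophobia_slope_sociality = 0,
                       site_colour_effect = -1.5,
                       covariate_effects = list(sex_M = 0, age_adult = 0,
                                                immigrant = 0),
                       day_length = 39600,
                       dawn = "06:00:00",
                       start_date = "2018-01-11",
                       seed = 1L) {
  cfg <- list(
    n_individuals_per_site = n_individuals_per_site,
    n_sites = n_sites,
    baseline_days = baseline_days,
    trial_days = trial_days,
    events_per_site_day = events_per_site_day,
    within_event_sd = within_event_sd,
    between_event_gap_min = between_event_gap_min,
    detections_per_member = detections_per_member,
    gregariousness_sd = gregariousness_sd,
    join_intercept = join_intercept,
    join_slope = join_slope,
    diet_intercept = diet_intercept,
    diet_slope_sociality = diet_slope_sociality,
    neophobia_slope_sociality = neophobia_slope_sociality,
    site_colour_effect = site_colour_effect,
    covariate_effects = covariate_effects,
    day_length = day_length,
    dawn = dawn,
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  count_fields <- c("n_individuals_per_site", "n_sites", "baseline_days",
                    "trial_days")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v)) {
      abort(paste0("sim_config: `", f, "` must be a positive integer count"),
            class = "flocknet_config_error")
    }
  }
  pos_fields <- c("events_per_site_day", "within_event_sd",
                  "between_event_gap_min", "detections_per_member",
                  "gregariousness_sd", "day_length")
  for (f in pos_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      abort(paste0("sim_config: `", f, "` must be a positive number"),
            class = "flocknet_config_error")
    }
  }
  num_fields <- c("join_intercept", "join_slope", "diet_intercept",
                  "diet_slope_sociality", "neophobia_slope_sociality",
                  "site_colour_effect")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort(paste0("sim_config: `", f, "` must be a finite number"),
            class = "flocknet_config_error")
    }
  }
  if (cfg$within_event_sd >= cfg$between_event_gap_min / 6) {
    abort(paste0("sim_config: `within_event_sd` must be below ",
                 "`between_event_gap_min` / 6 so bursts stay separable"),
          class = "flocknet_config_error")
  }
  if (!is.list(cfg$covariate_effects) ||
      !all(c("sex_M", "age_adult", "immigrant") %in%
             names(cfg$covariate_effects))) {
    abort(paste0("sim_config: `covariate_effects` must name ",
                 "sex_M, age_adult and immigrant"),
          class = "flocknet_config_error")
  }
  if (is.na(cfg$seed)) {
    abort("sim_config: `seed` must be an integer",
          class = "flocknet_config_error")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  sites:", x$n_sites, " birds/site:", x$n_individuals_per_site, "\n")
  cat("  days: baseline", x$baseline_days, "+ 2 trials x", x$trial_days, "\n")
  cat("  events/site-day:", x$events_per_site_day,
      " burst sd:", x$within_event_sd, "s  gap >=",
      x$between_event_gap_min, "s\n")
  cat("  diet slope (per sociality SD):", x$diet_slope_sociality,
      " colour effect (green):", x$site_colour_effect, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# period layout implied by a config: names, day offsets, dates
period_layout <- function(cfg) {
  tibble::tibble(
    period = c("baseline", "trial1", "trial2"),
    n_days = c(cfg$baseline_days, cfg$trial_days, cfg$trial_days),
    first_day = cumsum(c(0, cfg$baseline_days, cfg$trial_days)) + 1
  )
}

# which colour is novel at each site in each trial; site 1 starts red
novel_colour_for <- function(site_index, period) {
  first_red <- site_index %% 2 == 1
  if (period == "trial1") {
    if (first_red) "red" else "green"
  } else {
    if (first_red) "green" else "red"
  }
}
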