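#' Simulate one period of RFID feeder detections with ground truth
#'
#' Produces the bursty detection stream of one study period at every site.
#' For each site-day the number of flocking events is Poisson, event centres
#' are placed at least `between_event_gap_min` seconds apart within the
#' foraging day, each bird at the site joins an event with probability
#' `plogis(join_intercept + join_slope * z)` (z = standardised
#' gregariousness), and each member emits `1 + Poisson(detections_per_member)`
#' reads at Normal(centre, `within_event_sd`) times. During trials each read
#' is assigned to the novel feeder with probability
#' `plogis(diet_intercept + adventurousness + site_colour_effect * green)`;
#' each bird's chronologically first trial read instead uses
#' `neophobia_slope_sociality`, so first-arrival behaviour can be decoupled
#' from the usage effect.
#'
#' @param population Tibble from [simulate_population()].
#' @param config The [sim_config()] used to generate the population.
#' @param period One of `"baseline"`, `"trial1"`, `"trial2"`.
#' @return A list with `detections` (tibble: `tag_id`, `timestamp`,
#'   `site_id`, `feeder_id`, `food_type`, `period`, `feeder_position`,
#'   `novel_colour`, `day`, `time_s`, `true_event_id`) and `truth` (tibble of
#'   true events with list-column `member_ids`).
#' @export
simulate_period <- function(population, config,
                            period = c("baseline", "trial1", "trial2")) {
  period <- match.arg(period)
  validate_sim_config(config)
  if (!is.data.frame(population) || nrow(population) == 0) {
    abort("simulate_period(): `population` is empty", class = "flocknet_error")
  }
  layout <- period_layout(config)
  row <- layout[layout$period == period, ]
  period_index <- match(period, layout$period)

  withr::with_seed(config$seed + period_index * 1009L, {
    site_ids <- unique(population$site_id)
    det <- vector("list", length(site_ids))
    tru <- vector("list", length(site_ids))
    for (si in seq_along(site_ids)) {
      site <- site_ids[si]
      birds <- population[population$site_id == site, ]
      z <- birds$gregariousness / config$gregariousness_sd
      p_join <- plogis(config$join_intercept + config$join_slope * z)
      out <- simulate_site_period(birds, p_join, site, si, period, row, config)
      det[[si]] <- out$detections
      tru[[si]] <- out$truth
    }
    detections <- dplyr::bind_rows(det)
    truth <- dplyr::bind_rows(tru)
  })

  detections <- dplyr::arrange(detections, .data$site_id, .data$day,
                               .data$time_s, .data$tag_id)
  list(detections = detections, truth = truth)
}

# one site x one period; called inside the period's seeded RNG stream
simulate_site_period <- function(birds, p_join, site, site_index, period,
                                 layout_row, config) {
  L <- config$day_length
  gap <- config$between_event_gap_min
  margin <- 5 * config$within_event_sd
  n_birds <- nrow(birds)
  days <- layout_row$first_day + seq_len(layout_row$n_days) - 1L
  is_trial <- period != "baseline"
  colour <- if (is_trial) novel_colour_for(site_index, period) else NA_character_
  green <- isTRUE(colour == "green")

  det_days <- vector("list", length(days))
  tru_days <- vector("list", length(days))
  for (di in seq_along(days)) {
    day <- days[di]
    n_ev <- rpois(1, config$events_per_site_day)
    n_max <- max(1L, floor((L - 2 * margin) / gap) + 1L)
    n_ev <- min(n_ev, n_max)
    if (n_ev == 0) next
    span <- (L - 2 * margin) - (n_ev - 1) * gap
    centres <- margin + sort(runif(n_ev, 0, span)) + (seq_len(n_ev) - 1) * gap

    memb <- matrix(runif(n_ev * n_birds) < rep(p_join, each = n_ev),
                   nrow = n_ev)
    keep <- rowSums(memb) > 0
    if (!any(keep)) next
    memb <- memb[keep, , drop = FALSE]
    centres <- centres[keep]
    n_ev <- sum(keep)

    idx <- which(memb, arr.ind = TRUE) # one row per (event, bird) membership
    n_reads <- rpois(nrow(idx), config$detections_per_member) + 1L
    ev_of_read <- rep(idx[, 1], n_reads)
    bird_of_read <- rep(idx[, 2], n_reads)
    t_read <- round(pmin(pmax(
      rnorm(length(ev_of_read), centres[ev_of_read],
            config$within_event_sd), 0), L), 3)

    event_id <- sprintf("%s_d%02d_e%03d", site, day, seq_len(n_ev))
    dd <- tibble::tibble(
      tag_id = birds$tag_id[bird_of_read],
      site_id = site,
      period = period,
      day_index = day,
      time_s = t_read,
      true_event_id = event_id[ev_of_read]
    )

    if (is_trial) {
      eta <- config$diet_intercept + birds$adventurousness[bird_of_read] +
        config$site_colour_effect * green
      novel <- runif(nrow(dd)) < plogis(eta)
      # first read of each bird in this site-day is provisionally marked;
      # the true period-level first read is re-drawn below
      dd$food_type <- ifelse(novel, "novel", "familiar")
    } else {
      dd$food_type <- "baseline"
    }
    det_days[[di]] <- dd
    tru_days[[di]] <- tibble::tibble(
      event_id = event_id,
      site_id = site,
      period = period,
      day = day,
      centre_time = centres,
      n_members = rowSums(memb),
      member_ids = lapply(seq_len(n_ev),
                          function(e) birds$tag_id[memb[e, ]])
    )
  }

  det <- dplyr::bind_rows(det_days)
  tru <- dplyr::bind_rows(tru_days)
  if (nrow(det) > 0 && is_trial) {
    # redraw each bird's chronologically first read of the period with the
    # neophobia logit (sociality enters only via neophobia_slope_sociality)
    ord <- order(det$day_index, det$time_s)
    first_idx <- ord[!duplicated(det$tag_id[ord])]
    z_first <- birds$gregariousness[match(det$tag_id[first_idx],
                                          birds$tag_id)] /
      config$gregariousness_sd
    ce <- config$covariate_effects
    b_first <- birds[match(det$tag_id[first_idx], birds$tag_id), ]
    eta_first <- config$diet_intercept +
      config$neophobia_slope_sociality * z_first +
      config$site_colour_effect * green +
      ce$sex_M * (b_first$sex == "M") +
      ce$age_adult * (b_first$age == "adult") +
      ce$immigrant * b_first$immigrant
    det$food_type[first_idx] <- ifelse(runif(length(first_idx)) <
                                         plogis(eta_first),
                                       "novel", "familiar")
  }
  if (nrow(det) > 0) {
    det$feeder_id <- if (is_trial) {
      paste0(site, "_", ifelse(det$food_type == "novel", "NOV", "FAM"))
    } else {
      paste0(site, "_F1")
    }
    det$feeder_position <- ifelse(det$day_index %% 2 == 0,
                                  "swapped", "standard")
    det$novel_colour <- colour
    date <- config$start_date + det$day_index - 1L
    det$day <- date
    start_epoch <- unclass(as.Date(config$start_date)) * 86400
    det$timestamp <- structure(
      start_epoch + (det$day_index - 1) * 86400 +
        dawn_seconds(config$dawn) + det$time_s,
      class = c("POSIXct", "POSIXt"), tzone = "UTC")
    det <- det[, c("tag_id", "timestamp", "site_id", "feeder_id",
                   "food_type", "period", "feeder_position", "novel_colour",
                   "day", "time_s", "true_event_id")]
  }
  list(detections = det, truth = tru)
}

dawn_seconds <- function(dawn) {
  p <- as.numeric(strsplit(dawn, ":", fixed = TRUE)[[1]])
  p[1] * 3600 + p[2] * 60 + p[3]
}

#' Simulate a complete synthetic study (baseline plus two trials)
#'
#' Convenience wrapper running [simulate_population()] and
#' [simulate_period()] for the baseline and both trials under one seed.
#'
#' @param config A [sim_config()].
#' @return A list with `population`, `detections` (all periods, row-bound),
#'   `truth` (all true events) and `config`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_individuals_per_site = 8,
#'                                    baseline_days = 2, trial_days = 1,
#'                                    events_per_site_day = 5, seed = 3))
#' dplyr::count(study$detections, period)
simulate_study <- function(config) {
  population <- simulate_population(config)
  parts <- lapply(c("baseline", "trial1", "trial2"), function(p) {
    simulate_period(population, config, p)
  })
  list(
    population = population,
    detections = dplyr::bind_rows(lapply(parts, `[[`, "detections")),
    truth = dplyr::bind_rows(lapply(parts, `[[`, "truth")),
    config = config
  )
}
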