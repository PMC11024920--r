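#' Per-individual trial responses: novel-food usage, neophobia, latency
#'
#' Summarises one experimental trial's detection stream into one row per
#' bird detected during the trial:
#' \describe{
#'   \item{novel_count, familiar_count}{Detections on the novel and familiar
#'     feeders over the whole trial ("successes" and "fails" of the usage
#'     models).}
#'   \item{first_arrival_novel}{Whether the bird's chronologically first
#'     trial record was on the novel feeder.}
#'   \item{latency_clock}{Clock time (seconds since midnight) of the first
#'     novel-feeder record on its first-use day; `NA` for never-users.}
#'   \item{latency_elapsed}{Foraging time (seconds, nights excluded) between
#'     the bird's first trial detection and its first novel-feeder record;
#'     0 if the first record was on the novel feeder; `NA` for never-users.}
#'   \item{post_first_novel_count, post_first_familiar_count}{Counts
#'     strictly after the first novel-feeder record (0 for never-users).}
#' }
#'
#' @param trial_detections Detections restricted to one trial; every record
#'   must carry `food_type` `"novel"` or `"familiar"`.
#' @param dawn,day_length Foraging-day window used to accumulate
#'   `latency_elapsed` across days.
#' @return A tibble with one row per individual, keyed by `tag_id`.
#' @export
build_responses <- function(trial_detections, dawn = "06:00:00",
                            day_length = 39600) {
  det <- trial_detections
  if (nrow(det) == 0) {
    abort("build_responses(): empty trial stream", class = "flocknet_error")
  }
  if (!"food_type" %in% names(det) || anyNA(det$food_type) ||
      !all(det$food_type %in% c("novel", "familiar"))) {
    abort(paste0("build_responses(): every trial record needs food_type ",
                 "'novel' or 'familiar'"), class = "flocknet_validation_error")
  }
  if (length(unique(det$period)) > 1) {
    abort("build_responses(): stream spans more than one trial",
          class = "flocknet_validation_error")
  }
  if (!"time_s" %in% names(det) || !"day" %in% names(det)) {
    abort("build_responses(): need `time_s` and `day` columns",
          class = "flocknet_error")
  }
  det <- dplyr::arrange(det, .data$tag_id, .data$day, .data$time_s)
  day0 <- min(det$day)
  det$day_n <- as.numeric(det$day - day0)

  dplyr::group_by(det, .data$tag_id) |>
    dplyr::group_modify(function(d, key) {
      novel <- d$food_type == "novel"
      first_nov <- if (any(novel)) which(novel)[1] else NA_integer_
      if (!is.na(first_nov)) {
        lat_clock <- dawn_seconds(dawn) + d$time_s[first_nov]
        lat_elapsed <- elapsed_foraging(
          d$day_n[1], d$time_s[1],
          d$day_n[first_nov], d$time_s[first_nov], day_length)
        after <- seq_len(nrow(d)) > first_nov
      } else {
        lat_clock <- NA_real_
        lat_elapsed <- NA_real_
        after <- rep(FALSE, nrow(d))
      }
      tibble::tibble(
        site_id = d$site_id[1],
        period = d$period[1],
        novel_count = sum(novel),
        familiar_count = sum(!novel),
        n_detections = nrow(d),
        first_arrival_novel = novel[1],
        first_day = d$day[1],
        first_time_s = d$time_s[1],
        latency_clock = lat_clock,
        latency_elapsed = lat_elapsed,
        post_first_novel_count = sum(novel & after),
        post_first_familiar_count = sum(!novel & after)
      )
    }) |>
    dplyr::ungroup()
}

# foraging seconds between (day1, t1) and (day2, t2), nights excluded
elapsed_foraging <- function(day1, t1, day2, t2, day_length) {
  t1 <- min(max(t1, 0), day_length)
  t2 <- min(max(t2, 0), day_length)
  if (day2 == day1) return(t2 - t1)
  (day_length - t1) + (day2 - day1 - 1) * day_length + t2
}

#' Prior-period detection counts per individual
#'
#' Raw count of all feeder detections per bird in the period immediately
#' preceding a trial, used as the observation-effort covariate.
#'
#' @param prior_detections Detection tibble from the prior period.
#' @return A tibble `tag_id`, `prior_detections`.
#' @export
prior_detection_counts <- function(prior_detections) {
  if (nrow(prior_detections) == 0) {
    return(tibble::tibble(tag_id = character(), prior_detections = integer()))
  }
  dplyr::count(prior_detections, .data$tag_id, name = "prior_detections")
}
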