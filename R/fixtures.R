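#' Write a simulated study to CSV fixtures
#'
#' Serialises the detection stream, trait table and ground truth as plain
#' CSV. Timestamps are written as ISO-8601 with millisecond precision and
#' round-trip through [read_detections()] at that resolution.
#'
#' @param detections Detection tibble (from [simulate_period()] or
#'   [simulate_study()]).
#' @param population Population tibble; its public columns become
#'   `traits.csv`, the full table (with latent variables) becomes
#'   `truth_individuals.csv`.
#' @param truth True-event tibble, or `NULL` to skip the truth files.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixtures <- function(detections, population, truth, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("write_fixtures(): cannot create directory ", dir),
                   class = "flocknet_io_error")
  }
  paths <- c(detections = file.path(dir, "detections.csv"),
             traits = file.path(dir, "traits.csv"))
  pub <- c("tag_id", "timestamp", "site_id", "feeder_id", "food_type",
           "period", "feeder_position", "novel_colour")
  det_out <- detections[, intersect(pub, names(detections)), drop = FALSE]
  if ("timestamp" %in% names(det_out)) {
    det_out$timestamp <- format(det_out$timestamp,
                                "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  }
  readr::write_csv(det_out, paths[["detections"]], progress = FALSE)
  readr::write_csv(population[, c("tag_id", "site_id", "sex", "age",
                                  "immigrant")],
                   paths[["traits"]], progress = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths,
               truth_events = file.path(dir, "truth_events.csv"),
               truth_individuals = file.path(dir, "truth_individuals.csv"))
    tr <- truth
    tr$member_ids <- vapply(tr$member_ids, paste, "", collapse = ";")
    readr::write_csv(tr, paths[["truth_events"]], progress = FALSE)
    readr::write_csv(population, paths[["truth_individuals"]],
                     progress = FALSE)
  }
  invisible(paths)
}

#' Read an RFID detection log
#'
#' Parses a detection CSV (columns `tag_id`, `timestamp`, `site_id`,
#' `feeder_id`, `food_type`, `period`, plus any extras) and derives the
#' within-day working columns: `day` (date) and `time_s` (seconds since the
#' foraging day's dawn).
#'
#' @param path CSV file path.
#' @param dawn Clock time at which the foraging day starts ("HH:MM:SS").
#' @return A detection tibble ordered by site, day and time.
#' @export
read_detections <- function(path, dawn = "06:00:00") {
  if (!file.exists(path)) {
    abort(paste0("read_detections(): no such file: ", path),
          class = "flocknet_io_error")
  }
  det <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           tag_id = readr::col_character(),
                           timestamp = readr::col_character(),
                           .default = readr::col_guess()))
  if (nrow(det) == 0) {
    det$timestamp <- as.POSIXct(character(), tz = "UTC")
    det$day <- as.Date(character())
    det$time_s <- numeric()
    return(det)
  }
  ts <- as.POSIXct(det$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    abort(paste0("read_detections(): unparseable timestamp at data row ",
                 bad, " of ", path), class = "flocknet_io_error")
  }
  det$timestamp <- ts
  det$day <- as.Date(ts, tz = "UTC")
  det$time_s <- as.numeric(ts) -
    as.numeric(as.POSIXct(as.character(det$day), tz = "UTC")) -
    dawn_seconds(dawn)
  dplyr::arrange(det, .data$site_id, .data$day, .data$time_s, .data$tag_id)
}

#' Read a per-individual trait table
#'
#' @param path CSV with columns `tag_id`, `site_id`, `sex`, `age`,
#'   `immigrant`.
#' @return A trait tibble.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("read_traits(): no such file: ", path),
          class = "flocknet_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    tag_id = readr::col_character(),
                    site_id = readr::col_character(),
                    sex = readr::col_character(),
                    age = readr::col_character(),
                    immigrant = readr::col_logical()))
}
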