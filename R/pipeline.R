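#' Configuration for an end-to-end pipeline run
#'
#' A serialisable bundle of everything a run needs: either a [sim_config()]
#' (simulate the study) or input CSV paths, the segmentation parameters,
#' the model grid and the permutation plan. A saved configuration re-creates
#' a run exactly.
#'
#' @param sim A [sim_config()], or `NULL` when reading data from files.
#' @param detections_file,traits_file Input CSVs when `sim` is `NULL`.
#' @param gmm List of [detect_flocks()] parameters.
#' @param usage_metrics Centrality metrics fitted against proportional
#'   novel-food usage (one model each).
#' @param extra_responses Additional responses fitted against `strength`.
#' @param covariates Model covariates.
#' @param n_permutations Permutations per model.
#' @param collapse_window Seconds within which repeated reads of one bird
#'   at one feeder collapse to a single detection (0 disables).
#' @param seed Master seed for every stage.
#' @return A `run_config` object.
#' @export
run_config <- function(sim = sim_config(),
                       detections_file = NULL, traits_file = NULL,
                       gmm = list(max_components = 100,
                                  weight_prune_threshold = NULL,
                                  n_init = 1, model = "tied"),
                       usage_metrics = c("strength", "average_edge_weight",
                                         "eigenvector", "mean_flock_size",
                                         "n_unique_associates"),
                       extra_responses = c("neophobia_arrival",
                                           "latency_clock",
                                           "latency_elapsed",
                                           "post_first_usage"),
                       covariates = c("site_id", "sex", "age", "immigrant",
                                      "prior_detections"),
                       n_permutations = 10000,
                       collapse_window = 1,
                       seed = 1L) {
  if (is.null(sim) && is.null(detections_file)) {
    abort("run_config(): give either `sim` or `detections_file`",
          class = "flocknet_config_error")
  }
  structure(list(sim = sim, detections_file = detections_file,
                 traits_file = traits_file, gmm = gmm,
                 usage_metrics = usage_metrics,
                 extra_responses = extra_responses,
                 covariates = covariates,
                 n_permutations = n_permutations,
                 collapse_window = collapse_window,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$sim)) {
    x$sim <- unclass(x$sim)
    x$sim$start_date <- as.character(x$sim$start_date)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- if (!is.null(x$sim)) do.call(sim_config, x$sim) else NULL
  run_config(sim = sim, detections_file = x$detections_file,
             traits_file = x$traits_file, gmm = x$gmm,
             usage_metrics = x$usage_metrics,
             extra_responses = x$extra_responses,
             covariates = x$covariates,
             n_permutations = x$n_permutations,
             collapse_window = x$collapse_window, seed = x$seed)
}

#' Validate a detection table
#'
#' Schema and plausibility checks on a detection log: required columns,
#' legal `food_type` and `period` values, missing tags or timestamps, and
#' repeated reads of one bird at one feeder within `dup_window` seconds
#' (flagged, since a perched bird otherwise dominates counts; see
#' [collapse_detections()]). Row order is not required.
#'
#' @param detections A detection tibble or a CSV path.
#' @param dup_window Duplicate-read window in seconds.
#' @return A tibble of issues (`row`, `field`, `issue`); zero rows when
#'   clean.
#' @export
validate_detections <- function(detections, dup_window = 1) {
  if (is.character(detections)) detections <- read_detections(detections)
  issues <- list()
  required <- c("tag_id", "timestamp", "site_id", "feeder_id", "food_type",
                "period")
  miss <- setdiff(required, names(detections))
  if (length(miss) > 0) {
    issues <- c(issues, list(tibble::tibble(
      row = NA_integer_, field = miss, issue = "missing column")))
  }
  if ("tag_id" %in% names(detections)) {
    bad <- which(is.na(detections$tag_id) | detections$tag_id == "")
    if (length(bad) > 0) {
      issues <- c(issues, list(tibble::tibble(
        row = bad, field = "tag_id", issue = "empty tag id")))
    }
  }
  if ("timestamp" %in% names(detections)) {
    bad <- which(is.na(detections$timestamp))
    if (length(bad) > 0) {
      issues <- c(issues, list(tibble::tibble(
        row = bad, field = "timestamp", issue = "missing timestamp")))
    }
  }
  if ("food_type" %in% names(detections)) {
    bad <- which(!detections$food_type %in% c("baseline", "novel",
                                              "familiar"))
    if (length(bad) > 0) {
      issues <- c(issues, list(tibble::tibble(
        row = bad, field = "food_type",
        issue = paste0("unknown food_type '",
                       detections$food_type[bad], "'"))))
    }
  }
  if ("period" %in% names(detections)) {
    bad <- which(!detections$period %in% c("baseline", "trial1", "trial2"))
    if (length(bad) > 0) {
      issues <- c(issues, list(tibble::tibble(
        row = bad, field = "period",
        issue = paste0("unknown period '", detections$period[bad], "'"))))
    }
  }
  if (all(c("tag_id", "feeder_id", "timestamp") %in% names(detections)) &&
        nrow(detections) > 1) {
    ord <- order(detections$tag_id, detections$feeder_id,
                 detections$timestamp)
    d <- detections[ord, ]
    same <- d$tag_id[-1] == d$tag_id[-nrow(d)] &
      d$feeder_id[-1] == d$feeder_id[-nrow(d)]
    close <- as.numeric(difftime(d$timestamp[-1], d$timestamp[-nrow(d)],
                                 units = "secs")) <= dup_window
    dup <- which(same & close) + 1
    if (length(dup) > 0) {
      issues <- c(issues, list(tibble::tibble(
        row = ord[dup], field = "timestamp",
        issue = paste0("repeated read within ", dup_window, " s"))))
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(row = integer(), field = character(),
                          issue = character()))
  }
  dplyr::arrange(dplyr::bind_rows(issues), .data$row)
}

#' Collapse repeated antenna reads into detections
#'
#' RFID antennae scan many times per second, so a perched bird produces an
#' unbroken run of reads. Within each bird-feeder series, consecutive reads
#' separated by at most `window` seconds are collapsed into the bout's
#' first read.
#'
#' @param detections Detection tibble with `tag_id`, `feeder_id` and
#'   `time_s`/`day` (or `timestamp`).
#' @param window Bout gap in seconds; 0 returns the input unchanged.
#' @return The collapsed detection tibble.
#' @export
collapse_detections <- function(detections, window = 1) {
  if (window <= 0 || nrow(detections) < 2) return(detections)
  t_abs <- if ("timestamp" %in% names(detections)) {
    as.numeric(detections$timestamp)
  } else {
    as.numeric(detections$day) * 86400 + detections$time_s
  }
  ord <- order(detections$tag_id, detections$feeder_id, t_abs)
  d <- detections[ord, ]
  ts <- t_abs[ord]
  new_bout <- c(TRUE, d$tag_id[-1] != d$tag_id[-nrow(d)] |
                  d$feeder_id[-1] != d$feeder_id[-nrow(d)] |
                  diff(ts) > window)
  out <- d[new_bout, ]
  if (all(c("site_id", "day", "time_s") %in% names(out))) {
    out <- dplyr::arrange(out, .data$site_id, .data$day, .data$time_s,
                          .data$tag_id)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, validate, collapse, flock detection, network
#' construction, response building, model fitting and permutation testing,
#' writing every intermediate product to `out_dir`. Trial-1 models use
#' baseline-period networks and covariates, trial-2 models use
#' trial-1-period networks; a trial whose prior period is absent from the
#' data is skipped with a logged reason. The run is a pure function of the
#' configuration: re-running with the same `run_config` reproduces
#' `results.csv` byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `results` (tibble: one row per model
#'   term), `metrics`, `events`, `densities` and the output paths.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  completed <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  finish <- function(status) {
    writeLines(log_lines, file.path(out_dir, "run.log"))
    writeLines(c(paste0("status: ", status),
                 paste0("completed: ", paste(completed, collapse = ", "))),
               file.path(out_dir, "MANIFEST"))
  }

  result <- tryCatch({
    # ---- data ----
    if (!is.null(config$sim)) {
      say("simulating study (seed ", config$sim$seed, ")")
      study <- simulate_study(config$sim)
      detections <- study$detections
      traits <- study$population[, c("tag_id", "site_id", "sex", "age",
                                     "immigrant")]
      write_fixtures(detections, study$population, study$truth, out_dir)
    } else {
      say("reading ", config$detections_file)
      detections <- read_detections(config$detections_file)
      traits <- if (!is.null(config$traits_file)) {
        read_traits(config$traits_file)
      } else {
        NULL
      }
    }
    completed <- c(completed, "data")

    # ---- validate ----
    issues <- validate_detections(detections)
    if (nrow(issues) > 0) {
      say(nrow(issues), " validation issue(s); see validation_issues.csv")
      readr::write_csv(issues, file.path(out_dir, "validation_issues.csv"),
                       progress = FALSE)
      hard <- issues$issue[!grepl("repeated read", issues$issue)]
      if (length(hard) > 0) {
        abort(paste0("run_pipeline(): validation failed: ", hard[1]),
              class = "flocknet_validation_error")
      }
    }
    completed <- c(completed, "validate")

    # ---- collapse ----
    n0 <- nrow(detections)
    detections <- collapse_detections(detections, config$collapse_window)
    if (nrow(detections) < n0) {
      say("collapsed ", n0 - nrow(detections), " repeated read(s)")
    }
    completed <- c(completed, "collapse")

    # ---- flock detection ----
    say("segmenting flocking events")
    gmm <- config$gmm
    events <- detect_flocks(
      detections,
      max_components = gmm$max_components %||% 100,
      weight_prune_threshold = gmm$weight_prune_threshold,
      n_init = gmm$n_init %||% 1,
      seed = config$seed,
      model = gmm$model %||% "tied")
    say(nrow(events), " events across ",
        length(unique(paste(events$site_id, events$day))), " site-days")
    ev_out <- events
    ev_out$member_ids <- vapply(ev_out$member_ids, paste, "",
                                collapse = ";")
    readr::write_csv(ev_out, file.path(out_dir, "events.csv"),
                     progress = FALSE)
    completed <- c(completed, "detect")

    # ---- networks & metrics, per site and period ----
    say("building SRI networks")
    periods <- unique(events$period)
    det_counts <- dplyr::count(event_assignments(events), .data$period,
                               .data$site_id, .data$tag_id)
    metrics_list <- list()
    densities <- list()
    for (p in periods) {
      ev_p <- events[events$period == p, ]
      gbi_p <- build_gbi(ev_p)
      gbi_out <- tibble::as_tibble(gbi_p, rownames = "event_id")
      readr::write_csv(gbi_out,
                       file.path(out_dir, paste0("gbi_", p, ".csv")),
                       progress = FALSE)
      for (s in unique(ev_p$site_id)) {
        ev_ps <- ev_p[ev_p$site_id == s, ]
        gbi_ps <- build_gbi(ev_ps)
        net <- sri_network(gbi_ps, period = p)
        export_network(net, file.path(out_dir,
                                      paste0("network_", p, "_", s, ".csv")))
        cnt <- det_counts[det_counts$period == p & det_counts$site_id == s, ]
        m <- node_metrics(net, gbi_ps,
                          stats::setNames(cnt$n, cnt$tag_id))
        m$site_id <- s
        metrics_list[[paste(p, s)]] <- m
        if (nrow(net$weights) >= 2) {
          densities[[paste(p, s)]] <- tibble::tibble(
            period = p, site_id = s, n_nodes = nrow(net$weights),
            n_edges = sum(net$weights[upper.tri(net$weights)] > 0),
            density_pct = network_density(net))
        }
      }
    }
    metrics <- dplyr::bind_rows(metrics_list)
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"),
                     progress = FALSE)
    densities <- dplyr::bind_rows(densities)
    readr::write_csv(densities, file.path(out_dir, "densities.csv"),
                     progress = FALSE)
    completed <- c(completed, "network")

    # ---- responses & models ----
    say("fitting dietary models")
    prior_of <- c(trial1 = "baseline", trial2 = "trial1")
    results <- list()
    responses_all <- list()
    null_dir <- file.path(out_dir, "null_distributions")
    model_i <- 0L
    for (trial in intersect(c("trial1", "trial2"), periods)) {
      prior_p <- prior_of[[trial]]
      if (!prior_p %in% periods) {
        say("skipping ", trial, " models: prior period ", prior_p,
            " absent from the data")
        next
      }
      resp <- build_responses(
        detections[detections$period == trial, ])
      responses_all[[trial]] <- resp
      prior_counts <- prior_detection_counts(
        detections[detections$period == prior_p, ])
      mdat <- assemble_model_data(
        resp, metrics[metrics$period == prior_p, ], traits, prior_counts)

      specs <- rbind(
        expand.grid(response = "usage", metric = config$usage_metrics,
                    stringsAsFactors = FALSE),
        expand.grid(response = config$extra_responses, metric = "strength",
                    stringsAsFactors = FALSE))
      for (k in seq_len(nrow(specs))) {
        model_i <- model_i + 1L
        fit <- fit_dietary_glm(mdat, response = specs$response[k],
                               metric = specs$metric[k],
                               covariates = config$covariates)
        pt <- permutation_test(fit,
                               n_permutations = config$n_permutations,
                               seed = config$seed + model_i)
        if (!dir.exists(null_dir)) dir.create(null_dir)
        readr::write_csv(
          tibble::as_tibble(pt$null),
          file.path(null_dir, paste0("null_", trial, "_",
                                     specs$response[k], "_",
                                     specs$metric[k], ".csv")),
          progress = FALSE)
        row <- dplyr::left_join(tidy(fit), tidy(pt)[, c("term", "p_rand")],
                                by = "term")
        row <- dplyr::mutate(row, trial = trial,
                             response = specs$response[k],
                             metric = specs$metric[k],
                             dispersion = fit$dispersion,
                             n_obs = fit$n_obs, .before = 1)
        results[[model_i]] <- row
      }
    }
    if (length(responses_all) > 0) {
      readr::write_csv(dplyr::bind_rows(responses_all),
                       file.path(out_dir, "responses.csv"),
                       progress = FALSE)
    }
    results <- dplyr::bind_rows(results)
    if (nrow(results) > 0) {
      readr::write_csv(results, file.path(out_dir, "results.csv"),
                       progress = FALSE)
      jsonlite::write_json(results, file.path(out_dir, "results.json"),
                           digits = NA, pretty = TRUE)
    }
    completed <- c(completed, "models")

    say("done")
    finish("ok")
    list(results = results, metrics = metrics, events = events,
         densities = densities,
         responses = dplyr::bind_rows(responses_all),
         out_dir = out_dir)
  }, error = function(e) {
    say("ERROR: ", conditionMessage(e))
    finish("failed")
    stop(e)
  })
  invisible(result)
}
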