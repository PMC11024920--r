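# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# detection tibble from explicit (tag, time) bursts on one site-day
make_stream <- function(times, tags, site = "S1", day = as.Date("2018-01-11"),
                        period = "baseline", food_type = "baseline") {
  tibble::tibble(
    tag_id = tags, site_id = site, day = day, time_s = times,
    period = period, food_type = food_type,
    feeder_id = paste0(site, "_F1"))
}

# bird-level usage data with a known sociality effect on the novel logit;
# returns a modelling table compatible with fit_dietary_glm()
make_bird_usage <- function(n, slope, intercept = -0.4, mean_total = 40,
                            strata = NULL) {
  z <- rnorm(n)
  total <- rpois(n, mean_total) + 1
  novel <- rbinom(n, total, plogis(intercept + slope * z))
  tibble::tibble(
    tag_id = sprintf("U%04d", seq_len(n)),
    site_id = strata %||% rep("S1", n),
    strength = z,
    novel_count = novel,
    familiar_count = total - novel)
}

# full single-site generator replicate: truth-event network -> strengths,
# trial responses, prior counts; returns the assembled modelling table
make_replicate_data <- function(n_birds, diet_slope, seed,
                                baseline_days = 12, trial_days = 4) {
  cfg <- sim_config(n_individuals_per_site = n_birds, n_sites = 1,
                    baseline_days = baseline_days, trial_days = trial_days,
                    diet_slope_sociality = diet_slope, seed = seed)
  pop <- simulate_population(cfg)
  base <- simulate_period(pop, cfg, "baseline")
  trial <- simulate_period(pop, cfg, "trial1")
  gbi <- build_gbi(base$truth)
  net <- sri_network(gbi, period = "baseline")
  metrics <- node_metrics(net, gbi)
  resp <- build_responses(trial$detections)
  prior <- prior_detection_counts(base$detections)
  suppressMessages(
    assemble_model_data(resp, metrics, traits = pop, prior = prior))
}

expect_no_issue_rows <- function(issues) {
  testthat::expect_identical(nrow(issues), 0L)
}
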