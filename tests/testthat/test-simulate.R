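test_that("population has the configured size and unique tags per site", {
  cfg <- sim_config(n_individuals_per_site = 20, n_sites = 2, seed = 3)
  pop <- simulate_population(cfg)
  expect_identical(nrow(pop), 40L)
  expect_equal(unname(table(pop$site_id)), c(20L, 20L), ignore_attr = TRUE)
  expect_false(anyDuplicated(pop$tag_id) > 0)
  expect_true(all(pop$sex %in% c("M", "F")))
  expect_true(all(pop$age %in% c("adult", "juvenile")))
})

test_that("identical config and seed reproduce the simulation exactly", {
  cfg <- sim_config(n_individuals_per_site = 10, baseline_days = 2,
                    trial_days = 1, events_per_site_day = 6, seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$truth, s2$truth)
})

test_that("latent gregariousness follows its configured distribution", {
  cfg <- sim_config(n_individuals_per_site = 5000, n_sites = 2,
                    gregariousness_sd = 1, seed = 29)
  pop <- simulate_population(cfg)
  expect_lt(abs(sd(pop$gregariousness) - 1), 0.03)
  expect_lt(abs(mean(pop$gregariousness)), 0.05)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_sites = 0), "n_sites",
               class = "flocknet_config_error")
  expect_error(sim_config(events_per_site_day = -1), "events_per_site_day",
               class = "flocknet_config_error")
  expect_error(sim_config(within_event_sd = 100,
                          between_event_gap_min = 300),
               "within_event_sd", class = "flocknet_config_error")
  expect_error(sim_config(join_slope = NA), "join_slope",
               class = "flocknet_config_error")
})

test_that("with null slopes, novel-food use is independent of sociality", {
  cfg <- sim_config(n_individuals_per_site = 500, n_sites = 2,
                    trial_days = 4, join_slope = 0,
                    diet_slope_sociality = 0, seed = 17)
  pop <- simulate_population(cfg)
  trial <- simulate_period(pop, cfg, "trial1")
  prop <- trial$detections |>
    dplyr::group_by(tag_id) |>
    dplyr::summarise(p = mean(food_type == "novel"))
  prop$greg <- pop$gregariousness[match(prop$tag_id, pop$tag_id)]
  expect_lt(abs(cor(prop$p, prop$greg)), 0.05)
})

test_that("a positive diet slope raises novel use in gregarious birds", {
  cfg <- sim_config(n_individuals_per_site = 100, n_sites = 2,
                    diet_slope_sociality = 0.5, seed = 19)
  pop <- simulate_population(cfg)
  trial <- simulate_period(pop, cfg, "trial1")
  prop <- trial$detections |>
    dplyr::group_by(tag_id) |>
    dplyr::summarise(p = mean(food_type == "novel"), n = dplyr::n())
  prop$greg <- pop$gregariousness[match(prop$tag_id, pop$tag_id)]
  q <- quantile(prop$greg, c(0.25, 0.75))
  expect_gt(mean(prop$p[prop$greg >= q[2]]),
            mean(prop$p[prop$greg <= q[1]]))
})

test_that("tight bursts place every read near exactly one true centre", {
  cfg <- sim_config(n_individuals_per_site = 15, n_sites = 1,
                    baseline_days = 3, within_event_sd = 2,
                    between_event_gap_min = 600, seed = 23)
  pop <- simulate_population(cfg)
  out <- simulate_period(pop, cfg, "baseline")
  centres <- setNames(out$truth$centre_time, out$truth$event_id)
  ev_day <- setNames(out$truth$day, out$truth$event_id)
  d_own <- abs(out$detections$time_s - centres[out$detections$true_event_id])
  expect_true(all(d_own <= 5 * cfg$within_event_sd))
  # within its own day, no read is near any other event's centre
  read_day <- out$truth$day[match(out$detections$true_event_id,
                                  out$truth$event_id)]
  n_near <- vapply(seq_len(nrow(out$detections)), function(i) {
    same_day <- ev_day == read_day[i]
    sum(abs(out$detections$time_s[i] - centres[same_day]) <=
          5 * cfg$within_event_sd)
  }, 0)
  expect_true(all(n_near == 1))
})

test_that("event truth respects the minimum gap and non-empty membership", {
  cfg <- sim_config(n_individuals_per_site = 12, baseline_days = 4, seed = 31)
  pop <- simulate_population(cfg)
  out <- simulate_period(pop, cfg, "baseline")
  expect_true(all(out$truth$n_members >= 1))
  gaps <- out$truth |>
    dplyr::group_by(site_id, day) |>
    dplyr::summarise(g = min(c(Inf, diff(sort(centre_time)))),
                     .groups = "drop")
  expect_true(all(gaps$g >= cfg$between_event_gap_min - 1e-9))
})

test_that("realised group sizes match the joint-membership model", {
  # Poisson-binomial oracle: group size = sum of independent Bernoulli
  # joins, conditioned on being non-empty (empty events are dropped)
  pb_pmf <- function(p) {
    f <- 1
    for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
    f # probabilities of sizes 0..n
  }
  n_rep <- 10
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_individuals_per_site = 12, n_sites = 1,
                      baseline_days = 30, events_per_site_day = 20,
                      seed = 100 + r)
    pop <- simulate_population(cfg)
    out <- simulate_period(pop, cfg, "baseline")
    p_join <- plogis(cfg$join_intercept +
                       cfg$join_slope * pop$gregariousness /
                         cfg$gregariousness_sd)
    pmf <- pb_pmf(p_join)           # sizes 0..n
    pmf <- pmf[-1] / sum(pmf[-1])   # condition on size >= 1
    sizes <- out$truth$n_members
    obs <- tabulate(sizes, nbins = length(p_join))
    # pool upper tail so expected counts stay reasonable
    cut <- max(3, which(cumsum(pmf) > 0.99)[1])
    obs_b <- c(obs[seq_len(cut - 1)], sum(obs[cut:length(obs)]))
    pmf_b <- c(pmf[seq_len(cut - 1)], sum(pmf[cut:length(pmf)]))
    pvals[r] <- suppressWarnings(
      chisq.test(obs_b, p = pmf_b)$p.value)
  }
  expect_true(all(pvals > 0.01 / n_rep)) # Bonferroni at alpha = 0.01
})

test_that("an oracle logistic fit recovers the configured diet slope", {
  cfg <- sim_config(n_individuals_per_site = 250, n_sites = 2,
                    diet_slope_sociality = 0.5, seed = 37)
  pop <- simulate_population(cfg)
  trial <- simulate_period(pop, cfg, "trial1")
  counts <- trial$detections |>
    dplyr::group_by(tag_id, site_id) |>
    dplyr::summarise(novel = sum(food_type == "novel"),
                     familiar = sum(food_type == "familiar"),
                     .groups = "drop")
  counts$z <- pop$gregariousness[match(counts$tag_id, pop$tag_id)] /
    cfg$gregariousness_sd
  orac <- glm(cbind(novel, familiar) ~ z + site_id, family = binomial(),
              data = counts)
  expect_lt(abs(coef(orac)[["z"]] - cfg$diet_slope_sociality), 0.1)
})

test_that("fixtures round-trip through the CSV readers", {
  cfg <- sim_config(n_individuals_per_site = 8, baseline_days = 2,
                    trial_days = 1, events_per_site_day = 5, seed = 41)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(study$detections, study$population, study$truth,
                          dir)
  back <- read_detections(paths[["detections"]])
  expect_identical(nrow(back), nrow(study$detections))
  ord <- dplyr::arrange(study$detections, site_id, day, time_s, tag_id)
  expect_identical(back$tag_id, ord$tag_id)
  expect_identical(back$food_type, ord$food_type)
  expect_equal(as.numeric(back$timestamp), as.numeric(ord$timestamp),
               tolerance = 2e-3)
  expect_equal(back$time_s, ord$time_s, tolerance = 2e-3)
  traits <- read_traits(paths[["traits"]])
  expect_identical(traits$tag_id, study$population$tag_id)
  truth_back <- readr::read_csv(paths[["truth_events"]],
                                show_col_types = FALSE)
  expect_identical(nrow(truth_back), nrow(study$truth))
})

test_that("an empty stream writes a header-only CSV", {
  cfg <- sim_config(n_individuals_per_site = 3, seed = 1)
  pop <- simulate_population(cfg)
  dir <- withr::local_tempdir()
  empty <- simulate_period(pop, cfg, "baseline")$detections[0, ]
  paths <- write_fixtures(empty, pop, NULL, dir)
  lines <- readLines(paths[["detections"]])
  expect_identical(length(lines), 1L)
  back <- read_detections(paths[["detections"]])
  expect_identical(nrow(back), 0L)
})

test_that("simulating from an empty population errors", {
  cfg <- sim_config(n_individuals_per_site = 3, seed = 1)
  pop <- simulate_population(cfg)
  expect_error(simulate_period(pop[0, ], cfg, "baseline"), "empty",
               class = "flocknet_error")
})
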