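trial_stream <- function(rows) {
  # rows: list of c(tag, day_offset, time_s, food)
  tibble::tibble(
    tag_id = vapply(rows, `[[`, "", 1),
    site_id = "S1",
    period = "trial1",
    day = as.Date("2018-01-23") + as.numeric(vapply(rows, `[[`, "", 2)),
    time_s = as.numeric(vapply(rows, `[[`, "", 3)),
    food_type = vapply(rows, `[[`, "", 4))
}

test_that("usage counts are the novel and familiar detection totals", {
  set.seed(2)
  rows <- c(
    lapply(seq_len(30), function(i) c("X", "0", 100 + i, "novel")),
    lapply(seq_len(70), function(i) c("X", "0", 5000 + i, "familiar")))
  resp <- build_responses(trial_stream(rows))
  expect_identical(resp$novel_count, 30L)
  expect_identical(resp$familiar_count, 70L)
  expect_equal(resp$novel_count / resp$n_detections, 0.3)
})

test_that("first-arrival, latency and post-first-use follow the record order", {
  rows <- list(
    c("A", "0", "1000", "novel"),     # A arrives straight onto novel
    c("A", "0", "2000", "familiar"),
    c("A", "0", "3000", "novel"),
    c("B", "0", "30000", "familiar"), # B first uses novel next day
    c("B", "1", "1000", "novel"),
    c("B", "1", "1500", "familiar"),
    c("C", "0", "500", "familiar"))   # C never uses novel
  resp <- build_responses(trial_stream(rows), day_length = 39600)
  a <- resp[resp$tag_id == "A", ]
  expect_true(a$first_arrival_novel)
  expect_equal(a$latency_elapsed, 0)
  expect_identical(a$post_first_novel_count, 1L)
  expect_identical(a$post_first_familiar_count, 1L)

  b <- resp[resp$tag_id == "B", ]
  expect_false(b$first_arrival_novel)
  # foraging time: rest of day 0 (39600 - 30000) plus 1000 s of day 1
  expect_equal(b$latency_elapsed, 9600 + 1000)
  expect_equal(b$latency_clock, 6 * 3600 + 1000)

  c_ <- resp[resp$tag_id == "C", ]
  expect_true(is.na(c_$latency_clock))
  expect_true(is.na(c_$latency_elapsed))
  expect_identical(c_$post_first_novel_count, 0L)
  expect_identical(c_$post_first_familiar_count, 0L)
})

test_that("trial streams are validated", {
  bad <- trial_stream(list(c("A", "0", "100", "blue")))
  expect_error(build_responses(bad), "food_type",
               class = "flocknet_validation_error")
  two <- trial_stream(list(c("A", "0", "100", "novel")))
  two$period <- "trial1"
  mixed <- dplyr::bind_rows(two, dplyr::mutate(two, period = "trial2"))
  expect_error(build_responses(mixed), class = "flocknet_validation_error")
})

test_that("prior detection counts conserve the stream length", {
  cfg <- sim_config(n_individuals_per_site = 10, baseline_days = 2, seed = 6)
  base <- simulate_period(simulate_population(cfg), cfg, "baseline")
  counts <- prior_detection_counts(base$detections)
  expect_identical(sum(counts$prior_detections), nrow(base$detections))
  empty <- prior_detection_counts(base$detections[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("birds missing from the prior network are dropped and logged", {
  resp <- tibble::tibble(
    tag_id = c("A", "B", "C"), site_id = "S1",
    novel_count = c(5L, 3L, 8L), familiar_count = c(5L, 7L, 2L),
    first_arrival_novel = c(TRUE, FALSE, TRUE))
  metrics <- tibble::tibble(tag_id = c("A", "B"), strength = c(1, 2))
  expect_message(
    d <- assemble_model_data(resp, metrics),
    "dropped 1 bird")
  expect_identical(d$tag_id, c("A", "B"))
  expect_identical(attr(d, "dropped")$tag_id, "C")
  d2 <- assemble_model_data(resp, metrics, include_missing = TRUE)
  expect_identical(nrow(d2), 3L)
  expect_equal(d2$strength[d2$tag_id == "C"], 0)
})

test_that("a perfectly balanced response gives a null slope", {
  d <- tibble::tibble(
    tag_id = sprintf("T%d", 1:20), site_id = "S1",
    strength = rnorm(20),
    novel_count = 50L, familiar_count = 50L)
  fit <- fit_dietary_glm(d, response = "usage", metric = "strength",
                         covariates = character())
  expect_lt(abs(tidy(fit)$estimate[2]), 1e-6)
})

test_that("quasi-binomial fits match the independent IRLS oracle", {
  path <- system.file("extdata", "usage_fixture_40_synthetic.csv",
                      package = "flocknet")
  d <- readr::read_csv(path, show_col_types = FALSE)
  fit <- fit_dietary_glm(d, response = "usage", metric = "strength",
                         covariates = c("site_id", "sex", "age",
                                        "immigrant", "prior_detections"))
  X <- fit$fit$x
  orac <- oracle_irls(X, d$novel_count, d$familiar_count)
  td <- tidy(fit)
  expect_equal(unname(td$estimate), unname(orac$coefficients),
               tolerance = 1e-6)
  expect_equal(unname(td$std.error), unname(orac$se), tolerance = 1e-6)
  expect_equal(fit$dispersion, orac$phi, tolerance = 1e-6)
  expect_equal(unname(td$statistic), unname(orac$t), tolerance = 1e-6)
})

test_that("dispersion is near 1 for binomial data and above 1 for
           beta-binomial data", {
  set.seed(12)
  n <- 300
  z <- rnorm(n)
  total <- rpois(n, 60) + 1
  p <- plogis(-0.2 + 0.3 * z)
  bin <- tibble::tibble(
    tag_id = sprintf("T%d", 1:n), site_id = "S1", strength = z,
    novel_count = rbinom(n, total, p))
  bin$familiar_count <- total - bin$novel_count
  fit_bin <- fit_dietary_glm(bin, "usage", covariates = character())
  expect_gt(fit_bin$dispersion, 0.7)
  expect_lt(fit_bin$dispersion, 1.4)

  # beta-binomial: success probability itself is noisy
  p_bb <- plogis(-0.2 + 0.3 * z + rnorm(n, 0, 0.8))
  bb <- bin
  bb$novel_count <- rbinom(n, total, p_bb)
  bb$familiar_count <- total - bb$novel_count
  fit_bb <- fit_dietary_glm(bb, "usage", covariates = character())
  expect_gt(fit_bb$dispersion, 1.5)
})

test_that("quasi-binomial coefficients equal the plain binomial fit", {
  set.seed(13)
  d <- make_bird_usage(60, slope = 0.4)
  fit <- fit_dietary_glm(d, "usage", covariates = character())
  plain <- glm(cbind(novel_count, familiar_count) ~ strength,
               family = binomial(), data = d)
  expect_lt(max(abs(tidy(fit)$estimate - coef(plain))), 1e-10)
})

test_that("doubling all counts keeps the coefficient but shrinks the SE", {
  set.seed(14)
  d <- make_bird_usage(60, slope = 0.4)
  f1 <- fit_dietary_glm(d, "usage", covariates = character())
  d2 <- dplyr::mutate(d, novel_count = 2L * novel_count,
                      familiar_count = 2L * familiar_count)
  f2 <- fit_dietary_glm(d2, "usage", covariates = character())
  expect_equal(tidy(f2)$estimate, tidy(f1)$estimate, tolerance = 1e-8)
  # dispersion roughly doubles too, so compare binomial-scale SEs
  se1 <- tidy(f1)$std.error / sqrt(f1$dispersion)
  se2 <- tidy(f2)$std.error / sqrt(f2$dispersion)
  expect_true(all(se2 < se1))
})

test_that("latency models drop never-users and use gaussian errors", {
  set.seed(15)
  n <- 30
  d <- tibble::tibble(
    tag_id = sprintf("T%d", 1:n), site_id = "S1", strength = rnorm(n),
    latency_clock = c(rnorm(25, 30000, 5000), rep(NA, 5)),
    latency_elapsed = c(abs(rnorm(25, 8000, 3000)), rep(NA, 5)))
  fit <- fit_dietary_glm(d, "latency_clock", covariates = character())
  expect_identical(fit$n_obs, 25L)
  expect_identical(fit$family, "gaussian")
  expect_true(any(attr <- fit$dropped$reason == "never used the novel feeder"))
  ols <- lm(latency_clock ~ strength, data = d)
  expect_equal(tidy(fit)$estimate, unname(coef(ols)), tolerance = 1e-10)
})

test_that("single-level covariates are dropped with a message", {
  set.seed(16)
  d <- make_bird_usage(40, slope = 0.3)
  d$sex <- "M"
  expect_message(
    fit <- fit_dietary_glm(d, "usage", covariates = c("site_id", "sex")),
    "single-level")
  expect_false("sexM" %in% tidy(fit)$term)
})

test_that("too few observations for the parameter count errors", {
  set.seed(17)
  d <- make_bird_usage(6, slope = 0)
  expect_error(fit_dietary_glm(d, "usage",
                               covariates = character()),
               "observations", class = "flocknet_error")
})

test_that("glance reports sample size, dispersion and convergence", {
  set.seed(18)
  d <- make_bird_usage(50, slope = 0.4)
  fit <- fit_dietary_glm(d, "usage", covariates = character())
  g <- glance(fit)
  expect_identical(g$n_obs, 50L)
  expect_true(g$converged)
  expect_identical(g$family, "quasibinomial")
  expect_equal(g$df.residual, 48L, ignore_attr = TRUE)
})

test_that("the simulated sociality effect is recovered with the right sign", {
  hits <- 0
  for (r in 1:20) {
    d <- withr::with_seed(300 + r, make_bird_usage(150, slope = 0.5))
    fit <- fit_dietary_glm(d, "usage", covariates = character())
    hits <- hits + (tidy(fit)$estimate[2] > 0)
  }
  expect_gte(hits, 18)
})
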