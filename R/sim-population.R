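#' Generate a synthetic tagged population with latent sociality
#'
#' Draws one row per bird: demographic traits (independent Bernoulli(0.5)
#' sex, age class and immigrant status), a latent `gregariousness`
#' (Normal(0, `gregariousness_sd`)) that drives flock joining, and the
#' implied `adventurousness` — the bird-level logit contribution to
#' novel-food preference (sociality slope times standardised gregariousness
#' plus any configured trait effects).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `tag_id`, `site_id`, `sex`, `age`,
#'   `immigrant`, `gregariousness`, `adventurousness`; exactly
#'   `n_individuals_per_site` rows per site, tag ids unique across sites.
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_individuals_per_site = 5))
#' table(pop$site_id)
simulate_population <- function(config) {
  validate_sim_config(config)
  n_total <- config$n_individuals_per_site * config$n_sites
  withr::with_seed(config$seed, {
    pop <- tibble::tibble(
      tag_id = sprintf("T%04d", seq_len(n_total)),
      site_id = rep(paste0("S", seq_len(config$n_sites)),
                    each = config$n_individuals_per_site),
      sex = sample(c("M", "F"), n_total, replace = TRUE),
      age = sample(c("adult", "juvenile"), n_total, replace = TRUE),
      immigrant = sample(c(TRUE, FALSE), n_total, replace = TRUE),
      gregariousness = rnorm(n_total, 0, config$gregariousness_sd)
    )
  })
  z <- pop$gregariousness / config$gregariousness_sd
  ce <- config$covariate_effects
  pop$adventurousness <- config$diet_slope_sociality * z +
    ce$sex_M * (pop$sex == "M") +
    ce$age_adult * (pop$age == "adult") +
    ce$immigrant * pop$immigrant
  pop
}
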