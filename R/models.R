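#' Assemble the modelling table for one trial
#'
#' Joins trial responses to prior-period node metrics, demographic traits
#' and prior detection counts. Individuals detected in the trial but absent
#' from the prior-period network have undefined centrality and are excluded
#' (recorded in the `dropped` attribute); set `include_missing = TRUE` to
#' keep them with zero centrality for sensitivity analysis. Birds absent
#' from the prior period get `prior_detections = 0`.
#'
#' @param responses Trial responses from [build_responses()].
#' @param metrics Prior-period node metrics from [node_metrics()] (bind rows
#'   across sites for a multi-site study).
#' @param traits Trait table (`tag_id`, `sex`, `age`, `immigrant`).
#' @param prior Prior detection counts from [prior_detection_counts()].
#' @param include_missing Keep birds missing from the prior network, with
#'   zero strength/centrality.
#' @return A tibble, one row per modelled bird, with attribute `dropped`.
#' @export
assemble_model_data <- function(responses, metrics, traits = NULL,
                                prior = NULL, include_missing = FALSE) {
  metric_cols <- intersect(
    c("strength", "degree", "average_edge_weight", "eigenvector",
      "mean_flock_size", "n_unique_associates"), names(metrics))
  m <- metrics[, c("tag_id", metric_cols)]
  out <- dplyr::left_join(responses, m, by = "tag_id")
  missing_net <- !out$tag_id %in% m$tag_id
  dropped <- tibble::tibble(tag_id = character(), reason = character())
  if (any(missing_net)) {
    if (include_missing) {
      for (col in metric_cols) {
        out[[col]][missing_net] <- 0
      }
    } else {
      dropped <- tibble::tibble(tag_id = out$tag_id[missing_net],
                                reason = "absent from prior-period network")
      out <- out[!missing_net, ]
    }
  }
  if (!is.null(traits)) {
    out <- dplyr::left_join(out,
                            traits[, intersect(c("tag_id", "sex", "age",
                                                 "immigrant"),
                                               names(traits))],
                            by = "tag_id")
  }
  if (!is.null(prior)) {
    out <- dplyr::left_join(out, prior, by = "tag_id")
    out$prior_detections[is.na(out$prior_detections)] <- 0L
  }
  if (nrow(dropped) > 0) {
    inform(paste0("assemble_model_data(): dropped ", nrow(dropped),
                  " bird(s) absent from the prior-period network"))
  }
  attr(out, "dropped") <- dropped
  out
}

response_families <- c(usage = "quasibinomial",
                       post_first_usage = "quasibinomial",
                       neophobia_arrival = "quasibinomial",
                       latency_clock = "gaussian",
                       latency_elapsed = "gaussian")

#' Fit a dietary-decision GLM
#'
#' Fits the trial-level generalised linear models relating a dietary
#' response to prior social centrality and covariates. Proportional usage
#' responses (`usage`, `post_first_usage`) enter as a two-column
#' successes/failures binomial response with a quasi-binomial error
#' structure: coefficients equal the plain binomial fit, while standard
#' errors are inflated by the square root of the Pearson dispersion
#' `phi = sum(pearson residuals^2) / (n - p)`, and Wald tests use t on
#' `n - p` df. The binary first-arrival response is also quasi-binomial;
#' latencies use a gaussian error structure.
#'
#' Rows with missing response or predictors are dropped and recorded;
#' covariates with fewer than two observed levels are removed from the
#' formula with a message. Predictors are left on their raw scale unless
#' `standardize = TRUE` (z-scores numeric predictors, for cross-metric
#' comparison); `log1p_prior = TRUE` log-transforms the prior detection
#' count.
#'
#' @param data Modelling table from [assemble_model_data()].
#' @param response One of `"usage"`, `"neophobia_arrival"`,
#'   `"latency_clock"`, `"latency_elapsed"`, `"post_first_usage"`.
#' @param metric Centrality/social-measure column used as the focal
#'   predictor (e.g. `"strength"`, `"average_edge_weight"`,
#'   `"eigenvector"`, `"mean_flock_size"`, `"n_unique_associates"`).
#' @param covariates Character vector of additional predictor columns.
#' @param standardize Z-score numeric predictors.
#' @param log1p_prior Apply `log1p` to `prior_detections`.
#' @return A `diet_fit` object; see [tidy.diet_fit()] and
#'   [glance.diet_fit()].
#' @export
fit_dietary_glm <- function(data,
                            response = c("usage", "neophobia_arrival",
                                         "latency_clock", "latency_elapsed",
                                         "post_first_usage"),
                            metric = "strength",
                            covariates = c("site_id", "sex", "age",
                                           "immigrant", "prior_detections"),
                            standardize = FALSE,
                            log1p_prior = FALSE) {
  response <- match.arg(response)
  if (!metric %in% names(data)) {
    abort(paste0("fit_dietary_glm(): no metric column `", metric, "`"),
          class = "flocknet_error")
  }
  covariates <- intersect(covariates, names(data))
  family_name <- response_families[[response]]

  d <- data
  dropped <- attr(data, "dropped") %||%
    tibble::tibble(tag_id = character(), reason = character())

  # response columns
  if (response == "usage") {
    d$.succ <- d$novel_count
    d$.fail <- d$familiar_count
  } else if (response == "post_first_usage") {
    d$.succ <- d$post_first_novel_count
    d$.fail <- d$post_first_familiar_count
    zero <- (d$.succ + d$.fail) == 0
    if (any(zero)) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        tag_id = d$tag_id[zero], reason = "no post-first-use detections"))
      d <- d[!zero, ]
    }
  } else if (response == "neophobia_arrival") {
    d$.y <- as.numeric(d$first_arrival_novel)
  } else {
    d$.y <- d[[if (response == "latency_clock") "latency_clock"
               else "latency_elapsed"]]
    never <- is.na(d$.y)
    if (any(never)) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        tag_id = d$tag_id[never], reason = "never used the novel feeder"))
      d <- d[!never, ]
    }
  }

  if (log1p_prior && "prior_detections" %in% covariates) {
    d$prior_detections <- log1p(d$prior_detections)
  }

  preds <- c(metric, covariates)
  keep <- stats::complete.cases(d[, preds, drop = FALSE])
  if (any(!keep)) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      tag_id = d$tag_id[!keep], reason = "missing predictor value"))
    d <- d[keep, ]
  }
  # single-level covariates carry no information and break the contrasts
  degenerate <- covariates[vapply(covariates, function(cv) {
    length(unique(d[[cv]])) < 2
  }, TRUE)]
  if (length(degenerate) > 0) {
    inform(paste0("fit_dietary_glm(): dropping single-level covariate(s): ",
                  paste(degenerate, collapse = ", ")))
    covariates <- setdiff(covariates, degenerate)
  }
  if (standardize) {
    for (v in c(metric, covariates)) {
      if (is.numeric(d[[v]]) && stats::sd(d[[v]]) > 0) {
        d[[v]] <- as.numeric(scale(d[[v]]))
      }
    }
  }

  rhs <- paste(c(metric, covariates), collapse = " + ")
  lhs <- if (family_name == "quasibinomial" &&
               response %in% c("usage", "post_first_usage")) {
    "cbind(.succ, .fail)"
  } else {
    ".y"
  }
  fml <- stats::as.formula(paste(lhs, "~", rhs))
  n_params <- length(c(metric, covariates)) + 1
  if (nrow(d) < n_params + 5) {
    abort(paste0("fit_dietary_glm(): only ", nrow(d),
                 " observations for ", n_params, " parameters"),
          class = "flocknet_error")
  }

  fam <- if (family_name == "quasibinomial") quasibinomial() else gaussian()
  fit <- withCallingHandlers(
    glm(fml, family = fam, data = d, x = TRUE, y = TRUE),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  separation <- family_name == "quasibinomial" &&
    any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)

  structure(list(
    fit = fit,
    response = response,
    metric = metric,
    covariates = covariates,
    formula = fml,
    family = family_name,
    data = d,
    dropped = dropped,
    dispersion = s$dispersion,
    n_obs = nrow(d),
    converged = fit$converged,
    flagged = !fit$converged || separation
  ), class = "diet_fit")
}

#' @export
print.diet_fit <- function(x, ...) {
  cat("<diet_fit> ", x$response, " ~ ", x$metric,
      if (length(x$covariates)) paste0(" + ", paste(x$covariates,
                                                    collapse = " + ")),
      "\n", sep = "")
  cat("  family: ", x$family, "  n = ", x$n_obs,
      "  dispersion = ", signif(x$dispersion, 4),
      if (x$flagged) "  [FLAGGED]", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a dietary GLM fit
#'
#' @param x A `diet_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (t on `n - p` df) and `p.value`.
#' @export
tidy.diet_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, 1]),
    std.error = unname(cf[, 2]),
    statistic = unname(cf[, 3]),
    p.value = unname(cf[, 4])
  )
}

#' One-row summary of a dietary GLM fit
#'
#' @param x A `diet_fit`.
#' @param ... Unused.
#' @return A tibble with the response, focal metric, family, sample size,
#'   number of dropped birds, Pearson dispersion, residual df and
#'   convergence flags.
#' @export
glance.diet_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    metric = x$metric,
    family = x$family,
    n_obs = x$n_obs,
    n_dropped = nrow(x$dropped),
    dispersion = x$dispersion,
    df.residual = x$fit$df.residual,
    converged = x$converged,
    flagged = x$flagged
  )
}
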