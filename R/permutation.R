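#' Permute values within strata
#'
#' Randomly reassigns values among individuals of the same stratum (e.g.
#' the same site in the same period), leaving the multiset of values within
#' every stratum — and everything across strata — unchanged. Rows of a
#' matrix or data frame move as a unit, so paired counts such as
#' (novel, familiar) stay together.
#'
#' @param values A vector, matrix or data frame; one entry/row per
#'   individual.
#' @param strata Stratum label per individual (no `NA`s).
#' @return `values` with entries permuted within each stratum.
#' @export
#' @examples
#' set.seed(1)
#' permute_within_strata(1:6, strata = c(1, 1, 1, 2, 2, 2))
permute_within_strata <- function(values, strata) {
  n <- if (is.null(dim(values))) length(values) else nrow(values)
  if (length(strata) != n) {
    abort("permute_within_strata(): `strata` length must match `values`",
          class = "flocknet_error")
  }
  if (anyNA(strata)) {
    abort("permute_within_strata(): every individual needs a stratum",
          class = "flocknet_error")
  }
  idx <- seq_len(n)
  for (s in unique(strata)) {
    in_s <- which(strata == s)
    if (length(in_s) > 1) idx[in_s] <- in_s[sample.int(length(in_s))]
  }
  if (is.null(dim(values))) values[idx] else values[idx, , drop = FALSE]
}

#' Stratified node-permutation test for a dietary GLM
#'
#' Social network metrics of different individuals are not independent, so
#' asymptotic GLM p-values are complemented by a node-attribute permutation
#' null: the response variable is reshuffled among individuals within the
#' same stratum (site, within one period), the model is refitted with the
#' predictor matrix untouched, and each term's coefficient is recorded. The
#' two-tailed permutation p-value is
#' `p_rand = (1 + #permutations with |coef| >= |observed|) / (B + 1)`,
#' which can never be exactly zero.
#'
#' Permutation RNG streams are pre-drawn from the master seed, so results
#' do not depend on execution order. Non-convergent permutation refits are
#' redrawn with fresh seeds; if more than 1% of draws fail the test aborts
#' with a diagnostic.
#'
#' @param fit A [fit_dietary_glm()] result.
#' @param n_permutations Number of permutations (default 10,000).
#' @param seed Master seed.
#' @param strata Stratum per modelled bird; defaults to the `site_id`
#'   column of the modelled data (a single stratum if absent).
#' @return A `perm_test` object: per-term observed coefficients and
#'   `p_rand`, with the full null distributions stored in `$null`.
#' @export
permutation_test <- function(fit, n_permutations = 10000, seed = 1L,
                             strata = NULL) {
  if (!inherits(fit, "diet_fit")) {
    abort("permutation_test(): `fit` must be a diet_fit",
          class = "flocknet_error")
  }
  if (!fit$converged) {
    abort("permutation_test(): observed model did not converge",
          class = "flocknet_error")
  }
  X <- fit$fit$x
  n <- nrow(X)
  strata <- strata %||% fit$data[["site_id"]] %||% rep(1L, n)
  if (length(strata) != n) {
    abort("permutation_test(): `strata` length must match modelled birds",
          class = "flocknet_error")
  }

  binom <- fit$family == "quasibinomial"
  if (binom) {
    y <- fit$fit$y                      # proportion of successes
    wts <- fit$fit$prior.weights        # total counts
    resp <- cbind(y, wts)               # permute as a unit
  } else {
    resp <- matrix(fit$fit$y, ncol = 1)
  }
  obs <- coef(fit$fit)
  terms <- names(obs)

  refit_coefs <- function(resp_perm) {
    if (binom) {
      f <- suppressWarnings(
        glm.fit(X, resp_perm[, 1], weights = resp_perm[, 2],
                family = binomial(),
                control = stats::glm.control(maxit = 100)))
      if (!f$converged) return(NULL)
      f$coefficients
    } else {
      lm.fit(X, resp_perm[, 1])$coefficients
    }
  }

  null <- matrix(NA_real_, n_permutations, length(terms),
                 dimnames = list(NULL, terms))
  n_redrawn <- 0L
  max_redraw <- max(1, ceiling(0.01 * n_permutations))
  withr::with_seed(as.integer(seed), {
    perm_seeds <- sample.int(2147483646L, n_permutations)
    redraw_seeds <- sample.int(2147483646L, max_redraw + 1L)
    for (b in seq_len(n_permutations)) {
      set.seed(perm_seeds[b])
      cf <- refit_coefs(permute_within_strata(resp, strata))
      while (is.null(cf)) {
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraw) {
          abort(paste0("permutation_test(): more than 1% of permutation ",
                       "refits failed to converge (", n_redrawn, " of ",
                       n_permutations, " draws)"),
                class = "flocknet_error")
        }
        set.seed(redraw_seeds[n_redrawn])
        cf <- refit_coefs(permute_within_strata(resp, strata))
      }
      null[b, ] <- cf
    }
  })
  if (n_redrawn > 0) {
    inform(paste0("permutation_test(): redrew ", n_redrawn,
                  " non-convergent permutation(s)"))
  }

  p_rand <- vapply(terms, function(tm) {
    (1 + sum(abs(null[, tm]) >= abs(obs[[tm]]))) / (n_permutations + 1)
  }, 0)

  structure(list(
    terms = tibble::tibble(term = terms, estimate = unname(obs),
                           p_rand = unname(p_rand)),
    null = null,
    n_permutations = n_permutations,
    seed = as.integer(seed),
    n_redrawn = n_redrawn,
    response = fit$response,
    metric = fit$metric
  ), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$response, " ~ ", x$metric, ", B = ",
      x$n_permutations, "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Tidy a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (observed coefficient) and
#'   `p_rand`.
#' @export
tidy.perm_test <- function(x, ...) {
  x$terms
}
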