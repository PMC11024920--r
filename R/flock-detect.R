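#' Segment a detection stream into flocking events
#'
#' Fission--fusion foraging produces a bursty temporal stream at each
#' feeder: flocks arrive, feed, and depart, separated by quiet gaps. Each
#' site-day's detection times are modelled as a one-dimensional Gaussian
#' mixture; the number of components is chosen by BIC and every detection is
#' assigned to its maximum-responsibility component. A component is a
#' flocking event; its members are the distinct tags assigned to it.
#'
#' Model selection starts from a gap-statistic guess at the number of bursts
#' (two-class split of the inter-detection gaps) and hill-descends the BIC in
#' both directions, stopping after `patience` consecutive non-improvements.
#' Components share a common variance by default (`model = "tied"`), which
#' is markedly more robust against splitting a burst into likelihood-spike
#' sub-components than the free-variance fit; both variants are constrained
#' by a 1-second component-SD floor (the antenna's time resolution scale).
#' Components whose mixture weight falls below `weight_prune_threshold` are
#' pruned and their detections reassigned to the nearest surviving component
#' mean.
#'
#' Detections at different feeders of one site (e.g. the paired novel and
#' familiar trial feeders) are pooled: the feeders stand within a metre of
#' each other, so a flock spans both. Day boundaries partition the stream;
#' no event spans days.
#'
#' @param detections Detection tibble with at least `tag_id`, `site_id` and
#'   either `time_s` + `day` or a `timestamp` column.
#' @param max_components Upper bound on mixture components per site-day
#'   (additionally capped at one component per three detections).
#' @param weight_prune_threshold Minimum mixture weight for a component to
#'   survive; default `0.5 / n` detections of its site-day.
#' @param n_init Number of EM initialisations per candidate K: the
#'   deterministic largest-gaps split plus `n_init - 1` seeded jitters.
#' @param seed Integer seed for the extra initialisations.
#' @param model `"tied"` (common variance, default) or `"free"`.
#' @param patience Consecutive BIC non-improvements before the K search
#'   stops in a direction.
#' @param dawn Used to derive `time_s` if only `timestamp` is present.
#' @return A tibble of flocking events (`event_id`, `site_id`, `period`,
#'   `day`, `start_time`, `end_time`, `n_members`, `n_detections`,
#'   `member_ids` list-column), sorted by site, day and start time, with the
#'   per-detection assignment available via [event_assignments()].
#' @export
#' @examples
#' det <- tibble::tibble(
#'   tag_id = c("A", "B", "C", "A", "B"),
#'   site_id = "S1", day = as.Date("2018-01-11"),
#'   time_s = c(100, 101, 103, 1000, 1002), period = "baseline")
#' ev <- detect_flocks(det)
#' ev$n_members
detect_flocks <- function(detections, max_components = 100,
                          weight_prune_threshold = NULL, n_init = 1,
                          seed = 1L, model = c("tied", "free"),
                          patience = 3, dawn = "06:00:00") {
  model <- match.arg(model)
  empty <- tibble::tibble(
    event_id = character(), site_id = character(), period = character(),
    day = as.Date(character()), start_time = numeric(),
    end_time = numeric(), n_members = integer(), n_detections = integer(),
    member_ids = list())
  if (is.null(detections) || nrow(detections) == 0) {
    attr(empty, "detections") <- detections
    class(empty) <- c("flock_events", class(empty))
    return(empty)
  }
  if (!"time_s" %in% names(detections)) {
    if (!"timestamp" %in% names(detections)) {
      abort("detect_flocks(): need `time_s` + `day` or a `timestamp` column",
            class = "flocknet_error")
    }
    detections$day <- as.Date(detections$timestamp, tz = "UTC")
    detections$time_s <- as.numeric(detections$timestamp) -
      as.numeric(as.POSIXct(as.character(detections$day), tz = "UTC")) -
      dawn_seconds(dawn)
  }
  if (any(detections$time_s < 0, na.rm = TRUE)) {
    warn("detect_flocks(): detections before dawn; times clamped to 0")
    detections$time_s <- pmax(detections$time_s, 0)
  }
  if (!"period" %in% names(detections)) detections$period <- NA_character_

  detections <- dplyr::arrange(detections, .data$site_id, .data$day,
                               .data$time_s, .data$tag_id)
  key <- paste(detections$site_id, detections$day)
  groups <- split(seq_len(nrow(detections)), key)
  # keep chronological order of site-days, not alphabetical split() order
  groups <- groups[unique(key)]

  withr::with_seed(as.integer(seed), {
    ev_list <- vector("list", length(groups))
    assign_all <- character(nrow(detections))
    for (gi in seq_along(groups)) {
      rows <- groups[[gi]]
      dd <- detections[rows, ]
      comp <- segment_site_day(dd$time_s, max_components,
                               weight_prune_threshold, n_init, model,
                               patience)
      ord <- order(vapply(split(dd$time_s, comp), min, 0))
      rank <- match(comp, ord)
      event_id <- sprintf("%s_%s_gmm%03d", dd$site_id[1],
                          format(dd$day[1]), sort(unique(rank)))
      assign_all[rows] <- event_id[rank]
      ev_list[[gi]] <- tibble::tibble(
        event_id = event_id,
        site_id = dd$site_id[1],
        period = dd$period[1],
        day = dd$day[1],
        start_time = as.numeric(tapply(dd$time_s, rank, min)),
        end_time = as.numeric(tapply(dd$time_s, rank, max)),
        n_members = as.integer(tapply(dd$tag_id, rank,
                                      function(x) length(unique(x)))),
        n_detections = as.integer(tabulate(rank)),
        member_ids = lapply(split(dd$tag_id, rank),
                            function(x) sort(unique(x)))
      )
    }
  })
  events <- dplyr::bind_rows(ev_list)
  detections$event_id <- assign_all
  attr(events, "detections") <- detections
  class(events) <- c("flock_events", class(events))
  events
}

#' Per-detection event assignments from a flock detection
#'
#' @param events A [detect_flocks()] result.
#' @return The input detections with an `event_id` column.
#' @export
event_assignments <- function(events) {
  det <- attr(events, "detections")
  if (is.null(det)) {
    abort("event_assignments(): no detection-level assignments attached",
          class = "flocknet_error")
  }
  det
}

# component labels (integers) for one site-day's detection times
segment_site_day <- function(x, max_components, prune, n_init, model,
                             patience) {
  n <- length(x)
  if (n == 1) return(1L)
  if (diff(range(x)) < 1e-9) return(rep(1L, n))
  kcap <- min(max_components, max(1, ceiling(n / 3)))
  fit <- select_gmm(x, kcap, n_init, model, patience)
  comp <- max.col(fit$resp)
  # prune light components: reassign their points to nearest surviving mean
  prune <- prune %||% (0.5 / n)
  wt <- tabulate(comp, nbins = length(fit$mu)) / n
  live <- which(wt >= prune & tabulate(comp, nbins = length(fit$mu)) > 0)
  if (length(live) == 0) live <- which.max(wt)
  if (length(live) < length(unique(comp))) {
    dead <- setdiff(unique(comp), live)
    for (k in dead) {
      pts <- comp == k
      comp[pts] <- live[apply(abs(outer(x[pts], fit$mu[live], "-")), 1,
                              which.min)]
    }
  }
  match(comp, sort(unique(comp)))
}

# BIC model selection: gap-statistic K guess + local hill descent
select_gmm <- function(x, kcap, n_init, model, patience) {
  xs <- sort(x)
  n <- length(x)
  var_floor <- 1 # component SD floor of 1 s
  cache <- new.env(parent = emptyenv())
  fit_k <- function(K) {
    key <- as.character(K)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    best <- NULL
    for (i in seq_len(max(1, n_init))) {
      mu0 <- gmm_gap_init(xs, K)
      if (i > 1) mu0 <- sort(mu0 + rnorm(K, 0, diff(range(x)) / (4 * K)))
      f <- gmm_em(x, K, var_floor, mu0, model)
      if (!is.null(f) && (is.null(best) || f$ll > best$ll)) best <- f
    }
    n_par <- if (model == "tied") 2 * K else 3 * K - 1
    bic <- if (is.null(best)) Inf else -2 * best$ll + n_par * log(n)
    got <- list(f = best, bic = bic)
    cache[[key]] <- got
    got
  }
  K0 <- min(max(gmm_guess_k(xs), 1L), kcap)
  best <- fit_k(K0)
  best_K <- K0
  for (dir in c(1L, -1L)) {
    worse <- 0
    K <- best_K
    repeat {
      K <- K + dir
      if (K < 1 || K > kcap) break
      cand <- fit_k(K)
      if (cand$bic < best$bic) {
        best <- cand
        best_K <- K
        worse <- 0
      } else if (is.finite(cand$bic) || is.finite(best$bic)) {
        worse <- worse + 1
      }
      if (worse >= patience) break
    }
  }
  if (is.null(best$f)) { # pathological; fall back to one component
    best <- fit_k(1L)
  }
  out <- best$f
  out$K <- best_K
  out
}

# initial means: split sorted times at the K-1 largest gaps
gmm_gap_init <- function(xs, K) {
  if (K == 1) return(mean(xs))
  g <- diff(xs)
  cut <- sort(order(g, decreasing = TRUE)[seq_len(K - 1)])
  grp <- findInterval(seq_along(xs), cut + 0.5) + 1
  as.numeric(vapply(split(xs, grp), mean, 0))
}

# burst-count guess: gaps exceeding max(mean gap, 4 x median gap)
gmm_guess_k <- function(xs) {
  g <- diff(xs)
  if (length(g) < 1 || all(g <= 0)) return(1L)
  th <- max(mean(g), 4 * median(g))
  1L + sum(g > th)
}

# vectorised univariate EM; returns NULL on numerical failure
gmm_em <- function(x, K, var_floor, mu0, model, max_iter = 40, tol = 1e-6) {
  n <- length(x)
  mu <- mu0
  sg2 <- rep(max((diff(range(x)) / (4 * K))^2, var_floor), K)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  r <- matrix(1, n, 1)
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- -0.5 * sweep(outer(x, mu, "-")^2, 2, sg2, "/") -
      rep(0.5 * log(2 * pi * sg2) - log(w), each = n)
    mx <- logd[cbind(seq_len(n), max.col(logd))]
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    if (!is.finite(ll)) return(NULL)
    r <- exp(logd - lse)
    nk <- pmax(colSums(r), 1e-10)
    w <- nk / n
    sx <- colSums(r * x)
    mu <- sx / nk
    ss <- colSums(r * x^2) - 2 * mu * sx + mu^2 * nk
    sg2 <- if (model == "tied") {
      rep(max(sum(ss) / n, var_floor), K)
    } else {
      pmax(ss / nk, var_floor)
    }
    if (!all(is.finite(mu)) || !all(is.finite(sg2))) return(NULL)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(ll = ll, mu = mu, sg2 = sg2, w = w, resp = r)
}

#' Build the group-by-individual matrix
#'
#' Rows are flocking events, columns are individuals, cells are binary
#' membership indicators.
#'
#' @param events Event tibble with `event_id` and `member_ids` columns.
#' @param individuals Optional universe of tag ids. Individuals never seen
#'   in any event appear as all-zero columns only when `include_all = TRUE`;
#'   otherwise columns are the union of observed members.
#' @param include_all Include never-observed individuals as zero columns.
#' @return An integer matrix with event ids as row names and tag ids as
#'   column names.
#' @export
#' @examples
#' ev <- tibble::tibble(event_id = c("e1", "e2"),
#'                      member_ids = list(c("A", "B"), c("B", "C")))
#' build_gbi(ev)
build_gbi <- function(events, individuals = NULL, include_all = FALSE) {
  if (anyDuplicated(events$event_id)) {
    abort("build_gbi(): duplicate event ids", class = "flocknet_error")
  }
  observed <- sort(unique(unlist(events$member_ids)))
  cols <- if (include_all && !is.null(individuals)) {
    sort(unique(c(observed, individuals)))
  } else {
    observed
  }
  gbi <- matrix(0L, nrow = nrow(events), ncol = length(cols),
                dimnames = list(events$event_id, cols))
  for (i in seq_len(nrow(events))) {
    gbi[i, match(events$member_ids[[i]], cols)] <- 1L
  }
  gbi
}

#' Typical group size
#'
#' The group size encountered by the average individual: each event of size
#' n contributes n individual-memberships that each experienced a group of
#' size n, so the estimate is `sum(n^2) / sum(n)`. The standard error is the
#' SE of the mean over those `sum(n)` memberships.
#'
#' @param events Event tibble with an `n_members` column, or a numeric
#'   vector of group sizes.
#' @return A tibble with `typical_group_size`, `se` and `n_events`.
#' @export
#' @examples
#' typical_group_size(c(1, 5))$typical_group_size # 26/6
typical_group_size <- function(events) {
  sizes <- if (is.data.frame(events)) events$n_members else events
  if (length(sizes) == 0) {
    abort("typical_group_size(): no events", class = "flocknet_error")
  }
  v <- rep(sizes, sizes) # group size experienced by each membership
  tibble::tibble(
    typical_group_size = mean(v),
    se = stats::sd(v) / sqrt(length(v)),
    n_events = length(sizes)
  )
}
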