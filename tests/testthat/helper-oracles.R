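# Independent oracles, deliberately avoiding the code paths they check.

# IRLS for a binomial-logit GLM, written from the normal equations only
# (no glm/glm.fit). Returns coefficients and quasi-binomial inference.
oracle_irls <- function(X, succ, fail, max_iter = 100, tol = 1e-12) {
  n <- nrow(X)
  m <- succ + fail
  y <- succ / m
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- m * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    XtWX <- t(X) %*% (w * X)
    beta_new <- drop(solve(XtWX, t(X) %*% (w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  pearson <- sum(m * (y - mu)^2 / (mu * (1 - mu)))
  p <- ncol(X)
  phi <- pearson / (n - p)
  cov_q <- phi * solve(t(X) %*% ((m * mu * (1 - mu)) * X))
  se <- sqrt(diag(cov_q))
  list(coefficients = beta, se = se, phi = phi,
       t = beta / se, df = n - p)
}

# power iteration for the leading eigenvector of a symmetric non-negative
# matrix, restricted to its largest connected component (BFS by hand)
oracle_eigen_centrality <- function(w, iters = 10000) {
  n <- nrow(w)
  adj <- w > 0
  comp <- integer(n)
  cid <- 0
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  main <- which(comp == which.max(tabulate(comp)))
  scores <- stats::setNames(numeric(n), rownames(w))
  if (length(main) == 1) {
    scores[main] <- 1
    return(scores)
  }
  sub <- w[main, main]
  # accelerated power iteration: repeated squaring computes A^(2^35) %*% 1,
  # i.e. tens of billions of power steps, so the iterate converges to the
  # leading eigenvector even when the spectral gap is tiny
  M <- sub / max(abs(sub))
  for (i in seq_len(35)) {
    M <- M %*% M
    M <- M / max(abs(M))
  }
  v <- drop(M %*% rep(1, length(main)))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(50)) { # polish with plain power steps
    v_new <- drop(sub %*% v)
    v_new <- v_new / sqrt(sum(v_new^2))
    v <- v_new
  }
  scores[main] <- v / max(v)
  scores
}

# brute-force SRI by looping over dyads and events
oracle_sri <- function(gbi) {
  ids <- colnames(gbi)
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      x <- 0
      na <- 0
      nb <- 0
      for (e in seq_len(nrow(gbi))) {
        ia <- gbi[e, a] == 1
        ib <- gbi[e, b] == 1
        if (ia && ib) x <- x + 1
        if (ia) na <- na + 1
        if (ib) nb <- nb + 1
      }
      denom <- na + nb - x
      w[a, b] <- if (denom > 0) x / denom else 0
    }
  }
  w
}
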