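# Independent oracle implementations used to cross-check the package.
# These deliberately use naive, direct formulations (explicit loops,
# exhaustive enumeration, exact arithmetic) and share no code with the
# implementation under test.

# Textbook Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running_min <- Inf
  for (i in n:1) {
    val <- p[ord[i]] * n / i
    running_min <- min(running_min, val, 1)
    q[ord[i]] <- running_min
  }
  q
}

# Product-limit estimator; deaths processed before censorings at ties.
# Returns surv at each distinct death time.
oracle_km <- function(time, status) {   # status 1 = death
  dt <- sort(unique(time[status == 1]))
  s <- 1
  out <- data.frame(time = dt, surv = NA_real_, n_risk = NA_real_,
                    n_event = NA_real_)
  for (i in seq_along(dt)) {
    t <- dt[i]
    at_risk <- sum(time > t | (time == t))  # censored at t still at risk
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
  }
  out
}

# Mantel-Cox log-rank chi-square by explicit O-E and hypergeometric
# variance sums over distinct death times.
oracle_logrank <- function(time_a, status_a, time_b, status_b) {
  times <- sort(unique(c(time_a[status_a == 1], time_b[status_b == 1])))
  O_minus_E <- 0
  V <- 0
  for (t in times) {
    n_a <- sum(time_a >= t)
    n_b <- sum(time_b >= t)
    d_a <- sum(time_a == t & status_a == 1)
    d_b <- sum(time_b == t & status_b == 1)
    n <- n_a + n_b
    d <- d_a + d_b
    if (n < 2) next
    e_a <- d * n_a / n
    v <- d * (n_a / n) * (n_b / n) * (n - d) / (n - 1)
    O_minus_E <- O_minus_E + (d_a - e_a)
    V <- V + v
  }
  chi2 <- O_minus_E^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Exhaustive DTW: enumerate every monotone warping path within the
# Sakoe-Chiba band, take the minimum summed squared difference, and return
# its square root.
oracle_dtw <- function(a, b, window = 1) {
  a <- unname(a)
  b <- unname(b)
  n <- length(a)
  m <- length(b)
  best <- Inf
  walk <- function(i, j, cost) {
    cost <- cost + (a[i] - b[j])^2
    if (cost >= best) return(invisible(NULL))
    if (i == n && j == m) {
      best <<- cost
      return(invisible(NULL))
    }
    for (step in list(c(1, 1), c(1, 0), c(0, 1))) {
      ii <- i + step[1]
      jj <- j + step[2]
      if (ii <= n && jj <= m && abs(ii - jj) <= window) walk(ii, jj, cost)
    }
  }
  if (abs(1 - 1) <= window) walk(1, 1, 0)
  sqrt(best)
}

# Weighted KS running sum over every position of the ranked list.
oracle_gsea_es <- function(scores, in_set, weight = 1) {
  n <- length(scores)
  nh <- sum(in_set)
  w <- abs(scores)^weight
  norm_hit <- sum(w[in_set])
  running <- 0
  extremum <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      running <- running + w[i] / norm_hit
    } else {
      running <- running - 1 / (n - nh)
    }
    if (abs(running) > abs(extremum)) extremum <- running
  }
  extremum
}

# Exact upper-tail hypergeometric by direct summation of binomial
# coefficients (exact in double precision for the small margins used).
oracle_hypergeom <- function(overlap, n_annotation, n_universe, n_hits) {
  ks <- overlap:min(n_annotation, n_hits)
  sum(choose(n_annotation, ks) *
        choose(n_universe - n_annotation, n_hits - ks)) /
    choose(n_universe, n_hits)
}

# NB log-likelihood maximizer by general-purpose optimization (BFGS with
# numeric gradient refinement via multiple restarts).
oracle_nb_fit <- function(y, X, s, alpha) {
  nll <- function(beta) {
    mu <- exp(drop(X %*% beta) + log(s))
    size <- 1 / alpha
    -sum(dnbinom(y, mu = mu, size = size, log = TRUE))
  }
  start <- qr.coef(qr(X), log((y + 0.5) / s))
  start[!is.finite(start)] <- 0
  fit <- optim(start, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  fit2 <- optim(fit$par, nll, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-15))
  if (fit2$value < fit$value) fit2$par else fit$par
}

# Adjusted Rand index (used when mclust is unavailable it would be
# reimplemented; here we delegate to mclust as the independent reference).
oracle_ari <- function(a, b) mclust::adjustedRandIndex(a, b)
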