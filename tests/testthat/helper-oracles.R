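# Independent oracles, coded from the defining formulas with deliberately
# different structure (scalar loops, direct choose() arithmetic) from the
# package implementation, plus small random-instance generators.

# ---- inverse-variance / DerSimonian-Laird oracles ----------------------

oracle_fixed <- function(theta, v, level = 0.95) {
  num <- 0; den <- 0
  for (i in seq_along(theta)) {
    num <- num + theta[i] / v[i]
    den <- den + 1 / v[i]
  }
  mu <- num / den
  se <- sqrt(1 / den)
  z <- qnorm(1 - (1 - level) / 2)
  list(theta = mu, ci_low = mu - z * se, ci_high = mu + z * se)
}

oracle_Q <- function(theta, v) {
  mu <- oracle_fixed(theta, v)$theta
  q <- 0
  for (i in seq_along(theta)) q <- q + (theta[i] - mu)^2 / v[i]
  q
}

oracle_dl <- function(theta, v, level = 0.95) {
  k <- length(theta)
  q <- oracle_Q(theta, v)
  sw <- sum(1 / v); sw2 <- sum(1 / v^2)
  tau2 <- max(0, (q - (k - 1)) / (sw - sw2 / sw))
  wstar <- 1 / (v + tau2)
  mu <- sum(wstar * theta) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  z <- qnorm(1 - (1 - level) / 2)
  list(theta = mu, ci_low = mu - z * se, ci_high = mu + z * se,
       tau2 = tau2, Q = q)
}

# ---- Mantel-Haenszel oracle --------------------------------------------

oracle_mh <- function(tabs, level = 0.95) {
  sumR <- 0; sumS <- 0; sumP <- 0
  for (tb in tabs) {
    N <- tb$n_t + tb$n_c
    sumR <- sumR + tb$r_t * tb$n_c / N
    sumS <- sumS + tb$r_c * tb$n_t / N
    sumP <- sumP + (tb$n_t * tb$n_c * (tb$r_t + tb$r_c) -
                      tb$r_t * tb$r_c * N) / N^2
  }
  lrr <- log(sumR / sumS)
  se <- sqrt(sumP / (sumR * sumS))
  z <- qnorm(1 - (1 - level) / 2)
  list(log_rr = lrr, ci_low = lrr - z * se, ci_high = lrr + z * se)
}

# ---- exact conditional oracle: full enumeration ------------------------

# joint support of the per-stratum treated-event counts, enumerated as a
# grid; probabilities of S = sum(x) at odds ratio psi by direct
# choose() products (safe at the small n used in tests).
oracle_exact_dist <- function(tabs, psi) {
  supports <- lapply(tabs, function(tb) {
    m <- tb$r_t + tb$r_c
    max(0, m - tb$n_c):min(tb$n_t, m)
  })
  grid <- expand.grid(supports)
  wt <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    w <- 1
    for (j in seq_along(tabs)) {
      tb <- tabs[[j]]; m <- tb$r_t + tb$r_c; x <- grid[r, j]
      w <- w * choose(tb$n_t, x) * choose(tb$n_c, m - x) * psi^x
    }
    wt[r] <- w
  }
  s <- rowSums(grid)
  p <- tapply(wt, s, sum) / sum(wt)
  data.frame(s = as.integer(names(p)), prob = as.numeric(p))
}

oracle_exact_ci <- function(tabs, level = 0.95, tol = 1e-9) {
  s_obs <- sum(vapply(tabs, `[[`, numeric(1), "r_t"))
  alpha2 <- (1 - level) / 2
  tail_ge <- function(lp) {
    d <- oracle_exact_dist(tabs, exp(lp))
    sum(d$prob[d$s >= s_obs])
  }
  tail_le <- function(lp) {
    d <- oracle_exact_dist(tabs, exp(lp))
    sum(d$prob[d$s <= s_obs])
  }
  d1 <- oracle_exact_dist(tabs, 1)
  smin <- min(d1$s); smax <- max(d1$s)
  bisect <- function(f, lo, hi) {
    flo <- f(lo)
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (hi - lo < tol) break
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }
  lo <- if (s_obs <= smin) -Inf else
    bisect(function(lp) tail_ge(lp) - alpha2, -15, 15)
  hi <- if (s_obs >= smax) Inf else
    bisect(function(lp) tail_le(lp) - alpha2, -15, 15)
  c(ci_low = lo, ci_high = hi)
}

# ---- random-instance generators ----------------------------------------

random_effects_df <- function(k, seed) {
  set.seed(seed)
  structure(data.frame(study_id = paste0("s", seq_len(k)),
                       theta = rnorm(k, 0, 0.8),
                       var = runif(k, 0.01, 0.5),
                       cc_applied = FALSE),
            class = c("effect_estimates", "data.frame"),
            scale = "log_rr", excluded = character())
}

# informative random 2x2 (not double-zero), per-arm n <= n_max
random_table <- function(n_max = 12, p = 0.3) {
  repeat {
    n_t <- sample(1:n_max, 1); n_c <- sample(1:n_max, 1)
    r_t <- rbinom(1, n_t, p); r_c <- rbinom(1, n_c, p)
    tb <- two_by_two(r_t, n_t, r_c, n_c)
    if (!(r_t == 0 && r_c == 0) && !is.null(harmsynth:::exact_stratum(tb)))
      return(tb)
  }
}

# all 2x2 tables with n_t, n_c <= n_max whose conditional distribution is
# informative (more than one table compatible with the margins)
all_informative_tables <- function(n_max) {
  out <- list()
  for (n_t in 1:n_max) for (n_c in 1:n_max)
    for (r_t in 0:n_t) for (r_c in 0:n_c) {
      tb <- two_by_two(r_t, n_t, r_c, n_c)
      if (!is.null(harmsynth:::exact_stratum(tb)))
        out[[length(out) + 1L]] <- tb
    }
  out
}
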