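# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive: plain loops, no shared code with the implementation.

# Running-sum enrichment score by direct enumeration over the whole list.
oracle_es <- function(scores, is_hit, weight_exponent = 1) {
  n <- length(scores)
  nh <- sum(is_hit)
  w <- abs(scores)^weight_exponent
  total <- sum(w[is_hit])
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      cur <- cur + if (total > 0) w[i] / total else 1 / nh
    } else {
      cur <- cur - 1 / (n - nh)
    }
    running[i] <- cur
  }
  # same declared tie-break as the implementation: positive side wins
  if (max(running) >= -min(running) - 1e-12) max(running) else min(running)
}

# Product-limit estimator tabulated by hand at each distinct event time.
oracle_km <- function(time, event, at) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# k-group log-rank chi-square from the per-event-time hypergeometric tables.
oracle_logrank <- function(time, event, group) {
  groups <- sort(unique(group))
  k <- length(groups)
  o_minus_e <- numeric(k)
  v <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    for (i in seq_len(k)) {
      ni <- sum(at_risk & group == groups[i])
      oi <- sum(time == t & event == 1 & group == groups[i])
      o_minus_e[i] <- o_minus_e[i] + oi - d * ni / n
      for (j in seq_len(k)) {
        nj <- sum(at_risk & group == groups[j])
        delta <- as.numeric(i == j)
        if (n > 1) {
          v[i, j] <- v[i, j] + d * (n - d) / (n - 1) * (ni / n) * (delta - nj / n)
        }
      }
    }
  }
  idx <- seq_len(k - 1)
  stat <- drop(t(o_minus_e[idx]) %*% solve(v[idx, idx, drop = FALSE]) %*% o_minus_e[idx])
  list(statistic = stat, df = k - 1, p_value = 1 - pchisq(stat, k - 1))
}

# Exact two-sided Mann-Whitney p by enumerating all group labelings.
oracle_mw_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  center <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - center) >= abs(u_obs - center))
}

# Fisher 2x2 two-sided p by hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  p_obs <- stats::dhyper(tab[1, 1], m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small random survival data set
random_records <- function(n, k_groups, seed) {
  set.seed(seed)
  tibble::tibble(
    time_months = round(stats::rexp(n, 0.1), 3),
    event = stats::rbinom(n, 1, 0.7),
    group = sample(LETTERS[seq_len(k_groups)], n, replace = TRUE)
  )
}
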