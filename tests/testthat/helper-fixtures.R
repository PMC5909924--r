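# Fixtures and definitional oracles shared across tests. The oracles are
# deliberately naive (nested loops straight from the definitions) so they
# stay independent of the vectorized implementations they check.

make_toy_ds <- function(n = 30, J = 5, seed = 1, censor_rate = 0.3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * J), n, J,
                dimnames = list(paste0("P", 1:n), paste0("g", 1:J)))
    beta <- rnorm(J, sd = 0.5)
    theta <- drop(scale(X %*% beta))
    t_event <- rexp(n, rate = exp(theta))
    t_cens <- rexp(n, rate = censor_rate * exp(mean(theta)))
    survival_dataset(X, time = pmin(t_event, t_cens),
                     event = as.numeric(t_event <= t_cens))
  })
}

# Partial log-likelihood straight from the nested-sum definition.
pll_nested_loop <- function(theta, time, event) {
  total <- 0
  for (i in seq_along(theta)) {
    if (event[i] == 1) {
      total <- total + theta[i] - log(sum(exp(theta[time >= time[i]])))
    }
  }
  total
}

# Risk-set matrix from the definitional double loop.
risk_matrix_loop <- function(time) {
  n <- length(time)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[j] >= time[i]) R[i, j] <- 1
  }
  R
}

# Weighted concordance from the definitional double loop; weight_fn(i)
# gives the pair weight when patient i is the earlier event (1 = Harrell).
concordance_loop <- function(time, event, score, weight_fn = function(i) 1) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- event[i] == 1 &&
      (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))
    if (!comparable) next
    w <- weight_fn(i)
    den <- den + w
    if (score[i] > score[j]) num <- num + w
    if (score[i] == score[j]) num <- num + 0.5 * w
  }
  num / den
}

# Textbook two-group log-rank chi-square: sum over event times of
# hypergeometric O-E in group 1, squared over the summed variance.
logrank_chisq_loop <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == unique(group)[1L]
  o_minus_e <- 0
  v <- 0
  for (s in sort(unique(time[event == 1]))) {
    at_risk <- time >= s
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == s)
    d1 <- sum(event == 1 & time == s & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n_tot
    if (n_tot > 1) {
      v <- v + d * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d) / (n_tot - 1)
    }
  }
  o_minus_e^2 / v
}

# Central finite differences of f at x.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

quiet_control <- function(n_iterations = 100L, seed = 1L, ...) {
  nncox_control(n_iterations = n_iterations, seed = seed, ...)
}
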