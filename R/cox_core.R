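#' Cox partial log-likelihood in matrix form
#'
#' Evaluates the Breslow-ties partial log-likelihood
#' \deqn{pl(\theta) = \sum_{i: e_i = 1} \Big( \theta_i -
#'   \log \sum_{j: t_j \ge t_i} e^{\theta_j} \Big)}
#' using a single matrix product against the risk-set indicator matrix
#' instead of the nested sums, with log-sum-exp stabilization. Each summand
#' is non-positive because every risk set contains its own patient, so the
#' value is always `<= 0`.
#'
#' @param theta Vector of per-patient log hazard ratios (prognostic index).
#' @param R Risk-set matrix from [build_risk_matrix()].
#' @param event 0/1 status vector; at least one event is required.
#' @param per_event If `TRUE`, divide by the number of events (useful for
#'   comparing across datasets; optimization always uses the raw sum).
#' @return A single number `<= 0`.
#' @export
#' @examples
#' t_obs <- c(1, 2, 3)
#' R <- build_risk_matrix(t_obs)
#' partial_log_likelihood(c(0.5, 0, -0.5), R, event = c(1, 1, 0))
partial_log_likelihood <- function(theta, R, event, per_event = FALSE) {
  assert_numeric_vector(theta, "theta")
  event <- assert_event_vector(event)
  n <- length(theta)
  if (!is.matrix(R) || nrow(R) != n || ncol(R) != n || length(event) != n) {
    abort("`theta`, `R` and `event` must agree in dimension.")
  }
  if (sum(event) < 1) abort("At least one observed event is required.")
  lse <- risk_logsumexp(R, theta)
  pll <- sum(event * (theta - lse))
  if (per_event) pll / sum(event) else pll
}

#' Gradient of the partial log-likelihood
#'
#' Analytic gradient of [partial_log_likelihood()] with respect to `theta`:
#' \deqn{\partial pl / \partial \theta_k = e_k - e^{\theta_k}
#'   \sum_{i: e_i = 1, t_k \ge t_i} 1 / \sum_{j: t_j \ge t_i} e^{\theta_j}}
#' computed with two matrix products. Entries always sum to zero, the
#' differential form of the likelihood's invariance to a constant shift in
#' `theta`.
#'
#' @inheritParams partial_log_likelihood
#' @return Numeric vector of length `n`.
#' @export
pll_gradient <- function(theta, R, event) {
  assert_numeric_vector(theta, "theta")
  event <- assert_event_vector(event)
  n <- length(theta)
  if (!is.matrix(R) || nrow(R) != n || ncol(R) != n || length(event) != n) {
    abort("`theta`, `R` and `event` must agree in dimension.")
  }
  if (sum(event) < 1) abort("At least one observed event is required.")
  m <- max(theta)
  e_theta <- exp(theta - m)
  denom <- drop(R %*% e_theta)
  # rows whose shifted denominator underflows are handled exactly via
  # softmax weights exp(theta_k - lse_i), which are always <= 1
  bad <- which(denom == 0 & event == 1)
  w <- ifelse(denom > 0, event / denom, 0)
  grad <- event - e_theta * drop(crossprod(R, w))
  for (i in bad) {
    in_risk <- R[i, ] == 1
    mi <- max(theta[in_risk])
    soft <- exp(theta - mi) * in_risk
    grad <- grad - soft / sum(soft)
  }
  grad
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' Given fitted log hazard ratios on the training patients, estimates the
#' cumulative baseline hazard as a right-continuous step function jumping at
#' each distinct event time `s` by `d_s / sum_{j at risk at s} exp(theta_j)`
#' where `d_s` counts events at `s` (Breslow ties). This is the unique
#' baseline consistent with the Breslow-ties partial likelihood, and with
#' `theta = 0` it reduces to the Nelson-Aalen estimator. Predicted survival
#' for a patient with index `theta_i` is
#' `S_i(t) = exp(-H0(t) * exp(theta_i))`.
#'
#' @param theta Fitted log hazard ratios on the same patients as
#'   `time`/`event`.
#' @param time Observed times.
#' @param event 0/1 status vector.
#' @return An object of class `baseline_hazard`: list with sorted distinct
#'   event `times` and the matching nondecreasing `cumulative_hazard`.
#' @export
breslow_baseline <- function(theta, time, event) {
  assert_numeric_vector(theta, "theta")
  assert_numeric_vector(time, "time", non_negative = TRUE)
  event <- assert_event_vector(event)
  if (sum(event) < 1) abort("At least one observed event is required.")
  event_times <- sort(unique(time[event == 1]))
  haz <- vapply(event_times, function(s) {
    sum(event[time == s]) / sum(exp(theta[time >= s]))
  }, numeric(1))
  structure(
    list(times = event_times, cumulative_hazard = cumsum(haz)),
    class = "baseline_hazard"
  )
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat(sprintf(
    "<baseline_hazard> %d event times in [%g, %g], H0(max) = %.4g\n",
    length(x$times), min(x$times), max(x$times),
    x$cumulative_hazard[length(x$cumulative_hazard)]
  ))
  invisible(x)
}

#' @describeIn breslow_baseline Tidy the step function into a tibble with
#'   columns `time` and `cumulative_hazard`.
#' @param x A `baseline_hazard` object.
#' @param ... Unused.
#' @export
tidy.baseline_hazard <- function(x, ...) {
  tibble(time = x$times, cumulative_hazard = x$cumulative_hazard)
}

# Evaluate the cumulative baseline hazard at arbitrary times
# (right-continuous step convention; 0 before the first event time).
baseline_at <- function(baseline, t) {
  idx <- findInterval(t, baseline$times)
  c(0, baseline$cumulative_hazard)[idx + 1L]
}

#' Predicted survival probabilities from a baseline hazard
#'
#' @param baseline A [breslow_baseline()] fit from training data.
#' @param theta Log hazard ratios of the patients to score.
#' @param times Times at which to evaluate survival.
#' @return Matrix with `length(theta)` rows and `length(times)` columns of
#'   survival probabilities `exp(-H0(t) exp(theta))`.
#' @export
predict_survival <- function(baseline, theta, times) {
  stopifnot(inherits(baseline, "baseline_hazard"))
  H0 <- baseline_at(baseline, times)
  exp(-outer(exp(theta), H0))
}
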