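#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering
#' matches the observed survival ordering. A pair is comparable when the
#' patient with the shorter time had an observed event (tied-time pairs
#' are comparable only when exactly one of the two is an event). A pair is
#' concordant when the shorter-lived patient has the higher score; ties in
#' the score count 0.5. An uninformative score gives 0.5.
#'
#' @param time Observed times.
#' @param event 0/1 status vector.
#' @param score Predicted risk score (log hazard ratio); higher = shorter
#'   predicted survival.
#' @return Concordance in `[0, 1]`.
#' @export
#' @examples
#' concordance_harrell(c(1, 2, 3), c(1, 1, 1), c(3, 1, 2))
concordance_harrell <- function(time, event, score) {
  cw <- concordance_pairs(time, event, score)
  if (cw$n_pairs == 0) abort("No comparable pairs: concordance is undefined.")
  cw$concordant / cw$n_pairs
}

# Shared pair machinery for the weighted and unweighted concordance.
# weights: per-patient weight applied to pairs in which that patient is the
# earlier event (1 for Harrell).
concordance_pairs <- function(time, event, score, weights = NULL) {
  assert_numeric_vector(time, "time", non_negative = TRUE)
  event <- assert_event_vector(event)
  assert_numeric_vector(score, "score")
  n <- length(time)
  if (length(event) != n || length(score) != n) {
    abort("`time`, `event` and `score` must have equal length.")
  }
  weights <- weights %||% rep(1, n)
  # comparable: earlier patient i has an event, and either t_i < t_j, or
  # t_i == t_j with j censored
  lt <- outer(time, time, "<")
  tie_t <- outer(time, time, "==")
  comparable <- (lt | (tie_t & outer(event, 1 - event, "*") == 1)) & (event == 1)
  w <- matrix(weights, n, n) * comparable
  hi <- outer(score, score, ">")
  tie_s <- outer(score, score, "==")
  list(
    concordant = sum(w * hi) + 0.5 * sum(w * tie_s),
    n_pairs = sum(w)
  )
}

# Kaplan-Meier estimator of the censoring survival function G; returns a
# function giving the left limit G(t-).
km_censoring_minus <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  steps_t <- sf$time
  steps_s <- sf$surv
  function(t) {
    idx <- findInterval(t, steps_t, left.open = TRUE)
    c(1, steps_s)[idx + 1L]
  }
}

#' IPCW concordance index
#'
#' Concordance with inverse-probability-of-censoring weights: each
#' comparable pair is weighted by `1 / G(t_i-)^2`, where `G` is the
#' Kaplan-Meier estimate of the censoring survival function and `t_i` the
#' earlier (event) time of the pair. This removes the bias of the
#' unweighted index when censoring is informative. Pairs whose weight
#' denominator is zero are excluded with a warning. With no censoring in
#' the data all weights are 1 and the value equals [concordance_harrell()]
#' exactly.
#'
#' @inheritParams concordance_harrell
#' @param cens_time,cens_event Optional sample from which to estimate the
#'   censoring distribution (e.g. the training set); defaults to
#'   `time`/`event` themselves.
#' @return Weighted concordance in `[0, 1]`.
#' @export
concordance_ipcw <- function(time, event, score,
                             cens_time = NULL, cens_event = NULL) {
  event <- assert_event_vector(event)
  G_minus <- km_censoring_minus(cens_time %||% time, cens_event %||% event)
  g <- G_minus(time)
  zero_g <- g == 0 & event == 1
  if (any(zero_g)) {
    warn(sprintf(
      "%d patient(s) with zero censoring-survival weight excluded from IPCW pairs.",
      sum(zero_g)
    ))
  }
  weights <- ifelse(g > 0, 1 / g^2, 0)
  cw <- concordance_pairs(time, event, score, weights = weights)
  if (cw$n_pairs == 0) abort("No comparable pairs: concordance is undefined.")
  cw$concordant / cw$n_pairs
}

#' Log-rank test of the median-dichotomized prognostic index
#'
#' Splits patients into high- and low-risk groups at the median score
#' (scores exactly at the median go to the low-risk group) and runs the
#' two-sample log-rank test comparing their survival curves.
#'
#' @inheritParams concordance_harrell
#' @return A list with `p_value`, `chisq` and the group sizes.
#' @export
logrank_dichotomized <- function(time, event, score) {
  assert_numeric_vector(score, "score")
  event <- assert_event_vector(event)
  cut <- median(score)
  group <- factor(ifelse(score > cut, "high", "low"), levels = c("low", "high"))
  if (any(table(group) == 0)) {
    abort("Median split produced an empty risk group; scores are too concentrated.")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- sd$chisq
  list(
    p_value = pchisq(chisq, df = 1L, lower.tail = FALSE),
    chisq = chisq,
    n_low = sum(group == "low"),
    n_high = sum(group == "high")
  )
}

#' Integrated Brier score from survival probability curves
#'
#' At each grid time t, the Brier score is the IPCW-weighted mean squared
#' error between the predicted survival probability and the observed
#' status: patients with an event by t contribute `S_i(t)^2 / G(t_i-)`,
#' patients still under observation contribute `(1 - S_i(t))^2 / G(t)`,
#' and patients censored by t contribute nothing. The scores are
#' integrated over `[0, t_max]` by the trapezoid rule and divided by
#' `t_max`, giving a time-averaged squared error (0 is perfect; 0.25 is
#' the constant-1/2 predictor on uncensored data).
#'
#' @param time,event Observed test outcomes.
#' @param surv Matrix of predicted survival probabilities, patients in rows
#'   and `grid_times` in columns.
#' @param grid_times Evaluation times (nondecreasing, within the observed
#'   range).
#' @param cens_time,cens_event Sample used for the censoring Kaplan-Meier
#'   weights (typically the training set); defaults to `time`/`event`.
#' @return Non-negative scalar.
#' @export
integrated_brier_score <- function(time, event, surv, grid_times,
                                   cens_time = NULL, cens_event = NULL) {
  assert_numeric_vector(time, "time", non_negative = TRUE)
  event <- assert_event_vector(event)
  if (length(grid_times) == 0L) abort("Empty time grid for the Brier score.")
  if (!is.matrix(surv) || nrow(surv) != length(time) || ncol(surv) != length(grid_times)) {
    abort("`surv` must be a patients x grid_times matrix.")
  }
  G_minus <- km_censoring_minus(cens_time %||% time, cens_event %||% event)
  g_at_event <- G_minus(time)
  bs <- vapply(seq_along(grid_times), function(k) {
    t <- grid_times[k]
    s_t <- surv[, k]
    had_event <- time <= t & event == 1
    at_risk <- time > t
    g_t <- G_minus(t * (1 + 1e-12)) # right-continuous G(t)
    w_event <- ifelse(had_event & g_at_event > 0, 1 / g_at_event, 0)
    w_risk <- if (g_t > 0) as.numeric(at_risk) / g_t else numeric(length(time))
    mean(s_t^2 * w_event + (1 - s_t)^2 * w_risk)
  }, numeric(1))
  t_max <- max(grid_times)
  if (t_max == 0) abort("Degenerate time grid: all times are 0.")
  if (length(grid_times) == 1L) return(bs)
  sum(diff(grid_times) * (head(bs, -1) + bs[-1]) / 2) / t_max
}

#' Integrated Brier score of a fitted prognostic index
#'
#' Convenience wrapper: builds survival curves
#' `S_i(t) = exp(-H0(t) exp(theta_i))` from a training-set Breslow baseline
#' and scores them on the test outcomes over the grid `{0, test event
#' times, t_max}`.
#'
#' @param theta Test-set log hazard ratios.
#' @param baseline A [breslow_baseline()] from the training data.
#' @inheritParams integrated_brier_score
#' @return Non-negative scalar.
#' @export
integrated_brier <- function(theta, baseline, time, event,
                             cens_time = NULL, cens_event = NULL) {
  stopifnot(inherits(baseline, "baseline_hazard"))
  event <- assert_event_vector(event)
  t_max <- max(time)
  grid_times <- sort(unique(c(0, time[event == 1 & time <= t_max], t_max)))
  surv <- predict_survival(baseline, theta, grid_times)
  integrated_brier_score(time, event, surv, grid_times, cens_time, cens_event)
}

#' Evaluate a fitted model on held-out data
#'
#' Computes the four survival accuracy metrics on a test set: Harrell's
#' concordance, IPCW concordance, the log-rank p-value of the
#' median-dichotomized prognostic index, and the integrated Brier score.
#' When the training data are supplied, the Breslow baseline hazard and
#' the censoring distribution used for weighting are estimated from them
#' (the recommended use); otherwise they fall back to the test set.
#'
#' @param fit An [nncox()] fit.
#' @param test Test [survival_dataset()].
#' @param train Optional training [survival_dataset()].
#' @return One-row tibble: `c_harrell`, `c_ipcw`, `logrank_p`,
#'   `integrated_brier`, `n_test`, `n_events_test`.
#' @export
evaluate_model <- function(fit, test, train = NULL) {
  stopifnot(inherits(fit, "nncox_fit"), inherits(test, "survival_dataset"))
  theta_test <- predict(fit, test)$pi
  ref <- train %||% test
  theta_ref <- predict(fit, ref)$pi
  baseline <- breslow_baseline(theta_ref, ref$time, ref$event)
  tibble(
    c_harrell = concordance_harrell(test$time, test$event, theta_test),
    c_ipcw = concordance_ipcw(test$time, test$event, theta_test,
                              cens_time = ref$time, cens_event = ref$event),
    logrank_p = logrank_dichotomized(test$time, test$event, theta_test)$p_value,
    integrated_brier = integrated_brier(theta_test, baseline, test$time, test$event,
                                        cens_time = ref$time, cens_event = ref$event),
    n_test = nrow(test$X),
    n_events_test = n_events(test)
  )
}

#' Repeated holdout evaluation harness
#'
#' The standard benchmarking protocol: repeatedly split the data 80/20,
#' select hyperparameters by k-fold cross-validation on the training part,
#' refit at the selected setting, and evaluate all four metrics on the
#' holdout. Per-repeat seeds are derived deterministically from the master
#' seed, so the whole table is reproducible.
#'
#' @param data A [survival_dataset()].
#' @param grid Hyperparameter grid for [cv_search()].
#' @param n_repeats Number of random splits (default 10).
#' @param test_fraction Holdout fraction (default 0.2).
#' @param k CV folds (default 5).
#' @param hidden_layers,hidden_size Architecture passed to [nncox()].
#' @param control [nncox_control()] used for all fits.
#' @param seed Master seed.
#' @return Tibble with one row per repeat: the selected `ridge` and
#'   `dropout`, and the four metrics with test-set sizes.
#' @export
repeated_holdout <- function(data, grid = hyperparameter_grid(),
                             n_repeats = 10L, test_fraction = 0.2, k = 5L,
                             hidden_layers = 1L, hidden_size = NULL,
                             control = nncox_control(), seed = 1L) {
  stopifnot(inherits(data, "survival_dataset"))
  purrr::map_dfr(seq_len(n_repeats), function(r) {
    split_seed <- derive_seed(seed, r * 3L)
    cv_seed <- derive_seed(seed, r * 3L + 1L)
    fit_seed <- derive_seed(seed, r * 3L + 2L)
    parts <- train_test_split(data, test_fraction, seed = split_seed)
    ctrl <- control
    ctrl$seed <- fit_seed
    cv <- cv_search(parts$train, grid, k, hidden_layers, hidden_size,
                    control = ctrl, seed = cv_seed)
    fit <- nncox(parts$train, hidden_layers = hidden_layers,
                 hidden_size = hidden_size, dropout = cv$best$dropout,
                 ridge = cv$best$ridge, control = ctrl)
    dplyr::bind_cols(
      tibble(repeat_id = r, ridge = cv$best$ridge, dropout = cv$best$dropout),
      evaluate_model(fit, parts$test, train = parts$train)
    )
  })
}
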