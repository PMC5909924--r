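test_that("Harrell concordance reproduces hand-enumerated pair counts", {
  # perfectly anti-ordered scores, all events
  expect_equal(concordance_harrell(c(1, 2, 3, 4), rep(1, 4), c(4, 3, 2, 1)), 1)
  # constant score: every comparable pair ties at 0.5
  expect_equal(concordance_harrell(c(1, 2, 3), rep(1, 3), c(2, 2, 2)), 0.5)
  # worked example: pairs (1,2) and (1,3) concordant, (2,3) discordant
  expect_equal(concordance_harrell(c(1, 2, 3), rep(1, 3), c(3, 1, 2)), 2 / 3)
})

test_that("comparable-pair rules handle censoring and tied times", {
  # earlier censored: only the (2 -> none) ... single usable pair comes from
  # patient 2's event at time 2 vs nobody later -> no pairs, error
  expect_error(concordance_harrell(c(1, 2), c(0, 1), c(2, 1)), "comparable")
  # tied times: both events excluded; event-vs-censored comparable
  expect_equal(concordance_harrell(c(2, 2, 5), c(1, 0, 1), c(3, 1, 0)), 1)
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      time <- sample(1:5, n, replace = TRUE)
      event <- c(1, rbinom(n - 1, 1, 0.6))
      score <- rnorm(n)
      expect_equal(concordance_harrell(time, event, score),
                   concordance_loop(time, event, score))
      # negation flips concordance around 1/2
      expect_equal(concordance_harrell(time, event, -score),
                   1 - concordance_harrell(time, event, score))
    }
  })
})

test_that("Harrell concordance agrees with the survival package on event-only data", {
  withr::with_seed(32, {
    n <- 60
    time <- rexp(n)
    score <- rnorm(n)
    ours <- concordance_harrell(time, rep(1, n), score)
    ref <- survival::concordance(survival::Surv(time, rep(1, n)) ~ score,
                                 reverse = TRUE)$concordance
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("IPCW concordance equals Harrell without censoring and matches the pair oracle", {
  withr::with_seed(33, {
    n <- 25
    time <- rexp(n)
    score <- rnorm(n)
    expect_identical(concordance_ipcw(time, rep(1, n), score),
                     concordance_harrell(time, rep(1, n), score))
    # constant score stays at 1/2 under any weighting
    time2 <- rexp(n); ev2 <- rbinom(n, 1, 0.7); ev2[1] <- 1
    expect_equal(concordance_ipcw(time2, ev2, rep(0, n)), 0.5)
  })
  # 4-patient censored example against the definitional weighted loop
  time <- c(1, 2, 3, 4); event <- c(1, 0, 1, 1); score <- c(2, 0, 1, -1)
  G <- nncox:::km_censoring_minus(time, event)
  ours <- concordance_ipcw(time, event, score)
  oracle <- concordance_loop(time, event, score, weight_fn = function(i) 1 / G(time[i])^2)
  expect_equal(ours, oracle)
})

test_that("median-split log-rank test matches the textbook statistic", {
  # identical duplicated groups: observed == expected, p = 1
  time <- rep(c(1, 2, 3, 4), 2); event <- rep(1, 8)
  score <- rep(c(1, 0), each = 4)
  res <- logrank_dichotomized(time, event, score)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_equal(res$chisq, 0, tolerance = 1e-12)

  # fully separated event times: decisive at n = 40
  time2 <- c(1:20 / 10, 5 + 1:20 / 10)
  score2 <- rep(c(1, 0), each = 20)
  expect_lt(logrank_dichotomized(time2, rep(1, 40), score2)$p_value, 0.01)

  # 6-patient worked table vs the hand-computed O-E/V chi-square
  t6 <- c(1, 2, 3, 4, 5, 6); e6 <- c(1, 1, 0, 1, 1, 1); s6 <- c(5, 1, 4, 2, 6, 3)
  grp <- s6 > median(s6)
  expect_equal(logrank_dichotomized(t6, e6, s6)$chisq,
               logrank_chisq_loop(t6, e6, grp), tolerance = 1e-10)

  expect_error(logrank_dichotomized(t6, e6, rep(1, 6)), "empty")
  # scores exactly at the median belong to the low-risk group
  res2 <- logrank_dichotomized(t6, e6, c(1, 2, 2, 2, 3, 4))
  expect_equal(res2$n_low, 4)
  expect_equal(res2$n_high, 2)
})

test_that("integrated Brier score reproduces closed-form cases", {
  # constant predicted survival 1/2 on uncensored data: BS(t) = 1/4 always
  n <- 6
  time <- 1:6; event <- rep(1, n)
  grid <- c(0, time)
  surv_half <- matrix(0.5, n, length(grid))
  expect_equal(integrated_brier_score(time, event, surv_half, grid), 0.25)
  # perfect survival prediction with no events before t_max
  surv_one <- matrix(1, n, length(grid))
  expect_equal(integrated_brier_score(time, rep(0, n), surv_one, grid), 0)
  # 5-patient uncensored brute force at each grid time
  withr::with_seed(34, {
    t5 <- c(1, 2, 3, 4, 5); e5 <- rep(1, 5)
    g5 <- c(0, t5)
    S <- matrix(runif(5 * 6), 5, 6)
    bs_hand <- vapply(seq_along(g5), function(k) {
      mean(ifelse(t5 <= g5[k], S[, k]^2, (1 - S[, k])^2))
    }, numeric(1))
    expected <- sum(diff(g5) * (bs_hand[-6] + bs_hand[-1]) / 2) / max(g5)
    expect_equal(integrated_brier_score(t5, e5, S, g5), expected)
  })
})

test_that("the null model upper-bounds a well-fit model on strong-signal data", {
  sim <- simulate_survival_data(simulation_config(
    n_groups = 1, patients_per_group = 150, n_genes = 12, n_signal_genes = 12,
    seed = 35
  ))
  parts <- train_test_split(sim$data, 0.3, seed = 1)
  fit <- nncox(parts$train, hidden_layers = 0, control = quiet_control(600, seed = 2))
  theta_tr <- predict(fit, parts$train)$pi
  theta_te <- predict(fit, parts$test)$pi
  bl_fit <- breslow_baseline(theta_tr, parts$train$time, parts$train$event)
  bl_null <- breslow_baseline(rep(0, nrow(parts$train$X)), parts$train$time, parts$train$event)
  ib_fit <- integrated_brier(theta_te, bl_fit, parts$test$time, parts$test$event,
                             cens_time = parts$train$time, cens_event = parts$train$event)
  ib_null <- integrated_brier(rep(0, nrow(parts$test$X)), bl_null,
                              parts$test$time, parts$test$event,
                              cens_time = parts$train$time, cens_event = parts$train$event)
  expect_lt(ib_fit, ib_null)
})

test_that("evaluate_model returns the four metrics in range", {
  ds <- make_toy_ds(n = 60, J = 5, seed = 36, censor_rate = 0.3)
  parts <- train_test_split(ds, 0.3, seed = 2)
  fit <- nncox(parts$train, hidden_layers = 0, control = quiet_control(300, seed = 3))
  rep1 <- evaluate_model(fit, parts$test, parts$train)
  expect_named(rep1, c("c_harrell", "c_ipcw", "logrank_p", "integrated_brier",
                       "n_test", "n_events_test"))
  expect_true(all(vapply(rep1, is.finite, logical(1))))
  expect_true(rep1$c_harrell >= 0 && rep1$c_harrell <= 1)
  expect_true(rep1$c_ipcw >= 0 && rep1$c_ipcw <= 1)
  expect_true(rep1$logrank_p > 0 && rep1$logrank_p <= 1)
  expect_gte(rep1$integrated_brier, 0)
})

test_that("repeated holdout is deterministic and shaped one row per repeat", {
  sim <- simulate_survival_data(simulation_config(
    n_groups = 1, patients_per_group = 80, n_genes = 10, n_signal_genes = 10,
    seed = 37
  ))
  grid <- hyperparameter_grid(ridge = c(0, 0.1), dropout = 1)
  r1 <- repeated_holdout(sim$data, grid, n_repeats = 2, k = 3,
                         hidden_layers = 0, control = quiet_control(60), seed = 5)
  expect_equal(nrow(r1), 2)
  r2 <- repeated_holdout(sim$data, grid, n_repeats = 2, k = 3,
                         hidden_layers = 0, control = quiet_control(60), seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$c_harrell > 0 & r1$c_harrell < 1))
})
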