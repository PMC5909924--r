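test_that("hidden width follows the square-root rule", {
  expect_equal(default_hidden_size(1000), 32)
  expect_equal(default_hidden_size(1), 1)
  expect_equal(default_hidden_size(143^2), 143)
})

test_that("forward pass degenerates correctly", {
  withr::with_seed(21, {
    X <- matrix(rnorm(20), 5, 4)
    # zero weights, zero bias: tanh(0) = 0 so theta = 0 whatever beta is
    m <- nncox_model(4, hidden_layers = 1, hidden_size = 3, seed = 1)
    m$W[] <- 0
    m$beta <- c(1, -2, 3)
    expect_equal(nncox_forward(m, X)$theta, rep(0, 5))

    # no hidden layer: exactly the linear Cox-PH predictor
    m0 <- nncox_model(4, hidden_layers = 0)
    m0$beta <- rnorm(4)
    expect_equal(nncox_forward(m0, X)$theta, drop(X %*% m0$beta))

    # tanh saturates to +/-1 and is odd through 0
    m1 <- nncox_model(1, hidden_layers = 1, hidden_size = 1, seed = 2)
    m1$W[] <- 1; m1$b[] <- 0; m1$beta <- 1
    expect_equal(nncox_forward(m1, matrix(0))$theta, 0)
    expect_equal(nncox_forward(m1, matrix(50))$theta, 1, tolerance = 1e-12)
    expect_error(nncox_forward(m, matrix(rnorm(10), 5, 2)), "features")
  })
})

test_that("cost reduces to the negative likelihood and grows with ridge", {
  withr::with_seed(22, {
    X <- matrix(rnorm(24), 6, 4)
    time <- c(3, 1, 4, 2, 5, 2); event <- c(1, 0, 1, 1, 1, 0)
    R <- build_risk_matrix(time)
    m <- nncox_model(4, hidden_layers = 1, hidden_size = 2, ridge = 0, seed = 3)
    m$beta <- rnorm(2)
    theta <- nncox_forward(m, X)$theta
    expect_equal(nncox_cost(m, X, R, event), -partial_log_likelihood(theta, R, event))
    lams <- c(0.1, 1, 10, 100)
    costs <- vapply(lams, function(l) { m$ridge_lambda <- l; nncox_cost(m, X, R, event) }, numeric(1))
    expect_true(all(diff(costs) > 0))
  })
})

test_that("backprop gradients match central differences for every parameter", {
  withr::with_seed(23, {
    X <- matrix(rnorm(24), 6, 4)
    time <- c(3, 1, 4, 2, 5, 2); event <- c(1, 0, 1, 1, 1, 0)
    R <- build_risk_matrix(time)
    for (hl in c(0L, 1L, 2L)) {
      m <- nncox_model(4, hidden_layers = hl, hidden_size = 2, ridge = 0.1, seed = hl + 1)
      m$beta <- rnorm(length(m$beta))
      if (hl >= 1) m$b <- rnorm(length(m$b), sd = 0.2)
      cg <- nncox:::cost_and_gradients(m, X, R, event)
      for (f in nncox:::param_names(m)) {
        fd <- vapply(seq_along(m[[f]]), function(i) {
          mp <- m; mp[[f]][i] <- mp[[f]][i] + 1e-6
          mm <- m; mm[[f]][i] <- mm[[f]][i] - 1e-6
          (nncox_cost(mp, X, R, event) - nncox_cost(mm, X, R, event)) / 2e-6
        }, numeric(1))
        denom <- pmax(abs(fd), 1)
        expect_lt(max(abs(fd - as.vector(cg$grads[[f]])) / denom), 1e-4)
      }
    }
  })
})

test_that("dropout gradients are exact with the mask held fixed", {
  withr::with_seed(24, {
    X <- matrix(rnorm(24), 6, 4)
    time <- c(3, 1, 4, 2, 5, 2); event <- c(1, 0, 1, 1, 1, 0)
    R <- build_risk_matrix(time)
    m <- nncox_model(4, hidden_layers = 1, hidden_size = 3, dropout = 0.5,
                     ridge = 0.2, seed = 5)
    m$beta <- rnorm(3)
    masks <- list(c(1, 0, 1))
    cg <- nncox:::cost_and_gradients(m, X, R, event, mode = "train", masks = masks)
    for (f in c("W", "b", "beta")) {
      fd <- vapply(seq_along(m[[f]]), function(i) {
        mp <- m; mp[[f]][i] <- mp[[f]][i] + 1e-6
        mm <- m; mm[[f]][i] <- mm[[f]][i] - 1e-6
        (nncox_cost(mp, X, R, event, mode = "train", masks = masks) -
           nncox_cost(mm, X, R, event, mode = "train", masks = masks)) / 2e-6
      }, numeric(1))
      expect_lt(max(abs(fd - as.vector(cg$grads[[f]]))), 1e-4)
    }
    # a dropped node contributes nothing, so its incoming weights get only
    # the ridge gradient
    expect_equal(as.vector(cg$grads$W[2, ]), as.vector(2 * m$ridge_lambda * m$W[2, ]))
  })
})

test_that("training is deterministic and its trace stays finite", {
  ds <- make_toy_ds(n = 40, J = 6, seed = 25)
  f1 <- nncox(ds, hidden_layers = 1, dropout = 0.7, control = quiet_control(80, seed = 9))
  f2 <- nncox(ds, hidden_layers = 1, dropout = 0.7, control = quiet_control(80, seed = 9))
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$model$W, f2$model$W)
  expect_true(all(is.finite(f1$loss_trace)))
  expect_length(f1$loss_trace, 80)
  # final model reproduces its recorded final likelihood
  R <- build_risk_matrix(ds$time)
  th <- nncox:::forward_pass(f1$model, ds$X, "eval")$theta
  expect_equal(partial_log_likelihood(th, R, ds$event), f1$final_pll)
})

test_that("retention probability 1 is exactly the deterministic network", {
  ds <- make_toy_ds(n = 30, J = 5, seed = 26)
  m <- nncox(ds, hidden_layers = 1, dropout = 1, control = quiet_control(40, seed = 3))$model
  # with p = 1 no masks are drawn: train and eval forward passes coincide
  # bit-for-bit, which is the no-dropout model
  fw_eval <- nncox:::forward_pass(m, ds$X, "eval")
  fw_train <- nncox:::forward_pass(m, ds$X, "train")
  expect_identical(fw_eval$theta, fw_train$theta)
  # and an all-ones mask under p < 1 reproduces the unscaled activations
  m$dropout_p <- 0.5
  fw_ones <- nncox:::forward_pass(m, ds$X, "train", masks = list(rep(1, m$hidden_size)))
  expect_identical(fw_ones$activations[[1]], fw_eval$activations[[1]])
})

test_that("the three optimizers all descend; Nesterov is no slower than plain descent", {
  ds <- make_toy_ds(n = 60, J = 8, seed = 27, censor_rate = 0.2)
  traces <- lapply(c("gradient", "momentum", "nesterov"), function(opt) {
    nncox(ds, hidden_layers = 1,
          control = quiet_control(120, seed = 4, optimizer = opt))$loss_trace
  })
  names(traces) <- c("gradient", "momentum", "nesterov")
  for (tr in traces) expect_lt(min(tr), tr[1])
  threshold <- min(traces$gradient)
  first_at <- function(tr) which(tr <= threshold)[1]
  expect_lte(first_at(traces$nesterov), first_at(traces$gradient))
})

test_that("zero-hidden training recovers the Cox partial-likelihood optimum", {
  ds <- make_toy_ds(n = 80, J = 4, seed = 28, censor_rate = 0.2)
  fit <- nncox(ds, hidden_layers = 0, control = quiet_control(1500, seed = 5))
  cph <- survival::coxph(survival::Surv(ds$time, ds$event) ~ ds$X, ties = "breslow")
  # the decaying-rate schedule stops short of the exact optimum; agreement is
  # to ~1e-2 on coefficients of order 1, with correlation essentially 1
  expect_lt(max(abs(tidy(fit)$estimate - coef(cph))), 0.03)
  expect_gt(cor(tidy(fit)$estimate, coef(cph)), 0.995)
  expect_true(all(sign(tidy(fit)$estimate[abs(coef(cph)) > 0.2]) ==
                  sign(coef(cph)[abs(coef(cph)) > 0.2])))
})

test_that("training aborts with a diagnostic when the cost blows up", {
  ds <- make_toy_ds(n = 20, J = 3, seed = 29)
  expect_error(
    nncox(ds, hidden_layers = 0,
          control = nncox_control(n_iterations = 200, learning_rate = 1e9,
                                  lr_decay = 1, seed = 1)),
    "iteration"
  )
})

test_that("model archives round-trip bit-exactly", {
  ds <- make_toy_ds(n = 25, J = 4, seed = 30)
  fit <- nncox(ds, hidden_layers = 1, dropout = 0.8, ridge = 0.01,
               control = quiet_control(30, seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  write_nncox(fit, path)
  back <- read_nncox(path)
  expect_identical(back, fit)
  expect_identical(predict(back, ds), predict(fit, ds))
  expect_error(read_nncox("nope.rds"), "not found")
})
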