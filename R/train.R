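#' Training configuration
#'
#' Full-batch gradient training schedule: a fixed number of iterations, a
#' learning rate initialized at 0.1 that decays by a factor of 0.9 whenever
#' the cost fails to improve on the running best, and one of three
#' optimizers (plain gradient descent, classical momentum, or Nesterov
#' accelerated gradient — the default).
#'
#' @param n_iterations Number of full-batch updates (default 10000).
#' @param learning_rate Initial learning rate.
#' @param lr_decay Multiplicative decay in (0, 1], applied at most once per
#'   iteration when the cost does not beat the running best.
#' @param optimizer `"nesterov"`, `"momentum"` or `"gradient"`.
#' @param momentum Momentum coefficient for the momentum-based optimizers.
#' @param seed Seed controlling weight initialization and dropout masks;
#'   identical seeds and configs give bit-identical training traces.
#' @return A list of class `nncox_control`.
#' @export
nncox_control <- function(n_iterations = 10000L, learning_rate = 0.1,
                          lr_decay = 0.9, optimizer = c("nesterov", "momentum", "gradient"),
                          momentum = 0.9, seed = NULL) {
  optimizer <- match.arg(optimizer)
  if (n_iterations < 1L) abort("`n_iterations` must be >= 1.")
  if (lr_decay <= 0 || lr_decay > 1) abort("`lr_decay` must be in (0, 1].")
  structure(
    list(
      n_iterations = as.integer(n_iterations), learning_rate = learning_rate,
      lr_decay = lr_decay, optimizer = optimizer, momentum = momentum,
      seed = seed
    ),
    class = "nncox_control"
  )
}

model_params <- function(model) model[param_names(model)]

set_params <- function(model, params) {
  model[names(params)] <- params
  model
}

#' Fit a neural-network Cox model
#'
#' Maximizes the ridge-regularized Cox partial log-likelihood over the
#' network weights by full-batch backpropagation. When `dropout < 1` a fresh
#' node-retention mask is drawn each iteration and the gradient is taken
#' with the mask fixed; at evaluation time hidden activations are scaled by
#' the retention probability instead.
#'
#' @param data A [survival_dataset()] with at least one observed event.
#' @param hidden_layers 0 (linear Cox-PH), 1 (default) or 2 hidden layers.
#' @param hidden_size Hidden width; defaults to the square root of the
#'   number of features ([default_hidden_size()]).
#' @param dropout Retention probability p in (0, 1]; 1 disables dropout.
#' @param ridge Ridge penalty lambda >= 0.
#' @param control A [nncox_control()] training schedule.
#' @param standardize Center and scale each feature to unit variance before
#'   training (default `TRUE`, as in glmnet). The scaling is stored in the
#'   model and applied automatically at prediction time, and reported
#'   coefficients/importances are transformed back to the original input
#'   scale, so results are expressed in the units of the supplied data.
#'   Unscaled log-expression inputs have large offsets that saturate the
#'   tanh layer, so disabling this is only sensible for pre-scaled data.
#' @return An object of class `nncox_fit`: the trained model, the
#'   per-iteration `loss_trace` of the regularized cost, the final
#'   evaluation-mode partial log-likelihood `final_pll`, and the resolved
#'   configuration.
#' @export
#' @examples
#' sim <- simulate_survival_data(simulation_config(
#'   n_groups = 2, patients_per_group = 40, n_genes = 50,
#'   n_signal_genes = 10, seed = 1))
#' fit <- nncox(sim$data, hidden_layers = 0,
#'              control = nncox_control(n_iterations = 50, seed = 1))
#' glance(fit)
nncox <- function(data, hidden_layers = 1L, hidden_size = NULL, dropout = 1,
                  ridge = 0, control = nncox_control(), standardize = TRUE) {
  stopifnot(inherits(data, "survival_dataset"))
  if (n_events(data) < 1L) abort("Model fitting requires at least one observed event.")
  X <- data$X
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, sd)
    scale[scale == 0] <- 1 # constant features carry no information; leave them at 0
    X <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  }
  R <- build_risk_matrix(data$time)
  event <- data$event

  with_seed_maybe(control$seed, {
    model <- nncox_model(
      ncol(X), hidden_layers = hidden_layers, hidden_size = hidden_size,
      dropout = dropout, ridge = ridge, feature_names = data$feature_names
    )
    trained <- run_training(model, X, R, event, control)
  })
  model <- trained$model
  final_pll <- partial_log_likelihood(forward_pass(model, X, "eval")$theta, R, event)
  if (standardize) {
    model$center <- center
    model$scale <- scale
  }
  structure(
    list(
      model = model,
      loss_trace = trained$loss_trace,
      final_pll = final_pll,
      final_learning_rate = trained$final_learning_rate,
      config = control,
      n_patients = nrow(X),
      n_events = n_events(data)
    ),
    class = "nncox_fit"
  )
}

run_training <- function(model, X, R, event, control) {
  use_dropout <- model$hidden_layers > 0L && model$dropout_p < 1
  mode <- if (use_dropout) "train" else "eval"
  nm <- param_names(model)
  velocity <- lapply(model_params(model), function(p) p * 0)
  # the step uses the per-event-normalized gradient so the default learning
  # rate is scale-free in the number of events; the cost itself stays the
  # raw-sum regularized negative partial log-likelihood
  lr <- control$learning_rate / sum(event)
  mu <- control$momentum
  best <- Inf
  trace <- numeric(control$n_iterations)

  blow_up <- function(it) {
    abort(sprintf("Training cost became non-finite at iteration %d.", it))
  }
  for (it in seq_len(control$n_iterations)) {
    masks <- if (use_dropout) sample_dropout_masks(model) else NULL
    eval_cg <- function(m) {
      tryCatch(cost_and_gradients(m, X, R, event, mode, masks),
               error = function(e) blow_up(it))
    }
    if (control$optimizer == "nesterov") {
      # gradient at the lookahead point, update from the current point
      lookahead <- set_params(model, purrr::map2(
        model_params(model), velocity, function(p, v) p + mu * v
      ))
      cg <- eval_cg(lookahead)
      velocity <- purrr::map2(velocity, cg$grads[nm], function(v, g) mu * v - lr * g)
      model <- set_params(model, purrr::map2(model_params(model), velocity, `+`))
    } else if (control$optimizer == "momentum") {
      cg <- eval_cg(model)
      velocity <- purrr::map2(velocity, cg$grads[nm], function(v, g) mu * v - lr * g)
      model <- set_params(model, purrr::map2(model_params(model), velocity, `+`))
    } else {
      cg <- eval_cg(model)
      model <- set_params(model, purrr::map2(
        model_params(model), cg$grads[nm], function(p, g) p - lr * g
      ))
    }
    if (!is.finite(cg$cost)) blow_up(it)
    trace[it] <- cg$cost
    if (cg$cost < best) {
      best <- cg$cost
    } else {
      lr <- lr * control$lr_decay
    }
  }
  list(model = model, loss_trace = trace, final_learning_rate = lr)
}

#' @export
print.nncox_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf(
    "  trained %d iterations (%s); final partial log-likelihood %.4f on %d patients (%d events)\n",
    length(x$loss_trace), x$config$optimizer, x$final_pll, x$n_patients, x$n_events
  ))
  invisible(x)
}

#' Predict prognostic indices
#'
#' @param object An [nncox()] fit.
#' @param newdata A [survival_dataset()], data frame or matrix of features.
#'   Feature columns are aligned by name to those seen at fit time when
#'   names are available; unknown or missing features are an error.
#' @param ... Unused.
#' @return A tibble with columns `patient_id` and `pi` (the log hazard
#'   ratio; higher = higher predicted risk).
#' @export
predict.nncox_fit <- function(object, newdata, ...) {
  X <- align_features(object$model, newdata)
  theta <- forward_pass(object$model, X, "eval")$theta
  tibble(
    patient_id = rownames(X) %||% paste0("P", seq_len(nrow(X))),
    pi = unname(theta)
  )
}

align_features <- function(model, newdata) {
  X <- if (inherits(newdata, "survival_dataset")) {
    newdata$X
  } else if (is.data.frame(newdata)) {
    as.matrix(newdata)
  } else {
    newdata
  }
  want <- model$feature_names
  if (!is.null(want) && !is.null(colnames(X))) {
    missing_ft <- setdiff(want, colnames(X))
    if (length(missing_ft)) {
      abort(sprintf(
        "New data is missing %d model feature(s): %s%s",
        length(missing_ft), paste(head(missing_ft, 5L), collapse = ", "),
        if (length(missing_ft) > 5L) ", ..." else ""
      ))
    }
    X <- X[, want, drop = FALSE]
  }
  X
}

#' @describeIn nncox Tidy the fitted parameters. For a zero-hidden-layer
#'   model, one row per feature with its Cox coefficient; otherwise one row
#'   per hidden node with its output-layer coefficient `beta` and bias.
#' @param x An `nncox_fit`.
#' @param ... Unused.
#' @export
tidy.nncox_fit <- function(x, ...) {
  m <- x$model
  if (m$hidden_layers == 0L) {
    est <- if (is.null(m$scale)) m$beta else m$beta / m$scale
    tibble(
      term = m$feature_names %||% paste0("feature_", seq_along(m$beta)),
      estimate = unname(est)
    )
  } else {
    tibble(
      node = seq_len(m$hidden_size),
      beta = unname(m$beta),
      bias = unname(m$b)
    )
  }
}

#' @describeIn nncox One-row model summary: architecture, regularization,
#'   final cost and partial log-likelihood.
#' @export
glance.nncox_fit <- function(x, ...) {
  tibble(
    hidden_layers = x$model$hidden_layers,
    hidden_size = x$model$hidden_size,
    dropout_p = x$model$dropout_p,
    ridge_lambda = x$model$ridge_lambda,
    n_iterations = length(x$loss_trace),
    final_cost = x$loss_trace[length(x$loss_trace)],
    final_pll = x$final_pll,
    n_patients = x$n_patients,
    n_events = x$n_events
  )
}

#' Save / load a fitted model archive
#'
#' A single self-describing archive holding all weights, layer sizes,
#' activation tag, regularization settings and the training configuration.
#' `read_nncox(write_nncox(fit, path))` round-trips bit-exactly.
#'
#' @param fit An `nncox_fit` (or bare `nncox_model`).
#' @param path Archive path.
#' @return `write_nncox` returns `path` invisibly; `read_nncox` returns the
#'   stored object.
#' @export
write_nncox <- function(fit, path) {
  stopifnot(inherits(fit, "nncox_fit") || inherits(fit, "nncox_model"))
  saveRDS(fit, path, version = 3L)
  invisible(path)
}

#' @rdname write_nncox
#' @export
read_nncox <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model archive not found: %s", path))
  obj <- readRDS(path)
  if (!inherits(obj, c("nncox_fit", "nncox_model"))) {
    abort(sprintf("File %s does not contain a model archive.", path))
  }
  obj
}
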