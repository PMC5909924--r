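#' Default hidden layer width
#'
#' The "pyramid" rule of thumb: the hidden layer gets the square root of the
#' number of input features, rounded, with a minimum of 1. A 20449-gene
#' input therefore gets 143 hidden nodes; 1000 genes get 32.
#'
#' @param n_features Number of input features (J >= 1).
#' @return Integer hidden-layer size.
#' @export
default_hidden_size <- function(n_features) {
  stopifnot(n_features >= 1)
  max(1L, as.integer(round(sqrt(n_features))))
}

#' Create an untrained neural-network Cox model
#'
#' The model maps a feature vector x to a log hazard ratio (prognostic
#' index) theta through 0, 1 or 2 fully connected tanh hidden layers and a
#' linear Cox output layer: with one hidden layer,
#' `theta = tanh(W x + b)' beta`. With `hidden_layers = 0` the model
#' degenerates to the standard linear Cox-PH predictor `theta = x' beta`.
#'
#' Hidden weights are initialized uniformly on
#' `±sqrt(6 / (fan_in + fan_out))` (the standard tanh-appropriate scheme),
#' biases and output coefficients at zero, so the initial prognostic index
#' is identically zero.
#'
#' @param n_features Number of input features J.
#' @param hidden_layers 0, 1 or 2 hidden layers. A second layer reuses the
#'   first layer's width.
#' @param hidden_size Hidden-layer width; default [default_hidden_size()].
#' @param dropout Retention probability p in (0, 1]: each hidden node is
#'   kept with probability p during a training iteration and its activation
#'   is scaled by p at evaluation time (weight-scaling rule). `1` disables
#'   dropout.
#' @param ridge Non-negative ridge penalty lambda on the squared L2 norms of
#'   the weight matrices and output coefficients (biases unpenalized).
#' @param feature_names Optional feature names stored for alignment checks.
#' @param seed Seed for weight initialization.
#' @return An object of class `nncox_model`.
#' @export
nncox_model <- function(n_features, hidden_layers = 1L, hidden_size = NULL,
                        dropout = 1, ridge = 0, feature_names = NULL,
                        seed = NULL) {
  if (!hidden_layers %in% c(0L, 1L, 2L)) abort("`hidden_layers` must be 0, 1 or 2.")
  if (dropout <= 0 || dropout > 1) abort("`dropout` (retention probability) must be in (0, 1].")
  if (ridge < 0) abort("`ridge` must be non-negative.")
  J <- as.integer(n_features)
  H <- if (hidden_layers == 0L) 0L else as.integer(hidden_size %||% default_hidden_size(J))

  glorot <- function(n_out, n_in) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
  }
  params <- with_seed_maybe(seed, {
    if (hidden_layers == 0L) {
      list(beta = numeric(J))
    } else if (hidden_layers == 1L) {
      list(W = glorot(H, J), b = numeric(H), beta = numeric(H))
    } else {
      list(W = glorot(H, J), b = numeric(H),
           W2 = glorot(H, H), b2 = numeric(H), beta = numeric(H))
    }
  })

  structure(
    c(params, list(
      n_features = J,
      hidden_layers = as.integer(hidden_layers),
      hidden_size = H,
      activation = "tanh",
      dropout_p = dropout,
      ridge_lambda = ridge,
      feature_names = feature_names,
      center = NULL,
      scale = NULL
    )),
    class = "nncox_model"
  )
}

#' @export
print.nncox_model <- function(x, ...) {
  arch <- if (x$hidden_layers == 0L) {
    sprintf("%d -> 1 (linear Cox-PH)", x$n_features)
  } else {
    paste(c(x$n_features, rep(x$hidden_size, x$hidden_layers), 1), collapse = " -> ")
  }
  cat(sprintf(
    "<nncox_model> %s | tanh | dropout p = %g | ridge lambda = %g\n",
    arch, x$dropout_p, x$ridge_lambda
  ))
  invisible(x)
}

param_names <- function(model) {
  switch(as.character(model$hidden_layers),
    "0" = "beta",
    "1" = c("W", "b", "beta"),
    "2" = c("W", "b", "W2", "b2", "beta")
  )
}

#' Sample dropout retention masks for one training iteration
#'
#' One Bernoulli(p) 0/1 vector per hidden layer; node-level, so a dropped
#' node is silenced for every patient in the batch.
#'
#' @param model An [nncox_model()].
#' @return A list of 0/1 vectors, one per hidden layer (empty list if the
#'   model has none or `dropout_p == 1`).
#' @export
sample_dropout_masks <- function(model) {
  if (model$hidden_layers == 0L || model$dropout_p == 1) return(list())
  lapply(seq_len(model$hidden_layers), function(l) {
    rbinom(model$hidden_size, 1L, model$dropout_p)
  })
}

# Full forward pass with caches for backprop.
# mode "train": multiply activations by the supplied masks (no scaling);
# mode "eval": scale activations by p (deterministic weight-scaling rule).
forward_pass <- function(model, X, mode = c("eval", "train"), masks = NULL) {
  mode <- match.arg(mode)
  if (ncol(X) != model$n_features) {
    abort(sprintf(
      "Input has %d features but the model expects %d.", ncol(X), model$n_features
    ))
  }
  if (!is.null(model$center)) {
    X <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  }
  if (model$hidden_layers == 0L) {
    return(list(theta = drop(X %*% model$beta), activations = list(),
                raw_tanh = list(), masks = list()))
  }
  p <- model$dropout_p
  use_mask <- mode == "train" && p < 1
  if (use_mask && is.null(masks)) {
    abort("Training-mode forward pass with dropout needs retention masks.")
  }
  scale_layer <- function(A, l) {
    if (use_mask) {
      sweep(A, 2L, masks[[l]], "*")
    } else if (mode == "eval" && p < 1) {
      A * p
    } else {
      A
    }
  }
  raw <- vector("list", model$hidden_layers)
  act <- vector("list", model$hidden_layers)
  Z1 <- sweep(X %*% t(model$W), 2L, model$b, "+")
  raw[[1L]] <- tanh(Z1)
  act[[1L]] <- scale_layer(raw[[1L]], 1L)
  if (model$hidden_layers == 2L) {
    Z2 <- sweep(act[[1L]] %*% t(model$W2), 2L, model$b2, "+")
    raw[[2L]] <- tanh(Z2)
    act[[2L]] <- scale_layer(raw[[2L]], 2L)
  }
  list(
    theta = drop(act[[model$hidden_layers]] %*% model$beta),
    activations = act, raw_tanh = raw,
    masks = if (use_mask) masks else list()
  )
}

#' Forward pass: prognostic index and hidden activations
#'
#' @param model An [nncox_model()].
#' @param X Patient-by-feature matrix with `model$n_features` columns.
#' @param mode `"eval"` (deterministic; dropout handled by scaling
#'   activations by p) or `"train"` (applies the supplied Bernoulli masks).
#' @param masks Per-layer retention masks from [sample_dropout_masks()];
#'   required in train mode when `dropout_p < 1`.
#' @return List with `theta` (n-vector of log hazard ratios) and
#'   `activations` (list of hidden activation matrices, empty for the
#'   zero-hidden-layer model).
#' @export
nncox_forward <- function(model, X, mode = c("eval", "train"), masks = NULL) {
  fw <- forward_pass(model, X, mode, masks)
  list(theta = fw$theta, activations = fw$activations)
}

ridge_penalty <- function(model) {
  if (model$ridge_lambda == 0) return(0)
  sq <- sum(model$beta^2)
  if (model$hidden_layers >= 1L) sq <- sq + sum(model$W^2)
  if (model$hidden_layers == 2L) sq <- sq + sum(model$W2^2)
  model$ridge_lambda * sq
}

#' Regularized training cost
#'
#' The negative partial log-likelihood plus the ridge term
#' `lambda * (||beta||^2 + ||W||^2)` (squared L2 norms; biases excluded).
#' With `lambda = 0` this is exactly `-partial_log_likelihood(theta)`.
#'
#' @inheritParams nncox_forward
#' @param R Risk-set matrix for the batch.
#' @param event 0/1 status vector for the batch.
#' @return A single finite number.
#' @export
nncox_cost <- function(model, X, R, event, mode = "eval", masks = NULL) {
  fw <- forward_pass(model, X, mode, masks)
  -partial_log_likelihood(fw$theta, R, event) + ridge_penalty(model)
}

# Analytic gradient of the regularized cost w.r.t. every parameter, computed
# by backpropagation with the dropout masks held fixed. Returns list(cost,
# grads) so the training loop gets both from one forward pass.
cost_and_gradients <- function(model, X, R, event, mode = "eval", masks = NULL) {
  fw <- forward_pass(model, X, mode, masks)
  theta <- fw$theta
  cost <- -partial_log_likelihood(theta, R, event) + ridge_penalty(model)
  g_theta <- -pll_gradient(theta, R, event) # d(-pll)/d theta
  lam <- model$ridge_lambda

  if (model$hidden_layers == 0L) {
    grads <- list(beta = drop(crossprod(X, g_theta)) + 2 * lam * model$beta)
    return(list(cost = cost, grads = grads))
  }

  p <- model$dropout_p
  use_mask <- mode == "train" && p < 1
  # derivative of the (possibly masked/scaled) activation w.r.t. raw tanh
  layer_scale <- function(l) {
    if (use_mask) masks[[l]] else if (mode == "eval" && p < 1) rep(p, model$hidden_size) else rep(1, model$hidden_size)
  }

  L <- model$hidden_layers
  A_last <- fw$activations[[L]]
  grads <- list(beta = drop(crossprod(A_last, g_theta)) + 2 * lam * model$beta)

  dA <- tcrossprod(g_theta, model$beta) # n x H at the last hidden layer
  if (L == 2L) {
    dZ2 <- sweep(dA, 2L, layer_scale(2L), "*") * (1 - fw$raw_tanh[[2L]]^2)
    grads$W2 <- crossprod(dZ2, fw$activations[[1L]]) + 2 * lam * model$W2
    grads$b2 <- colSums(dZ2)
    dA <- dZ2 %*% model$W2
  }
  dZ1 <- sweep(dA, 2L, layer_scale(1L), "*") * (1 - fw$raw_tanh[[1L]]^2)
  grads$W <- crossprod(dZ1, X) + 2 * lam * model$W
  grads$b <- colSums(dZ1)
  list(cost = cost, grads = grads)
}
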