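#' Event-stratified k-fold assignment
#'
#' Partitions patients into k disjoint folds, assigning shuffled event
#' patients round-robin before shuffled censored patients so every fold
#' receives at least one event whenever there are at least k events.
#'
#' @param n Number of patients.
#' @param k Number of folds (>= 2, <= n).
#' @param event 0/1 status vector of length n.
#' @param seed Integer seed.
#' @return List of k disjoint integer index vectors covering `1:n`.
#' @export
kfold_indices <- function(n, k = 5L, event, seed = NULL) {
  if (k < 2L || n < k) abort("Need 2 <= k <= n for k-fold assignment.")
  event <- assert_event_vector(event)
  if (length(event) != n) abort("`event` must have length n.")
  with_seed_maybe(seed, {
    ev <- sample(which(event == 1))
    ce <- sample(which(event == 0))
    ordered <- c(ev, ce)
    fold_of <- rep_len(seq_len(k), n)
    lapply(seq_len(k), function(f) sort(ordered[fold_of == f]))
  })
}

#' Hyperparameter grid
#'
#' Cross of ridge penalties and dropout retention probabilities, one row
#' per setting. The defaults search dropout alone (the regularizer the
#' underlying study settled on); a ridge search would typically use
#' `hyperparameter_grid(ridge = 10^(-4:2), dropout = 1)`.
#'
#' @param ridge Ridge penalty values.
#' @param dropout Retention probability values in (0, 1].
#' @return A tibble with columns `ridge` and `dropout`.
#' @export
hyperparameter_grid <- function(ridge = 0, dropout = c(0.3, 0.5, 0.7, 0.9, 1)) {
  tidyr::crossing(ridge = ridge, dropout = dropout)
}

#' Cross-validated hyperparameter search
#'
#' For each grid setting, trains on k-1 folds and scores Harrell's
#' concordance of the predicted prognostic index on the held-out fold;
#' settings are ranked by the mean validation concordance. Ties are broken
#' toward stronger regularization (larger ridge, then smaller dropout
#' retention). A fold whose fit aborts is recorded as missing, excluded
#' from that setting's mean, and reported with a warning.
#'
#' @param data Training [survival_dataset()].
#' @param grid Settings tibble from [hyperparameter_grid()].
#' @param k Number of folds (default 5).
#' @param hidden_layers,hidden_size Architecture passed to [nncox()].
#' @param control [nncox_control()] used for every fold fit.
#' @param seed Seed for the fold assignment.
#' @return An object of class `nncox_cv`: list with `profile` (tibble:
#'   setting, mean score, per-fold scores nested), `fold_scores` matrix
#'   (settings x folds), and `best` (one-row tibble of the selected
#'   setting).
#' @export
cv_search <- function(data, grid = hyperparameter_grid(), k = 5L,
                      hidden_layers = 1L, hidden_size = NULL,
                      control = nncox_control(), seed = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (nrow(grid) == 0L) abort("`grid` must contain at least one setting.")
  folds <- kfold_indices(nrow(data$X), k, data$event, seed = seed)
  n_settings <- nrow(grid)
  fold_scores <- matrix(NA_real_, n_settings, k)

  for (s in seq_len(n_settings)) {
    for (f in seq_len(k)) {
      val_idx <- folds[[f]]
      train_ds <- subset_dataset(data, setdiff(seq_len(nrow(data$X)), val_idx))
      val_ds <- subset_dataset(data, val_idx)
      score <- tryCatch({
        fit <- nncox(
          train_ds, hidden_layers = hidden_layers, hidden_size = hidden_size,
          dropout = grid$dropout[s], ridge = grid$ridge[s], control = control
        )
        theta <- predict(fit, val_ds)$pi
        concordance_harrell(val_ds$time, val_ds$event, theta)
      }, error = function(e) {
        warn(sprintf(
          "CV cell (setting %d, fold %d) failed and was excluded: %s",
          s, f, conditionMessage(e)
        ))
        NA_real_
      })
      fold_scores[s, f] <- score
    }
  }

  mean_scores <- rowMeans(fold_scores, na.rm = TRUE)
  # ties toward stronger regularization: larger ridge, then smaller dropout
  ord <- order(-mean_scores, -grid$ridge, grid$dropout)
  best_idx <- ord[1L]
  profile <- dplyr::mutate(
    grid,
    mean_score = mean_scores,
    n_folds_used = rowSums(!is.na(fold_scores)),
    selected = dplyr::row_number() == best_idx
  )
  structure(
    list(
      profile = profile,
      fold_scores = fold_scores,
      best = profile[best_idx, , drop = FALSE],
      k = k,
      hidden_layers = hidden_layers
    ),
    class = "nncox_cv"
  )
}

#' @export
print.nncox_cv <- function(x, ...) {
  cat(sprintf(
    "<nncox_cv> %d settings x %d folds; best: ridge = %g, dropout = %g (mean C = %.3f)\n",
    nrow(x$profile), x$k, x$best$ridge, x$best$dropout, x$best$mean_score
  ))
  invisible(x)
}

#' @describeIn cv_search Tidy the cross-validation profile: one row per
#'   (setting, fold) with the validation concordance.
#' @param x An `nncox_cv` object.
#' @param ... Unused.
#' @export
tidy.nncox_cv <- function(x, ...) {
  k <- ncol(x$fold_scores)
  dplyr::bind_cols(
    x$profile[rep(seq_len(nrow(x$profile)), each = k), c("ridge", "dropout")],
    tibble(
      fold = rep(seq_len(k), nrow(x$profile)),
      score = as.vector(t(x$fold_scores))
    )
  )
}

#' @describeIn cv_search One row per setting with its mean validation score.
#' @export
glance.nncox_cv <- function(x, ...) x$profile

#' Cross-validate, then refit the selected model
#'
#' Runs [cv_search()] and refits on the full training data at the selected
#' setting, which is how a final model is normally obtained.
#'
#' @inheritParams cv_search
#' @return List with `fit` (an `nncox_fit`) and `cv` (the `nncox_cv`
#'   profile).
#' @export
nncox_tune <- function(data, grid = hyperparameter_grid(), k = 5L,
                       hidden_layers = 1L, hidden_size = NULL,
                       control = nncox_control(), seed = NULL) {
  cv <- cv_search(data, grid, k, hidden_layers, hidden_size, control, seed)
  fit <- nncox(
    data, hidden_layers = hidden_layers, hidden_size = hidden_size,
    dropout = cv$best$dropout, ridge = cv$best$ridge, control = control
  )
  list(fit = fit, cv = cv)
}
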