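#' Configuration of the synthetic RNA-seq survival simulator
#'
#' Defaults reproduce the study design the package is tested against: four
#' patient sub-groups of 200 patients each (800 patients total), 1000
#' genes with 20% differentially expressed per group, a prognostic index
#' built from 100 randomly selected signal genes, Weibull event times
#' under proportional hazards, and exponential censoring at rate 0.05.
#'
#' The count model is negative binomial with log-normally distributed gene
#' base means and a common dispersion; group fold changes are uniform on
#' `±[de_log2fc_range]` on the log2 scale. The Weibull shape, baseline
#' scale (median event time 10 at zero prognostic index) and the true
#' coefficient law (uniform `±[0.1, 0.5]`, rescaled so the prognostic index
#' has standard deviation `pi_sd`) are package defaults; see the methods
#' vignette. The default `pi_sd = 2` makes the population concordance of
#' the true index about 0.83 (for proportional-hazards Weibull times the
#' uncensored concordance is `E[plogis(|theta_i - theta_j|)]`, independent
#' of the shape), i.e. a strong but not degenerate signal.
#'
#' @param n_groups Number of patient sub-groups.
#' @param patients_per_group Patients per sub-group.
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes differentially expressed per group.
#' @param n_signal_genes Number of genes carrying survival signal.
#' @param censoring_rate Rate of the exponential censoring distribution
#'   (events per time unit); must be > 0.
#' @param weibull_shape Shape of the Weibull event-time distribution.
#' @param baseline_scale Weibull baseline rate parameter.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion);
#'   0 gives Poisson counts.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal law of gene base
#'   means.
#' @param de_log2fc_range Two-sided range of absolute log2 fold changes.
#' @param pi_sd Target standard deviation of the true prognostic index.
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_groups = 4L, patients_per_group = 200L,
                              n_genes = 1000L, de_fraction = 0.20,
                              n_signal_genes = 100L, censoring_rate = 0.05,
                              weibull_shape = 1.5,
                              baseline_scale = log(2) / 10^1.5,
                              nb_dispersion = 0.2,
                              base_mean_meanlog = log(100), base_mean_sdlog = 1,
                              de_log2fc_range = c(0.5, 2),
                              pi_sd = 2, seed = NULL) {
  if (de_fraction <= 0 || de_fraction >= 1) abort("`de_fraction` must be in (0, 1).")
  if (n_signal_genes > n_genes) abort("`n_signal_genes` cannot exceed `n_genes`.")
  if (censoring_rate <= 0) abort("`censoring_rate` must be > 0.")
  if (nb_dispersion < 0) abort("`nb_dispersion` must be >= 0.")
  structure(
    list(
      n_groups = as.integer(n_groups),
      patients_per_group = as.integer(patients_per_group),
      n_genes = as.integer(n_genes), de_fraction = de_fraction,
      n_signal_genes = as.integer(n_signal_genes),
      censoring_rate = censoring_rate, weibull_shape = weibull_shape,
      baseline_scale = baseline_scale, nb_dispersion = nb_dispersion,
      base_mean_meanlog = base_mean_meanlog, base_mean_sdlog = base_mean_sdlog,
      de_log2fc_range = de_log2fc_range, pi_sd = pi_sd, seed = seed
    ),
    class = "simulation_config"
  )
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate grouped negative-binomial expression counts
#'
#' Draws a patient-by-gene count matrix: every gene gets a log-normal base
#' mean; within each patient group, that group's differentially expressed
#' genes have their mean multiplied by `2^lfc` with `lfc` uniform on
#' `±[de_log2fc_range]`. Counts are negative binomial at the given
#' dispersion. The model input matrix is `log2(count + 1)`.
#'
#' @param cfg A [simulation_config()].
#' @return List with `counts` (integer matrix), `log_expression`
#'   (`log2(count+1)`), `group_labels` (factor of length n) and
#'   `de_gene_sets` (per-group integer index sets, each of size
#'   `round(de_fraction * n_genes)`).
#' @export
simulate_expression <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed_maybe(cfg$seed, simulate_expression_impl(cfg))
}

simulate_expression_impl <- function(cfg) {
  n <- cfg$n_groups * cfg$patients_per_group
  J <- cfg$n_genes
  n_de <- round(cfg$de_fraction * J)
  base_mean <- stats::rlnorm(J, cfg$base_mean_meanlog, cfg$base_mean_sdlog)
  group_labels <- factor(rep(seq_len(cfg$n_groups), each = cfg$patients_per_group))

  de_gene_sets <- lapply(seq_len(cfg$n_groups), function(g) sort(sample.int(J, n_de)))
  lfc <- lapply(seq_len(cfg$n_groups), function(g) {
    sign <- sample(c(-1, 1), n_de, replace = TRUE)
    sign * runif(n_de, cfg$de_log2fc_range[1L], cfg$de_log2fc_range[2L])
  })

  counts <- matrix(0L, n, J)
  for (g in seq_len(cfg$n_groups)) {
    mu_g <- base_mean
    mu_g[de_gene_sets[[g]]] <- mu_g[de_gene_sets[[g]]] * 2^lfc[[g]]
    rows <- which(group_labels == g)
    draws <- nb_draw(length(rows) * J, rep(mu_g, each = length(rows)), cfg$nb_dispersion)
    counts[rows, ] <- matrix(draws, length(rows), J)
  }
  dimnames(counts) <- list(
    paste0("P", seq_len(n)),
    paste0("gene_", seq_len(J))
  )
  list(
    counts = counts,
    log_expression = log2(counts + 1),
    group_labels = group_labels,
    de_gene_sets = de_gene_sets
  )
}

#' Simulate survival outcomes from expression
#'
#' Picks `n_signal_genes` genes at random, draws their coefficients uniform
#' on `±[0.1, 0.5]`, and rescales so the centered linear prognostic index
#' `pi = (X_signal - colMeans) %*% beta` has standard deviation `pi_sd`.
#' Event times follow a proportional-hazards Weibull:
#' `T = (-log(U) / (scale * exp(pi)))^(1/shape)`; censoring times are
#' exponential at `censoring_rate`; the observed time is the minimum and
#' `event = (T <= C)`.
#'
#' @param log_expression Patient-by-gene matrix of log expression.
#' @param cfg A [simulation_config()].
#' @return List with `time`, `event`, `true_pi`, `signal_genes` (indices)
#'   and `true_beta` (length `n_genes`, nonzero only on the signal genes).
#' @export
simulate_survival_times <- function(log_expression, cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed_maybe(cfg$seed, simulate_survival_impl(log_expression, cfg))
}

simulate_survival_impl <- function(log_expression, cfg) {
  n <- nrow(log_expression)
  J <- ncol(log_expression)
  signal_genes <- sort(sample.int(J, cfg$n_signal_genes))
  beta_raw <- if (cfg$n_signal_genes > 0) {
    sample(c(-1, 1), cfg$n_signal_genes, replace = TRUE) *
      runif(cfg$n_signal_genes, 0.1, 0.5)
  } else {
    numeric(0)
  }
  Xs <- log_expression[, signal_genes, drop = FALSE]
  Xs <- sweep(Xs, 2L, colMeans(Xs), "-")
  pi_raw <- drop(Xs %*% beta_raw)
  s <- sd(pi_raw)
  scale_factor <- if (cfg$n_signal_genes > 0 && s > 0) cfg$pi_sd / s else 0
  true_pi <- pi_raw * scale_factor
  true_beta <- numeric(J)
  true_beta[signal_genes] <- beta_raw * scale_factor

  event_time <- (-log(runif(n)) / (cfg$baseline_scale * exp(true_pi)))^(1 / cfg$weibull_shape)
  cens_time <- rexp(n, cfg$censoring_rate)
  list(
    time = pmin(event_time, cens_time),
    event = as.numeric(event_time <= cens_time),
    true_pi = true_pi,
    signal_genes = signal_genes,
    true_beta = true_beta
  )
}

#' Draw censoring times from the simulator's censoring model
#'
#' Exposed separately so the censoring distribution can be checked by
#' estimation (the exponential-rate MLE is `1 / mean`).
#'
#' @param n Number of draws.
#' @param cfg A [simulation_config()].
#' @return Numeric vector of censoring times.
#' @export
simulate_censoring_times <- function(n, cfg = simulation_config()) {
  with_seed_maybe(cfg$seed, rexp(n, cfg$censoring_rate))
}

#' Simulate a complete expression + survival dataset
#'
#' Runs [simulate_expression()] then [simulate_survival_times()] and bundles
#' the result as a [survival_dataset()] ready for fitting, together with the
#' generating truth.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `nncox_simulation` with elements `data` (a
#'   [survival_dataset()] whose `X` is `log2(count+1)`) and `truth` (a list:
#'   `true_beta`, `true_pi`, `signal_genes`, `de_gene_sets`, `group_labels`,
#'   `counts`).
#' @export
#' @examples
#' sim <- simulate_survival_data(simulation_config(
#'   n_groups = 2, patients_per_group = 30, n_genes = 40,
#'   n_signal_genes = 8, seed = 7))
#' sim$data
simulate_survival_data <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed_maybe(cfg$seed, {
    expr <- simulate_expression_impl(cfg)
    surv <- simulate_survival_impl(expr$log_expression, cfg)
  })
  ds <- survival_dataset(
    expr$log_expression,
    time = surv$time, event = surv$event,
    patient_ids = rownames(expr$log_expression)
  )
  structure(
    list(
      data = ds,
      truth = list(
        true_beta = surv$true_beta,
        true_pi = surv$true_pi,
        signal_genes = surv$signal_genes,
        de_gene_sets = expr$de_gene_sets,
        group_labels = expr$group_labels,
        counts = expr$counts
      ),
      config = cfg
    ),
    class = "nncox_simulation"
  )
}

#' @export
print.nncox_simulation <- function(x, ...) {
  cat(sprintf(
    "<nncox_simulation> %d groups x %d patients, %d genes (%d signal); event rate %.2f\n",
    x$config$n_groups, x$config$patients_per_group, x$config$n_genes,
    x$config$n_signal_genes, mean(x$data$event)
  ))
  invisible(x)
}

#' Write a simulated dataset to files
#'
#' Writes the expression/survival pair in the format of
#' [write_survival_dataset()], plus a truth table (`gene`, `true_beta`) and
#' a JSON echo of the generating configuration.
#'
#' @param sim Result of [simulate_survival_data()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "nncox_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json")
  )
  write_survival_dataset(sim$data, paths[["expression"]], paths[["survival"]])
  readr::write_delim(
    tibble(gene = sim$data$feature_names, true_beta = sim$truth$true_beta),
    paths[["truth"]], delim = "\t"
  )
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
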