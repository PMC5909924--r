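# nncox

Neural-network Cox proportional-hazards regression for survival
prediction from high-dimensional expression data.

## What it is for

Given a patient × gene matrix of (normalized, log-transformed) expression
values and right-censored survival outcomes, `nncox` fits a feed-forward
network whose output layer is a Cox regression: the log hazard ratio
(prognostic index) of patient *i* is

    theta_i = tanh(W x_i + b)' beta        (one hidden layer; theta_i = x_i' beta with none)

trained by maximizing the ridge- and/or dropout-regularized Breslow
partial log-likelihood

    Cost = - sum_{i: e_i = 1} [ theta_i - log sum_{t_j >= t_i} exp(theta_j) ]
           + lambda (||beta||^2 + ||W||^2)

with the risk-set sums evaluated in matrix form against the indicator
matrix `R[i, j] = 1(t_j >= t_i)`. The package targets analysts building
prognostic models from RNA-seq cohorts who want a nonlinear alternative
to penalized Cox-PH with the same interface conventions: data frames and
tibbles in and out, `tidy()`/`glance()` methods, `autoplot()` figures.

It provides, as tested modules:

- the survival data model, risk-set matrix, and delimited-file I/O;
- the Cox core: matrix-form partial log-likelihood, exact analytic
  gradients, Breslow baseline hazard;
- the network with 0/1/2 tanh hidden layers, node-level dropout,
  ridge, and three full-batch optimizers (Nesterov default) with a
  decaying learning-rate schedule;
- 5-fold cross-validated grid search over ridge/dropout settings;
- four accuracy metrics: Harrell's C, IPCW C, median-dichotomized
  log-rank p, integrated Brier score, plus a repeated 80/20 holdout
  harness;
- interpretation: partial-derivative feature importance, hidden-node
  contributions (an exact additive decomposition of the prognostic
  index), top-variance node selection, node–gene correlation exports for
  preranked enrichment tools;
- a synthetic RNA-seq survival simulator (grouped negative-binomial
  counts, Weibull event times, exponential censoring) with known ground
  truth;
- a command-line interface (`inst/cli/nncox`) with `simulate`, `train`,
  `evaluate`, `importance` and `benchmark` subcommands.

See `vignettes/neural-cox-models.Rmd` for the methods and every numerical
convention.

## Worked example

```r
library(nncox)

# a full-size synthetic cohort: 4 groups x 200 patients, 1000 genes,
# 100 signal genes, exponential censoring at rate 0.05
sim <- simulate_survival_data(simulation_config(seed = 1))
sim$data
#> <survival_dataset> 800 patients x 1000 features; 457 events (57.1%), 343 censored

parts <- train_test_split(sim$data, test_fraction = 0.2, seed = 1)
fit <- nncox(parts$train, hidden_layers = 1, dropout = 0.7,
             control = nncox_control(n_iterations = 300, seed = 1))
fit
#> <nncox_model> 1000 -> 32 -> 1 | tanh | dropout p = 0.7 | ridge lambda = 0
#>   trained 300 iterations (nesterov); final partial log-likelihood -1219.8297 on 640 patients (370 events)

evaluate_model(fit, parts$test, train = parts$train)
#>   c_harrell    c_ipcw    logrank_p integrated_brier n_test n_events_test
#> 1 0.7034301 0.6820849 1.878751e-08        0.1292922    160            87
```

The holdout concordance (0.70 by both the unweighted and the
censoring-weighted index) says the fitted index orders 70% of comparable
patient pairs correctly; the log-rank p-value shows the median split into
high/low-risk groups separates the survival curves decisively; the
integrated Brier score (0.13, against 0.25 for an uninformative constant
predictor) measures calibrated probabilistic accuracy. For context, the
generating true index itself scores C ≈ 0.84 on this cohort and an
exactly-optimized ridge Cox reference lands within ~0.01 of the network
on the same splits — at these dimensions estimation noise, not the
optimizer, is the binding constraint.

Interpretation works on the fitted object:

```r
feature_importance(fit, parts$train) |> dplyr::arrange(dplyr::desc(abs(importance)))
#> # A tibble: 1,000 x 2   (top rows)
#>   feature  importance
#> 1 gene_35      -0.314
#> 2 gene_714      0.312
#> 3 gene_386      0.311

contrib <- node_contributions(fit, parts$train)  # 32 x 640, columns sum to theta
top_variance_nodes(contrib, 5)
#> [1] 11 24  7 31  4
rank_node_genes(node_gene_correlation(fit, parts$train))  # preranked enrichment input
```

Hyperparameter selection and the benchmarking protocol:

```r
cv <- cv_search(parts$train, hyperparameter_grid(dropout = c(0.5, 0.7, 1)),
                k = 5, control = nncox_control(n_iterations = 300, seed = 1))
reports <- repeated_holdout(sim$data, n_repeats = 10, seed = 1)  # one tibble row per repeat
```

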