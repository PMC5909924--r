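#' Feature importance by average partial derivatives
#'
#' For every patient, the partial derivative of the log hazard ratio with
#' respect to each input feature is computed analytically (for a single
#' tanh hidden layer, `d theta / d x_j = sum_h beta_h p (1 - tanh^2(z_h))
#' W_hj`, with the evaluation-time dropout scaling `p` applied); the
#' importance of a feature is the average derivative across patients. For
#' the zero-hidden-layer model this is exactly the Cox coefficient vector,
#' tying the score to the classical interpretation.
#'
#' @param fit An [nncox()] fit with 0 or 1 hidden layers.
#' @param data A [survival_dataset()] (or feature matrix) to average over.
#' @param node_level If `TRUE`, also return the per-node derivative matrix:
#'   average of `d a_h / d x_j` over patients.
#' @return A tibble with columns `feature` and `importance`; with
#'   `node_level = TRUE`, a list with `output` (that tibble) and
#'   `per_node` (H x J matrix).
#' @export
feature_importance <- function(fit, data, node_level = FALSE) {
  stopifnot(inherits(fit, "nncox_fit"))
  m <- fit$model
  if (m$hidden_layers > 1L) {
    abort("Partial-derivative importance is implemented for 0 or 1 hidden layers.")
  }
  X <- align_features(m, data)
  feat <- m$feature_names %||% paste0("feature_", seq_len(ncol(X)))
  inv_scale <- if (is.null(m$scale)) rep(1, ncol(X)) else 1 / m$scale
  if (m$hidden_layers == 0L) {
    out <- tibble(feature = feat, importance = unname(m$beta * inv_scale))
    if (!node_level) return(out)
    return(list(output = out, per_node = matrix(m$beta * inv_scale, 1L, ncol(X),
                                                dimnames = list("node_1", feat))))
  }
  p <- m$dropout_p
  fw <- forward_pass(m, X, "eval")
  dtanh <- 1 - fw$raw_tanh[[1L]]^2 # n x H
  # per-patient d theta / d x = (dtanh * beta') %*% W, scaled by p and by the
  # chain rule of any stored feature standardization; average over patients
  mean_dtanh_beta <- colMeans(dtanh) * m$beta * p # H
  importance <- drop(mean_dtanh_beta %*% m$W) * inv_scale # J
  out <- tibble(feature = feat, importance = unname(importance))
  if (!node_level) return(out)
  per_node <- (colMeans(dtanh) * p) * m$W # H x J, row-scaled
  per_node <- sweep(per_node, 2L, inv_scale, "*")
  dimnames(per_node) <- list(paste0("node_", seq_len(m$hidden_size)), feat)
  list(output = out, per_node = per_node)
}

#' Hidden-node contributions to the prognostic index
#'
#' Node h's contribution for patient i is its evaluation-mode activation
#' times its output-layer coefficient, `a_h(i) * beta_h`. For a single
#' hidden layer these contributions decompose the prognostic index
#' exactly: the columns sum to theta at machine precision, so each node
#' can be read as a survival-sensitive meta-feature.
#'
#' @param fit An [nncox()] fit with exactly one hidden layer.
#' @param data A [survival_dataset()] or feature matrix.
#' @return An H x n matrix of class `nncox_contributions` (nodes in rows,
#'   patients in columns).
#' @export
node_contributions <- function(fit, data) {
  stopifnot(inherits(fit, "nncox_fit"))
  m <- fit$model
  if (m$hidden_layers != 1L) {
    abort("Node contributions require exactly one hidden layer.")
  }
  X <- align_features(m, data)
  A <- forward_pass(m, X, "eval")$activations[[1L]] # n x H
  contrib <- t(A * rep(m$beta, each = nrow(A))) # H x n
  dimnames(contrib) <- list(
    paste0("node_", seq_len(m$hidden_size)),
    rownames(X) %||% paste0("P", seq_len(nrow(X)))
  )
  class(contrib) <- c("nncox_contributions", class(contrib))
  contrib
}

#' @describeIn node_contributions Long tibble: `node`, `patient_id`,
#'   `contribution`.
#' @param x An `nncox_contributions` matrix.
#' @param ... Unused.
#' @export
tidy.nncox_contributions <- function(x, ...) {
  m <- unclass(x)
  tibble(
    node = rep(seq_len(nrow(m)), times = ncol(m)),
    patient_id = rep(colnames(m), each = nrow(m)),
    contribution = as.vector(m)
  )
}

#' Select the highest-variance hidden nodes
#'
#' Ranks node-contribution rows by their across-patient variance and
#' returns the indices of the top k, descending; ties go to the lower
#' index. These are the nodes typically carried forward for clustering and
#' enrichment.
#'
#' @param contributions An H x n matrix from [node_contributions()] (any
#'   numeric matrix with nodes in rows works).
#' @param k Number of nodes to keep (default 20, capped at H).
#' @return Integer vector of row indices, length `min(k, H)`.
#' @export
top_variance_nodes <- function(contributions, k = 20L) {
  if (k > nrow(contributions)) abort("`k` cannot exceed the number of nodes.")
  vars <- apply(contributions, 1L, var)
  order(-vars, seq_along(vars))[seq_len(k)]
}

#' Node-gene Pearson correlations
#'
#' Pearson correlation between each gene's (log-transformed) expression
#' and each hidden node's evaluation-mode activation across patients. The
#' resulting ranked gene lists per node are the standard input to
#' preranked enrichment tools. Zero-variance genes have undefined
#' correlation and are returned as `NA` with a warning.
#'
#' @param fit An [nncox()] fit with exactly one hidden layer.
#' @param data A [survival_dataset()] with at least 3 patients.
#' @return An H x J matrix of correlations (nodes in rows).
#' @export
node_gene_correlation <- function(fit, data) {
  stopifnot(inherits(fit, "nncox_fit"))
  m <- fit$model
  if (m$hidden_layers != 1L) abort("Node-gene correlation requires one hidden layer.")
  X <- align_features(m, data)
  if (nrow(X) < 3L) abort("Need at least 3 patients to estimate correlations.")
  A <- forward_pass(m, X, "eval")$activations[[1L]]
  zero_var_gene <- apply(X, 2L, function(v) var(v) == 0)
  zero_var_node <- apply(A, 2L, function(v) var(v) == 0)
  r <- suppressWarnings(cor(A, X)) # H x J
  r[zero_var_node, ] <- NA_real_
  r[, zero_var_gene] <- NA_real_
  if (any(zero_var_gene)) {
    warn(sprintf("%d zero-variance gene(s) have undefined correlation (NA).",
                 sum(zero_var_gene)))
  }
  dimnames(r) <- list(
    paste0("node_", seq_len(m$hidden_size)),
    colnames(X) %||% paste0("feature_", seq_len(ncol(X)))
  )
  r
}

#' Export ranked gene lists per node
#'
#' Flattens a node-gene correlation matrix into a long tibble with genes
#' sorted by correlation, descending, within each node — the layout
#' expected by preranked enrichment tools. `NA` correlations are dropped.
#'
#' @param cor_matrix H x J matrix from [node_gene_correlation()].
#' @return Tibble with columns `node`, `gene`, `r`, sorted by `node` then
#'   `r` descending.
#' @export
rank_node_genes <- function(cor_matrix) {
  tibble(
    node = rep(rownames(cor_matrix), times = ncol(cor_matrix)),
    gene = rep(colnames(cor_matrix), each = nrow(cor_matrix)),
    r = as.vector(cor_matrix)
  ) |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::arrange(.data$node, dplyr::desc(.data$r))
}
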