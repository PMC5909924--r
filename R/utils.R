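# Internal helpers shared across modules.

# Run `expr` under a deterministic RNG stream when `seed` is supplied,
# restoring the caller's RNG state afterwards; otherwise use the ambient RNG.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a child seed from a master seed and a stream index, staying inside
# the 32-bit signed integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

assert_numeric_vector <- function(x, name, non_negative = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector with no missing values.", name))
  }
  if (non_negative && any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

assert_event_vector <- function(event, name = "event") {
  if (anyNA(event) || !all(event %in% c(0, 1))) {
    bad <- which(anyNA(event) | !(event %in% c(0, 1)))
    abort(sprintf(
      "`%s` must contain only 0 (censored) or 1 (event); offending row(s): %s.",
      name, paste(head(bad, 5L), collapse = ", ")
    ))
  }
  invisible(as.numeric(event))
}

# log(sum(exp(x))) over risk sets via one matrix product, stabilized by the
# global maximum. Rows whose shifted sum underflows to 0 (possible when the
# spread of theta exceeds ~745) are recomputed exactly with their own
# row-wise maximum; this keeps the one-product fast path while staying
# finite for any finite theta.
risk_logsumexp <- function(R, theta) {
  m <- max(theta)
  S <- drop(R %*% exp(theta - m))
  lse <- log(S) + m
  bad <- which(S == 0)
  for (i in bad) {
    in_risk <- R[i, ] == 1
    mi <- max(theta[in_risk])
    lse[i] <- log(sum(exp(theta[in_risk] - mi))) + mi
  }
  lse
}
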