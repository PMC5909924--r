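#' Construct a survival dataset
#'
#' Bundles a patient-by-feature matrix of (already normalized,
#' log-transformed) expression values with right-censored survival outcomes.
#' This is the universal input to model fitting, evaluation and
#' interpretation.
#'
#' @param x Numeric matrix or data frame, patients in rows and features in
#'   columns. Column names are used as feature names.
#' @param time Non-negative event or censoring time per patient.
#' @param event Status indicator per patient: 1 = death observed, 0 =
#'   censored.
#' @param patient_ids Optional character vector of patient identifiers;
#'   defaults to the row names of `x` or `"P1"..."Pn"`.
#'
#' @details Patients with `time == 0` are allowed only when censored: an
#'   event at time zero would put every patient in its risk set while
#'   contributing no usable ordering information, so it is rejected.
#'
#' @return An object of class `survival_dataset`: a list with elements `X`
#'   (numeric matrix), `time`, `event`, `feature_names`, `patient_ids`.
#' @export
#' @examples
#' ds <- survival_dataset(matrix(rnorm(20), 5, 4), time = 1:5,
#'                        event = c(1, 0, 1, 1, 0))
#' ds
survival_dataset <- function(x, time, event, patient_ids = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or data frame of expression values.")
  }
  n <- nrow(x)
  if (n < 2L) abort("A survival dataset needs at least 2 patients.")
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    abort(sprintf("Non-finite expression value at row %d, column %d.", bad[1L], bad[2L]))
  }
  if (length(time) != n || length(event) != n) {
    abort("`time` and `event` must have one entry per patient row of `x`.")
  }
  assert_numeric_vector(time, "time", non_negative = TRUE)
  event <- assert_event_vector(event)
  if (any(time == 0 & event == 1)) {
    abort(sprintf(
      "Event at time 0 is not allowed (row %s); zero times must be censored.",
      which(time == 0 & event == 1)[1L]
    ))
  }
  feature_names <- colnames(x) %||% paste0("feature_", seq_len(ncol(x)))
  if (anyDuplicated(feature_names)) {
    abort("Feature names must be unique.")
  }
  patient_ids <- patient_ids %||% rownames(x) %||% paste0("P", seq_len(n))
  patient_ids <- as.character(patient_ids)
  dimnames(x) <- list(patient_ids, feature_names)
  structure(
    list(
      X = x,
      time = as.numeric(time),
      event = event,
      feature_names = feature_names,
      patient_ids = patient_ids
    ),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "<survival_dataset> %d patients x %d features; %d events (%.1f%%), %d censored\n",
    nrow(x$X), ncol(x$X), sum(x$event), 100 * mean(x$event), sum(1 - x$event)
  ))
  invisible(x)
}

#' @export
dim.survival_dataset <- function(x) dim(x$X)

#' Coerce a survival dataset to a tibble
#'
#' One row per patient: `patient_id`, `time`, `event`, then one column per
#' feature.
#'
#' @param x A [survival_dataset()].
#' @param ... Unused.
#' @return A tibble with `n` rows.
#' @export
as_tibble.survival_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble(patient_id = x$patient_ids, time = x$time, event = x$event),
    as_tibble(x$X, .name_repair = "minimal")
  )
}

#' Number of observed events in a dataset
#' @param ds A [survival_dataset()].
#' @return Integer count of `event == 1` patients.
#' @export
n_events <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  as.integer(sum(ds$event))
}

subset_dataset <- function(ds, idx) {
  survival_dataset(
    ds$X[idx, , drop = FALSE],
    time = ds$time[idx],
    event = ds$event[idx],
    patient_ids = ds$patient_ids[idx]
  )
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a survival dataset from delimited files
#'
#' The expression file is a delimited matrix (tab or comma, auto-detected
#' from the header line) with a header row of feature names and patient ids
#' in the first column. The survival file has columns `patient_id`, `time`
#' and `event`. The returned dataset is restricted to the intersection of
#' patient ids, aligned in the expression file's order; patients present in
#' only one file are dropped with a warning.
#'
#' @param expression_path Path to the expression matrix file.
#' @param survival_path Path to the survival table file.
#' @return A [survival_dataset()].
#' @export
read_survival_dataset <- function(expression_path, survival_path) {
  if (!file.exists(expression_path)) {
    abort(sprintf("Expression file not found: %s", expression_path))
  }
  if (!file.exists(survival_path)) {
    abort(sprintf("Survival file not found: %s", survival_path))
  }
  # columns are parsed as text and converted with strtod (base as.numeric)
  # so that full-precision files round-trip bit-identically
  expr <- readr::read_delim(
    expression_path,
    delim = detect_delim(expression_path),
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  if (ncol(expr) < 2L) abort("Expression file must have an id column plus at least one feature.")
  ids <- as.character(expr[[1L]])
  xmat <- suppressWarnings(
    vapply(expr[-1L], as.numeric, numeric(nrow(expr)), USE.NAMES = TRUE)
  )
  if (!is.matrix(xmat)) xmat <- matrix(xmat, nrow = nrow(expr), dimnames = list(NULL, names(expr)[-1L]))
  if (anyNA(xmat)) {
    bad <- which(is.na(xmat), arr.ind = TRUE)
    abort(sprintf(
      "Non-numeric expression value (row %d, column %s) in %s.",
      bad[1L, 1L], colnames(xmat)[bad[1L, 2L]], expression_path
    ))
  }
  rownames(xmat) <- ids

  surv_raw <- readr::read_delim(
    survival_path,
    delim = detect_delim(survival_path),
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  surv <- surv_raw
  for (col in intersect(c("time", "event"), names(surv))) {
    surv[[col]] <- suppressWarnings(as.numeric(surv_raw[[col]]))
    if (anyNA(surv[[col]])) {
      abort(sprintf("Non-numeric value in survival column `%s` (row %d).",
                    col, which(is.na(surv[[col]]))[1L]))
    }
  }
  required <- c("patient_id", "time", "event")
  missing_cols <- setdiff(required, names(surv))
  if (length(missing_cols)) {
    abort(sprintf(
      "Survival file is missing required column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!is.numeric(surv$time)) abort("Survival column `time` must be numeric.")
  assert_event_vector(surv$event)

  surv_ids <- as.character(surv$patient_id)
  keep <- intersect(ids, surv_ids)
  if (length(keep) == 0L) abort("No patient ids are shared between the two files.")
  dropped <- setdiff(union(ids, surv_ids), keep)
  if (length(dropped)) {
    warn(sprintf(
      "%d patient id(s) present in only one file were dropped: %s%s",
      length(dropped), paste(head(dropped, 5L), collapse = ", "),
      if (length(dropped) > 5L) ", ..." else ""
    ))
  }
  ord <- ids[ids %in% keep]
  srow <- match(ord, surv_ids)
  survival_dataset(
    xmat[ord, , drop = FALSE],
    time = surv$time[srow],
    event = surv$event[srow],
    patient_ids = ord
  )
}

#' Write a survival dataset to delimited files
#'
#' Writes the same two-file format read by [read_survival_dataset()]:
#' round-tripping preserves values bit-identically (full precision output).
#'
#' @param ds A [survival_dataset()].
#' @param expression_path,survival_path Output paths.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @return `ds`, invisibly.
#' @export
write_survival_dataset <- function(ds, expression_path, survival_path, delim = "\t") {
  stopifnot(inherits(ds, "survival_dataset"))
  # %.17g guarantees binary64 round-trip through text
  full <- function(x) formatC(x, format = "g", digits = 17)
  expr <- dplyr::bind_cols(
    tibble(patient_id = ds$patient_ids),
    as_tibble(apply(ds$X, 2L, full), .name_repair = "minimal")
  )
  readr::write_delim(expr, expression_path, delim = delim, quote = "none")
  readr::write_delim(
    tibble(patient_id = ds$patient_ids, time = full(ds$time), event = ds$event),
    survival_path,
    delim = delim, quote = "none"
  )
  invisible(ds)
}

#' Risk-set indicator matrix
#'
#' Builds the n-by-n binary matrix `R` with `R[i, j] = 1` exactly when
#' `time[j] >= time[i]`: row i flags the patients still at risk at patient
#' i's observed time, with tied times mutually at risk. One matrix product
#' `R %*% exp(theta)` then evaluates every risk-set denominator of the Cox
#' partial likelihood at once, which is what makes full-batch network
#' training cheap.
#'
#' @param time Vector of non-negative, finite observation times.
#' @return An n-by-n numeric 0/1 matrix.
#' @export
#' @examples
#' build_risk_matrix(c(1, 2, 3))
build_risk_matrix <- function(time) {
  assert_numeric_vector(time, "time", non_negative = TRUE)
  R <- outer(time, time, FUN = "<=")
  storage.mode(R) <- "double"
  R
}

#' Split a dataset into training and test parts
#'
#' Random disjoint partition with `ceiling(n * (1 - test_fraction))` training
#' patients. Both parts must contain at least one observed event; the split
#' is resampled up to `max_tries` times to satisfy this, then errors.
#'
#' @param ds A [survival_dataset()].
#' @param test_fraction Fraction of patients held out, in (0, 1).
#' @param seed Integer seed making the split reproducible.
#' @param max_tries Resampling attempts before giving up.
#' @return A list with elements `train` and `test`, both `survival_dataset`s.
#' @export
train_test_split <- function(ds, test_fraction = 0.2, seed = NULL, max_tries = 25L) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be strictly between 0 and 1.")
  }
  n <- nrow(ds$X)
  n_train <- ceiling(n * (1 - test_fraction))
  if (n_train < 1L || n_train >= n) abort("Split leaves an empty part; adjust `test_fraction`.")
  with_seed_maybe(seed, {
    for (try in seq_len(max_tries)) {
      train_idx <- sort(sample.int(n, n_train))
      test_idx <- setdiff(seq_len(n), train_idx)
      if (sum(ds$event[train_idx]) >= 1 && sum(ds$event[test_idx]) >= 1) {
        return(list(train = subset_dataset(ds, train_idx),
                    test = subset_dataset(ds, test_idx)))
      }
    }
    abort(sprintf(
      "Could not produce a split with >= 1 event in each part after %d tries.",
      max_tries
    ))
  })
}
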