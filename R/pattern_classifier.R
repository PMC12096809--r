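# Unit-area Gaussian smoothing kernel on the 1-ms bin grid. The integration
# window is interpreted as total kernel support: sigma = support / 6,
# truncated at +/- 3 sigma.
gaussian_kernel <- function(integration_window_ms, bin_width_ms = 1) {
  sigma <- integration_window_ms / 6 / bin_width_ms
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  k / sum(k)
}

# 'same'-length convolution of counts with a symmetric kernel.
conv_same <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  y <- stats::convolve(c(numeric(r), x, numeric(r)), k, type = "open")
  y[(2L * r + 1L):(2L * r + length(x))]
}

#' Smooth a single-trial PSTH and restrict it to the response window
#'
#' Convolves a 1-ms-binned single-trial PSTH with a unit-area Gaussian of
#' total support `integration_window_ms` (sigma = support/6), then restricts
#' the result to the shared response window. Patterns shorter than the
#' window are zero-padded so all patterns of a unit share one length.
#'
#' @param trial_psth A single-trial [compute_psth()] with 1-ms bins.
#' @param window A [response_window()].
#' @param integration_window_ms Gaussian support, ms (2 or 200 by default
#'   elsewhere).
#' @return Object of class `smoothed_pattern`: list with `values`,
#'   `bin_width_ms`, `integration_window_ms`.
#' @export
smooth_pattern <- function(trial_psth, window, integration_window_ms) {
  stopifnot(inherits(trial_psth, "psth"), inherits(window, "response_window"))
  if (trial_psth$bin_width_ms != 1) stop("patterns require 1-ms bins", call. = FALSE)
  n <- length(trial_psth$counts)
  if (window$start_ms < 0) stop("window starts before the trial", call. = FALSE)
  sm <- conv_same(as.numeric(trial_psth$counts), gaussian_kernel(integration_window_ms))
  i0 <- floor(window$start_ms) + 1L
  n_bins <- max(1L, round(window$end_ms - window$start_ms))
  idx <- i0:(i0 + n_bins - 1L)
  vals <- numeric(n_bins)
  ok <- idx <= n
  vals[ok] <- sm[idx[ok]]
  structure(
    list(values = pmax(0, vals), bin_width_ms = 1,
         integration_window_ms = integration_window_ms),
    class = "smoothed_pattern"
  )
}

#' Assign one test pattern to the nearest template's class
#'
#' Euclidean distance between the test pattern and one template per
#' candidate call; the class of the minimal-distance template wins. Exact
#' distance ties are broken uniformly at random among the tied classes
#' (forced choice), consuming the current RNG stream.
#'
#' @param test Numeric vector (or `smoothed_pattern`).
#' @param templates Matrix with one column per candidate (same length as
#'   `test`), or list of `smoothed_pattern`s.
#' @param classes Character/integer vector of template classes (one per
#'   column).
#' @return The assigned class (single element of `classes`).
#' @export
classify_trial <- function(test, templates, classes) {
  if (inherits(test, "smoothed_pattern")) test <- test$values
  if (is.list(templates)) {
    templates <- vapply(templates, function(p) {
      if (inherits(p, "smoothed_pattern")) p$values else as.numeric(p)
    }, numeric(length(test)))
  }
  stopifnot(is.matrix(templates), nrow(templates) == length(test),
            ncol(templates) == length(classes))
  d2 <- colSums((templates - test)^2)
  dmin <- min(d2)
  tied <- unique(classes[d2 <= dmin + 1e-9 * (1 + dmin)])
  if (length(tied) == 1L) tied else tied[ceiling(stats::runif(1) * length(tied))]
}

# Precompute the smoothed-pattern matrix (window bins x all trials of all
# calls) plus bookkeeping vectors.
build_pattern_matrix <- function(call_sets, window, integration_window_ms) {
  cols <- list()
  call_of_col <- character(0)
  trial_of_col <- integer(0)
  for (id in names(call_sets)) {
    s <- call_sets[[id]]
    for (tr in seq_along(s$trials)) {
      p <- smooth_pattern(compute_psth(s, bin_width_ms = 1, trial = tr),
                          window, integration_window_ms)
      cols[[length(cols) + 1L]] <- p$values
      call_of_col <- c(call_of_col, id)
      trial_of_col <- c(trial_of_col, tr)
    }
  }
  list(
    P = do.call(cbind, cols),
    call_of_col = call_of_col,
    trial_of_col = trial_of_col
  )
}

#' Confusion matrix of single-trial spike-pattern classification
#'
#' The engine behind both the category-level (3 x 3) and within-category
#' (5 x 5) matrices. Per resample: a test (call, trial) is drawn -- test
#' calls are stratified so every call serves equally often -- one template
#' trial is drawn per candidate call (for the test call, from its other
#' trials, so a pattern is never compared to itself), the smoothed test
#' pattern is assigned to the class of the nearest template by Euclidean
#' distance (ties: forced choice), and assignments are accumulated into
#' row-stochastic probabilities (rows = true class).
#'
#' @param call_sets Named list of [spike_train_set()]s, one per call.
#' @param categories Named character vector mapping call id to category.
#' @param level `"category"` (all 15 calls, 3 classes) or `"within"`
#'   (restricted to `within_category`, classes = its 5 calls).
#' @param integration_window_ms Gaussian support for [smooth_pattern()].
#' @param window Shared [response_window()]; computed from 2-ms PSTHs via
#'   [shared_response_window()] when `NULL`.
#' @param n_resamples Number of resampling repetitions (default 10000).
#' @param seed Integer seed; the matrix is deterministic given
#'   `(data, seed, parameters)`.
#' @param within_category Category name, required for `level = "within"`.
#' @return Object of class `confusion_matrix`: list with `labels`, `probs`
#'   (row-stochastic K x K matrix), `counts`, `n_resamples`, `level`,
#'   `integration_window_ms`, `window`.
#' @export
confusion_matrix <- function(call_sets, categories,
                             level = c("category", "within"),
                             integration_window_ms = 2,
                             window = NULL,
                             n_resamples = 10000,
                             seed = 1L,
                             within_category = NULL) {
  level <- match.arg(level)
  stopifnot(!is.null(names(call_sets)),
            all(names(call_sets) %in% names(categories)))
  if (any(lengths(lapply(call_sets, `[[`, "trials")) < 2L)) {
    stop("every call needs at least 2 trials", call. = FALSE)
  }
  if (level == "within") {
    if (is.null(within_category)) stop("within_category required", call. = FALSE)
    keep <- names(call_sets)[categories[names(call_sets)] == within_category]
    if (length(keep) < 2L) stop("within_category must select >= 2 calls", call. = FALSE)
    call_sets <- call_sets[keep]
  }
  if (is.null(window)) {
    window <- shared_response_window(
      lapply(call_sets, compute_psth, bin_width_ms = 2)
    )
  }
  pm <- build_pattern_matrix(call_sets, window, integration_window_ms)
  call_ids <- names(call_sets)
  n_calls <- length(call_ids)
  class_of_call <- if (level == "category") {
    as.character(categories[call_ids])
  } else {
    call_ids
  }
  labels <- if (level == "category") {
    intersect(c("echolocation", "appeasement", "aggression"), unique(class_of_call))
  } else {
    call_ids
  }
  K <- length(labels)
  class_idx_of_call <- match(class_of_call, labels)

  col_of <- split(seq_along(pm$call_of_col), factor(pm$call_of_col, levels = call_ids))
  ntr <- lengths(col_of)
  n2 <- colSums(pm$P^2)
  G <- crossprod(pm$P)

  counts <- matrix(0L, K, K, dimnames = list(labels, labels))
  test_call_seq <- rep_len(seq_len(n_calls), n_resamples)
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      tc <- test_call_seq[r]
      tt <- ceiling(stats::runif(1) * ntr[tc])
      test_col <- col_of[[tc]][tt]
      u <- stats::runif(n_calls)
      tmpl_trial <- ceiling(u * ntr)
      # test call: draw from the other trials
      j <- ceiling(u[tc] * (ntr[tc] - 1L))
      tmpl_trial[tc] <- if (j >= tt) j + 1L else j
      tmpl_cols <- mapply(function(cols, k) cols[k], col_of, tmpl_trial)
      d2 <- n2[tmpl_cols] - 2 * G[test_col, tmpl_cols]
      dmin <- min(d2)
      tied <- unique(class_idx_of_call[d2 <= dmin + 1e-9 * (1 + abs(dmin))])
      assigned <- if (length(tied) == 1L) tied else tied[ceiling(stats::runif(1) * length(tied))]
      row <- class_idx_of_call[tc]
      counts[row, assigned] <- counts[row, assigned] + 1L
    }
  })
  probs <- counts / rowSums(counts)
  structure(
    list(labels = labels, probs = probs, counts = counts,
         n_resamples = n_resamples, level = level,
         integration_window_ms = integration_window_ms, window = window),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %s level, %g-ms integration, %d resamples\n",
              x$level, x$integration_window_ms, x$n_resamples))
  print(round(x$probs, 3))
  invisible(x)
}

#' Selectivity index of a confusion-matrix probability row
#'
#' `SI = max(p) - (mean(rest) + sd(rest))` with the sample (n-1) SD over the
#' remaining K-1 entries (for K = 2 the single remaining value has SD 0).
#' The highest possible value is 1, reached by a perfectly selective row.
#'
#' @param probs_row Numeric probability row (K >= 2, entries in `[0, 1]`).
#' @return Object of class `selectivity_index`: list with `si` and
#'   `best_class` (index or name of the maximal entry).
#' @export
selectivity_index <- function(probs_row) {
  x <- as.numeric(probs_row)
  if (length(x) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(x < -1e-9) || any(x > 1 + 1e-9)) stop("probabilities must be in [0,1]", call. = FALSE)
  i <- which.max(x)
  rest <- x[-i]
  s <- if (length(rest) > 1L) stats::sd(rest) else 0
  best <- if (!is.null(names(probs_row))) names(probs_row)[i] else i
  structure(list(si = x[i] - (mean(rest) + s), best_class = best),
            class = "selectivity_index")
}

#' @export
print.selectivity_index <- function(x, ...) {
  cat(sprintf("<selectivity_index> SI = %.3f (best: %s)\n", x$si, x$best_class))
  invisible(x)
}

#' Unit-level selectivity index of a confusion matrix
#'
#' The maximum over rows of the row-wise [selectivity_index()].
#'
#' @param cm A [confusion_matrix()].
#' @return List with `si` and `best_class`.
#' @export
unit_selectivity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sis <- apply(cm$probs, 1L, function(row) {
    names(row) <- cm$labels
    selectivity_index(row)$si
  })
  i <- which.max(sis)
  list(si = unname(sis[i]), best_class = cm$labels[i])
}
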