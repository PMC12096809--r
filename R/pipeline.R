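#' Build (or load) a run configuration
#'
#' A run is a pure function of its configuration: the seed fans out to every
#' stochastic stage. `config` may be a YAML file path or a named list;
#' missing entries take the defaults below.
#'
#' @param config Optional YAML path or named list of overrides.
#' @param ... Further overrides (highest precedence).
#' @return Named list of class `run_config` with entries `seed`, `n_faf`,
#'   `n_dac`, `n_trials`, `n_resamples`, `integration_windows_ms`,
#'   `bin_width_strength_ms`, `post_stimulus_ms`, `crit_sd`, `out_dir`.
#' @export
pipeline_config <- function(config = NULL, ...) {
  defaults <- list(
    seed = 1L, n_faf = 5L, n_dac = 5L, n_trials = 20L, n_resamples = 500L,
    integration_windows_ms = c(2, 200), bin_width_strength_ms = 2,
    post_stimulus_ms = 450, crit_sd = 2, out_dir = NULL
  )
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    bad <- setdiff(names(config), names(defaults))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    defaults[names(config)] <- config
  }
  over <- list(...)
  defaults[names(over)] <- over
  defaults$seed <- as.integer(defaults$seed)
  structure(defaults, class = "run_config")
}

#' Two-group comparison (t-test or Wilcoxon rank sum)
#'
#' Thin delegation to the standard tests; the choice between them (normal
#' vs. non-normal data) is the caller's.
#'
#' @param values_a,values_b Numeric samples (n >= 2 each).
#' @param test `"t"` (two-sided two-sample t-test) or `"ranksum"`
#'   (two-sided Wilcoxon rank sum).
#' @return List with `test`, `statistic`, `p`.
#' @export
compare_groups <- function(values_a, values_b, test = c("t", "ranksum")) {
  test <- match.arg(test)
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group", call. = FALSE)
  if (test == "t") {
    ht <- stats::t.test(a, b, var.equal = TRUE)
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value)
}

#' Multi-group comparison: one-way ANOVA with Tukey HSD
#'
#' @param groups Named list of >= 3 numeric samples.
#' @return List with `anova_F`, `anova_p`, and `pairs`: data.frame of all
#'   `choose(k, 2)` pairs with Tukey-adjusted p-values.
#' @export
compare_multi <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 3L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- data.frame(
    pair = rownames(tk), diff = tk[, "diff"], p_adj = tk[, "p adj"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(anova_F = an["group", "F value"], anova_p = an["group", "Pr(>F)"],
       pairs = pairs)
}

# Analyze one unit's call responses: preference indices plus, per
# integration window, the category confusion matrix, best-category
# probability and unit SI. Returns a one-row data.frame (NA-filled on a
# nonresponsive unit) and the matrices.
analyze_unit_calls <- function(profile, library, protocol, cfg) {
  sets <- lapply(library$calls, function(cl) {
    simulate_call_response(profile, cl, protocol)
  })
  manifest <- call_manifest(library)
  categories <- stats::setNames(manifest$category, manifest$call_id)
  row <- data.frame(
    unit_id = profile$unit_id, area = profile$area, responsive = FALSE,
    pi_cat = NA_integer_,
    pi_call_echolocation = NA_integer_, pi_call_appeasement = NA_integer_,
    pi_call_aggression = NA_integer_, stringsAsFactors = FALSE
  )
  matrices <- list()
  pref <- tryCatch(
    preference_result(sets, categories, bin_width_ms = cfg$bin_width_strength_ms,
                      crit_sd = cfg$crit_sd),
    vocsel_nonresponsive = function(e) NULL
  )
  if (is.null(pref)) {
    for (w in cfg$integration_windows_ms) {
      row[[sprintf("best_prob_%gms", w)]] <- NA_real_
      row[[sprintf("si_%gms", w)]] <- NA_real_
    }
    return(list(row = row, matrices = matrices))
  }
  row$responsive <- TRUE
  row$pi_cat <- pref$pi_cat
  for (cc in names(pref$pi_call)) {
    row[[paste0("pi_call_", cc)]] <- as.integer(pref$pi_call[[cc]])
  }
  for (w in cfg$integration_windows_ms) {
    cm <- confusion_matrix(
      sets, categories, level = "category", integration_window_ms = w,
      window = pref$window, n_resamples = cfg$n_resamples,
      seed = fan_seed(cfg$seed, "cm", profile$unit_id, w)
    )
    matrices[[sprintf("%gms", w)]] <- cm
    row[[sprintf("best_prob_%gms", w)]] <- max(diag(cm$probs))
    row[[sprintf("si_%gms", w)]] <- unit_selectivity(cm)$si
  }
  list(row = row, matrices = matrices)
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Synthesizes the 15-call library, builds an FAF-like and a dAC-like
#' cohort, simulates call responses, computes per-unit preference indices
#' and category-level confusion matrices at each integration window, and
#' aggregates population comparisons (dAC vs. FAF best-category probability
#' and selectivity index; 2-ms vs. 200-ms within each cohort). Deterministic
#' under a fixed configuration.
#'
#' @param config Passed to [pipeline_config()].
#' @param ... Config overrides.
#' @return Object of class `population_summary`: list with `units` (per-unit
#'   data.frame), `comparisons` (data.frame of group tests), `matrices`
#'   (per-unit confusion matrices), `library`, `config`.
#' @export
run_pipeline <- function(config = NULL, ...) {
  cfg <- pipeline_config(config, ...)
  library <- synth_call_library(cfg$seed)
  protocol <- trial_protocol(post_stimulus_ms = cfg$post_stimulus_ms,
                             n_trials = cfg$n_trials,
                             seed = fan_seed(cfg$seed, "spikes"))
  population <- make_population(
    list(
      list(template = faf_profile(unit_id = "faf"), n = cfg$n_faf),
      list(template = dac_profile(unit_id = "dac"), n = cfg$n_dac)
    ),
    seed = fan_seed(cfg$seed, "population")
  )
  rows <- list()
  matrices <- list()
  for (prof in population) {
    res <- analyze_unit_calls(prof, library, protocol, cfg)
    rows[[prof$unit_id]] <- res$row
    matrices[[prof$unit_id]] <- res$matrices
  }
  units <- do.call(rbind, rows)
  rownames(units) <- NULL

  comparisons <- list()
  ok <- units$responsive
  for (w in cfg$integration_windows_ms) {
    bp <- sprintf("best_prob_%gms", w)
    si <- sprintf("si_%gms", w)
    faf <- units[ok & units$area == "FAF", ]
    dac <- units[ok & units$area == "dAC", ]
    if (nrow(faf) >= 2 && nrow(dac) >= 2) {
      g <- compare_groups(dac[[bp]], faf[[bp]], "t")
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        comparison = sprintf("dAC_vs_FAF_best_prob_%gms", w), test = g$test,
        statistic = g$statistic, p = g$p,
        delta = mean(dac[[bp]]) - mean(faf[[bp]]), stringsAsFactors = FALSE
      )
      g <- compare_groups(dac[[si]], faf[[si]], "ranksum")
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        comparison = sprintf("dAC_vs_FAF_si_%gms", w), test = g$test,
        statistic = g$statistic, p = g$p,
        delta = stats::median(dac[[si]]) - stats::median(faf[[si]]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(cfg$integration_windows_ms) >= 2) {
    w1 <- sprintf("best_prob_%gms", cfg$integration_windows_ms[1])
    w2 <- sprintf("best_prob_%gms", cfg$integration_windows_ms[2])
    for (ar in c("FAF", "dAC")) {
      sub <- units[ok & units$area == ar, ]
      if (nrow(sub) >= 2) {
        g <- compare_groups(sub[[w1]], sub[[w2]], "t")
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          comparison = sprintf("%s_best_prob_%s_vs_%s", ar, w1, w2),
          test = g$test, statistic = g$statistic, p = g$p,
          delta = mean(sub[[w1]]) - mean(sub[[w2]]), stringsAsFactors = FALSE
        )
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame()

  out <- structure(
    list(units = units, comparisons = comparisons, matrices = matrices,
         library = library, config = cfg),
    class = "population_summary"
  )
  if (!is.null(cfg$out_dir)) write_population_summary(out, cfg$out_dir)
  out
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %d units (%d responsive)\n",
              nrow(x$units), sum(x$units$responsive)))
  if (nrow(x$comparisons)) {
    cat("group comparisons:\n")
    print(x$comparisons, digits = 3)
  }
  invisible(x)
}

#' Write a population summary's tables to disk
#'
#' CSV tables for units and comparisons, JSON for the confusion matrices.
#'
#' @param summary A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_population_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "population_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary$units, file.path(dir, "units.csv"), row.names = FALSE)
  utils::write.csv(summary$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  mats <- lapply(summary$matrices, function(ms) {
    lapply(ms, function(cm) {
      list(labels = cm$labels, probs = unclass(cm$probs),
           n_resamples = cm$n_resamples,
           integration_window_ms = cm$integration_window_ms)
    })
  })
  jsonlite::write_json(mats, file.path(dir, "confusion_matrices.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}
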