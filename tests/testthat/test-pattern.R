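single_trial_psth <- function(times, pre = 50, post = 150, bw = 1) {
  proto <- trial_protocol(pre_stimulus_ms = pre, post_stimulus_ms = post,
                          n_trials = 1, seed = 0)
  compute_psth(spike_train_set("u", "s", list(sort(times)), proto),
               bin_width_ms = bw, trial = 1)
}

test_that("smoothing preserves spike mass and respects the window", {
  p <- single_trial_psth(60.5)
  w <- response_window(50, 150)
  sp <- smooth_pattern(p, w, integration_window_ms = 2)
  expect_length(sp$values, 100)
  expect_equal(sum(sp$values), 1, tolerance = 1e-6) # unit-area kernel
  expect_equal(which.max(sp$values), 11) # bin [60, 61) is the 11th in window

  empty <- smooth_pattern(single_trial_psth(numeric(0)), w, 2)
  expect_true(all(empty$values == 0))
})

test_that("spikes 100 ms apart stay separable only at fine integration", {
  # oracle: the Gaussian sum for two unit impulses 100 ms apart. With
  # sigma = support/6, the 2-ms kernel leaves an empty gap between the
  # bumps, while the 200-ms kernel (sigma ~33 ms) fills the trough to
  # about 2/3 of the peak height.
  sigma <- 200 / 6
  g <- function(x, mu) stats::dnorm(x, mu, sigma)
  oracle_ratio <- (2 * g(110, 60.5)) / (g(60.5, 60.5) + g(60.5, 160.5))

  p <- single_trial_psth(c(60.5, 160.5), post = 250)
  w <- response_window(50, 250)
  n_maxima <- function(v) {
    v <- round(v, 12)
    sum(diff(sign(diff(v))) < 0 & v[2:(length(v) - 1)] > max(v) * 0.01)
  }
  fine <- smooth_pattern(p, w, 2)$values
  coarse <- smooth_pattern(p, w, 200)$values
  expect_equal(n_maxima(fine), 2)
  trough <- coarse[60] # bin [109, 110): midpoint between the spikes
  expect_equal(trough / max(coarse), oracle_ratio, tolerance = 0.05)
  expect_gt(trough / max(coarse), 0.6)
  expect_lt(fine[60] / max(fine), 1e-6)
})

test_that("classification matches brute-force distances and forced choice", {
  templates <- cbind(c(1, 0, 0, 0, 0), c(0, 0, 2, 0, 0), c(0, 0, 0, 0, 3))
  classes <- c("A", "B", "C")
  tests <- list(c(1, 0, 0, 0, 0), c(0, 1, 2, 0, 0), c(0, 0, 0, 1, 2.5),
                c(0.4, 0, 0.4, 0, 0))
  for (x in tests) {
    d2 <- colSums((templates - x)^2)
    expected <- classes[which.min(d2)]
    got <- vocsel:::with_seed(1, classify_trial(x, templates, classes))
    expect_equal(got, expected)
  }
  # exact tie: equidistant templates split uniformly
  tie_test <- c(0, 0, 0, 0, 0)
  eq <- cbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0), c(0, 0, 1, 0, 0))
  draws <- vocsel:::with_seed(99, replicate(3000, classify_trial(tie_test, eq, classes)))
  freq <- table(draws) / 3000
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 3000)))
})

test_that("disjoint deterministic patterns give the identity matrix", {
  cats <- c(a1 = "echolocation", a2 = "echolocation",
            b1 = "appeasement", b2 = "appeasement",
            c1 = "aggression", c2 = "aggression")
  onset <- c(a1 = 60, a2 = 70, b1 = 90, b2 = 100, c1 = 120, c2 = 130)
  sets <- lapply(names(cats), function(id) {
    make_deterministic_set("u", id, onset[[id]] + c(0, 1, 2))
  })
  names(sets) <- names(cats)
  cm <- confusion_matrix(sets, cats, level = "category", 2,
                         window = response_window(50, 150),
                         n_resamples = 1500, seed = 5)
  expect_equal(unname(cm$probs), diag(3))
})

test_that("confusion matrices are row-stochastic and seed-deterministic", {
  sets <- fixture_call_sets(dac_profile())
  cats <- fixture_categories()
  w <- response_window(52, 250)
  cm1 <- confusion_matrix(sets, cats, "category", 2, w, n_resamples = 400, seed = 7)
  cm2 <- confusion_matrix(sets, cats, "category", 2, w, n_resamples = 400, seed = 7)
  cm3 <- confusion_matrix(sets, cats, "category", 2, w, n_resamples = 400, seed = 8)
  expect_identical(cm1$probs, cm2$probs)
  expect_false(identical(cm1$probs, cm3$probs))
  expect_equal(unname(rowSums(cm1$probs)), rep(1, 3))
  expect_true(all(cm1$probs >= 0 & cm1$probs <= 1))
  expect_equal(sum(cm1$counts), 400)

  within <- confusion_matrix(sets, cats, "within", 2, w, n_resamples = 500,
                             seed = 7, within_category = "aggression")
  expect_equal(dim(within$probs), c(5, 5))
  expect_equal(unname(rowSums(within$probs)), rep(1, 5))
  expect_equal(within$labels, fixture_library()$categories$aggression)
})

test_that("selectivity index follows its closed-form examples", {
  expect_equal(selectivity_index(c(1, 0, 0))$si, 1)
  expect_equal(selectivity_index(c(1 / 3, 1 / 3, 1 / 3))$si, 0)
  expect_equal(selectivity_index(c(0.5, 0.3, 0.2))$si,
               0.5 - (0.25 + stats::sd(c(0.3, 0.2))))
  r <- c(a = 0.2, b = 0.7, c = 0.1)
  si <- selectivity_index(r)
  expect_equal(si$best_class, "b")
  expect_error(selectivity_index(0.5), "at least 2")
})

test_that("SI is bounded by 1 and decreases toward chance", {
  for (i in 1:50) {
    K <- sample(c(3, 5), 1)
    x <- vocsel:::with_seed(i, stats::runif(K))
    x <- x / sum(x)
    expect_lte(selectivity_index(x)$si, 1)
  }
  # interpolation from perfect selectivity to chance: SI = 1 - t
  for (t in seq(0, 1, by = 0.1)) {
    row <- (1 - t) * c(1, 0, 0) + t * rep(1 / 3, 3)
    expect_equal(selectivity_index(row)$si, 1 - t)
  }
})

test_that("templates never include the test trial itself", {
  # one call has a unique reproducible pattern in a single trial; if that
  # trial could serve as its own template, its row would be perfect. Build
  # 2-trial calls where trials within a call differ completely.
  cats <- c(x = "echolocation", y = "appeasement", z = "aggression")
  proto <- trial_protocol(pre_stimulus_ms = 50, post_stimulus_ms = 150,
                          n_trials = 2, seed = 0)
  sets <- list(
    x = spike_train_set("u", "x", list(c(60, 61), c(90, 91)), proto),
    y = spike_train_set("u", "y", list(c(60, 61), c(90, 91)), proto),
    z = spike_train_set("u", "z", list(c(60, 61), c(90, 91)), proto)
  )
  cm <- confusion_matrix(sets, cats, "category", 2,
                         window = response_window(50, 150),
                         n_resamples = 9000, seed = 3)
  # the test trial's own call can only offer its *other* trial (disjoint
  # spikes, positive distance), while the other calls tie at distance zero
  # whenever they draw the same-index trial: if the engine ever compared
  # the test trial to itself the diagonal would instead dominate (>= 0.5).
  # Exact enumeration gives diagonal 1/12.
  expect_true(all(abs(diag(cm$probs) - 1 / 12) < 0.03))
  expect_equal(unname(rowSums(cm$probs)), rep(1, 3))
})
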