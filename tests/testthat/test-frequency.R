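test_that("event classification uses the inclusive boundary rule", {
  cls <- classify_events(c(100, 500, 900), 500)
  expect_equal(cls$n_stained, 2L)
  expect_equal(cls$n_unstained, 1L)
  expect_equal(classify_events(c(1, 2, 3), 10)$n_stained, 0L)
  expect_error(classify_events(numeric(0), 1), "empty")

  # with known labels and a perfect threshold, counts equal ground truth
  set.seed(51)
  cfg <- simulation_config()
  ds <- simulate_experiment(simulation_config(
    seed = 51, n_events_per_sample = 500, time_points_h = c(0, 2),
    n_replicates = 1L, predator_levels = FALSE, initial_ratios = 0.5))
  et <- ds$cocultures[[1L]]
  truth_stained <- sum(et$events$true_label == "stained")
  thr <- fit_threshold(
    ds$monocultures[["mono_a_stained_t0"]]$events$intensity_dye,
    ds$monocultures[["mono_b_unstained_t0"]]$events$intensity_dye)
  if (thr$report$accuracy == 1) {
    expect_equal(classify_events(et, thr)$n_stained, truth_stained)
  } else {
    expect_lt(abs(classify_events(et, thr)$n_stained - truth_stained), 25)
  }
})

test_that("frequency estimates carry Wilson intervals", {
  est <- estimate_frequency(1000L, 2000L)
  expect_equal(est$freq_stained, 0.5)
  expect_equal(c(est$ci_low, est$ci_high), c(0.478, 0.522), tolerance = 1e-2)
  expect_true(est$ci_low <= est$freq_stained &&
                est$freq_stained <= est$ci_high)
  zero <- estimate_frequency(0L, 50L)
  expect_equal(zero$freq_stained, 0)
  expect_equal(zero$ci_low, 0)
  full <- estimate_frequency(50L, 50L)
  expect_equal(full$freq_stained, 1)
  expect_equal(full$ci_high, 1)
  # accepts classify_events() output directly
  est2 <- estimate_frequency(list(n_stained = 10L, n_unstained = 30L))
  expect_equal(est2$freq_stained, 0.25)
})

test_that("Wilson intervals achieve near-nominal coverage on simulated cocultures", {
  set.seed(52)
  p <- 0.37; n <- 2000L
  x <- rbinom(1000, n, p)
  covered <- vapply(x, function(xi) {
    est <- estimate_frequency(xi, n)
    est$ci_low <= p && p <= est$ci_high
  }, logical(1L))
  expect_gte(mean(covered), 0.93)
})

test_that("misclassification correction inverts the forward error map", {
  expect_equal(correct_frequency(0.3, 1, 0), 0.3)
  expect_equal(correct_frequency(0.52, 0.99, 0.02), 0.5 / 0.97)
  expect_equal(correct_frequency(0.01, 0.95, 0.02), 0)
  expect_error(correct_frequency(0.5, 0.4, 0.6), "tpr > fpr")
  for (p in c(0.1, 0.5, 0.9)) {
    for (rates in list(c(0.95, 0.02), c(0.8, 0.3), c(0.999, 0))) {
      p_obs <- rates[1L] * p + rates[2L] * (1 - p)
      expect_equal(correct_frequency(p_obs, rates[1L], rates[2L]), p)
    }
  }
})

test_that("the plate rule filters to 30-300 colonies then takes the densest plate", {
  meta <- demo_meta()
  ps <- plate_series(data.frame(
    dilution_exponent = c(3.79, 4.50, 5.19),
    A = c(240L, 90L, 12L), B = c(160L, 60L, 8L)), meta)
  est <- plate_frequency(ps, "A")
  expect_equal(est$n_gated, 150L)
  expect_equal(est$freq_stained, 0.6)
  expect_equal(est$dilution_exponent, 4.50)

  two <- plate_series(data.frame(dilution_exponent = c(4, 5),
                                 A = c(150L, 70L), B = c(100L, 50L)), meta)
  expect_equal(plate_frequency(two, "A")$n_gated, 250L)

  none <- plate_series(data.frame(dilution_exponent = c(4, 5),
                                  A = c(350L, 10L), B = c(60L, 10L)), meta)
  flagged <- plate_frequency(none, "A")
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$freq_stained))

  expect_error(plate_frequency(ps, "C"), "unknown focal")

  # invariance to plate ordering
  shuffled <- plate_series(ps$plates[c(3, 1, 2), ], meta)
  expect_equal(plate_frequency(shuffled, "A")$freq_stained,
               est$freq_stained)
})

test_that("method correlation recovers exact and noisy relationships", {
  ident <- correlate_methods(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(ident$r, 1)
  expect_equal(ident$slope, 1)
  anti <- correlate_methods(c(0.1, 0.5, 0.9), c(0.9, 0.5, 0.1))
  expect_equal(anti$r, -1)
  expect_error(correlate_methods(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3)),
               "zero variance")
  expect_error(correlate_methods(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")

  # observed r lies inside the Monte-Carlo envelope of its sampling model
  set.seed(53)
  p_true <- runif(50, 0.05, 0.95)
  n_fl <- 2000L; n_pl <- 150L
  draw_r <- function() {
    fl <- rbinom(50, n_fl, p_true) / n_fl
    pl <- rbinom(50, n_pl, p_true) / n_pl
    cor(fl, pl)
  }
  r_obs <- correlate_methods(rbinom(50, n_fl, p_true) / n_fl,
                             rbinom(50, n_pl, p_true) / n_pl)$r
  env <- quantile(replicate(2000, draw_r()), c(0.025, 0.975))
  expect_gte(r_obs, env[[1L]])
  expect_lte(r_obs, env[[2L]])
})

test_that("Fisher z comparison of correlations", {
  eq <- compare_correlations(0.8, 30, 0.8, 300)
  expect_equal(eq$z_difference, 0)
  expect_equal(eq$p_value, 1)

  got <- compare_correlations(0.9, 50, 0.5, 50)
  expect_equal(got$z_difference,
               (atanh(0.9) - atanh(0.5)) / sqrt(2 / 47))
  expect_equal(got$z_difference, 4.474, tolerance = 1e-3)

  fwd <- compare_correlations(0.9, 40, 0.3, 60)
  rev <- compare_correlations(0.3, 60, 0.9, 40)
  expect_equal(fwd$z_difference, -rev$z_difference)
  expect_equal(fwd$p_value, rev$p_value)
  expect_error(compare_correlations(1, 10, 0.5, 10), "< 1")
})
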