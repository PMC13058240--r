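test_that("ROC candidates reproduce hand-enumerated rates", {
  r <- roc_curve(stained = c(5, 4, 3), unstained = c(1, 2, 4))
  expect_equal(r$tpr[r$thresholds == 3], 1)
  expect_equal(r$fpr[r$thresholds == 3], 1 / 3)
  expect_equal(r$tpr[r$thresholds == 5], 1 / 3)
  expect_equal(r$fpr[r$thresholds == 5], 0)
  # sentinel above the maximum: the all-unstained point
  expect_equal(r$tpr[1L], 0)
  expect_equal(r$fpr[1L], 0)
  # rates are non-decreasing as the threshold decreases and end at 1
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_error(roc_curve(numeric(0), 1), "non-empty")
})

test_that("identical samples give a diagonal ROC", {
  x <- c(1, 2, 2, 5, 9)
  r <- roc_curve(x, x)
  expect_equal(r$tpr, r$fpr)
})

test_that("sorted-sweep ROC equals the exhaustive enumeration oracle", {
  set.seed(31)
  for (i in 1:60) {
    n1 <- sample(1:200, 1); n2 <- sample(1:200, 1)
    gen <- sample(1:3, 1)
    draw <- function(n) switch(gen,
      rnorm(n), round(rlnorm(n, 3, 2)), sample(-5:5, n, TRUE))
    st <- draw(n1); un <- draw(n2)
    got <- roc_curve(st, un)
    want <- roc_exhaustive(st, un)
    expect_equal(got$thresholds, want$thresholds)
    expect_equal(got$tpr, want$tpr)
    expect_equal(got$fpr, want$fpr)
  }
})

test_that("closest-top-left selection matches brute force, with tie rules", {
  rep1 <- select_threshold(roc_curve(c(5, 4, 3), c(1, 2, 4)))
  expect_equal(rep1$threshold, 3)
  expect_equal(rep1$accuracy, 5 / 6)
  expect_equal(rep1$average, 5 / 6)
  # equidistant candidates: lower FPR wins, so the higher threshold here
  rep2 <- select_threshold(roc_curve(c(5, 3), c(4, 1)))
  expect_equal(rep2$threshold, 5)
  expect_equal(rep2$fpr, 0)
  # randomized agreement with the literal brute-force selector
  set.seed(32)
  for (i in 1:40) {
    st <- sample(-10:30, sample(2:60, 1), TRUE)
    un <- sample(-10:30, sample(2:60, 1), TRUE)
    for (crit in c("closest_topleft", "balanced_accuracy")) {
      got <- select_threshold(roc_curve(st, un), crit)
      want <- select_exhaustive(st, un, crit)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$tpr, want$tpr)
      expect_equal(got$fpr, want$fpr)
    }
  }
})

test_that("threshold reports satisfy their metric identities", {
  set.seed(33)
  st <- rlnorm(300, 6, 1); un <- rlnorm(200, 2, 1)
  for (crit in c("closest_topleft", "balanced_accuracy")) {
    rep <- select_threshold(roc_curve(st, un), crit)
    expect_equal(rep$tnr, 1 - rep$fpr)
    expect_equal(rep$average, (rep$tpr + rep$tnr) / 2)
    expect_true(all(unlist(rep[c("tpr", "tnr", "fpr", "accuracy",
                                 "average")]) >= 0))
    expect_true(all(unlist(rep[c("tpr", "tnr", "fpr", "accuracy",
                                 "average")]) <= 1))
    expect_gte(rep$average, 0.5)
  }
})

test_that("evaluate_threshold applies the inclusive rule", {
  m <- evaluate_threshold(3, c(5, 4, 3), c(1, 2, 4))
  expect_equal(m$tpr, 1)
  expect_equal(m$tnr, 2 / 3)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(evaluate_threshold(-100, c(1, 2), c(3, 4))[c("tpr", "tnr")],
               list(tpr = 1, tnr = 0))
  expect_equal(evaluate_threshold(100, c(1, 2), c(3, 4))[c("tpr", "tnr")],
               list(tpr = 0, tnr = 1))
  expect_error(evaluate_threshold(1, numeric(0), 1), "non-empty")
})

test_that("the fitted classifier exposes the usual model interface", {
  set.seed(34)
  st <- rlnorm(500, 6, 0.8); un <- rlnorm(500, 1, 0.8)
  fit <- fit_threshold(st, un,
                       validate = list(stained = rlnorm(200, 6, 0.8),
                                       unstained = rlnorm(200, 1, 0.8)))
  expect_s3_class(fit, "stain_threshold")
  expect_named(coef(fit), "threshold")
  expect_gt(summary(fit)$validation$accuracy, 0.9)
  pred <- predict(fit, c(fit$threshold, fit$threshold - 1e-9))
  expect_equal(as.character(pred), c("stained", "unstained"))
  expect_output(print(fit), "threshold")
})

test_that("perfect separation yields a perfect in-between threshold", {
  set.seed(35)
  st <- rlnorm(400, 8, 0.5); un <- rlnorm(400, 1, 0.5)
  stopifnot(min(st) > max(un))
  for (crit in c("closest_topleft", "balanced_accuracy")) {
    fit <- fit_threshold(st, un, criterion = crit)
    expect_equal(fit$report$accuracy, 1)
    expect_gt(fit$threshold, max(un))
    expect_lte(fit$threshold, min(st))
  }
})

test_that("adding a stained observation above the threshold never lowers TPR", {
  set.seed(36)
  for (i in 1:20) {
    st <- rlnorm(50, 4, 1); un <- rlnorm(50, 2, 1)
    fit <- fit_threshold(st, un)
    t0 <- fit$threshold
    tpr0 <- evaluate_threshold(t0, st, un)$tpr
    tpr1 <- evaluate_threshold(t0, c(st, t0 * 1.5), un)$tpr
    expect_gte(tpr1, tpr0)
  }
})

test_that("the selected threshold approaches the equal-density crossing", {
  # equal log-scale sds and equal class sizes: the crossing of the two
  # densities sits midway between the log-means
  set.seed(37)
  mu1 <- 1; mu2 <- 7; s <- 1
  st <- rlnorm(1e5, mu2, s); un <- rlnorm(1e5, mu1, s)
  fit <- fit_threshold(st, un)
  expect_lt(abs(log(fit$threshold) - (mu1 + mu2) / 2), 2 * s)
})

test_that("pooled thresholds degenerate correctly and beat a t0 threshold on dilution series", {
  set.seed(38)
  one <- list(`0` = list(stained = rlnorm(300, 6, 1),
                         unstained = rlnorm(300, 1, 1)))
  gen <- pooled_threshold(one, "general")
  per <- pooled_threshold(one, "per_timepoint")
  expect_equal(gen$threshold, per[["0"]]$threshold)

  two <- c(one, setNames(one, "2"))
  gen2 <- pooled_threshold(two, "general")
  expect_equal(gen2$threshold, per[["0"]]$threshold)

  # simulated dye-dilution series over five time points
  cfg <- simulation_config()
  set.seed(39)
  samples <- lapply(0:4, function(g)
    list(stained = simulate_intensities("stained", g, 2000, cfg, "a"),
         unstained = simulate_intensities("unstained", g, 2000, cfg, "b")))
  names(samples) <- as.character(0:4 * 2)
  gen <- pooled_threshold(samples, "general")
  t0_thr <- fit_threshold(samples[[1L]]$stained, samples[[1L]]$unstained)
  acc_t0 <- mean(vapply(samples, function(s)
    evaluate_threshold(t0_thr$threshold, s$stained, s$unstained)$accuracy,
    numeric(1L)))
  expect_gte(mean(gen$per_timepoint$accuracy), acc_t0)
})

test_that("competitor-specific thresholds beat a unified one under autofluorescence offsets", {
  set.seed(40)
  identical_case <- compare_threshold_strategies(
    c(5, 6, 7), c(1, 2, 3), c(5, 6, 7), c(1, 2, 3))
  expect_equal(identical_case$separate$a_stained$threshold,
               identical_case$unified$threshold)

  cfg <- simulation_config(autofluor_offset = c(a = 0, b = 1.5))
  st_a <- simulate_intensities("stained", 3, 2000, cfg, "a")
  un_a <- simulate_intensities("unstained", 0, 2000, cfg, "a")
  st_b <- simulate_intensities("stained", 0, 2000, cfg, "b")
  un_b <- simulate_intensities("unstained", 0, 2000, cfg, "b")
  cmp <- compare_threshold_strategies(st_a, un_a, st_b, un_b)
  expect_gte(cmp$accuracy[["separate"]], cmp$accuracy[["unified"]])

  set.seed(41)
  perf <- compare_threshold_strategies(
    rlnorm(100, 9, 0.3), rlnorm(100, 1, 0.3),
    rlnorm(100, 9, 0.3), rlnorm(100, 1, 0.3))
  expect_equal(unname(perf$accuracy), c(1, 1))
})

test_that("retention curves summarise the dye decay", {
  flat <- retention_curve(list(`0` = rep(64, 10), `2` = rep(64, 5)))
  expect_equal(flat$mean, c(64, 64))
  expect_equal(flat$mean_log2, c(6, 6))

  one <- retention_curve(list(`4` = c(10, 20)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n, 2L)

  expect_warning(out <- retention_curve(list(`0` = 1:5, `2` = numeric(0))),
                 "omitted")
  expect_equal(out$time_h, 0)

  # halving per generation: mean log2 intensity drops by ~1 per step
  cfg <- simulation_config(autofluor_log_mean = log(1e-6),
                           autofluor_log_sd = 0.01)
  set.seed(42)
  samples <- lapply(0:4, function(g)
    simulate_intensities("stained", g, 20000, cfg, "a"))
  names(samples) <- as.character(0:4)
  rc <- retention_curve(samples)
  expect_equal(diff(rc$mean_log2), rep(-1, 4), tolerance = 0.05)
})
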