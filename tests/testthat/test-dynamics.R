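test_that("frequency trends recover exact logistic identities", {
  tr <- fit_frequency_trend(data.frame(time_h = c(0, 1),
                                       freq = plogis(c(0, 1))))
  expect_equal(tr$s_logit, 1, tolerance = 1e-9)

  flat <- fit_frequency_trend(data.frame(time_h = seq(0, 10, 2),
                                         freq = rep(0.4, 6)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$s_logit, 0)

  expect_error(fit_frequency_trend(data.frame(time_h = 0, freq = 0.5)),
               "2 time points")
  expect_error(fit_frequency_trend(data.frame(time_h = 0:1,
                                              freq = c(0.5, 1.2))),
               "\\[0, 1\\]")
})

test_that("noise-free selection dynamics give an exactly linear logit trajectory", {
  w <- 0.8; g_per_h <- 0.5
  t <- seq(0, 10, 2)
  f <- propagate_frequency(0.5, w, g_per_h * t)
  tr <- fit_frequency_trend(data.frame(time_h = t, freq = f))
  expect_equal(tr$s_logit, g_per_h * log(w), tolerance = 1e-10)
  # OLS residuals at machine precision
  lf <- qlogis(pmin(1 - 1e-3, pmax(1e-3, f)))
  res <- resid(lm(lf ~ t))
  expect_lt(max(abs(res)), 1e-10)
})

test_that("trends are equivariant under complementation and time shifts", {
  set.seed(61)
  for (i in 1:10) {
    n <- 2000L
    f_true <- propagate_frequency(0.3, 1.2, 0:5)
    x <- rbinom(6, n, f_true)
    d <- data.frame(time_h = seq(0, 10, 2), freq = x / n,
                    n_stained = x, n_gated = n)
    comp <- d
    comp$freq <- 1 - d$freq
    comp$n_stained <- n - x
    a <- fit_frequency_trend(d)
    b <- fit_frequency_trend(comp)
    expect_equal(b$slope, -a$slope)
    expect_equal(b$s_logit, -a$s_logit)

    shifted <- d
    shifted$time_h <- d$time_h + 17.3
    s <- fit_frequency_trend(shifted)
    expect_equal(s$slope, a$slope)
    expect_equal(s$s_logit, a$s_logit)
  }
})

test_that("pseudo-counts keep boundary frequencies usable", {
  d <- data.frame(time_h = c(0, 2, 4), freq = c(1, 0.5, 0),
                  n_stained = c(100L, 50L, 0L), n_gated = rep(100L, 3))
  tr <- fit_frequency_trend(d)
  expect_true(is.finite(tr$s_logit))
  expect_lt(tr$s_logit, 0)
})

test_that("selection rate is recovered from simulated competition trajectories", {
  set.seed(62)
  w <- 0.8; g_per_h <- 0.5
  truth <- g_per_h * log(w)
  t <- seq(0, 10, 2)
  est <- replicate(100, {
    f_true <- propagate_frequency(0.5, w, g_per_h * t)
    x <- rbinom(length(t), 2000L, f_true)
    fit_frequency_trend(data.frame(time_h = t, freq = x / 2000,
                                   n_stained = x, n_gated = 2000L))$s_logit
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 2 * se + 1e-4)
})

test_that("condition aggregation averages replicates and flags singletons", {
  agg <- aggregate_trends(c(0.2, 0.2, 0.2), rep("c1", 3))
  expect_equal(agg$mean_slope, 0.2)
  expect_equal(agg$se, 0)

  agg2 <- aggregate_trends(c(0.5, -0.5), c("c1", "c1"))
  expect_equal(agg2$mean_slope, 0)

  agg3 <- aggregate_trends(c(0.1, 0.3, -0.2), c("a", "a", "b"))
  expect_true(agg3$flagged[agg3$condition == "b"])
  expect_true(is.na(agg3$se[agg3$condition == "b"]))
})

test_that("per-condition trend signs match programmed truth in a 12-condition design", {
  # 3 ratios x 2 stained assignments x 2 predator levels; 8 conditions get
  # declining focal frequency, 4 get increasing
  set.seed(63)
  conditions <- expand.grid(ratio = c(0.1, 0.5, 0.9),
                            stained = c("a", "b"),
                            predator = c(FALSE, TRUE))
  w_by_cond <- ifelse(seq_len(12) %% 3 == 0, 1.25, 0.8)
  t <- seq(0, 10, 2)
  n_match <- 0L
  n_total <- 0L
  for (s in 1:10) {
    slopes <- character(0)
    for (ci in seq_len(12)) {
      reps <- vapply(1:3, function(r) {
        f_true <- propagate_frequency(conditions$ratio[ci], w_by_cond[ci],
                                      0.5 * t)
        x <- rbinom(length(t), 2000L, f_true)
        fit_frequency_trend(data.frame(time_h = t, freq = x / 2000,
                                       n_stained = x,
                                       n_gated = 2000L))$s_logit
      }, numeric(1L))
      n_total <- n_total + 1L
      if (sign(mean(reps)) == sign(log(w_by_cond[ci])))
        n_match <- n_match + 1L
    }
  }
  expect_gte(n_match / n_total, 0.95)
})

test_that("carrying capacity is the per-culture OD maximum averaged by condition", {
  od <- data.frame(condition = "c1", replicate = 1L,
                   time_h = c(0, 2, 4), od600 = c(0.1, 0.4, 0.35))
  cc <- carrying_capacity(od)
  expect_equal(cc$per_culture$max_od, 0.4)

  od3 <- do.call(rbind, lapply(1:3, function(r)
    data.frame(condition = "c1", replicate = r, time_h = c(0, 2),
               od600 = c(0.1, 0.3 + 0.1 * r))))
  cc3 <- carrying_capacity(od3)
  expect_equal(cc3$per_condition$mean_max_od, 0.5)

  # programmed K recovered from simulated logistic curves
  ds <- simulate_experiment(simulation_config(
    seed = 64, n_events_per_sample = 10L, n_replicates = 3L,
    predator_levels = FALSE, initial_ratios = 0.5))
  cc_sim <- carrying_capacity(ds$od)
  expect_equal(mean(cc_sim$per_condition$mean_max_od), 0.45,
               tolerance = 0.05)
})
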