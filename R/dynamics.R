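#' Temporal trend of a competitor-frequency trajectory
#'
#' For one replicate coculture, estimates (i) the ordinary least-squares
#' slope of frequency versus time (frequency per hour) and (ii) the
#' logit-scale selection rate `s_logit`: the OLS slope of
#' `ln(f / (1 - f))` versus time. Under discrete selection with constant
#' relative fitness `w` and `g` generations per hour, logit frequency is
#' exactly linear in time with slope `g * ln(w)`, so `s_logit` is the
#' per-hour selection-rate analogue of log relative fitness.
#'
#' Boundary frequencies are handled before the logit: when raw counts are
#' available the Haldane-Anscombe pseudo-count `f* = (x + 0.5)/(n + 1)` is
#' used; otherwise frequencies are clipped to `[1e-3, 1 - 1e-3]`.
#'
#' @param traj Data frame with numeric columns `time_h` and `freq`
#'   (frequency of the focal competitor in \[0, 1\]), and optionally integer
#'   columns `n_stained` and `n_gated` enabling the pseudo-count rule.
#' @return Object of class `"freq_trend"`: `slope`, `slope_se`, `s_logit`,
#'   `s_logit_se`, `n_points`.
#' @examples
#' fit_frequency_trend(data.frame(time_h = 0:5, freq = plogis(0.2 * (0:5))))
#' @export
fit_frequency_trend <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("time_h", "freq") %in% names(traj)))
  traj <- traj[order(traj$time_h), , drop = FALSE]
  if (nrow(traj) < 2L)
    stop("a trend needs at least 2 time points", call. = FALSE)
  if (any(traj$freq < 0 | traj$freq > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  t <- traj$time_h
  f <- traj$freq
  ols <- function(y) {
    fit <- stats::lm.fit(cbind(1, t), y)
    k <- fit$rank
    rss <- sum(fit$residuals^2)
    se <- if (length(y) > 2L) {
      sxx <- sum((t - mean(t))^2)
      sqrt(rss / (length(y) - 2L) / sxx)
    } else NA_real_
    c(slope = unname(fit$coefficients[2L]), se = se)
  }
  sl <- ols(f)
  if (all(c("n_stained", "n_gated") %in% names(traj))) {
    fstar <- (traj$n_stained + 0.5) / (traj$n_gated + 1)
  } else {
    fstar <- pmin(1 - 1e-3, pmax(1e-3, f))
  }
  lg <- ols(stats::qlogis(fstar))
  structure(list(slope = sl[["slope"]], slope_se = sl[["se"]],
                 s_logit = lg[["slope"]], s_logit_se = lg[["se"]],
                 n_points = nrow(traj)),
            class = "freq_trend")
}

#' @export
print.freq_trend <- function(x, ...) {
  cat(sprintf(
    "<freq_trend> slope %.4g/h (SE %.3g), s_logit %.4g/h (SE %.3g), %d points\n",
    x$slope, x$slope_se, x$s_logit, x$s_logit_se, x$n_points))
  invisible(x)
}

#' Per-condition aggregation of replicate trends
#'
#' Averages per-replicate slopes within each experimental condition and
#' tests the mean against zero with a two-sided normal z-test
#' (`SE = sd / sqrt(k)` across replicates). Conditions with a single
#' replicate are reported with `NA` standard error and flagged.
#'
#' @param slopes Numeric vector of per-replicate slope estimates (either the
#'   linear or the logit-scale slope).
#' @param condition Factor or character vector of the same length grouping
#'   replicates into conditions.
#' @return Data frame with one row per condition: `condition`, `k`,
#'   `mean_slope`, `se`, `z`, `p_value`, `flagged`.
#' @export
aggregate_trends <- function(slopes, condition) {
  stopifnot(length(slopes) == length(condition))
  condition <- as.character(condition)
  out <- do.call(rbind, lapply(split(seq_along(slopes), condition),
                               function(idx) {
    s <- slopes[idx]
    k <- length(s)
    m <- mean(s)
    se <- if (k >= 2L) stats::sd(s) / sqrt(k) else NA_real_
    z <- if (!is.na(se) && se > 0) m / se else NA_real_
    data.frame(condition = condition[idx[1L]], k = k, mean_slope = m,
               se = se, z = z,
               p_value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
               flagged = k < 2L)
  }))
  rownames(out) <- NULL
  out
}

#' Carrying capacity from OD600 series
#'
#' The assay-sense carrying capacity of a culture is the maximum optical
#' density it reaches during the experiment; per-condition capacity is the
#' arithmetic mean of the replicate maxima.
#'
#' @param od Either a list of [od_series()] objects or a data frame with
#'   columns `condition`, `replicate`, `time_h`, `od600`.
#' @return List with `per_culture` (data frame: condition, replicate,
#'   max_od) and `per_condition` (data frame: condition, k, mean_max_od).
#' @export
carrying_capacity <- function(od) {
  if (is.list(od) && !is.data.frame(od) &&
      all(vapply(od, inherits, logical(1L), "od_series"))) {
    od <- do.call(rbind, lapply(od, function(s) {
      data.frame(condition = condition_label(s$meta),
                 replicate = s$meta$replicate,
                 time_h = s$points$time_h, od600 = s$points$od600)
    }))
  }
  stopifnot(is.data.frame(od),
            all(c("condition", "replicate", "time_h", "od600") %in% names(od)))
  per_culture <- stats::aggregate(od600 ~ condition + replicate, data = od,
                                  FUN = max)
  names(per_culture)[names(per_culture) == "od600"] <- "max_od"
  per_condition <- do.call(rbind, lapply(
    split(per_culture, per_culture$condition), function(d)
      data.frame(condition = d$condition[1L], k = nrow(d),
                 mean_max_od = mean(d$max_od))))
  rownames(per_condition) <- NULL
  list(per_culture = per_culture[order(per_culture$condition,
                                       per_culture$replicate), ],
       per_condition = per_condition)
}

# Canonical condition label for grouping: ratio x stained x predator.
condition_label <- function(meta) {
  sprintf("ratio=%g|stained=%s|predator=%s",
          meta$initial_ratio,
          if (is.na(meta$stained_competitor)) "none" else meta$stained_competitor,
          if (meta$predator_present) "yes" else "no")
}
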