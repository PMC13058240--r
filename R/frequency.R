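#' Count stained and unstained cells in a gated coculture
#'
#' Applies the inclusive classification rule (stained iff dye intensity
#' `>= threshold`) to every gated event.
#'
#' @param events An [event_table()] of gated coculture events, or a numeric
#'   vector of dye intensities.
#' @param threshold Numeric threshold, a `"stain_threshold"` fit or a
#'   `"threshold_report"`.
#' @return List with integer elements `n_stained` and `n_unstained`.
#' @export
classify_events <- function(events, threshold) {
  if (inherits(threshold, "stain_threshold") ||
      inherits(threshold, "threshold_report"))
    threshold <- threshold$threshold
  v <- if (inherits(events, "event_table"))
    events$events$intensity_dye else as.numeric(events)
  if (length(v) == 0L)
    stop("cannot classify an empty event table", call. = FALSE)
  ns <- sum(v >= threshold)
  list(n_stained = as.integer(ns),
       n_unstained = as.integer(length(v) - ns))
}

# Wilson score interval for a binomial proportion; well-behaved at 0 and 1.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Stained-fraction estimate with Wilson confidence interval
#'
#' @param n_stained,n_gated Counts of stained cells and of all gated cells
#'   (`n_gated >= 1`). A list as returned by [classify_events()] may be given
#'   as `n_stained`, in which case `n_gated` is taken from it.
#' @param meta Optional [sample_meta()] attached to the estimate.
#' @param conf Confidence level of the Wilson score interval.
#' @return Object of class `"frequency_estimate"`: `n_gated`, `n_stained`,
#'   `freq_stained`, `ci_low`, `ci_high`, `method = "fluorescence"`.
#' @export
estimate_frequency <- function(n_stained, n_gated = NULL, meta = NULL,
                               conf = 0.95) {
  if (is.list(n_stained)) {
    n_gated <- n_stained$n_stained + n_stained$n_unstained
    n_stained <- n_stained$n_stained
  }
  stopifnot(length(n_stained) == 1L, length(n_gated) == 1L,
            n_gated >= 1, n_stained >= 0, n_stained <= n_gated)
  ci <- wilson_interval(n_stained, n_gated, conf)
  structure(list(meta = meta, n_gated = as.integer(n_gated),
                 n_stained = as.integer(n_stained),
                 freq_stained = n_stained / n_gated,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 freq_corrected = NULL, method = "fluorescence",
                 flagged = FALSE),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  if (x$flagged) {
    cat("<frequency_estimate> no evaluable data (flagged)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<frequency_estimate> %s: %d/%d stained, freq %.4f [%.4f, %.4f]\n",
    x$method, x$n_stained, x$n_gated, x$freq_stained, x$ci_low, x$ci_high))
  if (!is.null(x$freq_corrected))
    cat(sprintf("  misclassification-corrected: %.4f\n", x$freq_corrected))
  invisible(x)
}

#' Misclassification-corrected prevalence (Rogan-Gladen)
#'
#' Corrects an observed stained fraction for known classifier error rates:
#' `(freq_observed - fpr) / (tpr - fpr)`, clipped to \[0, 1\]. This is an
#' optional extension; the raw classified fraction remains the primary
#' estimate and is never replaced by the correction.
#'
#' @param freq_observed Observed stained fraction in \[0, 1\].
#' @param tpr,fpr True- and false-positive rates of the threshold on
#'   controls; requires `tpr > fpr` (an informative classifier).
#' @return Corrected fraction in \[0, 1\].
#' @export
correct_frequency <- function(freq_observed, tpr, fpr) {
  stopifnot(is.numeric(freq_observed), is.numeric(tpr), is.numeric(fpr))
  if (any(tpr <= fpr))
    stop("correction requires tpr > fpr (informative threshold)",
         call. = FALSE)
  pmin(1, pmax(0, (freq_observed - fpr) / (tpr - fpr)))
}

#' Competitor frequency from a dilution-plating series
#'
#' Applies the colony-counting convention: only plates whose total colony
#' count (both morphotypes) lies in the closed interval \[30, 300\] are
#' evaluable, and among those the plate with the highest total is used. The
#' focal competitor's frequency is its count divided by the plate total. If
#' no plate qualifies a flagged empty estimate is returned rather than an
#' error.
#'
#' @param series A [plate_series()].
#' @param focal Morphotype label of the focal competitor (must be one of the
#'   series' count columns).
#' @param min_colonies,max_colonies Evaluability bounds on the plate total
#'   (inclusive); defaults 30 and 300.
#' @return A `"frequency_estimate"` with `method = "plate"`; `flagged` is
#'   `TRUE` (with `freq_stained = NA`) when no plate qualifies.
#' @export
plate_frequency <- function(series, focal, min_colonies = 30,
                            max_colonies = 300) {
  stopifnot(inherits(series, "plate_series"))
  if (!focal %in% series$morphotypes)
    stop("unknown focal morphotype '", focal, "'; expected one of: ",
         paste(series$morphotypes, collapse = ", "), call. = FALSE)
  pl <- series$plates
  totals <- rowSums(pl[, series$morphotypes, drop = FALSE])
  ok <- totals >= min_colonies & totals <= max_colonies
  if (!any(ok)) {
    return(structure(list(meta = series$meta, n_gated = NA_integer_,
                          n_stained = NA_integer_,
                          freq_stained = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, freq_corrected = NULL,
                          method = "plate", flagged = TRUE,
                          dilution_exponent = NA_real_),
                     class = "frequency_estimate"))
  }
  sel <- which(ok)[which.max(totals[ok])]
  x <- unname(pl[[focal]][sel])
  n <- unname(totals[sel])
  ci <- wilson_interval(x, n)
  structure(list(meta = series$meta, n_gated = as.integer(n),
                 n_stained = as.integer(x), freq_stained = x / n,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 freq_corrected = NULL, method = "plate", flagged = FALSE,
                 dilution_exponent = pl$dilution_exponent[sel]),
            class = "frequency_estimate")
}

#' Agreement between fluorescence- and plate-derived frequencies
#'
#' Pearson correlation (with the two-sided t-test p-value) and the
#' least-squares line of plate frequency on fluorescence frequency, for the
#' paired estimates of the same samples by the two methods.
#'
#' @param freq_fluorescence,freq_plate Numeric vectors of paired frequencies
#'   (length >= 3, finite, non-constant).
#' @return List with `r`, `n`, `p_value`, `slope`, `intercept`.
#' @export
correlate_methods <- function(freq_fluorescence, freq_plate) {
  x <- as.numeric(freq_fluorescence)
  y <- as.numeric(freq_plate)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in one coordinate",
         call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), n = length(x),
       p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]))
}

#' Fisher z comparison of two correlation coefficients
#'
#' Tests whether two independent Pearson correlations differ:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value.
#'
#' @param r1,r2 Correlation coefficients with `|r| < 1`.
#' @param n1,n2 Sample sizes (each >= 4).
#' @return List with `z_difference` and `p_value`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 for the Fisher z transform", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z_difference = z, p_value = 2 * stats::pnorm(-abs(z)))
}
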