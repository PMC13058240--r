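#' ROC curve over all observed candidate thresholds
#'
#' Sweeps every distinct observed dye intensity from the stained and
#' unstained monoculture controls as a candidate classification threshold.
#' A cell is called stained when its intensity is greater than or equal to
#' the threshold, so at candidate `t` the true-positive rate is the fraction
#' of stained-control cells with intensity `>= t` and the false-positive rate
#' the fraction of unstained-control cells with intensity `>= t`. A sentinel
#' candidate above the maximum (`Inf`) contributes the all-unstained point
#' (TPR = FPR = 0). Any threshold strictly between two consecutive observed
#' values produces the same confusion counts as one of these candidates, so
#' the sweep over observed values is exhaustive.
#'
#' @param stained,unstained Numeric vectors of dye-channel intensities from
#'   the stained and unstained controls. Negative (background-subtracted)
#'   values are legal.
#' @return An object of class `"stain_roc"`: list with `thresholds`
#'   (descending), `tpr`, `fpr`, `n_stained`, `n_unstained`.
#' @examples
#' r <- roc_curve(c(5, 4, 3), c(1, 2, 4))
#' cbind(r$thresholds, r$tpr, r$fpr)
#' @export
roc_curve <- function(stained, unstained) {
  stained <- as.numeric(stained)
  unstained <- as.numeric(unstained)
  if (length(stained) == 0L || length(unstained) == 0L)
    stop("both stained and unstained intensities must be non-empty",
         call. = FALSE)
  if (anyNA(stained) || anyNA(unstained) ||
      any(!is.finite(stained)) || any(!is.finite(unstained)))
    stop("intensities must be finite", call. = FALSE)
  cand <- sort(unique(c(stained, unstained)), decreasing = TRUE)
  cand <- c(Inf, cand)
  ss <- sort(stained)
  su <- sort(unstained)
  ns <- length(stained)
  nu <- length(unstained)
  # count(x >= t) = n - count(x < t); findInterval(.., left.open = TRUE)
  # counts elements strictly below t in a sorted vector
  asc <- rev(cand)
  tp_asc <- ns - findInterval(asc, ss, left.open = TRUE)
  fp_asc <- nu - findInterval(asc, su, left.open = TRUE)
  tp_asc[is.infinite(asc)] <- 0L
  fp_asc[is.infinite(asc)] <- 0L
  structure(list(thresholds = cand,
                 tpr = rev(tp_asc) / ns,
                 fpr = rev(fp_asc) / nu,
                 n_stained = ns, n_unstained = nu),
            class = "stain_roc")
}

#' @export
print.stain_roc <- function(x, ...) {
  cat("<stain_roc> ", length(x$thresholds), " candidate thresholds, ",
      x$n_stained, " stained / ", x$n_unstained, " unstained cells\n",
      sep = "")
  invisible(x)
}

#' @param x A `"stain_roc"` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @rdname roc_curve
#' @export
plot.stain_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

# Confusion metrics at every ROC point; accuracy uses the class sizes.
roc_metrics <- function(roc) {
  tnr <- 1 - roc$fpr
  acc <- (roc$tpr * roc$n_stained + tnr * roc$n_unstained) /
    (roc$n_stained + roc$n_unstained)
  list(tnr = tnr, accuracy = acc, average = (roc$tpr + tnr) / 2)
}

new_threshold_report <- function(threshold, criterion, tpr, fpr, accuracy,
                                 n_stained, n_unstained, validation = NULL) {
  structure(list(threshold = threshold, criterion = criterion,
                 tpr = tpr, tnr = 1 - fpr, fpr = fpr,
                 accuracy = accuracy, average = (tpr + (1 - fpr)) / 2,
                 n_stained = n_stained, n_unstained = n_unstained,
                 validation = validation),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "<threshold_report> threshold = %.6g (%s)\n  TPR %.4f  TNR %.4f  FPR %.4f  accuracy %.4f  average %.4f\n",
    x$threshold, x$criterion, x$tpr, x$tnr, x$fpr, x$accuracy, x$average))
  if (!is.null(x$validation))
    cat(sprintf(
      "  hold-out: TPR %.4f  TNR %.4f  accuracy %.4f\n",
      x$validation$tpr, x$validation$tnr, x$validation$accuracy))
  invisible(x)
}

#' Select the optimal threshold from a ROC curve
#'
#' Two selection criteria are available. `"closest_topleft"` (the default)
#' picks the candidate minimising the Euclidean distance
#' `sqrt(fpr^2 + (1 - tpr)^2)` to the perfect-classification corner of ROC
#' space. `"balanced_accuracy"` maximises the average of TPR and TNR. Ties
#' are broken in favour of the lower FPR, then the higher threshold, so the
#' method never over-calls stained cells.
#'
#' @param roc A [roc_curve()] result.
#' @param criterion `"closest_topleft"` or `"balanced_accuracy"`.
#' @return A `"threshold_report"`: selected threshold plus TPR, TNR, FPR,
#'   accuracy and average at that point.
#' @export
select_threshold <- function(roc,
                             criterion = c("closest_topleft",
                                           "balanced_accuracy")) {
  stopifnot(inherits(roc, "stain_roc"))
  criterion <- match.arg(criterion)
  m <- roc_metrics(roc)
  score <- switch(criterion,
                  closest_topleft = roc$fpr^2 + (1 - roc$tpr)^2,
                  balanced_accuracy = -m$average)
  best <- order(score, roc$fpr, -roc$thresholds)[1L]
  new_threshold_report(roc$thresholds[best], criterion,
                       tpr = roc$tpr[best], fpr = roc$fpr[best],
                       accuracy = m$accuracy[best],
                       n_stained = roc$n_stained,
                       n_unstained = roc$n_unstained)
}

#' Evaluate a fixed threshold on labelled controls
#'
#' Applies the inclusive classification rule (stained iff intensity
#' `>= threshold`) to a stained and an unstained control sample and reports
#' the confusion-rate metrics. Used for hold-out validation of thresholds
#' derived from an independent control pair.
#'
#' @param threshold Numeric dye-intensity threshold.
#' @param stained,unstained Numeric intensity vectors, both non-empty.
#' @return List with `tpr`, `tnr`, `fpr`, `accuracy`, `average`.
#' @export
evaluate_threshold <- function(threshold, stained, unstained) {
  if (length(stained) == 0L || length(unstained) == 0L)
    stop("both stained and unstained intensities must be non-empty",
         call. = FALSE)
  stopifnot(length(threshold) == 1L, !is.na(threshold))
  tp <- sum(stained >= threshold)
  tn <- sum(unstained < threshold)
  ns <- length(stained)
  nu <- length(unstained)
  tpr <- tp / ns
  tnr <- tn / nu
  list(tpr = tpr, tnr = tnr, fpr = 1 - tnr,
       accuracy = (tp + tn) / (ns + nu), average = (tpr + tnr) / 2)
}

#' Fit a stained/unstained classification threshold
#'
#' The central estimator: from a stained and an unstained monoculture
#' control it builds the exhaustive ROC over observed dye intensities,
#' selects the optimal threshold under the chosen criterion, and returns a
#' fitted classifier with the usual accessor methods ([coef()] for the
#' threshold, [predict()] to classify new intensities, [plot()] for the ROC
#' curve, [summary()] for the full report).
#'
#' @param stained,unstained Numeric dye intensities of the stained and
#'   unstained controls (typically gated monoculture events pooled across
#'   sampling time points).
#' @param criterion Threshold selection rule, see [select_threshold()].
#' @param validate Optional list with elements `stained` and `unstained`: a
#'   second, independent control pair on which the selected threshold is
#'   evaluated (hold-out validation).
#' @return An object of class `"stain_threshold"`.
#' @examples
#' fit <- fit_threshold(stained = c(5, 4, 3), unstained = c(1, 2, 4))
#' coef(fit)
#' predict(fit, c(0.5, 3.2, 10))
#' @export
fit_threshold <- function(stained, unstained,
                          criterion = c("closest_topleft",
                                        "balanced_accuracy"),
                          validate = NULL) {
  criterion <- match.arg(criterion)
  roc <- roc_curve(stained, unstained)
  report <- select_threshold(roc, criterion)
  if (!is.null(validate)) {
    stopifnot(is.list(validate),
              all(c("stained", "unstained") %in% names(validate)))
    report$validation <- evaluate_threshold(report$threshold,
                                            validate$stained,
                                            validate$unstained)
  }
  structure(list(threshold = report$threshold, criterion = criterion,
                 report = report, roc = roc, call = match.call()),
            class = "stain_threshold")
}

#' @export
print.stain_threshold <- function(x, ...) {
  cat("Fluorescence classification threshold (criterion: ",
      x$criterion, ")\n", sep = "")
  cat(sprintf("  threshold: %.6g\n", x$threshold))
  cat(sprintf("  TPR %.4f  TNR %.4f  accuracy %.4f  average %.4f\n",
              x$report$tpr, x$report$tnr, x$report$accuracy,
              x$report$average))
  invisible(x)
}

#' @export
summary.stain_threshold <- function(object, ...) {
  out <- object$report
  attr(out, "n_candidates") <- length(object$roc$thresholds)
  out
}

#' @export
coef.stain_threshold <- function(object, ...) {
  c(threshold = object$threshold)
}

#' Classify new dye intensities with a fitted threshold
#'
#' @param object A fitted [fit_threshold()] classifier.
#' @param newdata Numeric vector of dye intensities, or an [event_table()]
#'   (its `intensity_dye` column is used).
#' @param ... Unused.
#' @return Factor with levels `"unstained"`, `"stained"`; the inclusive rule
#'   assigns intensities equal to the threshold to `"stained"`.
#' @export
predict.stain_threshold <- function(object, newdata, ...) {
  if (inherits(newdata, "event_table"))
    newdata <- newdata$events$intensity_dye
  factor(ifelse(newdata >= object$threshold, "stained", "unstained"),
         levels = c("unstained", "stained"))
}

#' @export
plot.stain_threshold <- function(x, ...) {
  plot(x$roc, ...)
  graphics::points(x$report$fpr, x$report$tpr, pch = 19, col = "red3")
  graphics::legend("bottomright", bty = "n", pch = 19, col = "red3",
                   legend = sprintf("threshold = %.4g", x$threshold))
  invisible(x)
}

#' General versus per-time-point thresholds
#'
#' Derives classification thresholds from monoculture controls sampled at
#' several time points. In `"general"` mode all stained and all unstained
#' intensities are pooled across time points before the ROC sweep, yielding
#' one threshold that already integrates the gradual dye dilution; in
#' `"per_timepoint"` mode a separate threshold is fitted at every time point.
#' In both modes the fitted threshold(s) are evaluated on each time point's
#' own controls.
#'
#' @param samples Named list keyed by time (hours); each element a list with
#'   numeric elements `stained` and `unstained`.
#' @param mode `"general"` or `"per_timepoint"`.
#' @param criterion Passed to [fit_threshold()].
#' @return For `"general"`: a `"stain_threshold"` with an extra
#'   `per_timepoint` data frame of accuracies. For `"per_timepoint"`: a named
#'   list of `"stain_threshold"` fits.
#' @export
pooled_threshold <- function(samples, mode = c("general", "per_timepoint"),
                             criterion = "closest_topleft") {
  mode <- match.arg(mode)
  stopifnot(is.list(samples), length(samples) >= 1L)
  ok <- vapply(samples, function(s)
    is.list(s) && all(c("stained", "unstained") %in% names(s)), logical(1L))
  if (!all(ok))
    stop("each sample must be a list with 'stained' and 'unstained'",
         call. = FALSE)
  if (mode == "per_timepoint") {
    fits <- lapply(samples, function(s)
      fit_threshold(s$stained, s$unstained, criterion = criterion))
    return(fits)
  }
  fit <- fit_threshold(unlist(lapply(samples, `[[`, "stained")),
                       unlist(lapply(samples, `[[`, "unstained")),
                       criterion = criterion)
  per_tp <- do.call(rbind, lapply(names(samples), function(tp) {
    m <- evaluate_threshold(fit$threshold, samples[[tp]]$stained,
                            samples[[tp]]$unstained)
    data.frame(time = tp, tpr = m$tpr, tnr = m$tnr,
               accuracy = m$accuracy, average = m$average)
  }))
  fit$per_timepoint <- per_tp
  fit
}

#' Competitor-specific versus unified thresholds
#'
#' In a pairwise assay either competitor can carry the dye, and each stained
#' monoculture is compared against an unstained monoculture of its
#' competitor. This helper contrasts two strategies: separate thresholds,
#' one per stained competitor, versus a single unified threshold fitted on
#' both control pairs pooled. Mean classification accuracy across the two
#' pairs is reported for each strategy; competitor-specific thresholds win
#' whenever the two competitors differ, e.g. in autofluorescence.
#'
#' @param stained_a Dye intensities of the competitor-A stained monoculture.
#' @param unstained_a Intensities of the unstained competitor-A monoculture.
#' @param stained_b,unstained_b Likewise for competitor B.
#' @param criterion Passed to [fit_threshold()].
#' @return List with elements `separate` (two `"stain_threshold"` fits, for
#'   A stained and B stained), `unified` (one fit), and `accuracy` (named
#'   numeric: mean accuracy of each strategy).
#' @export
compare_threshold_strategies <- function(stained_a, unstained_a,
                                         stained_b, unstained_b,
                                         criterion = "closest_topleft") {
  for (v in list(stained_a, unstained_a, stained_b, unstained_b))
    if (length(v) == 0L)
      stop("all four intensity sets must be non-empty", call. = FALSE)
  # each stained competitor is classified against its competitor's
  # unstained control: A-stained vs B-unstained and vice versa
  fit_a <- fit_threshold(stained_a, unstained_b, criterion = criterion)
  fit_b <- fit_threshold(stained_b, unstained_a, criterion = criterion)
  unified <- fit_threshold(c(stained_a, stained_b),
                           c(unstained_a, unstained_b),
                           criterion = criterion)
  acc_sep <- mean(c(fit_a$report$accuracy, fit_b$report$accuracy))
  acc_uni <- mean(c(
    evaluate_threshold(unified$threshold, stained_a, unstained_b)$accuracy,
    evaluate_threshold(unified$threshold, stained_b, unstained_a)$accuracy))
  list(separate = list(a_stained = fit_a, b_stained = fit_b),
       unified = unified,
       accuracy = c(separate = acc_sep, unified = acc_uni))
}

#' Dye retention curve
#'
#' Per-time-point location and scale summaries of the gated stained-cell dye
#' intensity, used to check the temporal decay of the transient dye signal
#' (mean fluorescence per stained cell roughly halves each division). Empty
#' time points are omitted with a warning.
#'
#' @param samples Named list keyed by time in hours; each element a numeric
#'   intensity vector or an [event_table()].
#' @return Data frame with `time_h`, `n`, `mean`, `median`, `sd` and
#'   `mean_log2` (mean of log2 intensity over positive values).
#' @export
retention_curve <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  rows <- lapply(names(samples), function(tp) {
    v <- samples[[tp]]
    if (inherits(v, "event_table")) v <- v$events$intensity_dye
    v <- as.numeric(v)
    if (length(v) == 0L) {
      warning("no events at time ", tp, "; point omitted", call. = FALSE)
      return(NULL)
    }
    pos <- v[v > 0]
    data.frame(time_h = as.numeric(tp), n = length(v), mean = mean(v),
               median = stats::median(v), sd = stats::sd(v),
               mean_log2 = if (length(pos)) mean(log2(pos)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no time point with events", call. = FALSE)
  out[order(out$time_h), , drop = FALSE]
}
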