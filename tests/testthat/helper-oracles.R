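# Independent oracles used to cross-check the production implementations.
# These deliberately use the slowest, most literal formulation of each rule.

# Exhaustive O(n * m) ROC enumeration over every unique observed intensity
# (plus the all-unstained sentinel), classifying stained iff intensity >= t.
roc_exhaustive <- function(stained, unstained) {
  cand <- c(Inf, sort(unique(c(stained, unstained)), decreasing = TRUE))
  tpr <- vapply(cand, function(t) mean(stained >= t), numeric(1L))
  fpr <- vapply(cand, function(t) mean(unstained >= t), numeric(1L))
  list(thresholds = cand, tpr = tpr, fpr = fpr)
}

# Brute-force threshold selection: score every candidate, then apply the
# tie rules literally (min distance, then min fpr, then max threshold).
select_exhaustive <- function(stained, unstained,
                              criterion = "closest_topleft") {
  r <- roc_exhaustive(stained, unstained)
  score <- if (criterion == "closest_topleft")
    sqrt(r$fpr^2 + (1 - r$tpr)^2)
  else
    -(r$tpr + (1 - r$fpr)) / 2
  best <- which(score == min(score))
  best <- best[r$fpr[best] == min(r$fpr[best])]
  best <- best[which.max(r$thresholds[best])]
  list(threshold = r$thresholds[best], tpr = r$tpr[best], fpr = r$fpr[best])
}

# Winding-number point-in-polygon oracle (non-zero rule). Only meaningful
# away from the boundary, where it must agree with any membership rule.
winding_inside <- function(px, py, vertices) {
  vx <- vertices[, 1L]; vy <- vertices[, 2L]
  nv <- length(vx)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    wn <- 0L
    for (k in seq_len(nv)) {
      j <- if (k == nv) 1L else k + 1L
      if (vy[k] <= y) {
        if (vy[j] > y &&
            (vx[j] - vx[k]) * (y - vy[k]) - (x - vx[k]) * (vy[j] - vy[k]) > 0)
          wn <- wn + 1L
      } else if (vy[j] <= y &&
                 (vx[j] - vx[k]) * (y - vy[k]) - (x - vx[k]) * (vy[j] - vy[k]) < 0) {
        wn <- wn - 1L
      }
    }
    wn != 0L
  }, logical(1L))
}

# Distance from a point to the closest polygon edge, to exclude points too
# near the boundary for a fair oracle comparison.
polygon_edge_distance <- function(px, py, vertices) {
  vx <- vertices[, 1L]; vy <- vertices[, 2L]
  nv <- length(vx)
  dmin <- rep(Inf, length(px))
  for (k in seq_len(nv)) {
    j <- if (k == nv) 1L else k + 1L
    dx <- vx[j] - vx[k]; dy <- vy[j] - vy[k]
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - vx[k]) * dx + (py - vy[k]) * dy) / len2))
    dmin <- pmin(dmin, sqrt((px - (vx[k] + t * dx))^2 +
                              (py - (vy[k] + t * dy))^2))
  }
  dmin
}

# Literal reading of the plating rule: keep plates with total colonies in
# [30, 300]; among those use the one with the highest total.
plate_pick_bruteforce <- function(totals) {
  best <- NA_integer_
  for (i in seq_along(totals)) {
    if (totals[i] >= 30 && totals[i] <= 300) {
      if (is.na(best) || totals[i] > totals[best]) best <- i
    }
  }
  best
}
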