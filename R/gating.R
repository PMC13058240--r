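#' Polygon gate on dye versus autofluorescence intensity
#'
#' A gate is an ordered polygon in the (dye intensity, autofluorescence
#' intensity) plane; events inside or on the boundary are retained.
#'
#' @param vertices Two-column numeric matrix (x = dye channel, y =
#'   autofluorescence channel) with at least three rows, in drawing order.
#' @param name Optional gate name.
#' @return Object of class `"polygon_gate"`.
#' @seealso [default_cell_gate()] for the built-in bacteria gate.
#' @export
polygon_gate <- function(vertices, name = "custom") {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("a polygon gate needs a numeric matrix of >= 3 (x, y) vertices",
         call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("gate vertices must be finite", call. = FALSE)
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, name = name), class = "polygon_gate")
}

#' @export
print.polygon_gate <- function(x, ...) {
  cat("<polygon_gate> '", x$name, "', ", nrow(x$vertices),
      " vertices\n", sep = "")
  invisible(x)
}

#' Range gate on brightfield area
#'
#' Closed interval on the brightfield-area channel used to separate bacteria
#' from larger objects such as ciliate predators.
#'
#' @param low,high Inclusive bounds in area units, `low <= high`.
#' @return Object of class `"range_gate"`.
#' @export
range_gate <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L, is.finite(low), is.finite(high))
  if (low > high) stop("range gate requires low <= high", call. = FALSE)
  structure(list(low = low, high = high), class = "range_gate")
}

#' Built-in two-stage bacteria gate
#'
#' The default polygon gate retaining bacterial cells (stained or not) in the
#' (dye intensity, autofluorescence intensity) plane, and the default
#' brightfield-area range (2 to 150 area units) excluding ciliates.
#'
#' @return `default_cell_gate()` returns a [polygon_gate()];
#'   `default_area_gate()` a [range_gate()].
#' @export
default_cell_gate <- function() {
  polygon_gate(matrix(c(
    0,            0,
    1000,         0,
    14147935.62,  0,
    14147935.62,  18258919.88,
    129532.65,    11248522.44,
    5402.53,      22932.84,
    0,            1481.21), ncol = 2L, byrow = TRUE),
    name = "bacteria")
}

#' @rdname default_cell_gate
#' @export
default_area_gate <- function() range_gate(2, 150)

#' Point-in-polygon predicate
#'
#' Boundary-inclusive membership test, vectorised over points. Uses ray
#' casting with explicit on-edge detection (relative tolerance 1e-9), so
#' points lying exactly on a vertex or edge count as inside.
#'
#' @param x,y Numeric vectors of point coordinates (recycled to a common
#'   length).
#' @param gate A [polygon_gate()].
#' @return Logical vector, `TRUE` for points inside or on the boundary.
#' @export
point_in_polygon <- function(x, y, gate) {
  stopifnot(inherits(gate, "polygon_gate"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("point coordinates must be finite", call. = FALSE)
  vx <- gate$vertices[, 1L]
  vy <- gate$vertices[, 2L]
  nv <- length(vx)
  scale <- max(abs(c(vx, vy)), 1)
  eps <- 1e-9 * scale
  inside <- logical(n)
  on_edge <- logical(n)
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-edge test: point within the segment's bounding box and collinear
    dx <- x2 - x1; dy <- y2 - y1
    cross <- (x - x1) * dy - (y - y1) * dx
    seg_len <- sqrt(dx * dx + dy * dy)
    within <- x >= pmin(x1, x2) - eps & x <= pmax(x1, x2) + eps &
      y >= pmin(y1, y2) - eps & y <= pmax(y1, y2) + eps
    on_edge <- on_edge | (within & abs(cross) <= eps * max(seg_len, 1))
    # ray casting: horizontal ray to +infinity, half-open edge rule
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Two-stage gating of an event table
#'
#' Retains events inside the polygon gate on (dye, autofluorescence)
#' intensity and, when the area channel is present, inside the closed
#' brightfield-area range. Order is preserved and gating is idempotent. A
#' summary of counts removed by each gate is attached as attribute
#' `"gating_summary"`.
#'
#' @param events An [event_table()] carrying `intensity_dye` and
#'   `intensity_auto` columns (and optionally `area`).
#' @param polygon A [polygon_gate()]; default [default_cell_gate()].
#' @param area A [range_gate()]; default [default_area_gate()]. Ignored,
#'   with a note in the summary, when the table has no area column.
#' @return A gated [event_table()] (possibly empty).
#' @export
gate_cells <- function(events, polygon = default_cell_gate(),
                       area = default_area_gate()) {
  stopifnot(inherits(events, "event_table"),
            inherits(polygon, "polygon_gate"), inherits(area, "range_gate"))
  ev <- events$events
  n0 <- nrow(ev)
  if (n0 == 0L) {
    out <- events
    attr(out, "gating_summary") <- data.frame(
      stage = c("input", "polygon", "area"), retained = c(0L, 0L, 0L))
    return(out)
  }
  if (!"intensity_auto" %in% names(ev))
    stop("polygon gating requires an 'intensity_auto' column", call. = FALSE)
  keep_poly <- point_in_polygon(ev$intensity_dye, ev$intensity_auto, polygon)
  n_poly <- sum(keep_poly)
  if ("area" %in% names(ev)) {
    keep_area <- keep_poly & ev$area >= area$low & ev$area <= area$high
  } else {
    keep_area <- keep_poly
  }
  out <- events
  out$events <- ev[keep_area, , drop = FALSE]
  rownames(out$events) <- NULL
  attr(out, "gating_summary") <- data.frame(
    stage = c("input", "polygon", "area"),
    retained = c(n0, n_poly, sum(keep_area)),
    area_gate_applied = "area" %in% names(ev))
  out
}
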