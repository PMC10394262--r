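# Metric primitives: polyline length, calibration, alignment, point-to-polyline
# distance and threshold snapping. All distances here are in pixels unless a
# scale factor is applied by the caller.

# Coerce points to an n x 2 numeric matrix (columns x, y). Accepts a numeric
# vector of length 2, a 2-column matrix, or a data frame with x/y columns.
as_xy <- function(points, arg = "points") {
  if (is.data.frame(points)) {
    if (!all(c("x", "y") %in% names(points))) {
      abort(sprintf("`%s` data frame must have columns `x` and `y`.", arg))
    }
    m <- cbind(as.numeric(points$x), as.numeric(points$y))
  } else if (is.matrix(points)) {
    if (ncol(points) != 2) {
      abort(sprintf("`%s` matrix must have exactly 2 columns.", arg))
    }
    m <- matrix(as.numeric(points), ncol = 2, dimnames = NULL)
  } else if (is.numeric(points) && length(points) == 2) {
    m <- matrix(as.numeric(points), ncol = 2)
  } else {
    abort(sprintf("`%s` must be a 2-column matrix, an x/y data frame, or a length-2 numeric.", arg))
  }
  colnames(m) <- c("x", "y")
  if (!all(is.finite(m))) {
    abort(sprintf("`%s` contains non-finite coordinates.", arg))
  }
  m
}

#' Length of a polyline in pixels
#'
#' Sums the Euclidean lengths of consecutive straight segments of a traced
#' gallery. Length is additive under concatenation at a shared point and
#' invariant under translation and rotation.
#'
#' @param points Polyline vertices in order: a data frame with `x`/`y` columns
#'   or a 2-column matrix. At least 2 points.
#' @return Total length in pixels (a single non-negative number).
#' @examples
#' polyline_length(data.frame(x = c(0, 3), y = c(0, 4))) # 5
#' @export
polyline_length <- function(points) {
  m <- as_xy(points)
  if (nrow(m) < 2) {
    abort("A polyline needs at least 2 points; got a degenerate polyline.")
  }
  d <- diff(m)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Pixel-to-millimetre calibration from a scale line
#'
#' Converts the traced scale object (a line of known real-world length drawn
#' over the image) into a mm-per-pixel factor.
#'
#' @param scale_line The two endpoints of the traced scale object (2-row
#'   data frame or matrix).
#' @param scale_mm Real-world length of the scale object in millimetres.
#' @return Millimetres per pixel (positive scalar).
#' @examples
#' scale_factor(rbind(c(0, 0), c(100, 0)), scale_mm = 10) # 0.1
#' @export
scale_factor <- function(scale_line, scale_mm) {
  m <- as_xy(scale_line, "scale_line")
  if (nrow(m) != 2) {
    abort("`scale_line` must have exactly 2 points.")
  }
  if (!is.numeric(scale_mm) || length(scale_mm) != 1 || !is.finite(scale_mm) || scale_mm <= 0) {
    abort("`scale_mm` must be a single positive number.")
  }
  px <- polyline_length(m)
  if (px <= 0) {
    abort("Calibration failed: the scale line has zero pixel length.")
  }
  scale_mm / px
}

#' Align coordinates to a reference point
#'
#' Subtracts the clicked reference landmark from every coordinate so that
#' images taken with a repositioned camera share one frame. With no reference
#' point the coordinates are returned unchanged (the image's top-left corner,
#' the origin, acts as the landmark).
#'
#' @param points A data frame with `x`/`y` columns (other columns are kept) or
#'   a 2-column matrix.
#' @param ref_point The landmark as `c(x, y)`, or `NULL` for the origin.
#' @return `points` with the same shape, translated.
#' @export
translate_to_ref <- function(points, ref_point = NULL) {
  if (is.null(ref_point)) {
    return(points)
  }
  r <- as_xy(ref_point, "ref_point")
  if (nrow(r) != 1) {
    abort("`ref_point` must be a single point.")
  }
  if (is.data.frame(points)) {
    points$x <- points$x - r[1, 1]
    points$y <- points$y - r[1, 2]
    points
  } else {
    m <- as_xy(points)
    m[, 1] <- m[, 1] - r[1, 1]
    m[, 2] <- m[, 2] - r[1, 2]
    m
  }
}

#' Shortest distance from a point to a polyline
#'
#' Minimum Euclidean distance from `p` to any straight segment of the polyline
#' (the point is projected onto each segment, not just compared with the
#' clicked vertices), together with the arc-length position of the nearest
#' point along the polyline. This is the contact test behind branch
#' attachment and merge detection.
#'
#' @param p A single point `c(x, y)`.
#' @param points Polyline vertices (>= 2 points).
#' @return A list with `distance` (px), `arclength` (px position of the
#'   nearest point along the polyline) and `closest` (the nearest point,
#'   length-2 numeric).
#' @export
point_to_polyline_distance <- function(p, points) {
  pm <- as_xy(p, "p")
  if (nrow(pm) != 1) abort("`p` must be a single point.")
  m <- as_xy(points)
  if (nrow(m) < 2) abort("A polyline needs at least 2 points.")
  ptpd_impl(pm, m)
}

# fast path: pm a 1x2 matrix, m an n x 2 matrix, no validation
ptpd_impl <- function(pm, m) {
  a <- m[-nrow(m), , drop = FALSE]
  b <- m[-1, , drop = FALSE]
  ab <- b - a
  seg_len2 <- ab[, 1]^2 + ab[, 2]^2
  ap_x <- pm[1, 1] - a[, 1]
  ap_y <- pm[1, 2] - a[, 2]
  t <- ifelse(seg_len2 > 0, (ap_x * ab[, 1] + ap_y * ab[, 2]) / seg_len2, 0)
  t <- pmin(1, pmax(0, t))
  qx <- a[, 1] + t * ab[, 1]
  qy <- a[, 2] + t * ab[, 2]
  d <- sqrt((pm[1, 1] - qx)^2 + (pm[1, 2] - qy)^2)

  i <- which.min(d)
  seg_len <- sqrt(seg_len2)
  cum <- c(0, cumsum(seg_len))
  list(
    distance = unname(d[i]),
    arclength = unname(cum[i] + t[i] * seg_len[i]),
    closest = c(x = unname(qx[i]), y = unname(qy[i]))
  )
}

# Point on a polyline at a given arc-length position (clamped to [0, L]).
point_at_arclength <- function(points, s) {
  m <- as_xy(points)
  d <- diff(m)
  seg_len <- sqrt(d[, 1]^2 + d[, 2]^2)
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- min(max(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, nrow(m) - 1)
  t <- if (seg_len[i] > 0) (s - cum[i]) / seg_len[i] else 0
  c(x = unname(m[i, 1] + t * d[i, 1]), y = unname(m[i, 2] + t * d[i, 2]))
}

# Local direction (unit vector) of a polyline at arc-length s.
direction_at_arclength <- function(points, s) {
  m <- as_xy(points)
  d <- diff(m)
  seg_len <- sqrt(d[, 1]^2 + d[, 2]^2)
  cum <- c(0, cumsum(seg_len))
  i <- findInterval(min(max(s, 0), cum[length(cum)]), cum, rightmost.closed = TRUE)
  i <- min(i, nrow(m) - 1)
  if (seg_len[i] == 0) return(c(1, 0))
  unname(d[i, ] / seg_len[i])
}

#' Snap nearby points into shared nodes
#'
#' Partitions points into clusters by single-linkage: two points belong to the
#' same cluster whenever they are connected by a chain of pairs each strictly
#' closer than `threshold_px`. Gallery start/end points and branch attachment
#' points that fall in one cluster are treated as the same network node. Ties
#' at exactly the threshold do not merge. The partition does not depend on
#' the row order of the input.
#'
#' @param points A data frame with `x`/`y` columns (extra columns are kept).
#' @param threshold_px Snapping distance in pixels (> 0).
#' @return The input as a tibble with an integer `cluster` column (numbered by
#'   first appearance). Cluster centroids are available via
#'   [cluster_centers()].
#' @export
snap_endpoints <- function(points, threshold_px) {
  if (!is.numeric(threshold_px) || length(threshold_px) != 1 || threshold_px <= 0) {
    abort("`threshold_px` must be a single positive number.")
  }
  pts <- if (is.data.frame(points)) as_tibble(points) else as_tibble(as_xy(points))
  m <- as_xy(pts)
  n <- nrow(m)
  if (n == 0) {
    pts$cluster <- integer(0)
    return(pts)
  }

  # union-find over pairs with distance strictly below the threshold
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      dx <- m[(i + 1):n, 1] - m[i, 1]
      dy <- m[(i + 1):n, 2] - m[i, 2]
      hits <- which(dx * dx + dy * dy < threshold_px^2)
      for (j in i + hits) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  pts$cluster <- match(roots, unique(roots))
  pts
}

#' Centroids of snapped point clusters
#'
#' @param snapped Output of [snap_endpoints()].
#' @return A tibble with one row per cluster: `cluster`, centroid `x`, `y`,
#'   and member count `n`.
#' @export
cluster_centers <- function(snapped) {
  snapped |>
    group_by(.data$cluster) |>
    summarise(x = mean(.data$x), y = mean(.data$y), n = dplyr::n(), .groups = "drop") |>
    arrange(.data$cluster)
}
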