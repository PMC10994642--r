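#' Pixel-to-millimetre calibration factors
#'
#' @param fx mm per pixel along x (> 0).
#' @param fy mm per pixel along y (> 0).
#' @return A list of class `locog_calibration`.
#' @export
calibration <- function(fx, fy = fx) {
  fx <- as.numeric(fx); fy <- as.numeric(fy)
  if (!is.finite(fx) || !is.finite(fy) || fx <= 0 || fy <= 0) {
    stop_locog("calibration factors must be finite and > 0",
               "locog_validation_error")
  }
  structure(list(fx = fx, fy = fy), class = "locog_calibration")
}

#' Derive calibration from background-grid measurements
#'
#' Each measurement is a pair of clicked grid points of known physical
#' separation, labelled by the axis it measures. The factor per axis is the
#' mean of known_mm / |pixel separation along that axis| over its pairs,
#' mirroring how known grid distances are measured on the photograph.
#'
#' @param grid_points a data frame (or tibble) with columns `axis`
#'   (`"x"`/`"y"`), `x1`, `y1`, `x2`, `y2` (pixel coordinates of the pair)
#'   and `mm` (known distance).
#' @return A [calibration()].
#' @examples
#' g <- data.frame(axis = c("x", "y"), x1 = 0, y1 = 0,
#'                 x2 = c(40, 0), y2 = c(0, 40), mm = 10)
#' calibrate_from_grid(g)
#' @export
calibrate_from_grid <- function(grid_points) {
  g <- as.data.frame(grid_points)
  need <- c("axis", "x1", "y1", "x2", "y2", "mm")
  if (!all(need %in% names(g))) {
    stop_locog(paste("grid measurements need columns:", paste(need, collapse = ", ")),
               "locog_schema_error")
  }
  if (!all(g$axis %in% c("x", "y")) || !any(g$axis == "x") || !any(g$axis == "y")) {
    stop_locog("need at least one measurement per axis, labelled 'x' or 'y'",
               "locog_validation_error")
  }
  if (any(g$mm <= 0)) {
    stop_locog("known distances must be positive", "locog_validation_error")
  }
  dpx <- ifelse(g$axis == "x", abs(g$x2 - g$x1), abs(g$y2 - g$y1))
  if (any(dpx == 0)) {
    stop_locog("degenerate calibration: zero pixel separation along the measured axis",
               "locog_degenerate_error")
  }
  f <- g$mm / dpx
  calibration(fx = mean(f[g$axis == "x"]), fy = mean(f[g$axis == "y"]))
}

#' Hand map: calibration, digit axes, and region geometry for one hand
#'
#' @param calibration a [calibration()].
#' @param digit_axes named numeric vector `D1..D5` of axis angles in degrees,
#'   measured from the image's lower edge to the digit midline, in \[0, 180).
#' @param regions named list `D1..D5`, `palm` of polygons (n x 2 matrices of
#'   pixel coordinates, implicitly closed).
#' @param crease polyline (n x 2 matrix) separating digits from palm.
#' @return A list of class `locog_handmap`.
#' @export
hand_map <- function(calibration, digit_axes, regions, crease) {
  structure(
    list(calibration = calibration,
         digit_axes = digit_axes[DIGITS],
         regions = regions[REGIONS],
         crease = crease),
    class = "locog_handmap"
  )
}

#' Validate a hand map
#'
#' Checks digit axes (all five digits present, angles in \[0, 180)), region
#' polygons (all six present, simple, digit interiors pairwise disjoint), the
#' crease polyline, and — when targets are supplied — that every target lies
#' inside its own digit's polygon.
#'
#' @param hm a `locog_handmap`.
#' @param targets optional target tibble (`id`, `digit`, `x`, `y`).
#' @return `hm`, invisibly.
#' @export
validate_hand_map <- function(hm, targets = NULL) {
  ax <- hm$digit_axes
  if (is.null(names(ax)) || !all(DIGITS %in% names(ax)) || anyNA(ax[DIGITS])) {
    stop_locog("digit_axes must name all of D1..D5", "locog_config_error")
  }
  if (any(ax < 0 | ax >= 180)) {
    stop_locog("digit axis angles must lie in [0, 180) degrees",
               "locog_validation_error")
  }
  if (!all(REGIONS %in% names(hm$regions))) {
    stop_locog("regions must name D1..D5 and palm", "locog_config_error")
  }
  for (r in REGIONS) {
    poly <- hm$regions[[r]]
    if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3) {
      stop_locog(paste0("region ", r, " is not an n x 2 polygon (n >= 3)"),
                 "locog_validation_error")
    }
    if (!polygon_is_simple(poly)) {
      stop_locog(paste0("region ", r, " polygon self-intersects"),
                 "locog_validation_error")
    }
  }
  for (i in 1:4) for (j in (i + 1):5) {
    if (polygons_overlap(hm$regions[[DIGITS[i]]], hm$regions[[DIGITS[j]]])) {
      stop_locog(paste0("digit polygons ", DIGITS[i], " and ", DIGITS[j],
                        " have overlapping interiors"), "locog_validation_error")
    }
  }
  if (!is.matrix(hm$crease) || ncol(hm$crease) != 2 || nrow(hm$crease) < 2) {
    stop_locog("crease must be an n x 2 polyline (n >= 2)", "locog_validation_error")
  }
  if (!is.null(targets)) {
    for (i in seq_len(nrow(targets))) {
      poly <- hm$regions[[targets$digit[i]]]
      inside <- point_in_polygon(targets$x[i], targets$y[i], poly)
      if (!(inside$interior || inside$boundary)) {
        stop_locog(sprintf("target %s lies outside its digit polygon (%s)",
                           targets$id[i], targets$digit[i]),
                   "locog_validation_error")
      }
    }
  }
  invisible(hm)
}

# ---- low-level polygon predicates --------------------------------------

segments_of <- function(poly) {
  n <- nrow(poly)
  list(x1 = poly[, 1], y1 = poly[, 2],
       x2 = poly[c(2:n, 1), 1], y2 = poly[c(2:n, 1), 2])
}

# squared distance from point to each segment of a polyline/polygon
point_segdist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 == 0, 0, pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2)))
  cx <- x1 + t * dx; cy <- y1 + t * dy
  (px - cx)^2 + (py - cy)^2
}

# interior + boundary test for a single point against a polygon.
# Interior via even-odd ray casting (mgcv::in.out); boundary via
# point-to-edge distance within tolerance (pixels).
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  s <- segments_of(poly)
  on_bd <- min(point_segdist2(px, py, s$x1, s$y1, s$x2, s$y2)) <= tol^2
  interior <- as.logical(mgcv::in.out(poly, matrix(c(px, py), 1)))
  list(interior = interior && !on_bd, boundary = on_bd)
}

on_polyline <- function(px, py, line, tol = 1e-9) {
  n <- nrow(line)
  min(point_segdist2(px, py, line[-n, 1], line[-n, 2],
                     line[-1, 1], line[-1, 2])) <= tol^2
}

seg_intersects <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  # proper intersection test (shared endpoints ignored) for simplicity checks
  d <- function(x1, y1, x2, y2, x3, y3) (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
  d1 <- d(bx1, by1, bx2, by2, ax1, ay1)
  d2 <- d(bx1, by1, bx2, by2, ax2, ay2)
  d3 <- d(ax1, ay1, ax2, ay2, bx1, by1)
  d4 <- d(ax1, ay1, ax2, ay2, bx2, by2)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  s <- segments_of(poly)
  for (i in seq_len(n - 1)) {
    js <- setdiff(seq(i + 1, n), c(i, i %% n + 1, (i - 2) %% n + 1))
    for (j in js) {
      if (seg_intersects(s$x1[i], s$y1[i], s$x2[i], s$y2[i],
                         s$x1[j], s$y1[j], s$x2[j], s$y2[j])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

polygons_overlap <- function(a, b) {
  # interiors overlap if any vertex of one lies strictly inside the other,
  # or any edges properly cross
  for (i in seq_len(nrow(a))) {
    r <- point_in_polygon(a[i, 1], a[i, 2], b)
    if (r$interior) return(TRUE)
  }
  for (i in seq_len(nrow(b))) {
    r <- point_in_polygon(b[i, 1], b[i, 2], a)
    if (r$interior) return(TRUE)
  }
  sa <- segments_of(a); sb <- segments_of(b)
  for (i in seq_along(sa$x1)) {
    if (any(seg_intersects(sa$x1[i], sa$y1[i], sa$x2[i], sa$y2[i],
                           sb$x1, sb$y1, sb$x2, sb$y2))) {
      return(TRUE)
    }
  }
  FALSE
}

polygon_centroid <- function(poly) {
  c(mean(poly[, 1]), mean(poly[, 2]))
}
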