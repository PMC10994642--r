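#' Classify response points into hand regions
#'
#' Point-in-polygon classification over the six regions (`D1`..`D5`, `palm`)
#' with the boundary rules used for scoring:
#'
#' * a point lying exactly on the digit-palm crease belongs to the adjoining
#'   digit, never the palm;
#' * a point strictly palm-side of the crease that is in no digit polygon is
#'   the palm (even just outside the palm polygon's own outline);
#' * a point on a boundary shared by two digits goes to the digit whose
#'   midline (axis line through the digit polygon centroid) is nearest, ties
#'   to the lower-indexed digit;
#' * a point in no region and not palm-side of the crease is
#'   `"unclassifiable"`.
#'
#' @param points an n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @param hm a [hand_map()].
#' @param tol boundary tolerance in pixels.
#' @return Character vector of region labels (`D1`..`D5`, `palm`,
#'   `unclassifiable`).
#' @export
assign_region <- function(points, hm, tol = 1e-9) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  n <- nrow(points)
  px <- points[, 1]; py <- points[, 2]

  min_d2 <- function(x1, y1, x2, y2) {
    d2 <- rep(Inf, n)
    for (k in seq_along(x1)) {
      d2 <- pmin(d2, point_segdist2(px, py, x1[k], y1[k], x2[k], y2[k]))
    }
    d2
  }
  member <- matrix(FALSE, n, length(REGIONS), dimnames = list(NULL, REGIONS))
  for (r in REGIONS) {
    poly <- hm$regions[[r]]
    s <- segments_of(poly)
    on_bd <- min_d2(s$x1, s$y1, s$x2, s$y2) <= tol^2
    inside <- as.logical(mgcv::in.out(poly, points))
    member[, r] <- inside | on_bd
  }
  cr <- hm$crease
  ncr <- nrow(cr)
  on_crease <- min_d2(cr[-ncr, 1], cr[-ncr, 2], cr[-1, 1], cr[-1, 2]) <= tol^2

  # signed perpendicular distance of each point to each digit midline
  mid_dist <- vapply(DIGITS, function(d) {
    ctr <- polygon_centroid(hm$regions[[d]])
    t <- hm$digit_axes[[d]] * pi / 180
    abs((px - ctr[1]) * sin(t) + (py - ctr[2]) * cos(t))
  }, numeric(n))
  if (n == 1) mid_dist <- matrix(mid_dist, nrow = 1, dimnames = list(NULL, DIGITS))

  nearest_digit <- function(i, candidates) {
    d <- mid_dist[i, candidates]
    candidates[which.min(d)]  # which.min takes the first (lower index) on ties
  }
  palm_side <- py > crease_y_at(hm$crease, px)

  out <- character(n)
  for (i in seq_len(n)) {
    hits <- DIGITS[member[i, DIGITS]]
    if (length(hits) == 1) {
      out[i] <- hits
    } else if (length(hits) > 1) {
      out[i] <- nearest_digit(i, hits)
    } else if (on_crease[i]) {
      out[i] <- nearest_digit(i, DIGITS)
    } else if (member[i, "palm"] || palm_side[i]) {
      out[i] <- "palm"
    } else {
      out[i] <- "unclassifiable"
    }
  }
  out
}

# y of the crease polyline at given x (piecewise linear, clamped to the
# nearest endpoint outside the polyline's x-range)
crease_y_at <- function(crease, x) {
  ord <- order(crease[, 1])
  cx <- crease[ord, 1]; cy <- crease[ord, 2]
  stats::approx(cx, cy, xout = pmin(pmax(x, min(cx)), max(cx)),
                ties = "ordered")$y
}

#' Label every trial of a session as on-target or misreferral
#'
#' A misreferral is a response landing on a different digit than the one
#' stimulated, or on the palm. Error vectors are computed only for
#' non-misreferral trials (error magnitude is undefined across digits).
#' Unclassifiable responses (outside every region and not palm-side of the
#' crease) are flagged with `is_misreferral = NA` and logged with a warning.
#'
#' @param s a `locog_session`.
#' @param mode decomposition mode passed to [error_vector()].
#' @return A tibble with one row per trial: `block`, `target_id`, `digit`,
#'   `subzone`, `response_region`, `is_misreferral`, `ex`, `ey`, `e_abs`,
#'   `e_long`, `e_trans` (errors `NA` for misreferrals).
#' @export
detect_misreferrals <- function(s, mode = c("orthogonal", "as_printed")) {
  mode <- match.arg(mode)
  hm <- s$hand_map
  tr <- s$trials
  tg <- s$targets[match(tr$target_id, s$targets$id), ]
  region <- assign_region(cbind(tr$x, tr$y), hm)
  if (any(region == "unclassifiable")) {
    warning(sprintf("%d response(s) unclassifiable; flagged and excluded",
                    sum(region == "unclassifiable")), call. = FALSE)
  }
  is_mis <- ifelse(region == "unclassifiable", NA, region != tg$digit)
  ex <- (tr$x - tg$x) * hm$calibration$fx
  ey <- (tr$y - tg$y) * hm$calibration$fy
  theta <- hm$digit_axes[tg$digit]
  d <- decompose_error(ex, ey, theta, s$hand_side, mode)
  keep <- !is.na(is_mis) & !is_mis
  na_out <- function(v) ifelse(keep, v, NA_real_)
  tibble::tibble(
    block = tr$block,
    target_id = tr$target_id,
    digit = tg$digit,
    subzone = tg$subzone,
    response_region = region,
    is_misreferral = is_mis,
    ex = na_out(ex),
    ey = na_out(ey),
    e_abs = na_out(sqrt(ex^2 + ey^2)),
    e_long = na_out(d$e_long),
    e_trans = na_out(d$e_trans)
  )
}
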