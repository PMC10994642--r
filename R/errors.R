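#' Localization error vector for one target-response pair
#'
#' `Ex`/`Ey` are the calibrated signed differences (response minus target) in
#' mm. `e_abs` is the Euclidean distance. The directional decomposition uses
#' the digit's axis angle (degrees from the image's lower edge to the digit
#' midline):
#'
#' * `mode = "orthogonal"` (default) projects the error onto the unit distal
#'   axis and the unit ulnar perpendicular. With raster coordinates (y down,
#'   fingertips up) the distal axis is `(cos t, -sin t)`, so
#'   `e_long = Ex cos(t) - Ey sin(t)` (positive = distal) and
#'   `e_trans = s (Ex sin(t) + Ey cos(t))` with `s = +1` for right hands and
#'   `-1` for left hands (positive = ulnar on either hand). This conserves
#'   magnitude: `e_long^2 + e_trans^2 = e_abs^2`.
#' * `mode = "as_printed"` applies the legacy formulas
#'   `e_long = Ex sin(t) + Ey cos(t)` and `e_trans = Ex cos(t) + Ey sin(t)`
#'   verbatim. These are not orthogonal (their squares do not sum to
#'   `e_abs^2` except at special angles) and carry no hand-side mirror; they
#'   are provided for literal reproduction of the legacy computation.
#'
#' @param target one-row target (list or tibble row with `digit`, `x`, `y`).
#' @param response_px numeric length-2 response (pixels).
#' @param hm the session's [hand_map()].
#' @param hand_side `"left"` or `"right"`.
#' @param mode `"orthogonal"` or `"as_printed"`.
#' @return A list of class `locog_error` with fields `ex`, `ey`, `e_abs`,
#'   `e_long`, `e_trans`, `mode`.
#' @export
error_vector <- function(target, response_px, hm,
                         hand_side = c("right", "left"),
                         mode = c("orthogonal", "as_printed")) {
  hand_side <- match.arg(hand_side)
  mode <- match.arg(mode)
  theta_deg <- hm$digit_axes[[target$digit]]
  if (is.null(theta_deg) || is.na(theta_deg)) {
    stop_locog(paste0("no axis angle configured for digit ", target$digit),
               "locog_config_error")
  }
  ex <- (response_px[[1]] - target$x) * hm$calibration$fx
  ey <- (response_px[[2]] - target$y) * hm$calibration$fy
  d <- decompose_error(ex, ey, theta_deg, hand_side, mode)
  structure(list(ex = ex, ey = ey, e_abs = sqrt(ex^2 + ey^2),
                 e_long = d$e_long, e_trans = d$e_trans, mode = mode),
            class = "locog_error")
}

# vectorized decomposition core (ex, ey in mm; theta in degrees)
decompose_error <- function(ex, ey, theta_deg, hand_side, mode) {
  t <- theta_deg * pi / 180
  if (mode == "as_printed") {
    list(e_long = ex * sin(t) + ey * cos(t),
         e_trans = ex * cos(t) + ey * sin(t))
  } else {
    s <- ifelse(hand_side == "right", 1, -1)
    list(e_long = ex * cos(t) - ey * sin(t),
         e_trans = s * (ex * sin(t) + ey * cos(t)))
  }
}

#' Aggregate error metrics over a target subset
#'
#' Means of the absolute, longitudinal and transverse errors over the
#' non-misreferral trials whose target belongs to `target_subset`;
#' misreferrals in the subset are counted but excluded from the means.
#'
#' @param metrics per-trial metrics from [detect_misreferrals()] (one session).
#' @param target_subset character vector of target ids (default: all).
#' @return A list with `mean_abs`, `mean_long`, `mean_trans`, `n_trials`
#'   (trials contributing to the means) and `n_excluded` (misreferrals or
#'   unclassifiable responses in the subset).
#' @export
aggregate_errors <- function(metrics, target_subset = unique(metrics$target_id)) {
  m <- metrics[metrics$target_id %in% target_subset, ]
  if (nrow(m) == 0) {
    stop_locog("no trials in the requested target subset", "locog_validation_error")
  }
  keep <- !m$is_misreferral & !is.na(m$e_abs)
  if (!any(keep)) {
    stop_locog("all trials in the subset are misreferrals; aggregate undefined",
               "locog_undefined_aggregate_error")
  }
  list(mean_abs = mean(m$e_abs[keep]),
       mean_long = mean(m$e_long[keep]),
       mean_trans = mean(m$e_trans[keep]),
       n_trials = sum(keep),
       n_excluded = sum(!keep))
}

#' Mirror a session across a vertical image axis
#'
#' Reflects all geometry (targets, responses, region polygons, crease) as
#' `x -> 2 cx - x`, flips the hand side, and mirrors the digit axis angles
#' (`t -> 180 - t`, taken mod 180). Canonical error metrics are invariant
#' under this operation, which is also how left-hand photographs can be
#' brought into a right-hand frame.
#'
#' @param s a `locog_session`.
#' @param cx x coordinate of the mirror axis (pixels); defaults to the mean
#'   target x.
#' @return The mirrored `locog_session`.
#' @export
mirror_session <- function(s, cx = mean(s$targets$x)) {
  flip <- function(m) { m[, 1] <- 2 * cx - m[, 1]; m }
  hm <- s$hand_map
  hm$regions <- lapply(hm$regions, flip)
  hm$crease <- flip(hm$crease)
  hm$digit_axes <- (180 - hm$digit_axes) %% 180
  s$hand_map <- hm
  s$targets$x <- 2 * cx - s$targets$x
  s$trials$x <- 2 * cx - s$trials$x
  s$hand_side <- if (s$hand_side == "right") "left" else "right"
  s
}
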