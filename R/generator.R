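#' Ground-truth parameters for the synthetic session generator
#'
#' Defaults emulate the published group-level picture of healthy and
#' nerve-injured hands:
#'
#' * `error_sd_mm = 4`: per-component response scatter of a healthy digit.
#'   Absolute error magnitudes are only ever shown graphically in the source
#'   figures, so this is a chosen, realistic value, not an anchored one.
#' * `long_bias_mm = -3`: mean longitudinal error; negative = proximal, the
#'   direction of the well-documented proximal response bias.
#' * `trans_bias_mm`: per-digit mean transverse error; healthy hands carry a
#'   small radial (negative) bias of -1.1 mm on D5 and none elsewhere.
#' * `injury_inflation = 2.5`: multiplicative scatter factor on digits inside
#'   the injured territory (chosen).
#' * `injured_trans_bias_d5_mm = -7.05`: D5 transverse bias when the ulnar
#'   nerve is injured (additional to territory inflation).
#' * `misreferral_rate_control = 0.02` / `misreferral_rate_injured = 0.10`:
#'   per-trial misreferral probability for healthy-territory and
#'   injured-territory stimulations (chosen).
#' * `confusion_kernel_control` / `confusion_kernel_patient`: joint (from,
#'   to) distributions of misreferral events. The control kernel puts 0.74 of
#'   its mass on the D3-D4 confusion pair and never refers to the palm; the
#'   patient kernel is diffuse with distance decay and includes the palm.
#'
#' @param ... named overrides of any default.
#' @return A list of class `locog_generator_params`.
#' @export
generator_params <- function(...) {
  p <- list(
    error_sd_mm = 4,
    long_bias_mm = -3,
    trans_bias_mm = c(D1 = 0, D2 = 0, D3 = 0, D4 = 0, D5 = -1.1),
    injury_inflation = 2.5,
    injured_trans_bias_d5_mm = -7.05,
    misreferral_rate_control = 0.02,
    misreferral_rate_injured = 0.10,
    confusion_kernel_control = control_confusion_kernel(),
    confusion_kernel_patient = patient_confusion_kernel(),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) {
    stop_locog(paste("unknown generator parameter(s):", paste(bad, collapse = ", ")),
               "locog_config_error")
  }
  p[names(over)] <- over
  validate_generator_params(structure(p, class = "locog_generator_params"))
}

validate_generator_params <- function(p) {
  if (p$error_sd_mm <= 0 || p$injury_inflation <= 0) {
    stop_locog("scatter parameters must be > 0", "locog_validation_error")
  }
  for (r in c(p$misreferral_rate_control, p$misreferral_rate_injured)) {
    if (r < 0 || r > 1) stop_locog("misreferral rates must lie in [0, 1]",
                                   "locog_validation_error")
  }
  for (k in list(p$confusion_kernel_control, p$confusion_kernel_patient)) {
    if (!is.matrix(k) || !identical(dim(k), c(5L, 6L)) || any(k < 0) ||
        abs(sum(k) - 1) > 1e-9 || any(diag(k[, 1:5]) != 0)) {
      stop_locog("confusion kernels must be 5x6, nonnegative, zero-diagonal, summing to 1",
                 "locog_validation_error")
    }
  }
  p
}

#' Default healthy-hand confusion kernel
#'
#' Joint (from, to) distribution of misreferral events in healthy hands:
#' 0.74 of the mass on the D3<->D4 pair, the rest on other adjacent-digit
#' confusions, none to the palm.
#' @return 5 x 6 matrix (rows D1-D5, columns D1-D5 + palm) summing to 1.
#' @export
control_confusion_kernel <- function() {
  k <- matrix(0, 5, 6, dimnames = list(DIGITS, REGIONS))
  k["D3", "D4"] <- 0.37
  k["D4", "D3"] <- 0.37
  k["D2", "D3"] <- 0.05
  k["D3", "D2"] <- 0.05
  k["D4", "D5"] <- 0.05
  k["D5", "D4"] <- 0.05
  k["D1", "D2"] <- 0.03
  k["D2", "D1"] <- 0.03
  k
}

#' Default injured-hand confusion kernel
#'
#' Diffuse joint (from, to) distribution: weight decays with inter-digit
#' distance (1, 1/2, 1/4, 1/8) and every digit also refers to the palm with
#' the weight of an adjacent digit, emulating the broadened misreferral
#' pattern after nerve injury.
#' @return 5 x 6 matrix summing to 1.
#' @export
patient_confusion_kernel <- function() {
  k <- matrix(0, 5, 6, dimnames = list(DIGITS, REGIONS))
  for (i in 1:5) {
    for (j in 1:5) if (j != i) k[i, j] <- 2^(-(abs(i - j) - 1))
    k[i, "palm"] <- 1
  }
  k / sum(k)
}

# stylized right-hand geometry in mm (origin top-left, y down, tips up).
# Digits are deliberately generous (40 mm wide, 70-105 mm long): wide enough
# that the on-digit rejection sampling of responses truncates the planted
# Gaussian scatter only mildly, so planted biases and scatter inflation stay
# recoverable by the analysis chain.
HAND_GEOM <- list(
  centers_x = c(D1 = 30, D2 = 74, D3 = 118, D4 = 162, D5 = 206),
  half_width = 20,
  lengths = c(D1 = 70, D2 = 95, D3 = 105, D4 = 100, D5 = 90),
  crease_y = 150,
  palm_bottom = 240,
  target_depths = c(distal = 16, proximal = 26),
  target_offset = 5
)

#' Generate a stylized hand map with the standard 18-target layout
#'
#' Builds a synthetic photographed hand: five rectangular digit polygons
#' (30 mm wide, 45-75 mm long, 4 mm apart) above a horizontal digit-palm
#' crease, a palm polygon below it, near-vertical digit axes with a small
#' angular jitter, and a calibration close to 0.25 mm/px (jittered per hand
#' and per axis). Targets sit in the subzone quadrants of each distal pad
#' (+-4 mm transverse, 10 and 20 mm from the tip); the thumb carries only the
#' two radial subzones. Left hands are mirrored geometrically.
#'
#' @param seed integer seed (determinism: same seed, same map).
#' @param hand_side `"right"` or `"left"`.
#' @return A list with elements `map` (a [hand_map()]) and `targets`
#'   (tibble `id`, `digit`, `subzone`, `x`, `y` in px).
#' @export
generate_hand_map <- function(seed = 1L, hand_side = c("right", "left")) {
  hand_side <- match.arg(hand_side)
  withr::with_seed(seed, {
    g <- HAND_GEOM
    fx <- 0.25 * (1 + runif(1, -0.02, 0.02))
    fy <- 0.25 * (1 + runif(1, -0.02, 0.02))
    axes <- pmin(pmax(90 + rnorm(5, 0, 3), 75), 105)
    names(axes) <- DIGITS
    regions <- list()
    for (d in DIGITS) {
      cx <- g$centers_x[[d]]
      tip <- g$crease_y - g$lengths[[d]]
      regions[[d]] <- cbind(
        c(cx - g$half_width, cx + g$half_width, cx + g$half_width, cx - g$half_width),
        c(tip, tip, g$crease_y, g$crease_y)
      )
    }
    span <- range(g$centers_x) + c(-1, 1) * (g$half_width + 5)
    regions$palm <- cbind(c(span[1], span[2], span[2], span[1]),
                          c(g$crease_y, g$crease_y, g$palm_bottom, g$palm_bottom))
    crease <- cbind(span, c(g$crease_y, g$crease_y))

    radial_sign <- -1  # right hand, palmar view: radial (thumb) side at -x
    rows <- list()
    for (d in DIGITS) {
      cx <- g$centers_x[[d]]
      tip <- g$crease_y - g$lengths[[d]]
      subz <- if (d == "D1") SUBZONES[1:2] else SUBZONES
      for (sz in subz) {
        side <- if (grepl("^radial", sz)) radial_sign else -radial_sign
        depth <- if (grepl("distal$", sz)) g$target_depths[["distal"]] else g$target_depths[["proximal"]]
        rows[[length(rows) + 1]] <- tibble::tibble(
          digit = d, subzone = sz,
          x = cx + side * g$target_offset, y = tip + depth)
      }
    }
    targets <- dplyr::bind_rows(rows)
    targets$id <- sprintf("T%02d", seq_len(nrow(targets)))
    if (hand_side == "left") {
      cx_mid <- mean(range(g$centers_x))
      flip <- function(m) { m[, 1] <- 2 * cx_mid - m[, 1]; m }
      regions <- lapply(regions, flip)
      crease <- flip(crease)
      targets$x <- 2 * cx_mid - targets$x
      axes <- (180 - axes) %% 180
    }
    # emit in pixels
    to_px <- function(m) { m[, 1] <- m[, 1] / fx; m[, 2] <- m[, 2] / fy; m }
    regions <- lapply(regions, to_px)
    crease <- to_px(crease)
    targets$x <- targets$x / fx
    targets$y <- targets$y / fy
    map <- hand_map(calibration(fx, fy), axes, regions, crease)
    list(map = map,
         targets = targets[, c("id", "digit", "subzone", "x", "y")])
  })
}

territory_digits <- function(nerve) {
  switch(nerve,
         median = c("D1", "D2", "D3", "D4"),
         ulnar = c("D4", "D5"),
         both = DIGITS)
}

# per-digit misreferral probability within a territory class, shaped so the
# joint (from, to) distribution of misreferral events equals the kernel and
# the expected overall rate within the class equals `rate`
class_misreferral_probs <- function(digits, kernel, rate, n_targets) {
  row_mass <- rowSums(kernel[digits, , drop = FALSE])
  if (sum(row_mass) == 0) return(setNames(rep(0, length(digits)), digits))
  j <- row_mass / sum(row_mass)
  n_class <- sum(n_targets[digits])
  pmin(1, rate * j * n_class / n_targets[digits])
}

uniform_point_in_polygon <- function(poly) {
  bb <- apply(poly, 2, range)
  repeat {
    p <- c(runif(1, bb[1, 1], bb[2, 1]), runif(1, bb[1, 2], bb[2, 2]))
    hit <- point_in_polygon(p[1], p[2], poly)
    if (hit$interior) return(p)
  }
}

#' Generate one synthetic test session
#'
#' Simulates five blocks over the standard 18-target layout. Each trial is a
#' misreferral with a per-digit probability shaped by the confusion kernel
#' (overall rate = the configured misreferral rate for the digit's territory
#' status); misreferral responses are placed uniformly inside the
#' kernel-drawn destination region. Other responses are the target plus the
#' planted bias and Gaussian scatter expressed in the digit frame
#' (longitudinal/transverse, rotated through the digit axis), rejection-
#' sampled to stay on the stimulated digit, and inflated within the injured
#' territory for `role = "patient_injured"`.
#'
#' @param params a [generator_params()].
#' @param role `"control"`, `"patient_injured"` or `"patient_uninjured"`.
#' @param nerve nerve condition for patients: `"median"`, `"ulnar"`, `"both"`.
#' @param hand_side `"right"` or `"left"`.
#' @param hand_role stored role of this hand; defaults to `"dominant"` for
#'   controls and `"injured"`/`"uninjured"` for patients.
#' @param participant_id id recorded in the session.
#' @param seed integer seed (defaults to `params$seed`).
#' @return A validated `locog_session`.
#' @export
generate_session <- function(params = generator_params(),
                             role = c("control", "patient_injured", "patient_uninjured"),
                             nerve = NULL,
                             hand_side = c("right", "left"),
                             hand_role = NULL,
                             participant_id = "S01",
                             seed = params$seed) {
  role <- match.arg(role)
  hand_side <- match.arg(hand_side)
  if (role != "control") {
    if (is.null(nerve) || !nerve %in% c("median", "ulnar", "both")) {
      stop_locog("patients need nerve = median/ulnar/both", "locog_config_error")
    }
  }
  if (is.null(hand_role)) {
    hand_role <- switch(role, control = "dominant",
                        patient_injured = "injured",
                        patient_uninjured = "uninjured")
  }
  if (!all(REGIONS %in% colnames(params$confusion_kernel_control))) {
    stop_locog("kernel columns must name D1..D5 and palm", "locog_config_error")
  }

  hmres <- generate_hand_map(seed = seed, hand_side = hand_side)
  hm <- hmres$map
  targets <- hmres$targets
  n_targets <- table(factor(targets$digit, levels = DIGITS))
  n_targets <- setNames(as.integer(n_targets), DIGITS)

  injured_set <- if (role == "patient_injured") territory_digits(nerve) else character(0)
  mis_p <- setNames(numeric(5), DIGITS)
  if (length(injured_set) > 0) {
    mis_p[injured_set] <- class_misreferral_probs(
      injured_set, params$confusion_kernel_patient,
      params$misreferral_rate_injured, n_targets)
    healthy <- setdiff(DIGITS, injured_set)
    if (length(healthy) > 0) {
      mis_p[healthy] <- class_misreferral_probs(
        healthy, params$confusion_kernel_control,
        params$misreferral_rate_control, n_targets)
    }
  } else {
    mis_p[DIGITS] <- class_misreferral_probs(
      DIGITS, params$confusion_kernel_control,
      params$misreferral_rate_control, n_targets)
  }

  s_ulnar <- if (hand_side == "right") 1 else -1
  withr::with_seed(seed + 1L, {
    trials <- dplyr::bind_rows(lapply(1:5, function(b) {
      tibble::tibble(block = b, target_id = sample(targets$id))
    }))
    tg <- targets[match(trials$target_id, targets$id), ]
    n <- nrow(trials)
    is_mis <- rbinom(n, 1, mis_p[tg$digit]) == 1
    rx <- numeric(n); ry <- numeric(n)

    # misreferral responses: kernel-drawn destination, uniform in its polygon
    for (i in which(is_mis)) {
      d <- tg$digit[i]
      kernel <- if (d %in% injured_set) params$confusion_kernel_patient
                else params$confusion_kernel_control
      w <- kernel[d, ]
      if (sum(w) == 0) { is_mis[i] <- FALSE; next }
      dest <- sample(REGIONS, 1, prob = w)
      if (is.null(hm$regions[[dest]])) {
        stop_locog(paste0("kernel names region absent from map: ", dest),
                   "locog_config_error")
      }
      p <- uniform_point_in_polygon(hm$regions[[dest]])
      rx[i] <- p[1]; ry[i] <- p[2]
    }

    # on-digit responses: digit-frame Gaussian around the target, redrawn
    # until inside the stimulated digit polygon
    for (d in DIGITS) {
      idx <- which(!is_mis & tg$digit == d)
      if (length(idx) == 0) next
      sd_d <- params$error_sd_mm *
        if (d %in% injured_set) params$injury_inflation else 1
      tb <- params$trans_bias_mm[[d]]
      if (d == "D5" && d %in% injured_set) tb <- params$injured_trans_bias_d5_mm
      t <- hm$digit_axes[[d]] * pi / 180
      poly <- hm$regions[[d]]
      pending <- idx
      guard <- 0L
      while (length(pending) > 0) {
        m <- length(pending)
        L <- rnorm(m, params$long_bias_mm, sd_d)
        Tr <- rnorm(m, tb, sd_d)
        dx_mm <- L * cos(t) + s_ulnar * Tr * sin(t)
        dy_mm <- -L * sin(t) + s_ulnar * Tr * cos(t)
        px <- tg$x[pending] + dx_mm / hm$calibration$fx
        py <- tg$y[pending] + dy_mm / hm$calibration$fy
        inside <- as.logical(mgcv::in.out(poly, cbind(px, py)))
        ok <- pending[inside]
        rx[ok] <- px[inside]; ry[ok] <- py[inside]
        pending <- pending[!inside]
        guard <- guard + 1L
        if (guard > 1000L) {
          # pathological parameters: collapse the remainder onto the target
          rx[pending] <- tg$x[pending]; ry[pending] <- tg$y[pending]
          break
        }
      }
    }
    trials$x <- rx
    trials$y <- ry
  })

  part <- if (role == "control") {
    participant(participant_id, "control")
  } else {
    inj_side <- if (role == "patient_injured") hand_side else setdiff(c("left", "right"), hand_side)
    nerves <- if (nerve == "both") c("median", "ulnar") else nerve
    participant(participant_id, "patient",
                injury = injury_record(nerves, "complete", inj_side,
                                       months_since_repair = 24))
  }
  session(part, hand_side, hand_role, hm, targets, trials)
}

#' Generate a full synthetic cohort
#'
#' Controls with two hands each (dominant/nondominant) and patients with an
#' injured and an uninjured hand, with per-participant seeds derived from
#' `seed`.
#'
#' @param composition named patient counts, e.g.
#'   `c(median = 5, ulnar = 8, both = 5)`.
#' @param n_controls number of controls.
#' @param params a [generator_params()].
#' @param seed integer base seed.
#' @return A list with `patients` (named list of
#'   `list(nerve, injured, uninjured)`) and `controls` (named list of
#'   `list(dominant, nondominant)`).
#' @export
generate_cohort <- function(composition = c(median = 5, ulnar = 8, both = 5),
                            n_controls = 33,
                            params = generator_params(),
                            seed = 1L) {
  nerves <- rep(names(composition), composition)
  patients <- list()
  for (i in seq_along(nerves)) {
    id <- sprintf("P%02d", i)
    base <- seed + 1000L + 10L * i
    patients[[id]] <- list(
      nerve = nerves[i],
      injured = generate_session(params, "patient_injured", nerves[i],
                                 hand_side = "right", participant_id = id,
                                 seed = base),
      uninjured = generate_session(params, "patient_uninjured", nerves[i],
                                   hand_side = "left", participant_id = id,
                                   seed = base + 1L)
    )
  }
  controls <- list()
  for (i in seq_len(n_controls)) {
    id <- sprintf("C%02d", i)
    base <- seed + 100000L + 10L * i
    controls[[id]] <- list(
      dominant = generate_session(params, "control", hand_side = "right",
                                  hand_role = "dominant", participant_id = id,
                                  seed = base),
      nondominant = generate_session(params, "control", hand_side = "left",
                                     hand_role = "nondominant",
                                     participant_id = id, seed = base + 1L)
    )
  }
  list(patients = patients, controls = controls)
}
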