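# shared fixtures and independent oracles, all built in code

# A tiny hand map with exactly known geometry, in a 0.25 mm/px frame:
# two-digit checks use D2/D3 which share a vertical edge at x = 100.
# D1, D4, D5 sit far left/right so the map still validates.
tiny_map <- function() {
  rect <- function(x1, y1, x2, y2) cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
  regions <- list(
    D1 = rect(-100, 20, -60, 100),
    D2 = rect(60, 20, 100, 100),
    D3 = rect(100, 20, 140, 100),
    D4 = rect(180, 20, 220, 100),
    D5 = rect(260, 20, 300, 100),
    palm = rect(-100, 100, 300, 200)
  )
  hand_map(
    calibration = calibration(0.25, 0.25),
    digit_axes = c(D1 = 90, D2 = 90, D3 = 90, D4 = 90, D5 = 90),
    regions = regions,
    crease = cbind(c(-100, 300), c(100, 100))
  )
}

# a deterministic full session with every response exactly on its target
noiseless_session <- function(seed = 1) {
  hmres <- generate_hand_map(seed)
  targets <- hmres$targets
  trials <- do.call(rbind, lapply(1:5, function(b) {
    data.frame(block = b, target_id = targets$id,
               x = targets$x, y = targets$y)
  }))
  session(participant("C01", "control"), "right", "dominant",
          hmres$map, targets, tibble::as_tibble(trials))
}

# ---- independent geometric oracle --------------------------------------

# classic crossing-number point-in-polygon, written independently of the
# package's mgcv-based test; the ray is cast from a half-tolerance vertical
# offset to dodge vertex degeneracies (boundary membership is decided first
# by an exact distance test, so the offset never changes a label)
oracle_pip <- function(px, py, poly, eps = 5e-10) {
  py <- py + eps
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_on_segments <- function(px, py, x1, y1, x2, y2, tol = 1e-9) {
  for (k in seq_along(x1)) {
    dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
    l2 <- dx^2 + dy^2
    t <- if (l2 == 0) 0 else max(0, min(1, ((px - x1[k]) * dx + (py - y1[k]) * dy) / l2))
    if ((px - (x1[k] + t * dx))^2 + (py - (y1[k] + t * dy))^2 <= tol^2) return(TRUE)
  }
  FALSE
}

oracle_assign_region <- function(p, hm) {
  digits <- c("D1", "D2", "D3", "D4", "D5")
  member <- logical(6)
  names(member) <- c(digits, "palm")
  for (r in names(member)) {
    poly <- hm$regions[[r]]
    n <- nrow(poly)
    bd <- oracle_on_segments(p[1], p[2], poly[, 1], poly[, 2],
                             poly[c(2:n, 1), 1], poly[c(2:n, 1), 2])
    member[r] <- bd || oracle_pip(p[1], p[2], poly)
  }
  cr <- hm$crease
  ncr <- nrow(cr)
  on_crease <- oracle_on_segments(p[1], p[2], cr[-ncr, 1], cr[-ncr, 2],
                                  cr[-1, 1], cr[-1, 2])
  mid_d <- sapply(digits, function(d) {
    poly <- hm$regions[[d]]
    ctr <- c(mean(poly[, 1]), mean(poly[, 2]))
    t <- hm$digit_axes[[d]] * pi / 180
    abs((p[1] - ctr[1]) * sin(t) + (p[2] - ctr[2]) * cos(t))
  })
  hits <- digits[member[digits]]
  if (length(hits) >= 1) {
    return(hits[which.min(mid_d[hits])])
  }
  if (on_crease) return(digits[which.min(mid_d)])
  cx <- sort(cr[, 1])
  crease_y <- approx(cr[order(cr[, 1]), 1], cr[order(cr[, 1]), 2],
                     xout = min(max(p[1], cx[1]), cx[length(cx)]),
                     ties = "ordered")$y
  if (member["palm"] || p[2] > crease_y) return("palm")
  "unclassifiable"
}

# independent 2x2 rotation-matrix oracle for the orthogonal decomposition
oracle_decompose <- function(ex, ey, theta_deg, hand_side) {
  t <- theta_deg * pi / 180
  u_distal <- c(cos(t), -sin(t))
  u_ulnar <- (if (hand_side == "right") 1 else -1) * c(sin(t), cos(t))
  R <- rbind(u_distal, u_ulnar)
  as.numeric(R %*% c(ex, ey))
}
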