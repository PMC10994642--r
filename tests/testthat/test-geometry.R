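test_that("grid calibration averages known-distance ratios per axis", {
  g <- data.frame(axis = c("x", "y", "y"),
                  x1 = c(0, 0, 0), y1 = c(0, 0, 0),
                  x2 = c(40, 0, 0), y2 = c(0, 100, 200),
                  mm = c(10, 25, 50))
  cal <- calibrate_from_grid(g)
  expect_equal(cal$fx, 0.25)
  expect_equal(cal$fy, 0.25)

  expect_error(calibrate_from_grid(transform(g, x2 = c(0, 0, 0))),
               class = "locog_degenerate_error")
  expect_error(calibrate_from_grid(transform(g, mm = -1)),
               class = "locog_validation_error")
  expect_error(calibrate_from_grid(g[g$axis == "x", ]),
               class = "locog_validation_error")
})

test_that("calibration is recovered from a jittered synthetic grid", {
  withr::with_seed(99, {
    f <- 0.21
    sigma <- 0.5
    dpx <- 200
    n <- 40
    g <- data.frame(axis = rep(c("x", "y"), each = n),
                    x1 = 0, y1 = 0, x2 = 0, y2 = 0, mm = f * dpx)
    g$x2[g$axis == "x"] <- dpx + rnorm(n, 0, sigma)
    g$y2[g$axis == "y"] <- dpx + rnorm(n, 0, sigma)
    cal <- calibrate_from_grid(g)
    tol <- 3 * sigma / dpx  # click jitter propagated to the ratio
    expect_lt(abs(cal$fx - f), tol)
    expect_lt(abs(cal$fy - f), tol)
  })
})

test_that("absolute error is the Euclidean distance in mm in either mode", {
  hm <- tiny_map()
  target <- list(digit = "D2", x = 80, y = 60)
  # 12 px right, 16 px down at 0.25 mm/px -> Ex 3, Ey 4 mm
  for (mode in c("orthogonal", "as_printed")) {
    ev <- error_vector(target, c(92, 76), hm, "right", mode)
    expect_equal(ev$ex, 3)
    expect_equal(ev$ey, 4)
    expect_equal(ev$e_abs, 5)
  }
})

test_that("as_printed mode evaluates the legacy formulas verbatim", {
  hm <- tiny_map()  # all axes at 90 degrees
  target <- list(digit = "D2", x = 80, y = 60)
  ev <- error_vector(target, c(92, 76), hm, "right", "as_printed")
  # at 90 degrees sin = 1, cos = 0: e_long = Ex, e_trans = Ey
  expect_equal(ev$e_long, ev$ex)
  expect_equal(ev$e_trans, ev$ey)
  hm0 <- hm; hm0$digit_axes["D2"] <- 0
  ev0 <- error_vector(target, c(92, 76), hm0, "right", "as_printed")
  # at 0 degrees: e_long = Ey, e_trans = Ex
  expect_equal(ev0$e_long, ev0$ey)
  expect_equal(ev0$e_trans, ev0$ex)
})

test_that("orthogonal decomposition conserves magnitude and matches a rotation oracle", {
  withr::with_seed(42, {
    n <- 1000
    ex <- runif(n, -20, 20); ey <- runif(n, -20, 20)
    theta <- runif(n, 0, 180)
    side <- sample(c("left", "right"), n, replace = TRUE)
    for (i in seq_len(n)) {
      d <- locognosia:::decompose_error(ex[i], ey[i], theta[i], side[i],
                                        "orthogonal")
      expect_equal(d$e_long^2 + d$e_trans^2, ex[i]^2 + ey[i]^2,
                   tolerance = 1e-9)
      o <- oracle_decompose(ex[i], ey[i], theta[i], side[i])
      expect_equal(c(d$e_long, d$e_trans), o, tolerance = 1e-9)
    }
  })
})

test_that("the two decomposition modes disagree away from the special angles", {
  for (theta in c(30, 45, 120, 157.5)) {
    d_orth <- locognosia:::decompose_error(3, 4, theta, "right", "orthogonal")
    d_lit <- locognosia:::decompose_error(3, 4, theta, "right", "as_printed")
    expect_gt(abs(d_orth$e_long - d_lit$e_long) +
                abs(d_orth$e_trans - d_lit$e_trans), 1e-6)
    # and the printed formulas are not magnitude-conserving there
    expect_gt(abs(d_lit$e_long^2 + d_lit$e_trans^2 - 25), 1e-6)
  }
})

test_that("canonical errors are invariant under mirroring the whole hand", {
  s <- generate_session(seed = 31)
  m <- detect_misreferrals(s)
  m2 <- detect_misreferrals(mirror_session(s))
  expect_identical(m2$response_region, m$response_region)
  expect_equal(m2$e_abs, m$e_abs, tolerance = 1e-9)
  expect_equal(m2$e_long, m$e_long, tolerance = 1e-9)
  expect_equal(m2$e_trans, m$e_trans, tolerance = 1e-9)
})

test_that("mm-space outputs are equivariant to a pixel rescale", {
  s <- generate_session(seed = 32)
  m <- detect_misreferrals(s)
  k <- 3.7
  s2 <- s
  s2$hand_map$calibration <- calibration(s$hand_map$calibration$fx / k,
                                         s$hand_map$calibration$fy / k)
  s2$hand_map$regions <- lapply(s$hand_map$regions, function(p) p * k)
  s2$hand_map$crease <- s$hand_map$crease * k
  s2$targets$x <- s$targets$x * k; s2$targets$y <- s$targets$y * k
  s2$trials$x <- s$trials$x * k; s2$trials$y <- s$trials$y * k
  m2 <- detect_misreferrals(s2)
  expect_identical(m2$response_region, m$response_region)
  expect_equal(m2$e_abs, m$e_abs, tolerance = 1e-9)
  expect_equal(m2$e_long, m$e_long, tolerance = 1e-9)
  expect_equal(m2$e_trans, m$e_trans, tolerance = 1e-9)
})

test_that("aggregation averages non-misreferral trials and counts exclusions", {
  m <- tibble::tibble(
    target_id = c("T01", "T01", "T02"),
    is_misreferral = c(FALSE, FALSE, TRUE),
    e_abs = c(4, 6, NA), e_long = c(-4, -6, NA), e_trans = c(0, 0, NA))
  agg <- aggregate_errors(m)
  expect_equal(agg$mean_abs, 5)
  expect_equal(agg$n_trials, 2)
  expect_equal(agg$n_excluded, 1)
  # restricting to an all-misreferral subset is an explicit error, not NaN
  expect_error(aggregate_errors(m, "T02"),
               class = "locog_undefined_aggregate_error")
  expect_error(aggregate_errors(m, "T09"), class = "locog_validation_error")
})

test_that("session-level means recover the planted error magnitude", {
  # a near-deterministic generator: 8 mm proximal shift, tiny scatter
  p <- generator_params(long_bias_mm = -8, error_sd_mm = 0.5,
                        trans_bias_mm = c(D1 = 0, D2 = 0, D3 = 0, D4 = 0, D5 = 0),
                        misreferral_rate_control = 0)
  s <- generate_session(p, seed = 77)
  agg <- aggregate_errors(detect_misreferrals(s))
  n <- agg$n_trials
  expect_lt(abs(agg$mean_long - (-8)), 4 * 0.5 / sqrt(n))
  expect_lt(abs(agg$mean_abs - 8), 0.3)
  expect_equal(agg$n_excluded, 0)
})
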