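test_that("the default zone map satisfies its structural invariants", {
  m <- marsh_zone_map()
  expect_equal(nrow(m$zones), 20)
  expect_true(all(table(m$zones$digit) == 4))
  for (z in 1:20) {
    # irreflexive, symmetric, same-digit adjacency
    expect_false(z %in% m$adjacency[[z]])
    for (a in m$adjacency[[z]]) {
      expect_true(z %in% m$adjacency[[a]])
      expect_identical(m$zones$digit[a], m$zones$digit[z])
    }
    # homologs are same-quadrant zones on immediately neighboring digits
    for (h in m$homologs[[z]]) {
      expect_identical(m$zones$quadrant[h], m$zones$quadrant[z])
      expect_equal(abs(match(m$zones$digit[h], c("D1", "D2", "D3", "D4", "D5")) -
                         match(m$zones$digit[z], c("D1", "D2", "D3", "D4", "D5"))), 1)
    }
  }
  # zones 1-14 cover D1-D3 fully plus the radial half of D4;
  # 15-20 cover the ulnar half of D4 plus D5
  z14 <- m$zones[m$zones$zone <= 14, ]
  expect_equal(sum(z14$digit %in% c("D1", "D2", "D3")), 12)
  expect_true(all(grepl("^radial", z14$quadrant[z14$digit == "D4"])))
  z6 <- m$zones[m$zones$zone >= 15, ]
  expect_true(all(grepl("^ulnar", z6$quadrant[z6$digit == "D4"])))
  expect_equal(sum(z6$digit == "D5"), 4)
})

test_that("trial scoring follows the 2/1/1/0 rule", {
  m <- marsh_zone_map()
  d3_rd <- m$zones$zone[m$zones$digit == "D3" & m$zones$quadrant == "radial-distal"]
  d3_rp <- m$zones$zone[m$zones$digit == "D3" & m$zones$quadrant == "radial-proximal"]
  d3_up <- m$zones$zone[m$zones$digit == "D3" & m$zones$quadrant == "ulnar-proximal"]
  d2_rd <- m$zones$zone[m$zones$digit == "D2" & m$zones$quadrant == "radial-distal"]
  d4_rd <- m$zones$zone[m$zones$digit == "D4" & m$zones$quadrant == "radial-distal"]
  d5_up <- m$zones$zone[m$zones$digit == "D5" & m$zones$quadrant == "ulnar-proximal"]

  expect_equal(score_trial(d3_rd, d3_rd, m), 2L)       # correct zone
  expect_equal(score_trial(d3_rd, d3_rp, m), 1L)       # edge-adjacent quadrant
  expect_equal(score_trial(d3_rd, d3_up, m), 0L)       # diagonal quadrant
  expect_equal(score_trial(d3_rd, d2_rd, m), 1L)       # homolog, neighbor digit
  expect_equal(score_trial(d3_rd, d4_rd, m), 1L)
  expect_equal(score_trial(d3_rd, d5_up, m), 0L)       # far digit, other quadrant
  expect_error(score_trial(d3_rd, 21, m), class = "locog_validation_error")

  # adjacency-based credit is symmetric
  for (z in 1:20) {
    for (a in m$adjacency[[z]]) {
      expect_equal(score_trial(z, a, m), score_trial(a, z, m))
    }
  }
})

test_that("percentage scores use the per-injury-type maxima", {
  # ulnar: 6 zones x 2 trials, all correct -> 24/24 = 100%
  uln <- marsh_zones_tested("ulnar")
  tr <- data.frame(stimulated = rep(uln, each = 2), reported = rep(uln, each = 2))
  res <- marsh_percent(tr, "ulnar")
  expect_equal(res$raw_score, 24L)
  expect_equal(res$max_score, 24L)
  expect_equal(res$percent, 100)

  # all wrong: 0%
  tr0 <- tr
  tr0$reported <- 1  # D1 is never adjacent or homologous to D4/D5 zones
  res0 <- marsh_percent(tr0, "ulnar")
  expect_equal(res0$percent, 0)

  # median: half of the 28 trials score 2, half 0 -> 50% of the 56 maximum
  med <- marsh_zones_tested("median")
  trm <- data.frame(stimulated = rep(med, each = 2), reported = rep(med, each = 2))
  far <- function(z) ifelse(z <= 8, 19, 1)  # distant digit, other quadrant
  trm$reported[seq(2, 28, by = 2)] <- far(trm$stimulated[seq(2, 28, by = 2)])
  pts <- mapply(score_trial, trm$stimulated, trm$reported,
                MoreArgs = list(map = marsh_zone_map()))
  expect_true(all(pts %in% c(0L, 2L)))
  resm <- marsh_percent(trm, "median")
  expect_equal(resm$max_score, 56L)
  expect_equal(resm$percent, 50)

  expect_equal(marsh_percent(data.frame(stimulated = 1, reported = 1),
                             "both")$max_score, 80L)
  # stimulating outside the permitted zones is a validation error
  expect_error(marsh_percent(data.frame(stimulated = 15, reported = 15), "median"),
               class = "locog_validation_error")
})

test_that("raw scores are order-invariant and additive over trial subsets", {
  m <- marsh_zone_map()
  withr::with_seed(61, {
    tr <- data.frame(stimulated = rep(marsh_zones_tested("both"), each = 2))
    tr$reported <- sample(1:20, nrow(tr), replace = TRUE)
  })
  r_all <- marsh_percent(tr, "both", m)
  r_shuf <- marsh_percent(tr[sample(nrow(tr)), ], "both", m)
  expect_equal(r_all$raw_score, r_shuf$raw_score)
  half <- seq_len(nrow(tr) / 2)
  expect_equal(r_all$raw_score,
               marsh_percent(tr[half, ], "both", m)$raw_score +
                 marsh_percent(tr[-half, ], "both", m)$raw_score)
})

test_that("a user-supplied zone map file round-trips and is validated", {
  m <- marsh_zone_map()
  f <- withr::local_tempfile(fileext = ".json")
  x <- list(
    zones = lapply(seq_len(20), function(i)
      list(zone = m$zones$zone[i], digit = m$zones$digit[i],
           quadrant = m$zones$quadrant[i])),
    adjacency = setNames(m$adjacency, as.character(1:20)),
    homologs = setNames(m$homologs, as.character(1:20))
  )
  jsonlite::write_json(x, f, auto_unbox = TRUE)
  m2 <- read_marsh_map(f)
  expect_equal(m2$zones, m$zones)
  expect_equal(m2$adjacency, m$adjacency)
  expect_equal(m2$homologs, m$homologs)

  # symmetry violations are caught
  x$adjacency[["1"]] <- c(x$adjacency[["1"]], 4L)
  jsonlite::write_json(x, f, auto_unbox = TRUE)
  expect_error(read_marsh_map(f), class = "locog_validation_error")
})
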