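targets18 <- generate_hand_map(seed = 1)$targets

test_that("nerve territories carry the documented target counts and overlap on D4", {
  med <- injured_targets("median", targets18)
  uln <- injured_targets("ulnar", targets18)
  both <- injured_targets("both", targets18)
  expect_length(med, 14)
  expect_length(uln, 8)
  expect_length(both, 18)
  expect_setequal(union(med, uln), targets18$id)
  d4 <- targets18$id[targets18$digit == "D4"]
  expect_setequal(intersect(med, uln), d4)
  expect_error(injured_targets("ulnar", targets18[targets18$digit != "D5", ]),
               class = "locog_config_error")
})

test_that("homologous pairing is a label-preserving involution", {
  inj <- generate_session(role = "patient_injured", nerve = "median",
                          hand_side = "right", seed = 41)
  uninj <- generate_session(role = "patient_uninjured", nerve = "median",
                            hand_side = "left", seed = 42)
  ids <- injured_targets("median", inj$targets)
  pairing <- homologous_pairing(ids, inj, uninj)
  expect_equal(nrow(pairing), 14)
  # same digit and subzone on the other side
  key <- function(s, id) {
    t <- s$targets[match(id, s$targets$id), ]
    paste(t$digit, t$subzone)
  }
  expect_identical(key(inj, pairing$inj_id), key(uninj, pairing$uninj_id))
  # pairing back returns the original set
  back <- homologous_pairing(pairing$uninj_id, uninj, inj)
  expect_setequal(back$uninj_id, ids)

  # removing one (digit, subzone) label from the uninjured layout leaves an
  # injured target without a homolog
  broken <- uninj
  broken$targets$subzone[1] <- broken$targets$subzone[2]
  expect_error(homologous_pairing(ids[1:2], inj, broken),
               class = "locog_pairing_error")
})

test_that("control matching reproduces proportional apportionment", {
  m <- match_controls(sprintf("C%02d", 1:33), c(median = 5, ulnar = 8, both = 5),
                      seed = 17)
  expect_equal(unname(m$counts), c(9, 15, 9))
  expect_equal(sum(m$counts), 33)
  expect_length(m$assignment, 33)
  expect_equal(unname(table(m$assignment)[c("median", "ulnar", "both")]),
               c(9, 15, 9), ignore_attr = TRUE)

  # same seed, same assignment; counts never depend on the seed
  m2 <- match_controls(sprintf("C%02d", 1:33), c(median = 5, ulnar = 8, both = 5),
                       seed = 17)
  expect_identical(m$assignment, m2$assignment)
  m3 <- match_controls(sprintf("C%02d", 1:33), c(median = 5, ulnar = 8, both = 5),
                       seed = 99)
  expect_identical(m$counts, m3$counts)

  all_med <- match_controls(letters[1:5], c(median = 7, ulnar = 0, both = 0))
  expect_true(all(all_med$assignment == "median"))
})

test_that("apportioned counts track exact proportions for random compositions", {
  withr::with_seed(55, {
    for (i in 1:500) {
      comp <- c(median = sample(0:12, 1), ulnar = sample(0:12, 1),
                both = sample(0:12, 1))
      if (sum(comp) == 0) comp["median"] <- 1
      n <- sample(3:60, 1)
      m <- suppressMessages(match_controls(as.character(seq_len(n)), comp))
      expect_equal(sum(m$counts), n)
      exact <- n * comp / sum(comp)
      expect_true(all(abs(m$counts - exact) <= 1))
    }
  })
})

test_that("control hands are averaged only when the paired gate passes", {
  # identical hands: gate cannot reject, averaging returns either hand
  one <- lapply(1:5, function(i) {
    s <- generate_session(participant_id = sprintf("C%02d", i), seed = 500 + i)
    list(dominant = s, nondominant = s)
  })
  names(one) <- sprintf("C%02d", 1:5)
  matching <- match_controls(names(one), c(median = 1, ulnar = 1, both = 1))
  ref <- control_reference(one, matching)
  expect_true(ref$hands_averaged)
  expect_equal(ref$gate$p, 1)
  expect_equal(ref$values$value, ref$values$dominant)

  # a planted 3 mm longitudinal asymmetry between hands is caught by the gate
  asym <- lapply(1:30, function(i) {
    list(
      dominant = generate_session(generator_params(long_bias_mm = -3),
                                  participant_id = sprintf("A%02d", i),
                                  hand_role = "dominant", seed = 600 + 2 * i),
      nondominant = generate_session(generator_params(long_bias_mm = -6),
                                     participant_id = sprintf("A%02d", i),
                                     hand_role = "nondominant",
                                     seed = 601 + 2 * i)
    )
  })
  names(asym) <- sprintf("A%02d", 1:30)
  matching2 <- match_controls(names(asym), c(median = 1, ulnar = 1, both = 1))
  ref2 <- control_reference(asym, matching2)
  expect_false(ref2$hands_averaged)
  expect_lt(ref2$gate$p, 0.05)
})

test_that("the 'both' condition equals the unrestricted whole-hand metric", {
  s <- generate_session(seed = 71)
  ids <- injured_targets("both", s$targets)
  expect_equal(metric_mean_abs_error(s, ids),
               aggregate_errors(detect_misreferrals(s))$mean_abs)
})
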