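test_that("partial eta squared follows t^2/(t^2+df)", {
  expect_equal(round(effect_size_from_t(4.5, 17), 2), 0.54)
  expect_equal(round(effect_size_from_t(3.1, 12), 2), 0.44)
  expect_equal(effect_size_from_t(0, 10), 0)
  expect_equal(effect_size_from_t(2, 4), 0.5)
  expect_error(effect_size_from_t(1, 0), class = "locog_validation_error")
})

test_that("identical paired samples give the trivial null result", {
  x <- rnorm(10)
  cmp <- compare_paired(x, x)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$effect_size, 0)
})

test_that("the paired decision tree follows the Shapiro-Wilk gate", {
  withr::with_seed(101, {
    a <- rnorm(20, 5, 2); b <- rnorm(20, 4, 2)
    cmp <- compare_paired(a, b)
    expect_identical(cmp$test_used, "t")
    expect_gte(cmp$gates$normality_p, 0.05)
    expect_equal(cmp$statistic, unname(t.test(a, b, paired = TRUE)$statistic))
    expect_equal(cmp$effect_size,
                 effect_size_from_t(cmp$statistic, cmp$df))

    # grossly log-normal differences go to the signed-rank branch
    a2 <- rlnorm(20, 0, 1.5); b2 <- rep(0, 20)
    cmp2 <- compare_paired(a2, b2)
    expect_identical(cmp2$test_used, "wilcoxon_signed_rank")
    expect_lt(cmp2$gates$normality_p, 0.05)
    expect_true(is.na(cmp2$df))
    expect_gte(cmp2$effect_size, 0)
    expect_lte(cmp2$effect_size, 1)
  })
  expect_error(compare_paired(c(1, 2, 3), c(0, 1, 2)),
               class = "locog_degenerate_error")
  expect_error(compare_paired(1:5, 1:4), class = "locog_validation_error")
})

test_that("decision trees are pure functions of their inputs", {
  withr::with_seed(7, {
    a <- rnorm(15); b <- rnorm(15)
  })
  c1 <- compare_paired(a, b)
  c2 <- compare_paired(a, b)
  expect_identical(c1, c2)
  u1 <- compare_unpaired(a, b)
  u2 <- compare_unpaired(a, b)
  expect_identical(u1, u2)
})

test_that("the unpaired tree applies Welch and rank fallbacks per its gates", {
  # identical constant-free samples: null result
  x <- c(1, 2, 3, 4, 5)
  cmp0 <- compare_unpaired(x, x)
  expect_equal(cmp0$p, 1, tolerance = 1e-12)
  expect_lt(cmp0$effect_size, 1e-12)

  # sigma ratio 3: Welch chosen in nearly all replicates
  withr::with_seed(313, {
    picks <- replicate(500, {
      a <- rnorm(30, 0, 1); b <- rnorm(30, 0, 3)
      compare_unpaired(a, b)$test_used
    })
  })
  expect_gte(mean(picks == "welch_t"), 0.90)
  expect_gte(mean(picks %in% c("welch_t", "mann_whitney")), 0.95)

  # heavy-tailed data fall through to Mann-Whitney
  withr::with_seed(17, {
    a <- rlnorm(30, 0, 1.5); b <- rlnorm(30, 0.2, 1.5)
    cmp <- compare_unpaired(a, b)
    expect_identical(cmp$test_used, "mann_whitney")
    expect_lt(cmp$gates$normality_p, 0.05)
  })
})

test_that("bias tests apply the Bonferroni-adjusted threshold", {
  withr::with_seed(29, {
    null_sample <- rnorm(33, 0, 5)
  })
  null_sample <- null_sample - mean(null_sample)  # exactly mean-zero
  cmp <- one_sample_bias_test(null_sample, family_size = 6)
  expect_false(cmp$significant)

  # a sample engineered to p ~ 0.028: nominal but not family-wise significant
  withr::with_seed(31, { base <- rnorm(33) })
  base <- (base - mean(base)) / sd(base)
  x <- base + 2.3 / sqrt(33)
  cmp2 <- one_sample_bias_test(x, family_size = 6)
  expect_lt(cmp2$p, 0.05)
  expect_gt(cmp2$p, 0.05 / 6)
  expect_false(cmp2$significant)
  expect_equal(cmp2$alpha_adjusted, 0.05 / 6)
  cmp3 <- one_sample_bias_test(x, family_size = 1)
  expect_true(cmp3$significant)

  expect_error(one_sample_bias_test(rep(1, 10)),
               class = "locog_degenerate_error")
})

test_that("a planted 5 mm bias is family-wise significant with near-certainty", {
  withr::with_seed(37, {
    hits <- replicate(200, {
      one_sample_bias_test(rnorm(33, -5, 5), family_size = 6)$significant
    })
  })
  expect_gte(mean(hits), 0.99)
})

test_that("validity correlations report r, df = n - 2, and r squared", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 11, 10, 13, 12, 15, 14, 17, 16, 18)
  v <- validity_correlation(x, -x)
  expect_equal(v$r, -1)
  expect_equal(v$df, 16)  # 18 patients -> r(16)
  expect_equal(v$r_squared, 1)

  withr::with_seed(41, {
    rs <- replicate(1000, {
      a <- rnorm(18)
      b <- -0.8 * a + sqrt(1 - 0.64) * rnorm(18)
      validity_correlation(a, b)$r
    })
  })
  expect_lt(abs(mean(rs) - (-0.8)), 0.05)

  expect_error(validity_correlation(rep(1, 5), 1:5),
               class = "locog_undefined_correlation_error")
  expect_error(validity_correlation(1:2, 2:1), class = "locog_validation_error")
  # pairwise-complete handling
  v2 <- validity_correlation(c(1, 2, NA, 4, 5), c(2, 4, 9, 8, 10))
  expect_equal(v2$n, 4)
  expect_equal(v2$r, 1)
})

test_that("comparison tables carry one tidy row per comparison", {
  withr::with_seed(5, { a <- rnorm(12); b <- rnorm(12, 1) })
  tab <- comparison_table(list(pair = compare_paired(a, b),
                               unpair = compare_unpaired(a, b)))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("test_used", "p", "effect_size", "gate_normality_p") %in%
                    names(tab)))
})
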