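#' Partial eta squared from a t statistic
#'
#' `eta_p^2 = t^2 / (t^2 + df)`, the effect size reported alongside every t
#' test in this pipeline (paired, Welch-corrected, and one-sample alike).
#'
#' @param t t statistic.
#' @param df degrees of freedom (> 0; fractional for Welch).
#' @return Partial eta squared in \[0, 1\].
#' @examples
#' effect_size_from_t(4.5, 17)  # 0.54
#' effect_size_from_t(3.1, 12)  # 0.44
#' @export
effect_size_from_t <- function(t, df) {
  if (any(df <= 0)) stop_locog("df must be > 0", "locog_validation_error")
  t^2 / (t^2 + df)
}

new_comparison <- function(design, test_used, statistic, df, p, effect_size,
                           gates, n, extra = list()) {
  structure(
    c(list(design = design, test_used = test_used, statistic = statistic,
           df = df, p = p, effect_size = effect_size, gates = gates, n = n),
      extra),
    class = "locog_comparison"
  )
}

#' @export
print.locog_comparison <- function(x, ...) {
  dftxt <- if (is.na(x$df)) "" else sprintf("(%.4g)", x$df)
  cat(sprintf("<%s comparison> %s%s = %.3f, p = %.4g, eta_p^2 = %.3f\n",
              x$design, x$test_used, dftxt, x$statistic, x$p, x$effect_size))
  invisible(x)
}

scale_resid <- function(x) {
  s <- sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

# signed z from a two-sided p-value of a rank test
z_from_rank_test <- function(p, statistic, null_expectation) {
  sgn <- if (statistic >= null_expectation) 1 else -1
  sgn * qnorm(pmax(p, .Machine$double.xmin) / 2, lower.tail = FALSE)
}

#' Paired comparison with normality-gated test choice
#'
#' Shapiro-Wilk on the paired differences decides the test: normal
#' (p >= `alpha_gate`) uses the paired t test, otherwise the Wilcoxon
#' matched-pairs signed-rank test (normal approximation). Effect size is
#' `t^2/(t^2+df)` for the t branch and `Z^2/N` for the rank branch.
#'
#' @param a,b paired samples (equal length >= 3).
#' @param alpha_gate Shapiro-Wilk gate alpha (default 0.05).
#' @return A `locog_comparison`.
#' @export
compare_paired <- function(a, b, alpha_gate = 0.05) {
  if (length(a) != length(b)) {
    stop_locog("paired samples must have equal length", "locog_validation_error")
  }
  n <- length(a)
  if (n < 3) stop_locog("need at least 3 pairs", "locog_validation_error")
  d <- a - b
  if (all(d == 0)) {
    # identical samples: no evidence of a difference, trivially
    return(new_comparison("paired", "t", 0, n - 1, 1, 0,
                          gates = list(normality_p = NA_real_), n = n))
  }
  if (sd(d) == 0) {
    stop_locog("paired differences have zero variance; test degenerate",
               "locog_degenerate_error")
  }
  sw <- shapiro.test(d)
  if (sw$p.value >= alpha_gate) {
    tt <- t.test(a, b, paired = TRUE)
    new_comparison("paired", "t", unname(tt$statistic), unname(tt$parameter),
                   tt$p.value,
                   effect_size_from_t(unname(tt$statistic), unname(tt$parameter)),
                   gates = list(normality_p = sw$p.value), n = n)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
    z <- z_from_rank_test(wt$p.value, unname(wt$statistic), n * (n + 1) / 4)
    new_comparison("paired", "wilcoxon_signed_rank", unname(wt$statistic),
                   NA_real_, wt$p.value, z^2 / n,
                   gates = list(normality_p = sw$p.value), n = n,
                   extra = list(z = z))
  }
}

#' Unpaired comparison with variance- and normality-gated test choice
#'
#' Levene's test (center = median) at `alpha_gate` decides pooled vs Welch
#' variance handling; Shapiro-Wilk on the internally studentized residuals
#' (each group centered and scaled by its own spread) decides parametric vs
#' Mann-Whitney. Effect size is `t^2/(t^2+df)` for t branches
#' and `Z^2/N` for the rank branch.
#'
#' @param a,b independent samples (each length >= 3).
#' @param alpha_gate gate alpha for both gates (default 0.05).
#' @return A `locog_comparison`.
#' @export
compare_unpaired <- function(a, b, alpha_gate = 0.05) {
  na <- length(a); nb <- length(b)
  if (na < 3 || nb < 3) {
    stop_locog("need at least 3 observations per group", "locog_validation_error")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(new_comparison("unpaired", "t", 0, na + nb - 2, 1, 0,
                            gates = list(normality_p = NA_real_,
                                         variance_p = NA_real_), n = na + nb))
    }
    stop_locog("both groups constant; test degenerate", "locog_degenerate_error")
  }
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(na, nb)))
  lev <- car::leveneTest(y, g, center = stats::median)
  variance_p <- lev[["Pr(>F)"]][1]
  var_equal <- is.na(variance_p) || variance_p >= alpha_gate
  # internally studentized residuals: scaling each group by its own spread
  # keeps the gate a test of normality rather than of homoscedasticity
  # (which the Levene gate already covers)
  resid <- c(scale_resid(a), scale_resid(b))
  sw <- tryCatch(shapiro.test(resid), error = function(e) list(p.value = NA_real_))
  normality_p <- sw$p.value
  gates <- list(normality_p = normality_p, variance_p = variance_p)
  if (!is.na(normality_p) && normality_p < alpha_gate) {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    z <- z_from_rank_test(wt$p.value, unname(wt$statistic), na * nb / 2)
    new_comparison("unpaired", "mann_whitney", unname(wt$statistic), NA_real_,
                   wt$p.value, z^2 / (na + nb), gates = gates, n = na + nb,
                   extra = list(z = z))
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
    new_comparison("unpaired", if (var_equal) "t" else "welch_t",
                   unname(tt$statistic), unname(tt$parameter), tt$p.value,
                   effect_size_from_t(unname(tt$statistic), unname(tt$parameter)),
                   gates = gates, n = na + nb)
  }
}

#' One-sample bias test against zero with Bonferroni correction
#'
#' One-sample t test of directional error means against zero. The
#' significance flag applies the Bonferroni-adjusted threshold
#' `alpha / family_size`, where `family_size` is the number of bias tests in
#' the analysis family (the default family in the digit-specific analysis is
#' 3 groups x 2 components = 6).
#'
#' @param values sample of per-participant mean directional errors (mm).
#' @param family_size number of tests in the Bonferroni family (>= 1).
#' @param alpha nominal alpha before correction (default 0.05).
#' @return A `locog_comparison` with extra fields `family_size`,
#'   `alpha_adjusted`, `significant`.
#' @export
one_sample_bias_test <- function(values, family_size = 1L, alpha = 0.05) {
  if (length(values) < 3) stop_locog("need at least 3 values", "locog_validation_error")
  if (family_size < 1) stop_locog("family_size must be >= 1", "locog_validation_error")
  if (sd(values) == 0) {
    stop_locog("values have zero variance; test degenerate", "locog_degenerate_error")
  }
  tt <- t.test(values, mu = 0)
  thr <- alpha / family_size
  new_comparison("one_sample", "t", unname(tt$statistic), unname(tt$parameter),
                 tt$p.value,
                 effect_size_from_t(unname(tt$statistic), unname(tt$parameter)),
                 gates = list(), n = length(values),
                 extra = list(family_size = as.integer(family_size),
                              alpha_adjusted = thr,
                              significant = tt$p.value < thr))
}

#' Pearson correlation for concurrent validity
#'
#' Pearson correlation between per-patient localization difference scores and
#' an external clinical score, reported as `r`, `df = n - 2`, `p`, and `r^2`.
#' Pairs with missing values are dropped (pairwise complete).
#'
#' @param x,y numeric vectors of equal length.
#' @return A list with `r`, `df`, `p`, `r_squared`, `n`.
#' @export
validity_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop_locog("x and y must have equal length", "locog_validation_error")
  }
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_locog("need at least 3 complete pairs", "locog_validation_error")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_locog("constant input; correlation undefined",
               "locog_undefined_correlation_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, df = unname(ct$parameter), p = ct$p.value,
       r_squared = r^2, n = n)
}

#' Flatten comparisons to a tidy table
#'
#' @param comparisons named list of `locog_comparison` objects.
#' @return A tibble with one row per comparison.
#' @export
comparison_table <- function(comparisons) {
  dplyr::bind_rows(lapply(names(comparisons), function(nm) {
    x <- comparisons[[nm]]
    tibble::tibble(
      comparison = nm, design = x$design, test_used = x$test_used,
      statistic = x$statistic, df = x$df, p = x$p,
      effect_size = x$effect_size, n = x$n,
      gate_normality_p = x$gates$normality_p %||% NA_real_,
      gate_variance_p = x$gates$variance_p %||% NA_real_,
      significant = x$significant %||% (x$p < 0.05)
    )
  }))
}
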