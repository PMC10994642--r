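#' Arcsine square-root transform of a proportion
#'
#' Variance-stabilizing transform `asin(sqrt(p))` (radians), applied to
#' misreferral proportions before group comparison; appropriate when many
#' scores sit near floor or ceiling.
#'
#' @param p proportion(s) in \[0, 1\].
#' @return Transformed value(s) in \[0, pi/2\].
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_locog("proportions must lie in [0, 1]", "locog_domain_error")
  }
  asin(sqrt(p))
}

#' Theoretical misreferral distribution under equal per-stimulation risk
#'
#' If every stimulation is equally likely to produce a misreferral, the
#' expected share of misreferrals attributed to a digit equals its share of
#' targets. With the standard layout (2 thumb targets, 4 per finger) this is
#' 11.11% for the thumb and 22.22% for each of D2-D5.
#'
#' @param layout named integer vector of target counts per digit
#'   (default the standard layout).
#' @return Named numeric vector of expected proportions (sums to 1).
#' @examples
#' round(100 * theoretical_distribution(), 2)
#' @export
theoretical_distribution <- function(layout = STANDARD_LAYOUT) {
  if (any(layout < 0) || sum(layout) <= 0) {
    stop_locog("layout must be nonnegative with a positive total", "locog_domain_error")
  }
  layout / sum(layout)
}

#' Chi-squared goodness of fit for misreferral counts
#'
#' Plain (uncorrected) chi-squared test of observed per-digit misreferral
#' counts against expected proportions, `X2 = sum((O - E)^2 / E)` with
#' `E = p * sum(O)` and `df = k - 1`. Expected cells below 5 trigger a
#' warning (the asymptotic distribution is still used).
#'
#' @param observed named integer vector of observed counts per digit.
#' @param expected_proportions expected proportions (summing to 1), e.g. from
#'   [theoretical_distribution()].
#' @return A list with `statistic`, `df`, `p`, `expected`.
#' @export
gof_chi_squared <- function(observed, expected_proportions = theoretical_distribution()) {
  if (length(observed) != length(expected_proportions)) {
    stop_locog("observed and expected must have equal length", "locog_validation_error")
  }
  n <- sum(observed)
  if (n <= 0) {
    stop_locog("no observed counts; goodness of fit undefined", "locog_domain_error")
  }
  if (abs(sum(expected_proportions) - 1) > 1e-8) {
    stop_locog("expected proportions must sum to 1", "locog_validation_error")
  }
  expected <- expected_proportions * n
  if (any(expected == 0 & observed > 0)) {
    stop_locog("expected count of 0 with nonzero observed; statistic undefined",
               "locog_undefined_statistic_error")
  }
  if (any(expected < 5)) {
    warning("expected cell count(s) below 5; asymptotic chi-squared may be inaccurate",
            call. = FALSE)
  }
  keep <- expected > 0
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- length(observed) - 1L
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Misreferral confusion matrix
#'
#' 5 x 6 matrix of proportions: rows are the stimulated ("referred from")
#' digits D1-D5, columns the response ("referred to") regions D1-D5 and palm.
#' Each cell is that (from, to) misreferral count divided by the total number
#' of misreferrals for the hand. With `pooling = "averaged_hands"`, supply
#' metrics for both hands of a participant as a list; per-hand proportion
#' matrices are computed first and then averaged.
#'
#' If there are no misreferrals the matrix is all zero and carries attribute
#' `no_misreferrals = TRUE`.
#'
#' @param metrics per-trial metrics from [detect_misreferrals()], or a list
#'   of two such tibbles when averaging hands.
#' @param pooling `"per_hand"` or `"averaged_hands"`.
#' @return A 5 x 6 numeric matrix of proportions.
#' @export
confusion_matrix <- function(metrics, pooling = c("per_hand", "averaged_hands")) {
  pooling <- match.arg(pooling)
  if (pooling == "averaged_hands") {
    if (!is.list(metrics) || inherits(metrics, "data.frame")) {
      stop_locog("averaged_hands pooling needs a list of per-hand metrics",
                 "locog_validation_error")
    }
    mats <- lapply(metrics, confusion_matrix, pooling = "per_hand")
    out <- Reduce(`+`, mats) / length(mats)
    attr(out, "no_misreferrals") <- all(vapply(mats, function(m)
      isTRUE(attr(m, "no_misreferrals")), logical(1)))
    return(out)
  }
  m <- matrix(0, 5, 6, dimnames = list(DIGITS, REGIONS))
  mis <- metrics[!is.na(metrics$is_misreferral) & metrics$is_misreferral, ]
  if (nrow(mis) == 0) {
    attr(m, "no_misreferrals") <- TRUE
    return(m)
  }
  tab <- table(factor(mis$digit, levels = DIGITS),
               factor(mis$response_region, levels = REGIONS))
  m[] <- tab / nrow(mis)
  attr(m, "no_misreferrals") <- FALSE
  m
}

#' Summarize misreferrals for one hand
#'
#' @param metrics per-trial metrics from [detect_misreferrals()].
#' @param expected_proportions expected per-digit proportions for the
#'   goodness-of-fit test (default [theoretical_distribution()]).
#' @return A list of class `locog_misreferral_summary`: `counts_by_digit`,
#'   `n_trials` (classifiable trials), `proportion_total`, `arcsine_value`,
#'   `confusion` (5 x 6 proportion matrix), and `gof` (`NULL` when there are
#'   no misreferrals).
#' @export
misreferral_summary <- function(metrics, expected_proportions = theoretical_distribution()) {
  ok <- !is.na(metrics$is_misreferral)
  n_trials <- sum(ok)
  mis <- metrics[ok & metrics$is_misreferral, ]
  counts <- table(factor(mis$digit, levels = DIGITS))
  counts <- setNames(as.integer(counts), DIGITS)
  p <- if (n_trials > 0) nrow(mis) / n_trials else 0
  gof <- if (nrow(mis) > 0) {
    suppressWarnings(gof_chi_squared(counts, expected_proportions))
  } else NULL
  structure(
    list(counts_by_digit = counts, n_trials = n_trials,
         proportion_total = p, arcsine_value = arcsine_transform(p),
         confusion = confusion_matrix(metrics), gof = gof),
    class = "locog_misreferral_summary"
  )
}

#' @export
print.locog_misreferral_summary <- function(x, ...) {
  cat(sprintf("<misreferral summary> %d/%d trials (%.1f%%), arcsine %.4f\n",
              sum(x$counts_by_digit), x$n_trials, 100 * x$proportion_total,
              x$arcsine_value))
  if (!is.null(x$gof)) {
    cat(sprintf("  goodness of fit vs expected: X2(%d) = %.2f, p = %.3g\n",
                x$gof$df, x$gof$statistic, x$gof$p))
  }
  invisible(x)
}

#' Write a confusion matrix as labelled CSV
#'
#' @param m matrix from [confusion_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(m, path) {
  df <- data.frame(referred_from = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
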