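#' Target ids within an injured nerve's territory
#'
#' Median nerve territory covers all targets on D1-D4 (14 of 18); ulnar
#' covers all targets on D4-D5 (8); injuries to both nerves cover all 18.
#' All four D4 targets belong to both territories: the anatomical
#' median/ulnar border runs through D4 and varies between individuals, so D4
#' is deliberately included in either set.
#'
#' @param nerve `"median"`, `"ulnar"` or `"both"`.
#' @param targets the session's target tibble (standard 18-target layout).
#' @return Character vector of target ids.
#' @export
injured_targets <- function(nerve = c("median", "ulnar", "both"), targets) {
  nerve <- match.arg(nerve)
  digits <- switch(nerve,
                   median = c("D1", "D2", "D3", "D4"),
                   ulnar = c("D4", "D5"),
                   both = DIGITS)
  if (!all(digits %in% targets$digit)) {
    stop_locog(paste0("layout lacks required digit(s) for the ", nerve,
                      " territory"), "locog_config_error")
  }
  targets$id[targets$digit %in% digits]
}

#' Homologous targets on the other hand
#'
#' Maps each target of the injured set to the target with the same digit and
#' subzone on the uninjured hand (the "Uninj" condition).
#'
#' @param inj_targets character vector of target ids on the injured hand.
#' @param injured_session,uninjured_session the two `locog_session`s.
#' @return A tibble with columns `inj_id`, `uninj_id`, `digit`, `subzone`.
#' @export
homologous_pairing <- function(inj_targets, injured_session, uninjured_session) {
  ti <- injured_session$targets
  tu <- uninjured_session$targets
  sel <- ti[match(inj_targets, ti$id), ]
  if (anyNA(sel$id)) {
    stop_locog("inj_targets contains ids absent from the injured session",
               "locog_referential_error")
  }
  key_i <- paste(sel$digit, sel$subzone)
  key_u <- paste(tu$digit, tu$subzone)
  idx <- match(key_i, key_u)
  if (anyNA(idx)) {
    stop_locog(paste("no homologous target for:",
                     paste(key_i[is.na(idx)], collapse = "; ")),
               "locog_pairing_error")
  }
  tibble::tibble(inj_id = sel$id, uninj_id = tu$id[idx],
                 digit = sel$digit, subzone = sel$subzone)
}

#' Proportionally match controls to the patient composition
#'
#' Controls are apportioned to the nerve-condition subgroups in proportion to
#' the patient composition: the median and ulnar shares are rounded to the
#' nearest integer and the remainder is assigned to the "both" condition
#' (with 33 controls and a (5, 8, 5)/18 patient composition this yields
#' 9/15/9). If nearest-integer rounding leaves a negative remainder, the
#' largest-remainder apportionment is used instead (logged). Which specific
#' controls land in which condition is drawn uniformly at random from `seed`.
#'
#' @param control_ids character vector of control participant ids.
#' @param patient_composition named counts, e.g.
#'   `c(median = 5, ulnar = 8, both = 5)`.
#' @param seed integer RNG seed.
#' @return A list of class `locog_matching`: `assignment` (named character
#'   vector id -> condition), `counts`, `seed`.
#' @export
match_controls <- function(control_ids, patient_composition, seed = 1L) {
  n <- length(control_ids)
  if (n == 0) stop_locog("no controls to match", "locog_validation_error")
  comp <- patient_composition[c("median", "ulnar", "both")]
  comp[is.na(comp)] <- 0
  names(comp) <- c("median", "ulnar", "both")
  if (sum(comp) <= 0) stop_locog("empty patient composition", "locog_validation_error")
  n_med <- round(n * comp[["median"]] / sum(comp))
  n_uln <- round(n * comp[["ulnar"]] / sum(comp))
  n_both <- n - n_med - n_uln
  if (n_both < 0) {
    # degenerate rounding: fall back to largest-remainder apportionment
    message("nearest-integer shares exceed n; using largest-remainder apportionment")
    exact <- n * comp / sum(comp)
    base <- floor(exact)
    extra <- order(exact - base, decreasing = TRUE)[seq_len(n - sum(base))]
    cts <- base
    cts[extra] <- cts[extra] + 1
    n_med <- cts[["median"]]; n_uln <- cts[["ulnar"]]; n_both <- cts[["both"]]
  }
  counts <- c(median = n_med, ulnar = n_uln, both = n_both)
  assignment <- withr::with_seed(seed, {
    setNames(sample(rep(names(counts), counts)), control_ids)
  })
  structure(list(assignment = assignment, counts = counts, seed = seed),
            class = "locog_matching")
}

#' Per-control reference values on matched territories
#'
#' For each control, the metric is evaluated per hand on the target subset of
#' the control's matched nerve condition. A paired t test across controls
#' (dominant vs nondominant) gates hand averaging: if it finds no difference
#' (p >= alpha) each control contributes the mean of its two hands; otherwise
#' hands are kept separate and the result is flagged.
#'
#' @param controls named list (by participant id) of lists with elements
#'   `dominant` and `nondominant`, each a `locog_session`.
#' @param matching a [match_controls()] result.
#' @param metric function(session, target_ids) -> scalar; default mean
#'   absolute error excluding misreferrals.
#' @param alpha gate alpha (default 0.05).
#' @return A list: `values` (tibble id, condition, dominant, nondominant,
#'   value), `hands_averaged` (logical), `gate` (the paired comparison).
#' @export
control_reference <- function(controls, matching,
                              metric = metric_mean_abs_error, alpha = 0.05) {
  ids <- names(controls)
  miss <- setdiff(ids, names(matching$assignment))
  if (length(miss) > 0) {
    stop_locog(paste("controls missing from matching:", paste(miss, collapse = ", ")),
               "locog_validation_error")
  }
  rows <- lapply(ids, function(id) {
    cond <- matching$assignment[[id]]
    hands <- controls[[id]]
    if (is.null(hands$dominant) || is.null(hands$nondominant)) {
      warning(paste0("control ", id, " lacks a hand; excluded"), call. = FALSE)
      return(NULL)
    }
    per_hand <- vapply(hands[c("dominant", "nondominant")], function(s) {
      ids_t <- injured_targets(cond, s$targets)
      metric(s, ids_t)
    }, numeric(1))
    tibble::tibble(id = id, condition = cond,
                   dominant = per_hand[["dominant"]],
                   nondominant = per_hand[["nondominant"]])
  })
  values <- dplyr::bind_rows(rows)
  if (nrow(values) < 3) {
    stop_locog("need at least 3 complete controls", "locog_validation_error")
  }
  gate <- compare_paired(values$dominant, values$nondominant)
  averaged <- gate$p >= alpha
  values$value <- if (averaged) (values$dominant + values$nondominant) / 2 else NA_real_
  list(values = values, hands_averaged = averaged, gate = gate)
}

#' Mean absolute localization error on a target subset
#'
#' Default metric for [control_reference()]: mean absolute error in mm over
#' non-misreferral trials of the given targets.
#'
#' @param s a `locog_session`.
#' @param target_ids target ids to include.
#' @return Scalar mm.
#' @export
metric_mean_abs_error <- function(s, target_ids) {
  aggregate_errors(detect_misreferrals(s), target_ids)$mean_abs
}
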