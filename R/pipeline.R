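#' Analysis configuration
#'
#' @param decomposition error decomposition mode, `"orthogonal"` or
#'   `"as_printed"`.
#' @param matching_seed seed for the random control-to-condition assignment.
#' @param alpha_gate alpha for the Shapiro-Wilk / Levene / hand-averaging
#'   gates.
#' @param bonferroni_family family size for the directional-bias tests
#'   (default 6: 3 groups x 2 components per digit analysis).
#' @return A list of class `locog_config`.
#' @export
run_config <- function(decomposition = c("orthogonal", "as_printed"),
                       matching_seed = 1L, alpha_gate = 0.05,
                       bonferroni_family = 6L) {
  structure(list(decomposition = match.arg(decomposition),
                 matching_seed = as.integer(matching_seed),
                 alpha_gate = alpha_gate,
                 bonferroni_family = as.integer(bonferroni_family)),
            class = "locog_config")
}

digit_mean <- function(metrics, targets, digit, component = "e_abs") {
  ids <- targets$id[targets$digit == digit]
  m <- metrics[metrics$target_id %in% ids & !is.na(metrics$is_misreferral) &
                 !metrics$is_misreferral, ]
  if (nrow(m) == 0) return(NA_real_)
  mean(m[[component]])
}

#' Summarize one participant's session(s)
#'
#' For a patient, supply `injured` and `uninjured` sessions: computes the
#' territory-restricted mean errors (Inj condition = targets in the injured
#' nerve's territory; Uninj = homologous targets on the other hand), their
#' difference score (Inj - Uninj; positive = impairment), per-digit means,
#' and misreferral summaries per hand. For a control, supply `dominant` and
#' `nondominant`: whole-hand and per-digit means plus misreferral summaries.
#' Overlay data (targets and responses with digit labels) are returned for
#' plotting or export.
#'
#' @param sessions named list of `locog_session`s: `injured`/`uninjured` or
#'   `dominant`/`nondominant`.
#' @param config a [run_config()].
#' @return A list of class `locog_participant_summary`.
#' @export
run_participant <- function(sessions, config = run_config()) {
  nms <- names(sessions)
  is_patient <- all(c("injured", "uninjured") %in% nms)
  if (!is_patient && !all(c("dominant", "nondominant") %in% nms)) {
    stop_locog("sessions must be injured/uninjured or dominant/nondominant",
               "locog_validation_error")
  }
  hands <- if (is_patient) c("injured", "uninjured") else c("dominant", "nondominant")
  metrics <- lapply(sessions[hands], detect_misreferrals, mode = config$decomposition)
  mis <- lapply(metrics, misreferral_summary)
  overlay <- dplyr::bind_rows(lapply(hands, function(h) {
    s <- sessions[[h]]
    tg <- s$targets[match(s$trials$target_id, s$targets$id), ]
    tibble::tibble(hand = h, block = s$trials$block, digit = tg$digit,
                   target_x = tg$x, target_y = tg$y,
                   response_x = s$trials$x, response_y = s$trials$y)
  }))
  per_digit <- dplyr::bind_rows(lapply(hands, function(h) {
    dplyr::bind_rows(lapply(c("D2", "D5"), function(d) {
      tibble::tibble(
        hand = h, digit = d,
        mean_abs = digit_mean(metrics[[h]], sessions[[h]]$targets, d, "e_abs"),
        mean_long = digit_mean(metrics[[h]], sessions[[h]]$targets, d, "e_long"),
        mean_trans = digit_mean(metrics[[h]], sessions[[h]]$targets, d, "e_trans"))
    }))
  }))
  out <- list(id = sessions[[hands[1]]]$participant$id,
              group = if (is_patient) "patient" else "control",
              metrics = metrics, misreferrals = mis, per_digit = per_digit,
              overlay = overlay)
  if (is_patient) {
    inj <- sessions$injured
    nerve <- nerve_condition(inj$participant$injury)
    inj_ids <- injured_targets(nerve, inj$targets)
    pairing <- homologous_pairing(inj_ids, inj, sessions$uninjured)
    agg_inj <- aggregate_errors(metrics$injured, inj_ids)
    agg_uninj <- aggregate_errors(metrics$uninjured, pairing$uninj_id)
    out$nerve <- nerve
    out$inj_mean <- agg_inj$mean_abs
    out$uninj_mean <- agg_uninj$mean_abs
    out$difference <- agg_inj$mean_abs - agg_uninj$mean_abs
  } else {
    out$hand_means <- vapply(hands, function(h)
      aggregate_errors(metrics[[h]])$mean_abs, numeric(1))
  }
  structure(out, class = "locog_participant_summary")
}

bias_family <- function(ps_controls, ps_by_group, digit, family_size, alpha) {
  groups <- c(list(controls = NULL), ps_by_group)
  rows <- list()
  for (g in names(groups)) {
    for (comp in c("mean_long", "mean_trans")) {
      vals <- if (g == "controls") {
        vapply(ps_controls, function(p) {
          v <- p$per_digit[[comp]][p$per_digit$digit == digit]
          mean(v)  # average the two hands
        }, numeric(1))
      } else {
        vapply(groups[[g]], function(p) {
          p$per_digit[[comp]][p$per_digit$digit == digit &
                                p$per_digit$hand == "injured"]
        }, numeric(1))
      }
      vals <- vals[!is.na(vals)]
      if (length(vals) < 3 || sd(vals) == 0) next
      cmp <- one_sample_bias_test(vals, family_size = family_size, alpha = alpha)
      rows[[paste(digit, g, comp, sep = "_")]] <- cmp
    }
  }
  rows
}

#' Run the full group-level analysis
#'
#' Executes, in order: per-participant summaries; the patient Inj-vs-Uninj
#' paired comparison; proportional control matching and the control
#' hand-averaging gate; patient-vs-control unpaired comparisons (injured and
#' uninjured hand); digit-specific subgroup analyses for D2 (median-injured
#' expected impaired) and D5 (ulnar-injured expected impaired); directional
#' bias tests with Bonferroni correction; the misreferral group comparison on
#' arcsine-transformed proportions; pooled goodness-of-fit tests and
#' confusion matrices; and optional validity correlations when clinical
#' scores are supplied.
#'
#' @param patients named list of `list(nerve, injured, uninjured)` (as from
#'   [generate_cohort()]).
#' @param controls named list of `list(dominant, nondominant)`.
#' @param config a [run_config()].
#' @param clinical optional named list (by patient id) of clinical score
#'   lists (e.g. `list(rosen = 250, marsh_injured = 80, ...)`).
#' @return A list of class `locog_group_report`.
#' @export
run_group <- function(patients, controls, config = run_config(),
                      clinical = NULL) {
  if (length(patients) < 3) stop_locog("no or too few patients (need >= 3)",
                                       "locog_validation_error")
  if (length(controls) < 3) stop_locog("too few controls (need >= 3)",
                                       "locog_validation_error")

  ps_pat <- lapply(patients, function(p)
    run_participant(p[c("injured", "uninjured")], config))
  ps_ctl <- lapply(controls, run_participant, config = config)

  patient_summaries <- dplyr::bind_rows(lapply(names(ps_pat), function(id) {
    p <- ps_pat[[id]]
    tibble::tibble(id = id, nerve = p$nerve, inj_mean = p$inj_mean,
                   uninj_mean = p$uninj_mean, difference = p$difference,
                   misreferral_prop_injured = p$misreferrals$injured$proportion_total)
  }))

  comparisons <- list()
  comparisons$inj_vs_uninj <- compare_paired(patient_summaries$inj_mean,
                                             patient_summaries$uninj_mean,
                                             alpha_gate = config$alpha_gate)

  composition <- table(factor(patient_summaries$nerve,
                              levels = c("median", "ulnar", "both")))
  composition <- setNames(as.integer(composition), names(composition))
  matching <- match_controls(names(controls), composition,
                             seed = config$matching_seed)
  ctl_ref <- control_reference(controls, matching, alpha = config$alpha_gate)
  ctl_values <- if (ctl_ref$hands_averaged) ctl_ref$values$value else
    (ctl_ref$values$dominant + ctl_ref$values$nondominant) / 2

  comparisons$injured_vs_controls <- compare_unpaired(
    patient_summaries$inj_mean, ctl_values, alpha_gate = config$alpha_gate)
  comparisons$uninjured_vs_controls <- compare_unpaired(
    patient_summaries$uninj_mean, ctl_values, alpha_gate = config$alpha_gate)

  # digit-specific subgroups: D2 expects impairment after median injury,
  # D5 after ulnar injury; the isolated other-nerve group is the patient
  # control group
  digit_specific <- list()
  spec_def <- list(
    D2 = list(expected = c("median", "both"), patient_control = "ulnar"),
    D5 = list(expected = c("ulnar", "both"), patient_control = "median")
  )
  ctl_digit_mean <- function(d) {
    vapply(ps_ctl, function(p) {
      mean(p$per_digit$mean_abs[p$per_digit$digit == d])
    }, numeric(1))
  }
  pat_digit_mean <- function(ids, d, hand) {
    vapply(ps_pat[ids], function(p) {
      p$per_digit$mean_abs[p$per_digit$digit == d & p$per_digit$hand == hand]
    }, numeric(1))
  }
  for (d in names(spec_def)) {
    def <- spec_def[[d]]
    exp_ids <- patient_summaries$id[patient_summaries$nerve %in% def$expected]
    pc_ids <- patient_summaries$id[patient_summaries$nerve == def$patient_control]
    res <- list(expected_ids = exp_ids, patient_control_ids = pc_ids)
    ctl_vals <- ctl_digit_mean(d)
    if (length(exp_ids) >= 3) {
      res$expected_inj_vs_uninj <- compare_paired(
        pat_digit_mean(exp_ids, d, "injured"),
        pat_digit_mean(exp_ids, d, "uninjured"), config$alpha_gate)
      res$expected_vs_controls <- compare_unpaired(
        pat_digit_mean(exp_ids, d, "injured"), ctl_vals, config$alpha_gate)
    }
    if (length(pc_ids) >= 3) {
      res$patient_control_inj_vs_uninj <- compare_paired(
        pat_digit_mean(pc_ids, d, "injured"),
        pat_digit_mean(pc_ids, d, "uninjured"), config$alpha_gate)
      res$patient_control_vs_controls <- compare_unpaired(
        pat_digit_mean(pc_ids, d, "injured"), ctl_vals, config$alpha_gate)
    }
    digit_specific[[d]] <- res
  }

  bias_tests <- list()
  for (d in names(spec_def)) {
    groups <- list(
      expected = ps_pat[patient_summaries$id[patient_summaries$nerve %in%
                                               spec_def[[d]]$expected]],
      patient_control = ps_pat[patient_summaries$id[patient_summaries$nerve ==
                                                      spec_def[[d]]$patient_control]]
    )
    bias_tests <- c(bias_tests,
                    bias_family(ps_ctl, groups, d,
                                config$bonferroni_family, 0.05))
  }

  # misreferrals: patients' injured hand vs controls (hand gate, then average)
  ctl_props <- vapply(ps_ctl, function(p)
    c(p$misreferrals$dominant$proportion_total,
      p$misreferrals$nondominant$proportion_total), numeric(2))
  # a degenerate gate (constant nonzero hand difference, possible in very
  # small cohorts with few misreferrals) is indeterminate: fall back to
  # averaging with a warning
  mis_gate <- tryCatch(
    compare_paired(ctl_props[1, ], ctl_props[2, ], config$alpha_gate),
    locog_degenerate_error = function(e) {
      warning("misreferral hand gate degenerate; hands averaged", call. = FALSE)
      NULL
    })
  ctl_mis <- colMeans(ctl_props)
  pat_mis <- patient_summaries$misreferral_prop_injured
  comparisons$misreferrals_patients_vs_controls <- compare_unpaired(
    arcsine_transform(pat_mis), arcsine_transform(ctl_mis), config$alpha_gate)

  pooled_counts <- function(summaries) {
    Reduce(`+`, lapply(summaries, function(m) m$counts_by_digit))
  }
  ctl_counts <- pooled_counts(lapply(ps_ctl, function(p)
    list(counts_by_digit = (p$misreferrals$dominant$counts_by_digit +
                              p$misreferrals$nondominant$counts_by_digit) / 2)))
  pat_counts <- pooled_counts(lapply(ps_pat, function(p) p$misreferrals$injured))
  gof <- list()
  if (sum(ctl_counts) > 0) {
    gof$controls <- suppressWarnings(
      gof_chi_squared(ctl_counts, theoretical_distribution()))
  }
  if (sum(pat_counts) > 0) {
    gof$patients_injured <- suppressWarnings(
      gof_chi_squared(pat_counts, theoretical_distribution()))
  }
  # average per-hand proportion matrices over control hands that made at
  # least one misreferral (proportions are undefined for the others)
  ctl_hand_metrics <- unlist(lapply(ps_ctl, function(p) p$metrics),
                             recursive = FALSE)
  with_mis <- vapply(ctl_hand_metrics, function(m)
    sum(m$is_misreferral, na.rm = TRUE) > 0, logical(1))
  ctl_confusion <- if (any(with_mis)) {
    confusion_matrix(ctl_hand_metrics[with_mis], "averaged_hands")
  } else {
    confusion_matrix(ctl_hand_metrics[[1]])
  }
  confusion <- list(
    controls = ctl_confusion,
    patients_injured = confusion_matrix(
      dplyr::bind_rows(lapply(ps_pat, function(p) p$metrics$injured))),
    patients_uninjured = confusion_matrix(
      dplyr::bind_rows(lapply(ps_pat, function(p) p$metrics$uninjured)))
  )

  validity <- NULL
  if (!is.null(clinical)) {
    ids <- intersect(patient_summaries$id, names(clinical))
    if (length(ids) >= 3) {
      diffs <- patient_summaries$difference[match(ids, patient_summaries$id)]
      grab <- function(f) vapply(clinical[ids], function(x)
        as.numeric(x[[f]] %||% NA_real_), numeric(1))
      validity <- list()
      rosen <- grab("rosen")
      if (sum(complete.cases(diffs, rosen)) >= 3) {
        validity$rosen <- validity_correlation(diffs, rosen)
      }
      mi <- grab("marsh_injured"); mu <- grab("marsh_uninjured")
      marsh_diff <- mi - mu
      if (sum(complete.cases(diffs, marsh_diff)) >= 3) {
        validity$marsh <- validity_correlation(diffs, marsh_diff)
      }
    }
  }

  structure(
    list(patient_summaries = patient_summaries,
         matching = matching,
         control_reference = ctl_ref,
         control_values = ctl_values,
         comparisons = comparisons,
         digit_specific = digit_specific,
         bias_tests = bias_tests,
         misreferral_hand_gate = mis_gate,
         gof = gof,
         confusion = confusion,
         validity = validity,
         comparison_table = comparison_table(c(comparisons, bias_tests)),
         manifest = list(config = unclass(config),
                         n_patients = length(patients),
                         n_controls = length(controls),
                         composition = as.list(composition),
                         matching_seed = config$matching_seed)),
    class = "locog_group_report"
  )
}

#' @export
print.locog_group_report <- function(x, ...) {
  cat(sprintf("<group report> %d patients, %d controls\n",
              x$manifest$n_patients, x$manifest$n_controls))
  print(x$comparisons$inj_vs_uninj)
  print(x$comparisons$injured_vs_controls)
  invisible(x)
}

#' Overlay plot of targets and responses
#'
#' Responses colored by stimulated digit over the target layout, mirroring
#' the individual-level inspection view. Requires ggplot2.
#'
#' @param summary a [run_participant()] result.
#' @return A ggplot object.
#' @export
plot_overlay <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_locog("ggplot2 is required for plotting", "locog_config_error")
  }
  ov <- summary$overlay
  ggplot2::ggplot(ov) +
    ggplot2::geom_point(ggplot2::aes(x = .data$target_x, y = .data$target_y),
                        color = "grey60", shape = 1, size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$response_x, y = .data$response_y,
                                     color = .data$digit), alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~hand) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "stimulated digit")
}
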