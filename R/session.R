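#' Construct a participant record
#'
#' @param id participant identifier.
#' @param group `"control"` or `"patient"`.
#' @param sex `"f"`, `"m"` or `"other"`.
#' @param age age in years.
#' @param handedness_score Waterloo handedness score, integer in \[-30, 30\].
#' @param injury for patients, an [injury_record()]; must be `NULL` for
#'   controls.
#' @return A list of class `locog_participant`.
#' @examples
#' participant("C01", "control", sex = "f", age = 31, handedness_score = 25)
#' @export
participant <- function(id, group = c("control", "patient"), sex = "other",
                        age = NA_real_, handedness_score = 0L, injury = NULL) {
  group <- match.arg(group)
  if (!is.numeric(handedness_score) || handedness_score < -30 || handedness_score > 30) {
    stop_locog("handedness_score must lie in [-30, 30]", "locog_validation_error")
  }
  if (group == "patient" && is.null(injury)) {
    stop_locog("patients must carry an injury record", "locog_validation_error")
  }
  if (group == "control" && !is.null(injury)) {
    stop_locog("controls must not carry an injury record", "locog_validation_error")
  }
  structure(
    list(id = as.character(id), group = group, sex = sex, age = age,
         handedness_score = as.integer(handedness_score), injury = injury),
    class = "locog_participant"
  )
}

#' Construct an injury record
#'
#' @param nerves character vector drawn from `"median"`, `"ulnar"` (nonempty).
#' @param completeness `"complete"` or `"partial"`.
#' @param side injured side, `"left"` or `"right"`.
#' @param months_since_repair months elapsed since surgical repair (> 0).
#' @return A list of class `locog_injury`.
#' @export
injury_record <- function(nerves, completeness = c("complete", "partial"),
                          side = c("left", "right"), months_since_repair) {
  completeness <- match.arg(completeness)
  side <- match.arg(side)
  nerves <- unique(as.character(nerves))
  if (length(nerves) == 0 || !all(nerves %in% c("median", "ulnar"))) {
    stop_locog("nerves must be a nonempty subset of {median, ulnar}",
               "locog_validation_error")
  }
  if (!is.numeric(months_since_repair) || months_since_repair <= 0) {
    stop_locog("months_since_repair must be > 0", "locog_validation_error")
  }
  structure(
    list(nerves = sort(nerves), completeness = completeness, side = side,
         months_since_repair = as.numeric(months_since_repair)),
    class = "locog_injury"
  )
}

#' Nerve condition implied by an injury record
#'
#' Collapses the injured nerve set to the analysis condition: `"median"`,
#' `"ulnar"`, or `"both"`.
#' @param injury an [injury_record()].
#' @return Character scalar.
#' @export
nerve_condition <- function(injury) {
  if (is.null(injury)) stop_locog("no injury record", "locog_validation_error")
  if (length(injury$nerves) == 2) "both" else injury$nerves
}

#' Assemble a test session
#'
#' A session is one hand's complete test: participant metadata, the hand map
#' (calibration, digit axes, region polygons, crease), the 18 marked targets
#' and the recorded trials (normally 5 blocks x 18 targets = 90).
#'
#' @param participant a [participant()].
#' @param hand_side `"left"` or `"right"`.
#' @param hand_role `"injured"`/`"uninjured"` for patients,
#'   `"dominant"`/`"nondominant"` for controls.
#' @param hand_map a [hand_map()].
#' @param targets tibble with columns `id`, `digit`, `subzone`, `x`, `y`
#'   (pixel coordinates).
#' @param trials tibble with columns `block`, `target_id`, `x`, `y`.
#' @param validate check invariants (default `TRUE`).
#' @return A list of class `locog_session`.
#' @export
session <- function(participant, hand_side = c("left", "right"),
                    hand_role = c("dominant", "nondominant", "injured", "uninjured"),
                    hand_map, targets, trials, validate = TRUE) {
  hand_side <- match.arg(hand_side)
  hand_role <- match.arg(hand_role)
  s <- structure(
    list(participant = participant, hand_side = hand_side,
         hand_role = hand_role, hand_map = hand_map,
         targets = tibble::as_tibble(targets),
         trials = tibble::as_tibble(trials)),
    class = "locog_session"
  )
  if (validate) validate_session(s)
  s
}

#' Validate a session's invariants
#'
#' Hard invariants (errors): target/trial schema, every trial's `target_id`
#' resolves, target multiset is the standard layout (2 thumb + 4 per finger),
#' hand role consistent with the participant group, positive calibration.
#' Soft invariants (warnings): fewer than 90 trials or blocks not covering
#' every target exactly once.
#'
#' @param s a `locog_session`.
#' @return `s`, invisibly.
#' @export
validate_session <- function(s) {
  tg <- s$targets
  tr <- s$trials
  need_t <- c("id", "digit", "subzone", "x", "y")
  if (!all(need_t %in% names(tg))) {
    stop_locog(paste("targets missing column(s):",
                     paste(setdiff(need_t, names(tg)), collapse = ", ")),
               "locog_schema_error")
  }
  need_r <- c("block", "target_id", "x", "y")
  if (!all(need_r %in% names(tr))) {
    stop_locog(paste("trials missing column(s):",
                     paste(setdiff(need_r, names(tr)), collapse = ", ")),
               "locog_schema_error")
  }
  if (anyDuplicated(tg$id)) {
    stop_locog("duplicate target ids", "locog_validation_error")
  }
  if (!all(tg$digit %in% DIGITS)) {
    stop_locog("target digit outside D1..D5", "locog_validation_error")
  }
  if (!all(tg$subzone %in% SUBZONES)) {
    stop_locog("unknown target subzone", "locog_validation_error")
  }
  counts <- table(factor(tg$digit, levels = DIGITS))
  if (!all(counts == STANDARD_LAYOUT)) {
    stop_locog(sprintf(
      "target layout is (%s); expected the standard (2,4,4,4,4)",
      paste(counts, collapse = ",")), "locog_validation_error")
  }
  if (any(tg$digit == "D1" & !grepl("^radial", tg$subzone))) {
    stop_locog("thumb targets must use radial subzones only",
               "locog_validation_error")
  }
  bad <- setdiff(tr$target_id, tg$id)
  if (length(bad) > 0) {
    stop_locog(paste("trial references unknown target id(s):",
                     paste(unique(bad), collapse = ", ")),
               "locog_referential_error")
  }
  role_pat <- s$hand_role %in% c("injured", "uninjured")
  is_pat <- s$participant$group == "patient"
  if (role_pat != is_pat) {
    stop_locog("hand_role injured/uninjured is for patients only (and vice versa)",
               "locog_validation_error")
  }
  if (nrow(tr) != 90) {
    warning(sprintf("session has %d trials (full design is 90); analyses use available trials",
                    nrow(tr)), call. = FALSE)
  } else {
    per_block <- split(tr$target_id, tr$block)
    ok <- length(per_block) == 5 &&
      all(vapply(per_block, function(ids) setequal(ids, tg$id) && !anyDuplicated(ids),
                 logical(1)))
    if (!ok) {
      warning("blocks do not each contain every target exactly once", call. = FALSE)
    }
  }
  validate_hand_map(s$hand_map, targets = tg)
  invisible(s)
}

sessions_of <- function(x) {
  # accept a single session or a list of sessions
  if (inherits(x, "locog_session")) list(x) else x
}

#' @export
print.locog_session <- function(x, ...) {
  p <- x$participant
  cat(sprintf("<locog_session> %s (%s), %s hand (%s): %d targets, %d trials\n",
              p$id, p$group, x$hand_side, x$hand_role,
              nrow(x$targets), nrow(x$trials)))
  invisible(x)
}

# ---- JSON serialization ------------------------------------------------

session_to_list <- function(s) {
  p <- s$participant
  part <- list(id = p$id, group = p$group, sex = p$sex, age = p$age,
               handedness_score = p$handedness_score)
  if (!is.null(p$injury)) {
    part$injury <- list(nerves = p$injury$nerves,
                        completeness = p$injury$completeness,
                        side = p$injury$side,
                        months_since_repair = p$injury$months_since_repair)
  }
  hm <- s$hand_map
  list(
    schema_version = 1L,
    participant = part,
    hand = list(side = s$hand_side, role = s$hand_role),
    calibration = list(fx = hm$calibration$fx, fy = hm$calibration$fy),
    digit_axes = as.list(hm$digit_axes),
    regions = lapply(hm$regions, function(m) unname(apply(m, 1, as.numeric, simplify = FALSE))),
    crease = unname(apply(hm$crease, 1, as.numeric, simplify = FALSE)),
    targets = lapply(seq_len(nrow(s$targets)), function(i) {
      t <- s$targets[i, ]
      list(id = t$id, digit = t$digit, subzone = t$subzone,
           position = c(t$x, t$y))
    }),
    trials = lapply(seq_len(nrow(s$trials)), function(i) {
      t <- s$trials[i, ]
      list(block = t$block, target_id = t$target_id, response = c(t$x, t$y))
    })
  )
}

session_from_list <- function(x, path = "<in-memory>") {
  req <- c("schema_version", "participant", "hand", "calibration",
           "digit_axes", "regions", "targets", "trials")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop_locog(paste0(path, ": missing top-level key(s): ",
                      paste(miss, collapse = ", ")), "locog_schema_error")
  }
  p <- x$participant
  for (f in c("id", "group")) {
    if (is.null(p[[f]])) {
      stop_locog(paste0(path, ": participant.", f, " is required"),
                 "locog_schema_error")
    }
  }
  inj <- NULL
  if (!is.null(p$injury)) {
    inj <- injury_record(unlist(p$injury$nerves), p$injury$completeness,
                         p$injury$side, p$injury$months_since_repair)
  }
  part <- participant(p$id, p$group, p$sex %||% "other",
                      p$age %||% NA_real_, p$handedness_score %||% 0L, inj)
  pts <- function(lst) {
    do.call(rbind, lapply(lst, function(q) as.numeric(unlist(q))))
  }
  hm <- hand_map(
    calibration = calibration(x$calibration$fx, x$calibration$fy),
    digit_axes = unlist(x$digit_axes),
    regions = lapply(x$regions, pts),
    crease = pts(x$crease)
  )
  tg_list <- x$targets
  tr_list <- x$trials
  targets <- tibble::tibble(
    id = vapply(tg_list, function(t) as.character(t$id), character(1)),
    digit = vapply(tg_list, function(t) as.character(t$digit), character(1)),
    subzone = vapply(tg_list, function(t) as.character(t$subzone), character(1)),
    x = vapply(tg_list, function(t) as.numeric(t$position[[1]]), numeric(1)),
    y = vapply(tg_list, function(t) as.numeric(t$position[[2]]), numeric(1))
  )
  trials <- tibble::tibble(
    block = vapply(tr_list, function(t) as.integer(t$block), integer(1)),
    target_id = vapply(tr_list, function(t) as.character(t$target_id), character(1)),
    x = vapply(tr_list, function(t) as.numeric(t$response[[1]]), numeric(1)),
    y = vapply(tr_list, function(t) as.numeric(t$response[[2]]), numeric(1))
  )
  session(part, x$hand$side, x$hand$role, hm, targets, trials)
}

#' Read a session file
#'
#' Parses and validates a session JSON file (schema: top-level keys
#' `schema_version`, `participant`, `hand`, `calibration`, `digit_axes`,
#' `regions`, `crease`, `targets`, `trials`).
#'
#' @param path path to a session JSON file.
#' @return A validated `locog_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) {
    stop_locog(paste0("no such file: ", path), "locog_io_error")
  }
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) {
                  stop_locog(paste0(path, ": malformed JSON (", conditionMessage(e), ")"),
                             "locog_parse_error")
                })
  session_from_list(x, path = path)
}

#' Write a session file
#'
#' Emits schema-conformant JSON with deterministic field ordering; optional
#' fields that are absent are omitted rather than null-filled.
#'
#' @param s a `locog_session`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  json <- jsonlite::toJSON(session_to_list(s), auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_locog(paste0("cannot write to ", path), "locog_io_error")
  invisible(path)
}

#' Export a per-trial metrics table as CSV
#'
#' One row per trial: participant id, hand side/role, block, target id,
#' digit, subzone, response region, misreferral flag, and the absolute /
#' longitudinal / transverse errors in mm (empty for misreferrals).
#'
#' @param s a `locog_session`.
#' @param metrics per-trial metrics from [detect_misreferrals()], aligned
#'   one-to-one with `s$trials`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trial_table <- function(s, metrics, path) {
  if (nrow(metrics) != nrow(s$trials)) {
    stop_locog(sprintf("metrics (%d rows) not aligned with trials (%d rows)",
                       nrow(metrics), nrow(s$trials)), "locog_alignment_error")
  }
  out <- data.frame(
    participant_id = s$participant$id,
    hand_side = s$hand_side,
    hand_role = s$hand_role,
    block = metrics$block,
    target_id = metrics$target_id,
    digit = metrics$digit,
    subzone = metrics$subzone,
    response_region = metrics$response_region,
    misreferral = metrics$is_misreferral,
    e_abs_mm = metrics$e_abs,
    e_long_mm = metrics$e_long,
    e_trans_mm = metrics$e_trans,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read optional clinical scores sidecar
#'
#' Sidecar JSON with any of the keys `rosen`, `marsh_injured`,
#' `marsh_uninjured`, `dash`, `mcgill`.
#' @param path sidecar path.
#' @return Named list of numeric scores.
#' @export
read_clinical_scores <- function(path) {
  x <- jsonlite::read_json(path)
  keep <- intersect(names(x), c("rosen", "marsh_injured", "marsh_uninjured",
                                "dash", "mcgill"))
  lapply(x[keep], as.numeric)
}
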