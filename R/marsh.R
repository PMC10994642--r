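#' Modified Marsh zone map
#'
#' The modified Marsh test divides the distal pads of the five digits into
#' quadrants, 20 zones in all. The default map numbers zones digit-by-digit
#' starting at D1, in quadrant order radial-distal, radial-proximal,
#' ulnar-distal, ulnar-proximal; so zones 1-4 are D1, 5-8 D2, 9-12 D3,
#' 13-16 D4 (13-14 the radial half, 15-16 the ulnar half), 17-20 D5. This is
#' the only numbering under which zones 1-14 (median-tested) cover D1-D3 plus
#' the radial half of D4, and 15-20 (ulnar-tested) the ulnar half of D4 plus
#' D5.
#'
#' Within a digit, zones are adjacent when their quadrants share an edge
#' (diagonal quadrants are not adjacent). A zone's homologs are the
#' same-quadrant zones on the immediately neighboring digit(s). All three
#' components can be overridden with [read_marsh_map()].
#'
#' @return A list of class `locog_marsh_map`: `zones` (tibble `zone`,
#'   `digit`, `quadrant`), `adjacency` and `homologs` (lists of integer
#'   vectors indexed by zone).
#' @export
marsh_zone_map <- function() {
  zones <- tibble::tibble(
    zone = 1:20,
    digit = rep(DIGITS, each = 4),
    quadrant = rep(SUBZONES, 5)
  )
  edge_adjacent <- list(
    "radial-distal" = c("radial-proximal", "ulnar-distal"),
    "radial-proximal" = c("radial-distal", "ulnar-proximal"),
    "ulnar-distal" = c("ulnar-proximal", "radial-distal"),
    "ulnar-proximal" = c("ulnar-distal", "radial-proximal")
  )
  adjacency <- lapply(1:20, function(z) {
    d <- zones$digit[z]; q <- zones$quadrant[z]
    zones$zone[zones$digit == d & zones$quadrant %in% edge_adjacent[[q]]]
  })
  homologs <- lapply(1:20, function(z) {
    d_i <- match(zones$digit[z], DIGITS)
    nb <- DIGITS[c(d_i - 1, d_i + 1)]
    nb <- nb[!is.na(nb)]
    zones$zone[zones$digit %in% nb & zones$quadrant == zones$quadrant[z]]
  })
  new_marsh_map(zones, adjacency, homologs)
}

new_marsh_map <- function(zones, adjacency, homologs) {
  m <- structure(list(zones = zones, adjacency = adjacency, homologs = homologs),
                 class = "locog_marsh_map")
  validate_marsh_map(m)
}

validate_marsh_map <- function(m) {
  z <- m$zones
  if (nrow(z) != 20 || !setequal(z$zone, 1:20)) {
    stop_locog("marsh map must define zones 1..20", "locog_validation_error")
  }
  if (!all(table(z$digit)[DIGITS] == 4)) {
    stop_locog("each digit must carry exactly 4 zones", "locog_validation_error")
  }
  for (i in 1:20) {
    adj <- m$adjacency[[i]]
    if (i %in% adj) stop_locog("adjacency must be irreflexive", "locog_validation_error")
    if (!all(vapply(adj, function(j) i %in% m$adjacency[[j]], logical(1)))) {
      stop_locog("adjacency must be symmetric", "locog_validation_error")
    }
    if (!all(z$digit[match(adj, z$zone)] == z$digit[match(i, z$zone)])) {
      stop_locog("adjacency must stay within a digit", "locog_validation_error")
    }
    hom <- m$homologs[[i]]
    d_i <- match(z$digit[match(i, z$zone)], DIGITS)
    d_h <- match(z$digit[match(hom, z$zone)], DIGITS)
    if (length(hom) > 0 && any(abs(d_h - d_i) != 1)) {
      stop_locog("homologs must link immediately neighboring digits",
                 "locog_validation_error")
    }
  }
  m
}

#' Read a Marsh zone map from JSON
#'
#' JSON with keys `zones` (array of `{zone, digit, quadrant}`), `adjacency`
#' and `homologs` (objects mapping zone number to arrays of zone numbers).
#' Intended for aligning with the official distributed materials when their
#' numbering differs from the default map.
#'
#' @param path JSON path.
#' @return A `locog_marsh_map`.
#' @export
read_marsh_map <- function(path) {
  x <- jsonlite::read_json(path)
  zones <- tibble::tibble(
    zone = vapply(x$zones, function(z) as.integer(z$zone), integer(1)),
    digit = vapply(x$zones, function(z) as.character(z$digit), character(1)),
    quadrant = vapply(x$zones, function(z) as.character(z$quadrant), character(1))
  )
  grab <- function(lst) {
    out <- vector("list", 20)
    for (i in 1:20) out[[i]] <- as.integer(unlist(lst[[as.character(i)]]))
    out
  }
  new_marsh_map(zones, grab(x$adjacency), grab(x$homologs))
}

#' Score one Marsh trial
#'
#' 2 points for the correct zone; 1 point for an adjacent zone of the same
#' digit; 1 point for the homologous (same-quadrant) zone of a neighboring
#' digit; 0 points otherwise.
#'
#' @param stimulated,reported zone numbers (1..20).
#' @param map a [marsh_zone_map()].
#' @return Integer points in `{0, 1, 2}`.
#' @export
score_trial <- function(stimulated, reported, map = marsh_zone_map()) {
  if (!stimulated %in% map$zones$zone || !reported %in% map$zones$zone) {
    stop_locog("unknown zone", "locog_validation_error")
  }
  if (reported == stimulated) return(2L)
  if (reported %in% map$adjacency[[stimulated]]) return(1L)
  if (reported %in% map$homologs[[stimulated]]) return(1L)
  0L
}

#' Zones tested per injury type
#'
#' Median-nerve patients are tested in zones 1-14, ulnar in 15-20, both in
#' all 20 (default map numbering).
#'
#' @param injury_type `"median"`, `"ulnar"` or `"both"`.
#' @return Integer vector of zone numbers.
#' @export
marsh_zones_tested <- function(injury_type = c("median", "ulnar", "both")) {
  switch(match.arg(injury_type), median = 1:14, ulnar = 15:20, both = 1:20)
}

#' Modified Marsh percentage score
#'
#' Sums trial scores and expresses them as a percentage of the maximum
#' attainable for the injury type: 2 points x 2 trials per zone x the number
#' of zones tested (median 56, ulnar 24, both 80).
#'
#' @param trials data frame with columns `stimulated`, `reported` (zones).
#' @param injury_type `"median"`, `"ulnar"` or `"both"`.
#' @param map a [marsh_zone_map()].
#' @return A list of class `locog_marsh_result`: `raw_score`, `max_score`,
#'   `percent`, `zones_tested`.
#' @export
marsh_percent <- function(trials, injury_type = c("median", "ulnar", "both"),
                          map = marsh_zone_map()) {
  injury_type <- match.arg(injury_type)
  zones <- marsh_zones_tested(injury_type)
  trials <- as.data.frame(trials)
  if (!all(c("stimulated", "reported") %in% names(trials))) {
    stop_locog("trials need columns stimulated, reported", "locog_schema_error")
  }
  if (!all(trials$stimulated %in% zones)) {
    stop_locog(sprintf("trial stimulates zone(s) outside those permitted for %s injury",
                       injury_type), "locog_validation_error")
  }
  pts <- mapply(score_trial, trials$stimulated, trials$reported,
                MoreArgs = list(map = map))
  raw <- sum(pts)
  max_score <- 2L * 2L * length(zones)
  structure(list(raw_score = as.integer(raw), max_score = max_score,
                 percent = 100 * raw / max_score, zones_tested = zones),
            class = "locog_marsh_result")
}

#' @export
print.locog_marsh_result <- function(x, ...) {
  cat(sprintf("<marsh result> %d/%d points = %.1f%% (%d zones tested)\n",
              x$raw_score, x$max_score, x$percent, length(x$zones_tested)))
  invisible(x)
}
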