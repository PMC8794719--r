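# Encounter-history containers. Histories are long-format data frames, one
# row per observation interval, in three dialects:
#   nest   : nest_id, female_id, age_class, attempt, year, start_doy,
#            day_index (1..27), state in {active, failed, hatched, censored}
#   female : female_id, age_class, year, month_index (1 = March .. 12 = Feb),
#            state in {alive, dead, censored}
#   brood  : brood_id, year, occasion_index (0 = initial egg count, 1..5 =
#            flush counts at 14, 24, 34, 44, 54 days post-hatch), count
# Long CSV rather than packed MARK "LDLD" strings keeps the data diff-able
# and testable; a one-way MARK exporter is provided for interoperability.

NEST_STATES <- c("active", "failed", "hatched", "censored")
FEMALE_STATES <- c("alive", "dead", "censored")
HISTORY_COLUMNS <- list(
  nest = c("nest_id", "female_id", "age_class", "attempt", "year",
           "start_doy", "day_index", "state"),
  female = c("female_id", "age_class", "year", "month_index", "state"),
  brood = c("brood_id", "year", "occasion_index", "count")
)

history_class <- function(dialect) paste0(dialect, "_histories")

#' Validate an encounter-history table
#'
#' Checks the invariants of the dialect: known states, interval indices within
#' the design window (27 days, 12 months, or occasions 0-5), no records after
#' a terminal state, and brood counts never exceeding the initial count.
#'
#' @param x Data frame in one of the three dialects.
#' @param dialect `"nest"`, `"female"` or `"brood"`.
#' @return `x` with class `<dialect>_histories`, or an error.
#' @export
validate_histories <- function(x, dialect = c("nest", "female", "brood")) {
  dialect <- match.arg(dialect)
  need <- HISTORY_COLUMNS[[dialect]]
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(dialect, " histories missing columns: ", paste(miss, collapse = ", "))
  x <- x[need]
  if (dialect == "nest") {
    if (!all(x$state %in% NEST_STATES)) stop("unknown nest state")
    if (!all(x$attempt %in% c("first", "renest"))) stop("unknown nest attempt")
    if (any(x$day_index < 1 | x$day_index > 27))
      stop("nest day_index must lie in 1..27")
    x <- x[order(x$nest_id, x$day_index), ]
    for (id in unique(x$nest_id)) {
      st <- x$state[x$nest_id == id]
      term <- which(st != "active")
      if (length(term) && any(term < length(st)))
        stop("nest ", id, ": records continue after a terminal state")
    }
  } else if (dialect == "female") {
    if (!all(x$state %in% FEMALE_STATES)) stop("unknown female state")
    if (any(x$month_index < 1 | x$month_index > 12))
      stop("female month_index must lie in 1..12 (1 = March)")
    x <- x[order(x$female_id, x$year, x$month_index), ]
    key <- paste(x$female_id, x$year)
    for (id in unique(key)) {
      sub <- x[key == id, ]
      if (any(diff(sub$month_index) != 1))
        stop("female ", sub$female_id[1], " year ", sub$year[1],
             ": monthly records must be consecutive after entry")
      term <- which(sub$state != "alive")
      if (length(term) > 1 || (length(term) && term < nrow(sub)))
        stop("female ", sub$female_id[1], " year ", sub$year[1],
             ": records continue after a terminal state")
    }
  } else {
    if (any(x$count < 0)) stop("brood counts must be >= 0")
    if (any(x$occasion_index < 0 | x$occasion_index > 5))
      stop("brood occasion_index must lie in 0..5")
    x <- x[order(x$brood_id, x$occasion_index), ]
    for (id in unique(x$brood_id)) {
      sub <- x[x$brood_id == id, ]
      if (sub$occasion_index[1] != 0)
        stop("brood ", id, ": missing initial count (occasion 0)")
      if (sub$count[1] < 1)
        stop("brood ", id, ": initial count must be >= 1")
      if (any(sub$count[-1] > sub$count[1]))
        stop("brood ", id, ": flush count exceeds initial count")
    }
  }
  rownames(x) <- NULL
  class(x) <- c(history_class(dialect), "data.frame")
  x
}

#' Read encounter histories from CSV
#'
#' @param path CSV file in the long format of the dialect.
#' @param dialect `"nest"`, `"female"` or `"brood"`.
#' @return A validated `<dialect>_histories` data frame.
#' @export
read_encounter_histories <- function(path,
                                     dialect = c("nest", "female", "brood")) {
  dialect <- match.arg(dialect)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_histories(x, dialect)
}

#' Write encounter histories to CSV
#'
#' Writes the long format read back bit-identically by
#' [read_encounter_histories()].
#'
#' @param x A `<dialect>_histories` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_encounter_histories <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Promote yearlings to adults in the year after confirmed survival
#'
#' A yearling (SY) alive at the start of March following her capture year is
#' an adult (ASY) in later demographic years. The rule is applied only to
#' birds confirmed alive through month 12 (not censored), since the fate of a
#' bird censored before the transition month is unknown.
#'
#' @param x A `female_histories` data frame spanning multiple years.
#' @return The table with `age_class` updated in later years.
#' @export
apply_age_transition <- function(x) {
  stopifnot(inherits(x, "female_histories"))
  for (id in unique(x$female_id)) {
    yrs <- sort(unique(x$year[x$female_id == id]))
    for (y in yrs) {
      sub <- x[x$female_id == id & x$year == y, ]
      survived <- nrow(sub) > 0 && sub$month_index[nrow(sub)] == 12 &&
        sub$state[nrow(sub)] == "alive"
      if (survived) x$age_class[x$female_id == id & x$year > y] <- "ASY"
    }
  }
  x
}

#' Export known-fate encounter histories as MARK-style LDLD strings
#'
#' Each monitored interval becomes a live/dead pair: `"10"` survived, `"11"`
#' died, `"00"` not monitored (before staggered entry or after censoring).
#' One-way export for interoperability; never read back.
#'
#' @param x A `nest_histories` or `female_histories` data frame.
#' @return Character vector of encounter strings named by individual.
#' @export
mark_known_fate_strings <- function(x) {
  if (inherits(x, "nest_histories")) {
    iv <- kf_intervals(x); width <- 27; id <- iv$id
  } else if (inherits(x, "female_histories")) {
    iv <- kf_intervals(x); width <- 12; id <- iv$id
  } else stop("expected nest or female histories")
  out <- vapply(unique(id), function(i) {
    sub <- iv[id == i, ]
    pairs <- rep("00", width)
    pairs[sub$interval] <- ifelse(sub$survived == 1, "10", "11")
    paste(pairs, collapse = "")
  }, character(1))
  names(out) <- unique(id)
  out
}
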