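#' @import data.table
NULL

utils::globalVariables(c(
  "encounter_id", "patient_id", "arrival", "measured_at", "age_years",
  "sex", "elective", "companion", "has_national_id", "hospital",
  "death_date", "on_oxygen", "agitated", "gcs", "avpu", "..keep_cols",
  ".reason", "complete", "oxygen_only", "minutes", "died_7d", ".order",
  ".vit_ok", ".full_ok", ".in_window", "tie", "..drop_cols", "..vit_cols"
))

.encounter_cols <- c("encounter_id", "patient_id", "arrival", "age_years",
                     "sex", "elective", "companion", "has_national_id",
                     "hospital", "death_date")

# ISO-8601 aware timestamp parsing ("2015-03-01T08:00:00Z" and friends);
# base as.POSIXct's tryFormats do not cover the T/Z variants
.parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                            "%Y-%m-%d"),
             optional = TRUE)
}

# normalise a raw records table: types, encounter ids, basic sanity
.normalise_records <- function(records) {
  dt <- as.data.table(records)
  need <- c("patient_id", "arrival", "age_years", "sex", "elective",
            "companion", "has_national_id", "measured_at")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(dt$arrival, "POSIXct")) {
    dt[, arrival := .parse_ts(arrival)]
  }
  if (!inherits(dt$measured_at, "POSIXct")) {
    dt[, measured_at := .parse_ts(measured_at)]
  }
  if (!"death_date" %in% names(dt)) dt[, death_date := as.Date(NA)]
  if (!inherits(dt$death_date, "Date")) {
    dd <- as.character(dt$death_date)
    dd[!is.na(dd) & dd == ""] <- NA_character_
    dt[, death_date := as.Date(dd)]
  } else {
    dt[, death_date := as.Date(death_date)]  # normalise IDate to Date
  }
  if (!"hospital" %in% names(dt)) dt[, hospital := NA_character_]
  for (col in c("elective", "companion", "has_national_id", "agitated",
                "on_oxygen")) {
    if (col %in% names(dt)) dt[, (col) := as.logical(get(col))]
  }
  if (!"encounter_id" %in% names(dt)) {
    dt[, encounter_id := paste(patient_id, format(arrival, "%Y%m%d%H%M%S"),
                               sep = "/")]
  }
  bad <- dt[!is.na(measured_at) & measured_at < arrival]
  if (nrow(bad)) {
    stop("vital record timestamp precedes arrival for encounter(s): ",
         paste(head(unique(bad$encounter_id), 3L), collapse = ", "),
         call. = FALSE)
  }
  dt
}

# one row per encounter, metadata only, preserving first-record order
.encounter_table <- function(records) {
  keep_cols <- intersect(.encounter_cols, names(records))
  enc <- records[, ..keep_cols]
  unique(enc, by = "encounter_id")
}

#' Read / write the encounters CSV dialect
#'
#' One row per vital-sign record with the encounter metadata repeated:
#' `patient_id`, `arrival` (ISO-8601), `age_years`, `sex`, `elective`,
#' `companion`, `has_national_id`, `hospital`, `death_date` (YYYY-MM-DD or
#' empty), `measured_at`, `sbp`, `hr`, `temp`, `rr`, `spo2`, `gcs` (or
#' `avpu`), `agitated`, `on_oxygen`. Encounters with no vital measurements
#' carry one row with empty vital fields.
#'
#' @param path CSV file path.
#' @return `read_encounters`: a `data.table` of typed records.
#' @export
read_encounters <- function(path) {
  dt <- data.table::fread(path, na.strings = c("", "NA"))
  .normalise_records(dt)
}

#' @rdname read_encounters
#' @param records a records table as produced by [generate_cohort()].
#' @export
write_encounters <- function(records, path) {
  dt <- as.data.table(records)
  out <- copy(dt)
  if (inherits(out$arrival, "POSIXct")) {
    out[, arrival := format(arrival, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  }
  if (inherits(out$measured_at, "POSIXct")) {
    out[, measured_at := format(measured_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  }
  data.table::fwrite(out, path)
  invisible(path)
}

#' Apply the eligibility filters
#'
#' Removes, in this fixed order, encounters of patients under 16 years,
#' elective admissions, registered healthy companions, and patients
#' without a national identifier. Each encounter is counted under the
#' first applicable reason only, so the counts and the kept set partition
#' the input.
#'
#' @param records a records table (see [read_encounters()]).
#' @return List with `kept` (records of eligible encounters) and `flow`
#'   (named integer vector of counts: `n_input`, `under_16`, `elective`,
#'   `companion`, `no_national_id`), counted at encounter grain.
#' @export
apply_eligibility <- function(records) {
  records <- .normalise_records(records)
  enc <- .encounter_table(records)
  reason <- rep(NA_character_, nrow(enc))
  reason[is.na(reason) & enc$age_years < 16] <- "under_16"
  reason[is.na(reason) & enc$elective] <- "elective"
  reason[is.na(reason) & enc$companion] <- "companion"
  reason[is.na(reason) & !enc$has_national_id] <- "no_national_id"
  flow <- c(
    n_input = nrow(enc),
    under_16 = sum(reason == "under_16", na.rm = TRUE),
    elective = sum(reason == "elective", na.rm = TRUE),
    companion = sum(reason == "companion", na.rm = TRUE),
    no_national_id = sum(reason == "no_national_id", na.rm = TRUE)
  )
  keep_ids <- enc$encounter_id[is.na(reason)]
  list(kept = records[encounter_id %in% keep_ids], flow = flow)
}

#' Keep only each patient's first hospital course
#'
#' Per patient, the encounter with the earliest arrival is retained;
#' later contacts in the inclusion period are dropped. Identical arrival
#' timestamps are resolved stably in favour of the first record, with a
#' warning.
#'
#' @inheritParams apply_eligibility
#' @return Records of the index encounters, with attribute
#'   `n_repeat_removed` giving the number of dropped encounters.
#' @export
select_index_contact <- function(records) {
  records <- .normalise_records(records)
  enc <- .encounter_table(records)
  enc[, .order := .I]
  first <- enc[order(arrival, .order), .SD[1L], by = patient_id]
  tied <- enc[duplicated(enc, by = c("patient_id", "arrival")), patient_id]
  if (length(tied)) {
    warning("tied arrival timestamps for patient(s) ",
            paste(head(unique(tied), 3L), collapse = ", "),
            "; keeping the first record", call. = FALSE)
  }
  n_removed <- nrow(enc) - nrow(first)
  out <- records[encounter_id %in% first$encounter_id]
  setattr(out, "n_repeat_removed", n_removed)
  out
}

#' First complete vital set within the observation window
#'
#' For each encounter, finds the earliest vital record measured within
#' `window_hours` of arrival in which all six score parameters (systolic
#' BP, heart rate, temperature, respiratory rate, saturation, level of
#' consciousness) *and* the oxygen-supplement status are documented.
#' Oxygen documentation is part of completeness: a record lacking only
#' `on_oxygen` does not qualify, but such encounters are flagged
#' (`oxygen_only`) so the exclusion accounting can report how many
#' patients were lost to that field alone.
#'
#' @inheritParams apply_eligibility
#' @param window_hours length of the window from arrival, boundary
#'   inclusive (default 4).
#' @return `data.table`, one row per encounter: `encounter_id`, `complete`
#'   (logical), `oxygen_only` (logical: incomplete, and the only
#'   undocumented field on some in-window record was `on_oxygen`), and the
#'   index vitals columns (`measured_at`, `sbp`, `hr`, `temp`, `rr`,
#'   `spo2`, `gcs`/`avpu`, `agitated`, `on_oxygen`) for complete
#'   encounters.
#' @export
first_complete_vitals <- function(records, window_hours = 4) {
  records <- .normalise_records(records)
  dt <- copy(records)
  dt[, .order := .I]
  has_avpu <- "avpu" %in% names(dt)
  has_gcs <- "gcs" %in% names(dt)
  loc_ok <- rep(FALSE, nrow(dt))
  if (has_avpu) loc_ok <- loc_ok | !is.na(dt$avpu)
  if (has_gcs) loc_ok <- loc_ok | !is.na(dt$gcs)
  vit_ok <- !is.na(dt$sbp) & !is.na(dt$hr) & !is.na(dt$temp) &
    !is.na(dt$rr) & !is.na(dt$spo2) & loc_ok & !is.na(dt$agitated)
  dt[, .vit_ok := vit_ok]
  dt[, .full_ok := vit_ok & !is.na(on_oxygen)]
  dt[, .in_window := !is.na(measured_at) &
       as.numeric(measured_at - arrival, units = "hours") <= window_hours]
  vit_cols <- intersect(
    c("measured_at", "sbp", "hr", "temp", "rr", "spo2", "gcs", "avpu",
      "agitated", "on_oxygen"), names(dt))
  all_enc <- unique(dt$encounter_id)
  hits <- dt[.in_window & .full_ok == TRUE]
  setorder(hits, measured_at, .order)
  hits <- unique(hits, by = "encounter_id")
  oxy_ids <- unique(dt[.in_window & .vit_ok == TRUE & is.na(on_oxygen),
                       encounter_id])
  res <- data.table(encounter_id = all_enc)
  res <- merge(res, hits[, c("encounter_id", vit_cols), with = FALSE],
               by = "encounter_id", all.x = TRUE, sort = FALSE)
  res[, complete := encounter_id %in% hits$encounter_id]
  res[, oxygen_only := !complete & encounter_id %in% oxy_ids]
  setcolorder(res, c("encounter_id", "complete", "oxygen_only", vit_cols))
  res[match(all_enc, encounter_id)]
}

#' Derive the 7-day mortality outcome
#'
#' Death within `followup_days` calendar days of arrival, day zero being
#' the arrival day itself: the outcome is `TRUE` when
#' `death_date - as.Date(arrival) <= followup_days` (so with the default
#' of 7, deaths on calendar-day offsets 0 through 7 count).
#'
#' @param encounters data.frame with `arrival` (POSIXct or parseable) and
#'   `death_date` (Date or parseable, `NA` = alive at last follow-up).
#' @param followup_days follow-up horizon in calendar days (default 7).
#' @return Logical vector.
#' @export
derive_outcome <- function(encounters, followup_days = 7) {
  arr <- .parse_ts(encounters$arrival)
  dd <- encounters$death_date
  dd <- if (inherits(dd, "Date")) as.Date(dd) else as.Date(as.character(dd))
  arr_date <- as.Date(arr, tz = "UTC")
  off <- as.integer(dd - arr_date)
  if (any(!is.na(off) & off < 0L)) {
    stop("death_date precedes arrival for ", sum(off < 0L, na.rm = TRUE),
         " encounter(s); data integrity violated", call. = FALSE)
  }
  !is.na(off) & off <= followup_days
}

#' Build the analysis cohort
#'
#' Runs the full selection process on a raw records table: eligibility
#' filters, first-contact deduplication, first complete vital set within
#' the window, outcome derivation, and scoring of the index vitals under
#' all supplied systems. Every input encounter is accounted for exactly
#' once in the exclusion flow.
#'
#' @inheritParams apply_eligibility
#' @param window_hours window for the first complete vital set (default 4).
#' @param followup_days mortality follow-up horizon (default 7).
#' @param systems named list of `ews_system` objects (default
#'   [ews_systems()]).
#' @param honor_agitation_with_gcs passed to [ews_score()].
#' @return List of class `ews_cohort`:
#' \describe{
#'   \item{cases}{data.frame, one row per included encounter: identifiers,
#'     demographics, index vitals, one score column per system, `died_7d`.}
#'   \item{flow}{`ews_flow` exclusion accounting (see
#'     [print.ews_flow()]).}
#'   \item{excluded}{data.frame of encounters that survived eligibility
#'     and deduplication but lacked a complete vital set in the window
#'     (demographics + `died_7d` + `oxygen_only`), for
#'     included-vs-excluded comparisons.}
#' }
#' @export
build_cohort <- function(records, window_hours = 4, followup_days = 7,
                         systems = ews_systems(),
                         honor_agitation_with_gcs = FALSE) {
  records <- .normalise_records(records)
  elig <- apply_eligibility(records)
  idx <- select_index_contact(elig$kept)
  n_repeat <- attr(idx, "n_repeat_removed")
  fcv <- first_complete_vitals(idx, window_hours = window_hours)
  enc <- .encounter_table(idx)
  enc <- merge(enc, fcv, by = "encounter_id", sort = FALSE)
  enc$died_7d <- derive_outcome(
    data.frame(arrival = enc$arrival, death_date = enc$death_date),
    followup_days = followup_days)
  included <- enc[complete == TRUE]
  excluded <- enc[complete == FALSE]
  flow <- structure(
    as.list(c(elig$flow,
              repeat_contact = n_repeat,
              no_vitals_in_window = nrow(excluded),
              oxygen_only_missing = sum(excluded$oxygen_only),
              included = nrow(included))),
    class = "ews_flow",
    window_hours = window_hours
  )
  cases <- as.data.frame(included[, !c("complete", "oxygen_only")])
  if (nrow(cases)) {
    sc <- score_all_systems(
      cases, systems = systems,
      honor_agitation_with_gcs = honor_agitation_with_gcs)
    cases <- cbind(cases, sc)
  } else {
    for (nm in names(systems)) cases[[nm]] <- integer(0)
  }
  drop_cols <- intersect(c("complete", "measured_at", "sbp", "hr", "temp",
                           "rr", "spo2", "gcs", "avpu", "agitated",
                           "on_oxygen"), names(excluded))
  structure(
    list(cases = cases,
         flow = flow,
         excluded = as.data.frame(excluded[, !..drop_cols])),
    class = "ews_cohort"
  )
}

#' @export
print.ews_flow <- function(x, ...) {
  cat("Selection process (encounters):\n")
  cat(sprintf("  raw input                 %6d\n", x$n_input))
  cat(sprintf("  - under 16 years          %6d\n", x$under_16))
  cat(sprintf("  - elective                %6d\n", x$elective))
  cat(sprintf("  - healthy companion       %6d\n", x$companion))
  cat(sprintf("  - no national id          %6d\n", x$no_national_id))
  cat(sprintf("  - repeat contact          %6d\n", x$repeat_contact))
  cat(sprintf("  - no complete vitals <=%gh %5d\n",
              attr(x, "window_hours") %||% 4, x$no_vitals_in_window))
  cat(sprintf("      of which oxygen-only  %6d\n", x$oxygen_only_missing))
  cat(sprintf("  included                  %6d\n", x$included))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ews_cohort <- function(x, ...) {
  print(x$flow)
  cat(sprintf("cases: %d rows, %d deaths within follow-up\n",
              nrow(x$cases), sum(x$cases$died_7d)))
  invisible(x)
}

#' Check exclusion-flow conservation
#'
#' Every encounter must be counted exactly once: the included count plus
#' all top-level exclusion counts must equal the raw input count
#' (`oxygen_only_missing` is a sub-count of `no_vitals_in_window` and is
#' not part of the sum).
#'
#' @param flow an `ews_flow`.
#' @return `TRUE` invisibly, or an error describing the imbalance.
#' @export
flow_is_conserved <- function(flow) {
  reasons <- c("under_16", "elective", "companion", "no_national_id",
               "repeat_contact", "no_vitals_in_window", "included")
  total <- sum(unlist(flow[reasons]))
  if (total != flow$n_input) {
    stop("exclusion flow not conserved: reasons sum to ", total,
         " but input was ", flow$n_input, call. = FALSE)
  }
  invisible(TRUE)
}
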