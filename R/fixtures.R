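# one encounter's worth of record rows with sensible defaults; vitals are
# all-normal unless overridden, and NA vital fields model missing documentation
.fixture_row <- function(encounter_id, patient_id = encounter_id,
                         arrival = "2015-03-01T08:00:00Z",
                         age_years = 50, sex = "male", elective = FALSE,
                         companion = FALSE, has_national_id = TRUE,
                         hospital = "Aarhus", death_date = NA,
                         measured_at = arrival,
                         sbp = 120, hr = 70, temp = 37, rr = 14, spo2 = 98,
                         gcs = 15, agitated = FALSE, on_oxygen = FALSE) {
  data.frame(encounter_id = encounter_id, patient_id = patient_id,
             arrival = arrival, age_years = age_years, sex = sex,
             elective = elective, companion = companion,
             has_national_id = has_national_id, hospital = hospital,
             death_date = as.Date(death_date),
             measured_at = measured_at, sbp = sbp, hr = hr, temp = temp,
             rr = rr, spo2 = spo2, gcs = gcs, agitated = agitated,
             on_oxygen = on_oxygen, stringsAsFactors = FALSE)
}

#' Deterministic test fixtures
#'
#' Small, fully enumerable encounter tables used by the unit tests (and
#' available for interactive exploration). Catalogue:
#' \describe{
#'   \item{`eligibility_toy`}{6 encounters: one per ineligibility reason
#'     (under-16, elective, companion, no national id) plus two eligible.}
#'   \item{`tie_cases`}{one patient with two encounters sharing an arrival
#'     timestamp, and one encounter with two complete vital sets sharing a
#'     measurement timestamp.}
#'   \item{`flow100`}{100 encounters with a hand-counted selection flow:
#'     5 under-16, 4 elective, 3 companion, 2 without national id,
#'     6 repeat contacts, 18 without a complete vital set within 4 h
#'     (2 of them lacking only oxygen documentation), 62 included; the
#'     included group contains deaths on day 0 and day 7 and a censored
#'     death on day 8.}
#'   \item{`roc_worked`}{a 6-observation score/outcome table (3 cases,
#'     3 controls, one cross-group tie) for worked all-pairs AUROC
#'     examples.}
#' }
#'
#' @param name fixture name.
#' @return A data.frame (records dialect, except `roc_worked` which has
#'   columns `score` and `outcome`).
#' @export
make_fixture <- function(name = c("eligibility_toy", "tie_cases", "flow100",
                                  "roc_worked")) {
  name <- match.arg(name)
  switch(name,
    eligibility_toy = do.call(rbind, list(
      .fixture_row("E01", "P01", age_years = 15),
      .fixture_row("E02", "P02", elective = TRUE),
      .fixture_row("E03", "P03", companion = TRUE),
      .fixture_row("E04", "P04", has_national_id = FALSE),
      .fixture_row("E05", "P05"),
      .fixture_row("E06", "P06", age_years = 80, sex = "female")
    )),
    tie_cases = do.call(rbind, list(
      # same patient, two encounters, identical arrival stamp
      .fixture_row("T01", "PT1", arrival = "2015-04-01T10:00:00Z",
                   measured_at = "2015-04-01T10:20:00Z"),
      .fixture_row("T02", "PT1", arrival = "2015-04-01T10:00:00Z",
                   measured_at = "2015-04-01T10:25:00Z", hr = 99),
      # one encounter, two complete sets at the same timestamp
      .fixture_row("T03", "PT2", arrival = "2015-04-02T10:00:00Z",
                   measured_at = "2015-04-02T10:30:00Z", hr = 60),
      .fixture_row("T03", "PT2", arrival = "2015-04-02T10:00:00Z",
                   measured_at = "2015-04-02T10:30:00Z", hr = 120)
    )),
    flow100 = .fixture_flow100(),
    roc_worked = data.frame(
      score = c(1, 2, 2, 3, 4, 5),
      outcome = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
    )
  )
}

.fixture_flow100 <- function() {
  rows <- list()
  day <- function(i) sprintf("2015-03-%02dT09:00:00Z", (i %% 28) + 1)
  k <- 0L
  add <- function(...) {
    k <<- k + 1L
    rows[[length(rows) + 1L]] <<- .fixture_row(sprintf("F%03d", k),
                                               sprintf("Q%03d", k), ...)
  }
  for (i in 1:5) add(age_years = 10 + i, arrival = day(i))
  for (i in 1:4) add(elective = TRUE, arrival = day(i + 5))
  for (i in 1:3) add(companion = TRUE, arrival = day(i + 9))
  for (i in 1:2) add(has_national_id = FALSE, arrival = day(i + 12))
  # 62 included encounters; two die in the window (day 0, day 7), one on
  # day 8 (counted alive at 7 days), scores vary with a touch of oxygen
  for (i in 1:62) {
    dd <- NA
    arr <- day(i + 14)
    if (i == 1) dd <- as.Date(substr(day(15), 1, 10))       # day 0
    if (i == 2) dd <- as.Date(substr(day(16), 1, 10)) + 7   # day 7
    if (i == 3) dd <- as.Date(substr(day(17), 1, 10)) + 8   # day 8
    add(arrival = arr, age_years = 40 + (i %% 40), death_date = dd,
        sex = if (i %% 2 == 0) "female" else "male",
        hr = 60 + 2 * (i %% 30), on_oxygen = i %% 10 == 0,
        measured_at = sub("T09:00:00", "T09:45:00", arr))
  }
  # 6 repeat contacts: second visits of the first six included patients
  for (i in 1:6) {
    k <- k + 1L
    rows[[length(rows) + 1L]] <- .fixture_row(
      sprintf("F%03d", k), sprintf("Q%03d", 14L + i),
      arrival = sprintf("2015-05-%02dT09:00:00Z", i),
      measured_at = sprintf("2015-05-%02dT09:30:00Z", i))
  }
  # 16 encounters with no complete set in the window: late or gappy
  for (i in 1:16) {
    k <- k + 1L
    arr <- day(i)
    rows[[length(rows) + 1L]] <- .fixture_row(
      sprintf("F%03d", k), sprintf("Q%03d", k),
      arrival = arr, age_years = 20 + i,
      measured_at = if (i %% 2 == 0) {
        sub("T09:00:00", "T14:30:00", arr)   # complete but after 4 h
      } else {
        sub("T09:00:00", "T09:40:00", arr)
      },
      rr = if (i %% 2 == 1) NA else 14,      # in-window set lacks RR
      death_date = if (i == 1) as.Date(substr(arr, 1, 10)) + 2 else NA)
  }
  # 2 encounters lacking only the oxygen-supplement field
  for (i in 1:2) {
    k <- k + 1L
    arr <- day(20 + i)
    rows[[length(rows) + 1L]] <- .fixture_row(
      sprintf("F%03d", k), sprintf("Q%03d", k), arrival = arr,
      measured_at = sub("T09:00:00", "T10:00:00", arr), on_oxygen = NA)
  }
  do.call(rbind, rows)
}
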