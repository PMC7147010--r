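test_that("eligibility filters remove each stated group once, in order", {
  toy <- make_fixture("eligibility_toy")
  res <- apply_eligibility(toy)
  expect_equal(unname(res$flow),
               c(6L, 1L, 1L, 1L, 1L))
  expect_setequal(unique(res$kept$encounter_id), c("E05", "E06"))
  # an encounter hitting several reasons is counted under the first only
  toy2 <- toy
  toy2$elective[toy2$encounter_id == "E01"] <- TRUE  # under-16 AND elective
  res2 <- apply_eligibility(toy2)
  expect_equal(unname(res2$flow[["under_16"]]), 1L)
  expect_equal(unname(res2$flow[["elective"]]), 1L)
  # adult acutely referred patient passes every filter
  ok <- apply_eligibility(make_fixture("eligibility_toy")[5, , drop = FALSE])
  expect_equal(sum(unlist(ok$flow[-1])), 0L)
})

test_that("the first hospital course is kept; ties resolve stably with warning", {
  toy <- data.frame(
    encounter_id = c("A1", "A2", "B1"),
    patient_id = c("p1", "p1", "p2"),
    arrival = c("2015-03-10T08:00:00Z", "2015-03-02T08:00:00Z",
                "2015-03-05T08:00:00Z"),
    age_years = 50, sex = "male", elective = FALSE, companion = FALSE,
    has_national_id = TRUE, measured_at = NA_character_,
    stringsAsFactors = FALSE
  )
  kept <- select_index_contact(toy)
  expect_setequal(unique(kept$encounter_id), c("A2", "B1"))
  expect_equal(attr(kept, "n_repeat_removed"), 1L)
  ties <- make_fixture("tie_cases")
  expect_warning(kept2 <- select_index_contact(ties), "tied arrival")
  expect_true("T01" %in% kept2$encounter_id)   # first record wins
  expect_false("T02" %in% kept2$encounter_id)
})

test_that("first complete vital set respects the window and oxygen documentation", {
  base <- make_fixture("tie_cases")[3:4, ]  # one encounter, two sets, same stamp
  fcv <- first_complete_vitals(base)
  expect_true(fcv$complete)
  expect_equal(fcv$hr, 60)  # first record wins the timestamp tie
  # complete set only after the window
  late <- base[1, ]
  late$measured_at <- "2015-04-02T15:10:00Z"  # 5h10 after arrival
  expect_false(first_complete_vitals(late)$complete)
  expect_true(first_complete_vitals(late, window_hours = 6)$complete)
  # boundary: exactly 4h counts as inside
  edge <- base[1, ]
  edge$measured_at <- "2015-04-02T14:00:00Z"
  expect_true(first_complete_vitals(edge)$complete)
  # missing oxygen documentation alone is flagged
  oxy <- base[1, ]
  oxy$on_oxygen <- NA
  r <- first_complete_vitals(oxy)
  expect_false(r$complete)
  expect_true(r$oxygen_only)
  # but not when another vital is missing too
  oxy2 <- oxy
  oxy2$rr <- NA
  r2 <- first_complete_vitals(oxy2)
  expect_false(r2$complete)
  expect_false(r2$oxygen_only)
  # earlier incomplete record does not pre-empt a later complete one
  two <- rbind(base[1, ], base[1, ])
  two$measured_at <- c("2015-04-02T10:10:00Z", "2015-04-02T10:40:00Z")
  two$temp[1] <- NA
  two$hr[2] <- 85
  r3 <- first_complete_vitals(two)
  expect_true(r3$complete)
  expect_equal(r3$hr, 85)
})

test_that("7-day mortality counts day 0 through day 7 and validates dates", {
  enc <- data.frame(
    arrival = rep("2015-03-10T23:00:00Z", 4),
    death_date = c("2015-03-10", "2015-03-17", "2015-03-18", NA)
  )
  expect_equal(derive_outcome(enc), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(derive_outcome(enc, followup_days = 8),
               c(TRUE, TRUE, TRUE, FALSE))
  bad <- data.frame(arrival = "2015-03-10T08:00:00Z",
                    death_date = "2015-03-09")
  expect_error(derive_outcome(bad), "precedes arrival")
})

test_that("the hand-counted 100-encounter fixture reproduces its flow exactly", {
  co <- build_cohort(make_fixture("flow100"))
  f <- co$flow
  expect_equal(f$n_input, 100L)
  expect_equal(f$under_16, 5L)
  expect_equal(f$elective, 4L)
  expect_equal(f$companion, 3L)
  expect_equal(f$no_national_id, 2L)
  expect_equal(f$repeat_contact, 6L)
  expect_equal(f$no_vitals_in_window, 18L)
  expect_equal(f$oxygen_only_missing, 2L)
  expect_equal(f$included, 62L)
  expect_true(flow_is_conserved(f))
  # outcomes: deaths on day 0 and day 7 count, day 8 does not
  expect_equal(sum(co$cases$died_7d), 2L)
  expect_equal(sum(co$excluded$died_7d), 1L)
  # all three score columns present and in range
  expect_true(all(c("TOKS", "mTOKS", "NEWS") %in% names(co$cases)))
  expect_true(all(co$cases$TOKS >= 0 & co$cases$TOKS <= 18))
})

test_that("all-complete toy cohorts pass through with zero exclusions", {
  toy <- make_fixture("eligibility_toy")[5:6, ]
  co <- build_cohort(toy)
  f <- co$flow
  expect_equal(f$included, 2L)
  expect_equal(sum(unlist(f[c("under_16", "elective", "companion",
                              "no_national_id", "repeat_contact",
                              "no_vitals_in_window")])), 0L)
})

test_that("exclusion flow is conserved on random cohorts (property)", {
  for (seed in c(11, 22, 33)) {
    sim <- generate_cohort(simulation_config(3000, seed = seed))
    co <- build_cohort(sim$encounters)
    expect_true(flow_is_conserved(co$flow))
  }
})

test_that("cohort construction is idempotent on an already-built cohort", {
  sim <- generate_cohort(simulation_config(2000, seed = 5))
  co1 <- build_cohort(sim$encounters)
  # feed the included encounters' records back through the pipeline
  rec2 <- as.data.frame(
    data.table::as.data.table(sim$encounters)[
      encounter_id %in% co1$cases$encounter_id])
  co2 <- build_cohort(rec2)
  expect_equal(co2$flow$included, co1$flow$included)
  expect_equal(sum(unlist(co2$flow[c("under_16", "elective", "companion",
                                     "no_national_id", "repeat_contact",
                                     "no_vitals_in_window")])), 0L)
  m1 <- co1$cases[order(co1$cases$encounter_id),
                  c("encounter_id", "TOKS", "mTOKS", "NEWS", "died_7d")]
  m2 <- co2$cases[order(co2$cases$encounter_id),
                  c("encounter_id", "TOKS", "mTOKS", "NEWS", "died_7d")]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("widening windows and follow-up never shrinks counts (monotonicity)", {
  sim <- generate_cohort(simulation_config(3000, seed = 8))
  inc <- vapply(c(2, 4, 8, 24), function(w)
    build_cohort(sim$encounters, window_hours = w)$flow$included, integer(1))
  expect_true(all(diff(inc) >= 0))
  deaths <- vapply(c(2, 7, 14, 30), function(fd)
    sum(build_cohort(sim$encounters, followup_days = fd)$cases$died_7d),
    integer(1))
  expect_true(all(diff(deaths) >= 0))
})

test_that("encounters round-trip through the CSV dialect", {
  sim <- generate_cohort(simulation_config(300, seed = 3))
  tmp <- tempfile(fileext = ".csv")
  write_encounters(sim$encounters, tmp)
  back <- read_encounters(tmp)
  expect_equal(nrow(back), nrow(sim$encounters))
  co1 <- build_cohort(sim$encounters)
  co2 <- build_cohort(back)
  expect_equal(co2$flow, co1$flow)
  expect_equal(sort(co2$cases$TOKS), sort(co1$cases$TOKS))
})

test_that("vital records before arrival are a data integrity error", {
  bad <- make_fixture("eligibility_toy")[5, ]
  bad$measured_at <- "2015-03-01T07:00:00Z"  # one hour before arrival
  expect_error(build_cohort(bad), "precedes arrival")
})
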