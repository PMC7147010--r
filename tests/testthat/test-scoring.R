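test_that("GCS converts to AVPU per the stated mapping and rejects bad input", {
  expect_equal(as.character(gcs_to_avpu(15)), "A")
  expect_equal(as.character(gcs_to_avpu(14)), "V")
  expect_equal(as.character(gcs_to_avpu(10)), "P")
  expect_equal(as.character(gcs_to_avpu(3)), "U")
  # total and order-reversing over the whole domain
  full <- gcs_to_avpu(3:15)
  expect_false(anyNA(full))
  expect_true(all(diff(as.integer(full)) <= 0))
  expect_error(gcs_to_avpu(2), "out of range.*2")
  expect_error(gcs_to_avpu(16), "out of range")
  expect_error(gcs_to_avpu(9.5), "out of range")
})

test_that("bundled systems validate with the published maxima", {
  sys <- ews_systems()
  for (nm in c("TOKS", "mTOKS", "NEWS")) {
    v <- validate_score_system(sys[[nm]])
    expect_length(v, 0)
  }
  expect_equal(attr(validate_score_system(sys$TOKS), "computed_max"), 18L)
  expect_equal(attr(validate_score_system(sys$mTOKS), "computed_max"), 20L)
  expect_equal(attr(validate_score_system(sys$NEWS), "computed_max"), 20L)
})

test_that("validation reports gaps, overlaps, zero-band and max defects", {
  toks <- ews_systems()$TOKS
  # delete the temperature zero band [36, 38)
  broken <- toks
  broken$scales$temp <- broken$scales$temp[
    !(broken$scales$temp$lower == 36), ]
  v <- validate_score_system(broken)
  expect_true(any(grepl("temp: gap over \\[36, 38\\)", v)))
  expect_true(any(grepl("temp: 0 zero bands", v)))
  # overlapping bands
  broken2 <- toks
  broken2$scales$hr$lower[3L] <- 45
  expect_true(any(grepl("hr: overlap", validate_score_system(broken2))))
  # declared max mismatch
  broken3 <- toks
  broken3$declared_max <- 17L
  expect_true(any(grepl("computed max 18 != declared max 17",
                        validate_score_system(broken3))))
  # malformed LOC rule
  broken4 <- toks
  broken4$loc_rule$avpu_points[["A"]] <- 1
  expect_true(any(grepl("A must map to 0", validate_score_system(broken4))))
})

test_that("parameter scoring follows the half-open band convention", {
  toks <- ews_systems()$TOKS
  expect_equal(score_parameter(toks$scales$temp, 37.0), 0L)
  expect_equal(score_parameter(toks$scales$temp, 40.0), 3L)
  expect_equal(score_parameter(toks$scales$spo2, 93.0), 0L)
  expect_equal(score_parameter(toks$scales$spo2, 84.0), 3L)
  # boundary values score in the band they open
  expect_equal(score_parameter(toks$scales$temp, c(34, 36, 38, 39, 40)),
               c(1L, 0L, 1L, 2L, 3L))
  expect_error(score_parameter(toks$scales$temp, Inf), "non-finite")
})

test_that("every finite value falls in exactly one band (partition property)", {
  set.seed(41)
  sys <- ews_systems()
  for (system in sys) {
    for (p in names(system$scales)) {
      sc <- system$scales[[p]]
      edges <- sc$lower[is.finite(sc$lower)]
      vals <- c(runif(300, -50, 300), edges, edges - 1e-9, edges + 1e-9)
      hits <- vapply(vals, function(x)
        sum(x >= sc$lower & x < sc$upper), integer(1))
      expect_true(all(hits == 1L))
      # and the fast path agrees with the unique matching band
      expected <- vapply(vals, function(x)
        sc$points[x >= sc$lower & x < sc$upper], integer(1))
      expect_equal(score_parameter(sc, vals), expected)
    }
  }
})

test_that("LOC scoring combines AVPU and agitation as configured", {
  toks_rule <- ews_systems()$TOKS$loc_rule
  expect_equal(score_loc(toks_rule, "A", FALSE), 0L)
  expect_equal(score_loc(toks_rule, "U", FALSE), 3L)
  expect_equal(score_loc(toks_rule, "A", TRUE), 1L)
  expect_equal(score_loc(toks_rule, c("V", "P"), c(TRUE, TRUE)), c(1L, 2L))
  news_rule <- ews_systems()$NEWS$loc_rule
  expect_equal(score_loc(news_rule, c("A", "V", "P", "U"), rep(FALSE, 4)),
               c(0L, 3L, 3L, 3L))
  expect_equal(score_loc(news_rule, "A", TRUE), 0L)  # NEWS has no agitation
  sum_rule <- modifyList(toks_rule, list(combination = "sum"))
  expect_equal(score_loc(sum_rule, "U", TRUE), 4L)
})

test_that("aggregate scores reproduce the worked examples", {
  sys <- ews_systems()
  v0 <- normal_vitals()
  expect_equal(unlist(score_all_systems(v0)),
               c(TOKS = 0L, mTOKS = 0L, NEWS = 0L))
  v_o2 <- normal_vitals(on_oxygen = TRUE)
  expect_equal(unlist(score_all_systems(v_o2)),
               c(TOKS = 0L, mTOKS = 2L, NEWS = 2L))
  worst_toks <- normal_vitals(sbp = 50, hr = 150, temp = 45, rr = 40,
                              spo2 = 70, avpu = "U", on_oxygen = TRUE)
  expect_equal(ews_score(sys$mTOKS, worst_toks), 20L)
  worst_news <- normal_vitals(sbp = 250, hr = 150, temp = 33, rr = 40,
                              spo2 = 80, avpu = "P", on_oxygen = TRUE)
  expect_equal(ews_score(sys$NEWS, worst_news), 20L)
})

test_that("incomplete vital sets are rejected with the missing fields named", {
  v <- normal_vitals()
  v$rr <- NA
  expect_error(ews_score(ews_systems()$TOKS, v), "missing: rr")
  v2 <- normal_vitals()
  v2$on_oxygen <- NA
  expect_error(ews_score(ews_systems()$TOKS, v2), "on_oxygen")
  v3 <- normal_vitals()
  v3$avpu <- NA
  expect_error(ews_score(ews_systems()$TOKS, v3), "loc")
  v4 <- normal_vitals(gcs = 14)  # both LOC encodings documented
  expect_error(ews_score(ews_systems()$TOKS, v4), "both AVPU and GCS")
})

test_that("oxygen delta and monotonicity hold on random vital sets", {
  v <- random_vitals(2000, seed = 7)
  sc <- score_all_systems(v)
  expect_identical(sc$mTOKS - sc$TOKS, 2L * as.integer(v$on_oxygen))
  with_o2 <- v
  with_o2$on_oxygen <- TRUE
  without <- v
  without$on_oxygen <- FALSE
  news <- ews_systems()$NEWS
  expect_true(all(ews_score(news, with_o2) >= ews_score(news, without)))
  # all scores within their declared range
  for (nm in names(sc)) {
    expect_true(all(sc[[nm]] >= 0L & sc[[nm]] <= ews_systems()[[nm]]$declared_max))
  }
})

test_that("agitation is zeroed when LOC comes from GCS unless overridden", {
  v <- normal_vitals(agitated = TRUE)
  v$avpu <- NULL
  v$gcs <- 15
  toks <- ews_systems()$TOKS
  expect_equal(ews_score(toks, v), 0L)
  expect_equal(ews_score(toks, v, honor_agitation_with_gcs = TRUE), 1L)
  # AVPU-recorded agitation always counts
  expect_equal(ews_score(toks, normal_vitals(agitated = TRUE)), 1L)
})

test_that("score systems load from JSON and reject malformed configs", {
  dir <- system.file("extdata", "scores", package = "ewscompare")
  toks <- load_score_system(file.path(dir, "toks.json"))
  expect_s3_class(toks, "ews_system")
  expect_equal(toks$name, "TOKS")
  expect_equal(toks$oxygen_points, 0L)
  # a config with a band removed fails validation at load time
  cfg <- jsonlite::fromJSON(file.path(dir, "toks.json"),
                            simplifyVector = FALSE)
  cfg$scales[[3]]$bands[[3]] <- NULL  # temperature zero band
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, null = "null")
  expect_error(load_score_system(tmp), "gap")
  expect_silent(load_score_system(tmp, validate = FALSE))
  # missing top-level fields
  tmp2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "x"), tmp2, auto_unbox = TRUE)
  expect_error(load_score_system(tmp2), "lacks field")
})
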