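#' Configuration of the synthetic emergency-department cohort
#'
#' The generator draws a single latent severity per encounter and lets it
#' drive everything the analysis assumes is correlated in real data:
#' vital-sign derangement (systolic BP down, heart and respiratory rate
#' up, temperature in either direction, saturation down, consciousness
#' down), agitation, oxygen administration, vital-sign documentation, and
#' 7-day mortality. Encounters split into a "minor injury" stratum (young,
#' near-zero severity, vitals frequently not measured) and a "medical"
#' stratum, which reproduces the published cohort's structure: excluded
#' patients are younger and healthier than included ones.
#'
#' Defaults target the published cohort margins: 52% female, ~2% 7-day
#' mortality and median age 61 (IQR 41-76) among encounters with a
#' complete vital set within 4 h, ~37% without such a set (~2% of those
#' lacking only the oxygen-supplement field), plus repeat visits and
#' under-16 / elective / companion / no-national-id records to exercise
#' the eligibility filters.
#'
#' @param n_encounters number of encounters to simulate.
#' @param seed integer seed; the same config and seed give identical
#'   output.
#' @param ... named overrides of any default component (see
#'   `simulation_defaults()` for the full list); unknown names error.
#' @return A validated list of class `ews_simconfig`.
#' @export
simulation_config <- function(n_encounters = 20000, seed = 1, ...) {
  cfg <- simulation_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown simulation parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- modifyList(cfg, dots)
  cfg$n_encounters <- as.integer(n_encounters)
  cfg$seed <- as.integer(seed)
  probs <- c(female = cfg$female_fraction, under16 = cfg$under16_fraction,
             elective = cfg$elective_rate, companion = cfg$companion_rate,
             no_id = cfg$no_id_rate, repeat_visit = cfg$repeat_visit_rate,
             minor = cfg$minor_fraction, temp_up = cfg$temp_up_fraction,
             oxygen_spont = cfg$oxygen_spontaneous,
             oxygen_only = cfg$oxygen_only_share,
             late_complete = cfg$late_complete_share,
             late_death = cfg$late_death_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities outside [0,1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (cfg$n_encounters < 1L) stop("n_encounters must be positive", call. = FALSE)
  if (cfg$oxygen_masking < 0 || cfg$oxygen_masking > 1) {
    stop("oxygen_masking must lie in [0,1]", call. = FALSE)
  }
  structure(cfg, class = "ews_simconfig")
}

#' @rdname simulation_config
#' @export
simulation_defaults <- function() {
  list(
    n_encounters = 20000L,
    seed = 1L,
    # demographics / eligibility
    female_fraction = 0.52,
    under16_fraction = 0.05,
    elective_rate = 0.03,
    companion_rate = 0.01,
    no_id_rate = 0.015,
    repeat_visit_rate = 0.08,
    hospital_weights = c(Aarhus = 0.30, Horsens = 0.16, Viborg = 0.17,
                         Randers = 0.20, Vest = 0.17),
    # case mix: minor-injury stratum vs medical stratum
    minor_fraction = 0.45,
    severity_minor_rate = 8,          # Exp rate; near-zero severity
    severity_shape = 1.3,             # Gamma shape, medical stratum
    severity_rate = 0.9,              # Gamma rate, medical stratum
    # ages (years); minor stratum young, medical stratum older
    age_minor = c(shape = 1.8, scale = 14, offset = 16),
    age_medical = c(alpha = 1.75, beta = 1.2, offset = 16, span = 80),
    # per-vital response to severity: baseline mean, severity slope, sd
    vitals = list(
      sbp = c(base = 127, slope = -16, sd = 16),
      hr = c(base = 78, slope = 13, sd = 12),
      rr = c(base = 15, slope = 3.2, sd = 2.4),
      temp = c(base = 36.9, slope_up = 0.9, slope_down = -0.8, sd = 0.45),
      spo2 = c(base = 97.5, slope = -4, sd = 1.3)
    ),
    temp_up_fraction = 0.7,           # febrile (vs hypothermic) response
    # consciousness: thresholds on severity + noise -> GCS bands
    loc_thresholds = c(V = 2.3, P = 3.0, U = 3.7),
    loc_noise_sd = 0.3,
    agitation_link = c(intercept = -4, slope = 0.8),
    # oxygen: prescribed on severity and on the clinician's impression of
    # chronic frailty (home oxygen, COPD), plus a spontaneous rate; when
    # given, observed spo2 and rr are pulled part-way back toward baseline
    oxygen_link = c(intercept = -4.6, slope = 1.8),
    oxygen_frailty_slope = 0.7,
    oxygen_spontaneous = 0.01,
    oxygen_masking = 0.7,
    # 7-day mortality, logistic in severity plus an unmeasured frailty
    # (comorbidity burden etc.) that no vital-sign score can see; the
    # intercept is calibrated so the included cohort sits at ~2%
    mortality_link = c(intercept = -7.95, slope = 1.05),
    mortality_frailty_sd = 2.2,
    late_death_rate = 0.01,           # deaths beyond day 7 (day 8-60)
    # documentation: probability of a complete in-window vital set,
    # logistic in severity per stratum (sicker -> more often measured)
    complete_link_minor = c(intercept = -1.3, slope = 1.5),
    complete_link_medical = c(intercept = 1.7, slope = 0.8),
    complete_frailty_slope = 0.3,     # chronically frail patients get measured
    oxygen_only_share = 0.024,        # incomplete lacking only on_oxygen
    late_complete_share = 0.30,       # incomplete with a full set after 4 h
    extra_row_rate = 0.35,            # earlier partial record before index
    window_hours = 4,
    start_date = "2015-03-01",
    period_days = 92
  )
}

.rbern <- function(n, p) runif(n) < p

# draw one vital as base + slope * severity + noise
.vital_draw <- function(n, par, s) par[["base"]] + par[["slope"]] * s +
  rnorm(n, 0, par[["sd"]])

#' Generate a synthetic emergency-department cohort
#'
#' Produces a records table in the encounters CSV dialect (one row per
#' vital record, metadata repeated; consciousness recorded as GCS, as at
#' triage) together with the generative ground truth, enabling oracle
#' checks such as "scoring the true severity bounds the AUROC of any
#' aggregate score".
#'
#' @param config an `ews_simconfig` from [simulation_config()].
#' @return List with `encounters` (records `data.table`) and `truth`
#'   (`data.table`: `encounter_id`, `severity`, `p_death`).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "ews_simconfig"))
  set.seed(config$seed)
  cfg <- config
  n <- cfg$n_encounters

  # --- patients and encounters -------------------------------------------
  n_base <- max(1L, round(n / (1 + cfg$repeat_visit_rate)))
  n_rep <- n - n_base
  patient_id <- sprintf("P%06d", seq_len(n_base))
  rep_idx <- if (n_rep > 0L) sample.int(n_base, n_rep) else integer(0)
  pid <- c(patient_id, patient_id[rep_idx])
  is_repeat <- c(rep(FALSE, n_base), rep(TRUE, n_rep))

  start <- as.POSIXct(paste0(cfg$start_date, " 00:00:00"), tz = "UTC")
  arr0 <- start + runif(n_base, 0, cfg$period_days * 86400)
  # repeat visit 10-80 days after the first contact
  arr <- c(arr0, arr0[rep_idx] + runif(n_rep, 10, 80) * 86400)

  # --- patient-level attributes (shared across visits) -------------------
  female_p <- .rbern(n_base, cfg$female_fraction)
  under16_p <- .rbern(n_base, cfg$under16_fraction)
  minor_p <- .rbern(n_base, cfg$minor_fraction)
  am <- cfg$age_minor
  aM <- cfg$age_medical
  age_p <- ifelse(
    minor_p,
    am[["offset"]] + rgamma(n_base, am[["shape"]], scale = am[["scale"]]),
    aM[["offset"]] + aM[["span"]] * rbeta(n_base, aM[["alpha"]], aM[["beta"]]))
  age_p <- pmin(round(age_p), 98)
  age_p[under16_p] <- sample(0:15, sum(under16_p), replace = TRUE)
  no_id_p <- .rbern(n_base, cfg$no_id_rate)

  female <- c(female_p, female_p[rep_idx])
  minor <- c(minor_p, .rbern(n_rep, cfg$minor_fraction))
  age <- c(age_p, age_p[rep_idx]) # ignore ageing over weeks
  no_id <- c(no_id_p, no_id_p[rep_idx])
  elective <- .rbern(n, cfg$elective_rate)
  companion <- .rbern(n, cfg$companion_rate)
  hospital <- sample(names(cfg$hospital_weights), n, replace = TRUE,
                     prob = cfg$hospital_weights)

  # --- latent severity and true vitals -----------------------------------
  sev <- ifelse(minor, rexp(n, cfg$severity_minor_rate),
                rgamma(n, cfg$severity_shape, cfg$severity_rate))
  v <- cfg$vitals
  sbp <- pmax(40, .vital_draw(n, v$sbp, sev))
  hr <- pmax(25, .vital_draw(n, v$hr, sev))
  rr <- pmax(6, .vital_draw(n, v$rr, sev))
  spo2 <- pmin(100, pmax(55, .vital_draw(n, v$spo2, sev)))
  tdir <- .rbern(n, cfg$temp_up_fraction)
  temp <- v$temp[["base"]] +
    ifelse(tdir, v$temp[["slope_up"]], v$temp[["slope_down"]]) * sev +
    rnorm(n, 0, v$temp[["sd"]])
  temp <- pmin(43, pmax(30, temp))

  u <- sev + rnorm(n, 0, cfg$loc_noise_sd)
  th <- cfg$loc_thresholds
  gcs <- rep(15L, n)
  gcs[u >= th[["V"]]] <- 14L
  idx <- u >= th[["P"]]
  gcs[idx] <- sample(9:13, sum(idx), replace = TRUE)
  idx <- u >= th[["U"]]
  gcs[idx] <- sample(3:8, sum(idx), replace = TRUE)
  agit <- .rbern(n, plogis(cfg$agitation_link[["intercept"]] +
                             cfg$agitation_link[["slope"]] * sev))

  # --- oxygen and masking -------------------------------------------------
  frailty <- rnorm(n, 0, cfg$mortality_frailty_sd)
  p_o2 <- plogis(cfg$oxygen_link[["intercept"]] +
                   cfg$oxygen_link[["slope"]] * sev +
                   cfg$oxygen_frailty_slope * frailty)
  on_o2 <- .rbern(n, p_o2) | .rbern(n, cfg$oxygen_spontaneous)
  k <- cfg$oxygen_masking
  spo2_obs <- ifelse(on_o2 & spo2 < v$spo2[["base"]],
                     spo2 + k * (v$spo2[["base"]] - spo2), spo2)
  spo2_obs <- pmin(100, spo2_obs)
  rr_obs <- ifelse(on_o2 & rr > v$rr[["base"]],
                   rr - k * (rr - v$rr[["base"]]), rr)

  # --- mortality ----------------------------------------------------------
  p_death <- plogis(cfg$mortality_link[["intercept"]] +
                      cfg$mortality_link[["slope"]] * sev + frailty)
  # patient-level death is drawn at the last visit so repeat visits never
  # postdate the death date
  is_last <- rep(TRUE, n)
  is_last[rep_idx] <- FALSE
  die7 <- .rbern(n, p_death) & is_last
  late <- !die7 & is_last & .rbern(n, cfg$late_death_rate)
  offset <- rep(NA_integer_, n)
  offset[die7] <- sample(0:7, sum(die7), replace = TRUE,
                         prob = c(25, 20, 15, 10, 10, 8, 7, 5))
  offset[late] <- sample(8:60, sum(late), replace = TRUE)
  death_date <- as.Date(rep(NA, n))
  has_d <- !is.na(offset)
  death_date[has_d] <- as.Date(arr[has_d], tz = "UTC") + offset[has_d]
  # propagate the death date to the patient's earlier visit
  pd <- death_date
  first_of_rep <- rep_idx
  pd[first_of_rep] <- death_date[n_base + seq_len(n_rep)]
  death_date <- pd

  # --- documentation / missingness ---------------------------------------
  fr_doc <- cfg$complete_frailty_slope * frailty
  cl <- ifelse(minor,
               plogis(cfg$complete_link_minor[["intercept"]] +
                        cfg$complete_link_minor[["slope"]] * sev + fr_doc),
               plogis(cfg$complete_link_medical[["intercept"]] +
                        cfg$complete_link_medical[["slope"]] * sev + fr_doc))
  complete <- .rbern(n, cl)
  oxy_only <- !complete & .rbern(n, cfg$oxygen_only_share)
  late_complete <- !complete & !oxy_only & .rbern(n, cfg$late_complete_share)

  enc_id <- sprintf("E%06d", seq_len(n))
  w <- cfg$window_hours

  meta <- data.table(
    encounter_id = enc_id, patient_id = pid, arrival = arr,
    age_years = age, sex = ifelse(female, "female", "male"),
    elective = elective, companion = companion, has_national_id = !no_id,
    hospital = hospital, death_date = death_date
  )

  vit <- data.table(sbp = round(sbp), hr = round(hr),
                    temp = round(temp, 1), rr = round(rr),
                    spo2 = round(pmin(100, spo2_obs)), gcs = gcs,
                    agitated = agit, on_oxygen = on_o2)

  rows <- vector("list", 4L)
  # index rows: complete within window
  t_index <- runif(n, 5, w * 60 - 10) * 60
  ix <- which(complete)
  r1 <- cbind(meta[ix], measured_at = arr[ix] + t_index[ix], vit[ix])
  rows[[1L]] <- r1
  # oxygen-only-missing rows: full vitals, on_oxygen undocumented
  ix <- which(oxy_only)
  r2 <- cbind(meta[ix], measured_at = arr[ix] + t_index[ix], vit[ix])
  r2$on_oxygen <- NA
  rows[[2L]] <- r2
  # otherwise-incomplete rows: in-window record with gaps, or a complete
  # record after the window, or no measurement at all
  ix <- which(!complete & !oxy_only)
  if (length(ix)) {
    r3 <- cbind(meta[ix], measured_at = arr[ix] + t_index[ix], vit[ix])
    drop2 <- sample(c("rr", "temp", "sbp", "spo2"), length(ix), replace = TRUE)
    for (cc in unique(drop2)) {
      jj <- which(drop2 == cc)
      r3[[cc]][jj] <- NA
      r3$gcs[jj[seq_len(floor(length(jj) / 2))]] <- NA
    }
    no_row <- .rbern(length(ix), 0.3)
    r3$measured_at[no_row] <- as.POSIXct(NA)
    for (cc in c("sbp", "hr", "temp", "rr", "spo2", "gcs", "agitated",
                 "on_oxygen")) {
      r3[[cc]][no_row] <- r3[[cc]][NA_integer_][1L]
    }
    rows[[3L]] <- r3
    ix4 <- ix[late_complete[ix]]
    if (length(ix4)) {
      r4 <- cbind(meta[ix4],
                  measured_at = arr[ix4] +
                    runif(length(ix4), w * 3600 + 600, 12 * 3600),
                  vit[ix4])
      rows[[4L]] <- r4
    }
  }
  # occasional earlier partial record ahead of the index set
  ix <- which(complete & .rbern(n, cfg$extra_row_rate))
  if (length(ix)) {
    r5 <- cbind(meta[ix],
                measured_at = arr[ix] + t_index[ix] * runif(length(ix), 0.2, 0.8),
                vit[ix])
    r5$temp <- NA_real_
    rows[[length(rows) + 1L]] <- r5
  }
  records <- rbindlist(rows, use.names = TRUE)
  setorder(records, encounter_id, measured_at, na.last = TRUE)

  truth <- data.table(encounter_id = enc_id, severity = sev,
                      p_death = p_death)
  list(encounters = records[], truth = truth)
}
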