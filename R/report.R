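#' Cohort characteristics table (included vs excluded)
#'
#' Summarises the analysis cohort against the encounters excluded for
#' lacking a complete vital set: counts and percentages for sex, 7-day
#' mortality and hospital, median and interquartile range for age.
#' Group differences are tested with the Wilcoxon rank-sum test
#' (continuous) and the chi-square test (categorical); a `p_value` below
#' 0.001 is the conventional flag used in cohort tables.
#'
#' @param cohort an `ews_cohort` from [build_cohort()].
#' @return data.frame with columns `characteristic`, `included`,
#'   `excluded`, `p_value`.
#' @export
characteristics_table <- function(cohort) {
  inc <- cohort$cases
  exc <- cohort$excluded
  pct <- function(k, n) sprintf("%d (%.0f%%)", k, ifelse(n > 0, 100 * k / n, 0))
  miqr <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 2)
    sprintf("%.0f [%.0f;%.0f]", q[2L], q[1L], q[3L])
  }
  safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_,
                                    warning = function(w) suppressWarnings(expr))
  p_sex <- if (nrow(exc)) safe_p(chisq.test(table(
    c(rep("inc", nrow(inc)), rep("exc", nrow(exc))),
    c(inc$sex, exc$sex)))$p.value) else NA_real_
  p_age <- if (nrow(exc)) safe_p(wilcox.test(inc$age_years,
                                             exc$age_years)$p.value)
           else NA_real_
  p_mort <- if (nrow(exc)) safe_p(chisq.test(table(
    c(rep("inc", nrow(inc)), rep("exc", nrow(exc))),
    c(inc$died_7d, exc$died_7d)))$p.value) else NA_real_
  out <- data.frame(
    characteristic = c("n", "female, n (%)", "median age [IQR]",
                       "7-day mortality, n (%)"),
    included = c(as.character(nrow(inc)),
                 pct(sum(inc$sex == "female"), nrow(inc)),
                 miqr(inc$age_years),
                 pct(sum(inc$died_7d), nrow(inc))),
    excluded = c(as.character(nrow(exc)),
                 pct(sum(exc$sex == "female"), nrow(exc)),
                 if (nrow(exc)) miqr(exc$age_years) else "",
                 pct(sum(exc$died_7d), nrow(exc))),
    p_value = c(NA, p_sex, p_age, p_mort),
    stringsAsFactors = FALSE
  )
  hosp <- sort(unique(c(inc$hospital, exc$hospital)))
  hosp <- hosp[!is.na(hosp)]
  if (length(hosp)) {
    hrows <- data.frame(
      characteristic = paste0("hospital: ", hosp),
      included = vapply(hosp, function(h)
        pct(sum(inc$hospital == h, na.rm = TRUE), nrow(inc)), ""),
      excluded = vapply(hosp, function(h)
        pct(sum(exc$hospital == h, na.rm = TRUE), nrow(exc)), ""),
      p_value = NA_real_, stringsAsFactors = FALSE
    )
    out <- rbind(out, hrows)
  }
  rownames(out) <- NULL
  out
}

#' Score distribution with mortality by score value
#'
#' For each score system, tabulates how many patients attained each score
#' value and the observed 7-day mortality at that value — the analogue of
#' a distribution-plus-mortality figure.
#'
#' @param cohort an `ews_cohort`.
#' @param score_cols score columns (default `c("TOKS", "mTOKS", "NEWS")`).
#' @return data.frame: `system`, `score`, `n`, `deaths`, `mortality_pct`.
#' @export
score_distribution <- function(cohort, score_cols = c("TOKS", "mTOKS", "NEWS")) {
  inc <- cohort$cases
  do.call(rbind, lapply(score_cols, function(sc) {
    agg <- stats::aggregate(inc$died_7d, by = list(score = inc[[sc]]),
                            FUN = function(x) c(n = length(x), d = sum(x)))
    data.frame(system = sc, score = agg$score, n = agg$x[, "n"],
               deaths = agg$x[, "d"],
               mortality_pct = round(100 * agg$x[, "d"] / agg$x[, "n"], 2))
  }))
}

# serialisable view of an ews_comparison
.comparison_as_list <- function(cmp) {
  list(
    n = cmp$n, n_cases = cmp$n_cases, alpha = cmp$alpha,
    estimates = lapply(cmp$estimates, function(e)
      list(auroc = e$auroc, se = e$se, ci_low = e$ci_low,
           ci_high = e$ci_high, conf_level = e$conf_level,
           n_cases = e$n_cases, n_controls = e$n_controls)),
    tests = cmp$tests,
    global = cmp$global
  )
}
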