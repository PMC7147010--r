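# Independent oracles and small input builders shared across test files.

# all-pairs Mann-Whitney AUROC: full credit when a case outscores a
# control, half credit on ties. O(m*n); the oracle the fast path must match.
auroc_oracle <- function(scores, outcomes) {
  x <- scores[outcomes]
  y <- scores[!outcomes]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# a one-row complete vital set with every parameter in its zero band
normal_vitals <- function(...) {
  v <- data.frame(sbp = 120, hr = 70, temp = 37, rr = 14, spo2 = 98,
                  avpu = "A", agitated = FALSE, on_oxygen = FALSE,
                  stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v
}

# n random complete vital sets spanning all bands, AVPU levels and flags
random_vitals <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    sbp = runif(n, 40, 260), hr = runif(n, 20, 180),
    temp = runif(n, 30, 43), rr = runif(n, 4, 50),
    spo2 = runif(n, 60, 100),
    avpu = sample(c("A", "V", "P", "U"), n, replace = TRUE),
    agitated = sample(c(TRUE, FALSE), n, replace = TRUE),
    on_oxygen = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# representative finite values, one per band of a scale
band_representatives <- function(scale) {
  mapply(function(lo, up) {
    if (!is.finite(lo)) up - 1 else if (!is.finite(up)) lo + 1 else (lo + up) / 2
  }, scale$lower, scale$upper)
}

# exhaustive maximisation of an aggregate score over band representatives,
# AVPU levels and both flags — the brute-force side of the max identity
brute_force_max <- function(system) {
  g <- expand.grid(
    sbp = band_representatives(system$scales$sbp),
    hr = band_representatives(system$scales$hr),
    temp = band_representatives(system$scales$temp),
    rr = band_representatives(system$scales$rr),
    spo2 = band_representatives(system$scales$spo2),
    avpu = c("A", "V", "P", "U"),
    agitated = c(TRUE, FALSE),
    on_oxygen = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  g$spo2 <- pmin(g$spo2, 100)
  max(ews_score(system, g))
}
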