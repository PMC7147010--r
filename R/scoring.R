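# Resolve level of consciousness for a vitals table holding either an
# `avpu` column, a `gcs` column, or both (exactly one non-NA per row).
# Agitation recorded alongside a GCS-derived LOC is zeroed by default:
# GCS does not capture agitation, so triage data carry no usable agitation
# signal; `honor_agitation_with_gcs = TRUE` overrides for sensitivity
# analysis.
.resolve_loc <- function(vitals, honor_agitation_with_gcs = FALSE) {
  has_avpu <- "avpu" %in% names(vitals)
  has_gcs <- "gcs" %in% names(vitals)
  if (!has_avpu && !has_gcs) {
    stop("vitals need an 'avpu' or 'gcs' column", call. = FALSE)
  }
  avpu <- if (has_avpu) as_avpu(vitals$avpu) else
    as_avpu(rep(NA_character_, nrow(vitals)))
  gcs <- if (has_gcs) vitals$gcs else rep(NA_real_, nrow(vitals))
  both <- !is.na(avpu) & !is.na(gcs)
  if (any(both)) {
    stop(sum(both), " row(s) record both AVPU and GCS; exactly one is allowed",
         call. = FALSE)
  }
  from_gcs <- is.na(avpu) & !is.na(gcs)
  if (any(from_gcs)) avpu[from_gcs] <- gcs_to_avpu(gcs[from_gcs])
  agitated <- as.logical(vitals$agitated)
  if (!honor_agitation_with_gcs) agitated[from_gcs & !is.na(agitated)] <- FALSE
  list(avpu = avpu, agitated = agitated, from_gcs = from_gcs)
}

# columns a row must document before it can be scored
.required_vital_cols <- function() c(.vital_params, "loc", "agitated", "on_oxygen")

# per-row missingness matrix (n x field) given resolved LOC
.vitals_missing <- function(vitals, loc) {
  n <- nrow(vitals)
  cols <- lapply(.vital_params, function(p) {
    if (!p %in% names(vitals)) rep(TRUE, n) else is.na(vitals[[p]])
  })
  names(cols) <- .vital_params
  cols$loc <- is.na(loc$avpu)
  cols$agitated <- is.na(loc$agitated)
  cols$on_oxygen <- if ("on_oxygen" %in% names(vitals)) {
    is.na(vitals$on_oxygen)
  } else rep(TRUE, n)
  do.call(cbind, cols)
}

#' Compute aggregate early-warning scores
#'
#' Scores each row of a vitals table under one system: the five numeric
#' parameter scales, the level-of-consciousness rule, plus the system's
#' oxygen points when `on_oxygen` is `TRUE`.
#'
#' @param system an `ews_system` (see [ews_systems()]).
#' @param vitals data.frame with columns `sbp`, `hr`, `temp`, `rr`, `spo2`
#'   (numeric), `agitated` and `on_oxygen` (logical), and exactly one of
#'   `avpu` (A/V/P/U) or `gcs` (3-15) documented per row.
#' @param honor_agitation_with_gcs score the agitation modifier even when
#'   LOC was derived from GCS (default `FALSE`: triage GCS carries no
#'   agitation information, so those rows get 0 agitation points).
#' @return Integer vector of aggregate scores, one per row.
#' @examples
#' v <- data.frame(sbp = 120, hr = 70, temp = 37, rr = 14, spo2 = 98,
#'                 avpu = "A", agitated = FALSE, on_oxygen = TRUE)
#' ews_score(ews_systems()$mTOKS, v)  # 2: oxygen supplement only
#' @export
ews_score <- function(system, vitals, honor_agitation_with_gcs = FALSE) {
  stopifnot(inherits(system, "ews_system"), is.data.frame(vitals))
  loc <- .resolve_loc(vitals, honor_agitation_with_gcs)
  miss <- .vitals_missing(vitals, loc)
  if (any(miss)) {
    bad <- which(rowSums(miss) > 0L)
    cols <- colnames(miss)[colSums(miss[bad, , drop = FALSE]) > 0L]
    stop("incomplete vital set in row(s) ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "",
         " (missing: ", paste(cols, collapse = ", "), ")", call. = FALSE)
  }
  total <- rep(0L, nrow(vitals))
  for (p in .vital_params) {
    total <- total + score_parameter(system$scales[[p]], vitals[[p]])
  }
  total <- total + score_loc(system$loc_rule, loc$avpu, loc$agitated)
  total + system$oxygen_points * as.integer(as.logical(vitals$on_oxygen))
}

#' Score a vitals table under all bundled systems
#'
#' @inheritParams ews_score
#' @param systems named list of `ews_system` objects
#'   (default [ews_systems()]: TOKS, mTOKS, NEWS).
#' @return data.frame with one integer column per system, rows aligned with
#'   `vitals`. By construction `mTOKS - TOKS` is 2 exactly on rows with
#'   supplemental oxygen and 0 otherwise.
#' @export
score_all_systems <- function(vitals, systems = ews_systems(),
                              honor_agitation_with_gcs = FALSE) {
  out <- lapply(systems, ews_score, vitals = vitals,
                honor_agitation_with_gcs = honor_agitation_with_gcs)
  as.data.frame(out, optional = TRUE)
}
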