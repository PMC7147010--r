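#' AVPU consciousness levels
#'
#' The four-level AVPU scale used by track-and-trigger scores:
#' `A` (alert), `V` (responds to voice), `P` (responds to pain),
#' `U` (unresponsive). Levels are ordered `A < V < P < U`.
#'
#' @format A character vector of the four level codes, in order.
#' @export
avpu_levels <- c("A", "V", "P", "U")

#' Coerce to an ordered AVPU factor
#'
#' @param x character vector (or factor) of AVPU codes.
#' @return An ordered factor with levels `A < V < P < U`; `NA` passes through.
#' @export
as_avpu <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% avpu_levels)
  if (any(bad)) {
    stop("invalid AVPU level(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected A, V, P or U)", call. = FALSE)
  }
  factor(x, levels = avpu_levels, ordered = TRUE)
}

#' Convert Glasgow Coma Scale totals to AVPU
#'
#' Triage in the emergency departments records consciousness as a GCS total
#' (3-15); ward scoring uses AVPU. The conversion is the one commonly used
#' when applying AVPU-based scores to triage data:
#' GCS 15 = A, GCS 14 = V, GCS 9-13 = P, GCS 3-8 = U.
#'
#' @param gcs integer vector of GCS totals in 3..15; `NA` passes through.
#' @return Ordered AVPU factor of the same length.
#' @examples
#' gcs_to_avpu(c(15, 14, 10, 3))
#' @export
gcs_to_avpu <- function(gcs) {
  gcs <- as.numeric(gcs)
  ok <- is.na(gcs) | (gcs >= 3 & gcs <= 15 & gcs == floor(gcs))
  if (!all(ok)) {
    stop("GCS total out of range (must be an integer in 3..15): ",
         paste(unique(gcs[!ok]), collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(gcs))
  out[!is.na(gcs) & gcs == 15] <- "A"
  out[!is.na(gcs) & gcs == 14] <- "V"
  out[!is.na(gcs) & gcs >= 9 & gcs <= 13] <- "P"
  out[!is.na(gcs) & gcs <= 8] <- "U"
  as_avpu(out)
}
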