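#' @importFrom stats var setNames quantile median rbinom rnorm runif rgamma
#'   rexp plogis pchisq pnorm qnorm wilcox.test chisq.test sd rbeta
#' @importFrom utils head modifyList
NULL

# parameters every system must scale, in canonical order
.vital_params <- c("sbp", "hr", "temp", "rr", "spo2")

.pkg_env <- new.env(parent = emptyenv())

#' Construct an early-warning-score system
#'
#' A score system is data: one ordered set of half-open threshold bands
#' `[lower, upper)` per vital parameter, a level-of-consciousness rule
#' (AVPU points, agitation points and how the two combine), a flat number
#' of points for receiving supplemental oxygen, and the declared maximum
#' aggregate score. The declared maximum doubles as a transcription
#' checksum: [validate_score_system()] recomputes the attainable maximum
#' from the bands and flags any mismatch.
#'
#' @param name system name, e.g. `"TOKS"`.
#' @param scales named list (names among sbp, hr, temp, rr, spo2) of
#'   data.frames with columns `lower`, `upper`, `points`; use `-Inf`/`Inf`
#'   for open ends.
#' @param loc_rule list with `avpu_points` (named numeric, A must be 0),
#'   `agitation_points` (single non-negative integer) and `combination`
#'   (`"max"` or `"sum"`).
#' @param oxygen_points points added when the patient is on supplemental
#'   oxygen (0 for TOKS, 2 for mTOKS and NEWS).
#' @param declared_max the system's published maximum aggregate score.
#' @return An object of class `ews_system`.
#' @seealso [load_score_system()], [ews_systems()], [validate_score_system()]
#' @export
ews_system <- function(name, scales, loc_rule, oxygen_points, declared_max) {
  stopifnot(is.character(name), length(name) == 1L)
  scales <- scales[intersect(.vital_params, names(scales))]
  scales <- lapply(scales, function(s) {
    s <- as.data.frame(s)[, c("lower", "upper", "points")]
    s$lower <- as.numeric(s$lower)
    s$upper <- as.numeric(s$upper)
    s$points <- as.integer(s$points)
    s[order(s$lower), , drop = FALSE]
  })
  structure(
    list(name = name, scales = scales, loc_rule = loc_rule,
         oxygen_points = as.integer(oxygen_points),
         declared_max = as.integer(declared_max)),
    class = "ews_system"
  )
}

#' @export
print.ews_system <- function(x, ...) {
  cat(sprintf("<ews_system> %s (max %d, oxygen %+d)\n",
              x$name, x$declared_max, x$oxygen_points))
  for (p in names(x$scales)) {
    b <- x$scales[[p]]
    cat(sprintf("  %-5s %s\n", p, paste(
      sprintf("[%s,%s)=%d", format(b$lower), format(b$upper), b$points),
      collapse = " ")))
  }
  lr <- x$loc_rule
  cat(sprintf("  loc   %s; agitated=%d; combine=%s\n",
              paste(names(lr$avpu_points), lr$avpu_points, sep = "=",
                    collapse = " "),
              lr$agitation_points, lr$combination))
  invisible(x)
}

#' Load a score system from a JSON configuration file
#'
#' The file holds `name`, `declared_max`, `oxygen_points`, `loc_rule` and
#' `scales` (one entry per parameter, each a list of
#' `{lower, upper, points}` bands). Open interval ends are encoded as JSON
#' `null` and mapped to minus/plus infinity.
#'
#' @param path path to the JSON file.
#' @param validate validate the system after loading (default `TRUE`);
#'   violations raise an error.
#' @return An `ews_system`.
#' @export
load_score_system <- function(path, validate = TRUE) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = FALSE)
  need <- c("name", "declared_max", "oxygen_points", "loc_rule", "scales")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("score-system config ", path, " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scales <- list()
  for (sc in cfg$scales) {
    bands <- do.call(rbind, lapply(sc$bands, function(b) {
      data.frame(lower = if (is.null(b$lower)) -Inf else as.numeric(b$lower),
                 upper = if (is.null(b$upper)) Inf else as.numeric(b$upper),
                 points = as.integer(b$points))
    }))
    scales[[sc$parameter]] <- bands
  }
  lr <- cfg$loc_rule
  loc_rule <- list(
    avpu_points = unlist(lr$avpu_points)[avpu_levels],
    agitation_points = as.integer(lr$agitation_points),
    combination = match.arg(lr$combination, c("max", "sum"))
  )
  sys <- ews_system(cfg$name, scales, loc_rule,
                    cfg$oxygen_points, cfg$declared_max)
  if (validate) {
    v <- validate_score_system(sys)
    if (length(v)) {
      stop("invalid score system in ", path, ":\n  ",
           paste(v, collapse = "\n  "), call. = FALSE)
    }
  }
  sys
}

#' The bundled TOKS, mTOKS and NEWS systems
#'
#' Loads (and caches) the three score systems shipped with the package:
#' TOKS (max 18, no oxygen points), mTOKS (TOKS plus 2 points for oxygen
#' supplement, max 20) and the RCP 2012 NEWS (max 20, 2 oxygen points).
#'
#' @return Named list of three `ews_system` objects
#'   (`TOKS`, `mTOKS`, `NEWS`).
#' @export
ews_systems <- function() {
  if (is.null(.pkg_env$systems)) {
    dir <- system.file("extdata", "scores", package = "ewscompare")
    .pkg_env$systems <- list(
      TOKS = load_score_system(file.path(dir, "toks.json")),
      mTOKS = load_score_system(file.path(dir, "mtoks.json")),
      NEWS = load_score_system(file.path(dir, "news.json"))
    )
  }
  .pkg_env$systems
}

# maximum attainable LOC points under the rule
.loc_max <- function(rule) {
  a <- max(rule$avpu_points)
  g <- rule$agitation_points
  if (rule$combination == "sum") a + g else max(a, g)
}

# maximum attainable aggregate score, recomputed from the bands
.system_max <- function(system) {
  sum(vapply(system$scales, function(s) max(s$points), integer(1))) +
    .loc_max(system$loc_rule) + system$oxygen_points
}

#' Validate a score system
#'
#' Checks that every parameter scale partitions the real line into
#' half-open `[lower, upper)` bands with no gaps or overlaps, that points
#' lie in 0..3 with exactly one zero band per scale, that the
#' level-of-consciousness rule is well formed (A maps to 0, points
#' non-decreasing in AVPU order), and that the maximum attainable score
#' recomputed from the bands equals `declared_max`. The last check acts as
#' a checksum on the transcription of the published scoring tables.
#'
#' @param system an `ews_system`.
#' @return Character vector of violations; empty (length 0) when the system
#'   is valid. The recomputed maximum is attached as attribute
#'   `computed_max`.
#' @export
validate_score_system <- function(system) {
  v <- character(0)
  missing <- setdiff(.vital_params, names(system$scales))
  if (length(missing)) {
    v <- c(v, paste0("missing scale(s): ", paste(missing, collapse = ", ")))
  }
  for (p in names(system$scales)) {
    b <- system$scales[[p]]
    if (any(b$points < 0L | b$points > 3L)) {
      v <- c(v, sprintf("%s: points outside 0..3", p))
    }
    if (any(b$lower >= b$upper)) {
      v <- c(v, sprintf("%s: band with lower >= upper", p))
    }
    if (is.finite(b$lower[1L])) {
      v <- c(v, sprintf("%s: gap over (-Inf, %g)", p, b$lower[1L]))
    }
    if (is.finite(b$upper[nrow(b)])) {
      v <- c(v, sprintf("%s: gap over [%g, Inf)", p, b$upper[nrow(b)]))
    }
    if (nrow(b) > 1L) {
      lo <- b$lower[-1L]
      up <- b$upper[-nrow(b)]
      gap <- lo > up
      if (any(gap)) {
        v <- c(v, sprintf("%s: gap over [%g, %g)", p, up[gap], lo[gap]))
      }
      ov <- lo < up
      if (any(ov)) {
        v <- c(v, sprintf("%s: overlap over [%g, %g)", p, lo[ov], up[ov]))
      }
    }
    nz <- sum(b$points == 0L)
    if (nz != 1L) {
      v <- c(v, sprintf("%s: %d zero bands (expected exactly 1)", p, nz))
    }
  }
  lr <- system$loc_rule
  if (length(lr$avpu_points) != 4L || any(is.na(lr$avpu_points))) {
    v <- c(v, "loc_rule: avpu_points must cover A, V, P, U")
  } else {
    if (lr$avpu_points[["A"]] != 0) v <- c(v, "loc_rule: A must map to 0")
    if (is.unsorted(lr$avpu_points)) {
      v <- c(v, "loc_rule: avpu_points must be non-decreasing in AVPU order")
    }
  }
  if (lr$agitation_points < 0) v <- c(v, "loc_rule: negative agitation points")
  cmax <- if (length(missing)) NA_integer_ else .system_max(system)
  if (!is.na(cmax) && cmax != system$declared_max) {
    v <- c(v, sprintf("computed max %d != declared max %d",
                      cmax, system$declared_max))
  }
  attr(v, "computed_max") <- cmax
  v
}

#' Score a single vital parameter against a threshold scale
#'
#' Bands are half-open `[lower, upper)`: a value exactly on a band's lower
#' threshold scores in that band, matching the ">= a - < b" convention of
#' the published tables.
#'
#' @param scale a data.frame of bands (`lower`, `upper`, `points`) as held
#'   in `ews_system$scales`, sorted and validated.
#' @param value numeric vector of measurements; `NA` propagates.
#' @return Integer vector of points.
#' @export
score_parameter <- function(scale, value) {
  value <- as.numeric(value)
  if (any(is.infinite(value) | is.nan(value))) {
    stop("non-finite vital value(s) cannot be scored", call. = FALSE)
  }
  idx <- findInterval(value, scale$lower)  # lower[i] <= x < lower[i+1]
  out <- rep(NA_integer_, length(value))
  out[!is.na(idx)] <- scale$points[idx[!is.na(idx)]]
  out
}

#' Score level of consciousness
#'
#' Combines AVPU points with the agitation modifier under the rule's
#' `combination` (`max` or `sum`). An alert, calm patient always scores 0.
#'
#' @param rule the `loc_rule` component of an `ews_system`.
#' @param loc AVPU levels (character or factor).
#' @param agitated logical vector.
#' @return Integer vector of points; `NA` where either input is `NA`.
#' @export
score_loc <- function(rule, loc, agitated) {
  loc <- as_avpu(loc)
  a <- rule$avpu_points[as.integer(loc)]
  g <- rule$agitation_points * as.integer(agitated)
  out <- if (rule$combination == "sum") a + g else pmax(a, g)
  as.integer(out)
}
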