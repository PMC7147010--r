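.check_roc_input <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  scores <- as.numeric(scores)
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes must have equal length", call. = FALSE)
  }
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]
  outcomes <- outcomes[keep]
  m <- sum(outcomes)
  n <- sum(!outcomes)
  if (m < 1L || n < 1L) {
    stop("degenerate outcome vector: need at least one case and one control ",
         "(got ", m, " cases, ", n, " controls)", call. = FALSE)
  }
  list(scores = scores, outcomes = outcomes, m = m, n = n)
}

#' Empirical ROC curve
#'
#' One operating point per unique score value, using the decision rule
#' "positive if score >= t", plus the trivial (0,0) endpoint at
#' `t = Inf`. Sensitivity (true positive rate) is plotted against
#' 1 - specificity (false positive rate).
#'
#' @param scores numeric risk scores; higher means higher predicted risk.
#' @param outcomes logical (or 0/1) outcome, `TRUE` = case.
#' @return An object of class `ews_roc`: a data.frame with columns
#'   `threshold`, `fpr`, `tpr`, ordered from (0,0) to (1,1).
#' @export
compute_roc <- function(scores, outcomes) {
  d <- .check_roc_input(scores, outcomes)
  o <- order(-d$scores)
  s <- d$scores[o]
  y <- d$outcomes[o]
  last <- cumsum(rle(s)$lengths)  # last index of each unique score, descending
  out <- data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, cumsum(!y)[last] / d$n),
    tpr = c(0, cumsum(y)[last] / d$m)
  )
  structure(out, class = c("ews_roc", "data.frame"),
            n_cases = d$m, n_controls = d$n)
}

#' @export
print.ews_roc <- function(x, ...) {
  cat(sprintf("<ews_roc> %d operating points, %d cases / %d controls\n",
              nrow(x), attr(x, "n_cases"), attr(x, "n_controls")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Area under an ROC curve by the trapezoidal rule
#'
#' @param roc an `ews_roc` from [compute_roc()].
#' @return The trapezoidal area, identical to the tie-corrected
#'   Mann-Whitney statistic of the underlying scores.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

# DeLong structural components ("placements") via midranks, O(n log n).
# v10[i] = P-hat(case i outranks a random control), half credit for ties;
# v01[j] analogous for controls. mean(v10) = mean(v01) = AUROC.
.delong_placements <- function(scores, outcomes) {
  x <- scores[outcomes]
  y <- scores[!outcomes]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(theta = sum(r_all[seq_len(m)] - r_x) / (m * n), v10 = v10, v01 = v01,
       m = m, n = n)
}

#' AUROC with DeLong variance and confidence interval
#'
#' The AUROC is the tie-corrected Mann-Whitney statistic: the probability
#' that a random case outscores a random control, with half credit for
#' ties. The variance comes from DeLong's structural components
#' (per-subject placement values), which are retained in the returned
#' object so that covariances with other scores measured on the same
#' subjects can be formed for paired tests.
#'
#' @inheritParams compute_roc
#' @param conf_level confidence level for the interval (default 0.95).
#' @param ci_method `"wald"` (normal interval on the AUROC scale, clipped
#'   to \[0,1\]) or `"logit"` (normal interval on the log-odds scale,
#'   back-transformed).
#' @return An object of class `ews_auroc`: list with `auroc`, `variance`,
#'   `se`, `ci_low`, `ci_high`, `n_cases`, `n_controls`, and the placement
#'   vectors `v10` (cases) and `v01` (controls).
#' @export
auroc <- function(scores, outcomes, conf_level = 0.95,
                  ci_method = c("wald", "logit")) {
  ci_method <- match.arg(ci_method)
  d <- .check_roc_input(scores, outcomes)
  pl <- .delong_placements(d$scores, d$outcomes)
  s10 <- if (pl$m > 1L) var(pl$v10) else 0
  s01 <- if (pl$n > 1L) var(pl$v01) else 0
  v <- s10 / pl$m + s01 / pl$n
  se <- sqrt(v)
  z <- qnorm(1 - (1 - conf_level) / 2)
  th <- pl$theta
  if (ci_method == "wald" || se == 0 || th %in% c(0, 1)) {
    ci <- c(max(0, th - z * se), min(1, th + z * se))
  } else {
    lo <- log(th / (1 - th))
    se_lo <- se / (th * (1 - th))
    ci <- plogis(c(lo - z * se_lo, lo + z * se_lo))
  }
  structure(
    list(auroc = th, variance = v, se = se,
         ci_low = ci[1L], ci_high = ci[2L], conf_level = conf_level,
         ci_method = ci_method, n_cases = pl$m, n_controls = pl$n,
         v10 = pl$v10, v01 = pl$v01),
    class = "ews_auroc"
  )
}

#' @export
print.ews_auroc <- function(x, digits = 3, ...) {
  cat(sprintf("AUROC %.*f (%d%%-CI %.*f-%.*f; %d cases, %d controls)\n",
              digits, x$auroc, round(100 * x$conf_level),
              digits, x$ci_low, digits, x$ci_high,
              x$n_cases, x$n_controls))
  invisible(x)
}

# covariance matrix of k correlated AUROCs on identical subjects;
# complete-case filtering is joint so placements stay aligned
.delong_cov <- function(score_list, outcomes) {
  outcomes <- as.logical(outcomes)
  keep <- !is.na(outcomes) &
    Reduce(`&`, lapply(score_list, function(s) !is.na(s)))
  pls <- lapply(score_list, function(s) {
    d <- .check_roc_input(s[keep], outcomes[keep])
    .delong_placements(d$scores, d$outcomes)
  })
  m <- pls[[1L]]$m
  n <- pls[[1L]]$n
  V10 <- sapply(pls, `[[`, "v10")
  V01 <- sapply(pls, `[[`, "v01")
  theta <- vapply(pls, `[[`, numeric(1), "theta")
  sigma <- stats::cov(V10) / m + stats::cov(V01) / n
  list(theta = theta, sigma = sigma, m = m, n = n)
}

#' DeLong test for two correlated AUROCs
#'
#' Tests equality of the AUROCs of two risk scores measured on the same
#' subjects. The variance of the AUROC difference accounts for the
#' within-subject correlation through the covariance of the DeLong
#' placement values; the statistic `delta^2 / var(delta)` is referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param score_a,score_b numeric scores for the same subjects.
#' @param outcomes logical outcome vector, `TRUE` = case.
#' @return An object of class `ews_paired_test`: list with `delta`
#'   (`AUROC(a) - AUROC(b)`), `se_delta`, `chi2`, `df`, `p_value`, and the
#'   two AUROCs `auroc_a`, `auroc_b`.
#' @export
paired_delong_test <- function(score_a, score_b, outcomes) {
  d <- .check_roc_input(score_a, outcomes)
  if (d$m < 2L || d$n < 2L) {
    stop("paired test needs at least 2 cases and 2 controls", call. = FALSE)
  }
  cv <- .delong_cov(list(a = score_a, b = score_b), outcomes)
  cv$theta <- unname(cv$theta)
  delta <- cv$theta[1L] - cv$theta[2L]
  vard <- cv$sigma[1L, 1L] + cv$sigma[2L, 2L] - 2 * cv$sigma[1L, 2L]
  if (vard <= .Machine$double.eps^0.75) {
    if (abs(delta) <= .Machine$double.eps^0.5) {
      chi2 <- 0
      p <- 1
      vard <- 0
    } else {
      stop("zero variance of the AUROC difference with nonzero delta; ",
           "the paired test is undefined", call. = FALSE)
    }
  } else {
    chi2 <- delta^2 / vard
    p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  }
  structure(
    list(delta = delta, se_delta = sqrt(vard), chi2 = chi2, df = 1L,
         p_value = p, auroc_a = cv$theta[1L], auroc_b = cv$theta[2L],
         n_cases = cv$m, n_controls = cv$n),
    class = "ews_paired_test"
  )
}

#' @export
print.ews_paired_test <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Paired DeLong test: delta = %.*f (AUROC %.*f vs %.*f), chi2(%d) = %.*f, p = %.2g\n",
    digits, x$delta, digits, x$auroc_a, digits, x$auroc_b,
    x$df, digits, x$chi2, x$p_value))
  invisible(x)
}

#' Compare the discrimination of all score systems on one cohort
#'
#' Computes one AUROC (with DeLong confidence interval) per score column
#' and all pairwise DeLong tests on the identical subject set, optionally
#' plus a global 2-degree-of-freedom contrast that all AUROCs are equal.
#'
#' @param cohort data.frame holding the score columns and the outcome
#'   column (e.g. the `cases` table from [build_cohort()]).
#' @param score_cols names of the score columns
#'   (default `c("TOKS", "mTOKS", "NEWS")`).
#' @param outcome_col name of the logical outcome column
#'   (default `"died_7d"`).
#' @param conf_level confidence level for AUROC intervals.
#' @param alpha significance threshold recorded in the report
#'   (default 0.05).
#' @param global also compute the global contrast (default `TRUE`).
#' @return An object of class `ews_comparison`: list with `estimates`
#'   (named list of `ews_auroc`), `tests` (data.frame of pairwise tests),
#'   `global` (list with `chi2`, `df`, `p_value`, or `NULL`), `alpha`, `n`.
#' @export
compare_systems <- function(cohort, score_cols = c("TOKS", "mTOKS", "NEWS"),
                            outcome_col = "died_7d", conf_level = 0.95,
                            alpha = 0.05, global = TRUE) {
  stopifnot(all(score_cols %in% names(cohort)),
            outcome_col %in% names(cohort))
  y <- as.logical(cohort[[outcome_col]])
  est <- lapply(score_cols, function(sc)
    auroc(cohort[[sc]], y, conf_level = conf_level))
  names(est) <- score_cols
  pairs <- utils::combn(score_cols, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    t <- paired_delong_test(cohort[[a]], cohort[[b]], y)
    data.frame(score_a = a, score_b = b, auroc_a = t$auroc_a,
               auroc_b = t$auroc_b, delta = t$delta, se_delta = t$se_delta,
               chi2 = t$chi2, df = t$df, p_value = t$p_value,
               significant = t$p_value < alpha)
  }))
  glob <- NULL
  if (global && length(score_cols) > 2L) {
    cv <- .delong_cov(as.list(cohort[score_cols]), y)
    k <- length(score_cols)
    L <- cbind(diag(k - 1L), 0) - cbind(0, diag(k - 1L))  # successive diffs
    d <- drop(L %*% cv$theta)
    S <- L %*% cv$sigma %*% t(L)
    chi2 <- tryCatch(drop(t(d) %*% solve(S, d)), error = function(e) NA_real_)
    glob <- list(chi2 = chi2, df = k - 1L,
                 p_value = pchisq(chi2, df = k - 1L, lower.tail = FALSE))
  }
  structure(
    list(estimates = est, tests = tests, global = glob, alpha = alpha,
         n = length(y), n_cases = sum(y)),
    class = "ews_comparison"
  )
}

#' @export
print.ews_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("<ews_comparison> n = %d (%d deaths)\n", x$n, x$n_cases))
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    cat(sprintf("  %-6s AUROC %.2f (%d%%-CI %.2f-%.2f)\n", nm, e$auroc,
                round(100 * e$conf_level), e$ci_low, e$ci_high))
  }
  cat("Pairwise DeLong tests:\n")
  print(x$tests[, c("score_a", "score_b", "delta", "chi2", "p_value")],
        digits = digits, row.names = FALSE)
  if (!is.null(x$global)) {
    cat(sprintf("Global contrast: chi2(%d) = %.*f, p = %.2g\n",
                x$global$df, digits, x$global$chi2, x$global$p_value))
  }
  invisible(x)
}

#' Plot overlaid ROC curves
#'
#' @param comparison an `ews_comparison`, or a named list of score vectors.
#' @param cohort,outcome_col used when `comparison` is an `ews_comparison`
#'   built from `cohort`: curves are recomputed from the same columns.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the list of `ews_roc` curves.
#' @export
plot_roc_curves <- function(comparison, cohort, outcome_col = "died_7d", ...) {
  score_cols <- names(comparison$estimates)
  y <- as.logical(cohort[[outcome_col]])
  curves <- lapply(score_cols, function(sc) compute_roc(cohort[[sc]], y))
  names(curves) <- score_cols
  cols <- c("#1b6ca8", "#d1495b", "#228b22", "#8a2be2")[seq_along(curves)]
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey50",
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  for (i in seq_along(curves)) {
    graphics::lines(curves[[i]]$fpr, curves[[i]]$tpr, col = cols[i], lwd = 2)
  }
  leg <- sprintf("%s (AUROC %.2f)", score_cols,
                 vapply(comparison$estimates, `[[`, numeric(1), "auroc"))
  graphics::legend("bottomright", legend = leg, col = cols, lwd = 2, bty = "n")
  invisible(curves)
}
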