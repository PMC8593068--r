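# Bespoke study measures: min-max normalized diagnostic accuracy, option
# rates with trial-then-grand averaging, the percentage-point inequity
# statistic, odds of unsafe undertreatment vs guideline care, the revision
# coefficient, and recommendation-improvement flags.

filter_records <- function(records, round = NULL, condition = NULL,
                           arm = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(round)) keep <- keep & records$round == round
  if (!is.null(condition)) keep <- keep & records$condition == condition
  if (!is.null(arm)) keep <- keep & records$arm == arm
  records[keep, , drop = FALSE]
}

#' Min-max normalized diagnostic accuracy
#'
#' Accuracy is `1 - |estimate - anchor| / max_error`: 1 for an estimate
#' equal to the 16% risk anchor, 0 for the farthest possible estimate
#' (100%, i.e. 84 percentage points of absolute error).
#'
#' @param estimate numeric vector of probability estimates in `[0, 100]`.
#' @param anchor the most accurate assessment (default 16).
#' @param max_error the largest attainable absolute error (default 84).
#' @return Numeric vector of accuracies in `[0, 1]`.
#' @export
#' @examples
#' normalized_accuracy(c(16, 100, 0))
normalized_accuracy <- function(estimate, anchor = RISK_ANCHOR,
                                max_error = MAX_ABS_ERROR) {
  if (any(is.na(estimate)) || any(estimate < 0 | estimate > 100))
    stop("estimates must lie in [0, 100]", call. = FALSE)
  1 - abs(estimate - anchor) / max_error
}

#' Option recommendation rates
#'
#' Fraction of clinicians recommending each option in a given round. With
#' `aggregate = "trial"` (the default, matching the study's presentation)
#' rates are computed within each trial and then averaged across trials
#' with equal weight; `aggregate = "pooled"` pools all selected records.
#'
#' @param records response-record data frame.
#' @param round round number to tabulate.
#' @param condition,arm optional filters.
#' @param aggregate `"trial"` or `"pooled"`.
#' @return Named probability vector over A, B, C, D (sums to 1).
#' @export
option_rates <- function(records, round, condition = NULL, arm = NULL,
                         aggregate = c("trial", "pooled")) {
  aggregate <- match.arg(aggregate)
  sel <- filter_records(records, round, condition, arm)
  if (nrow(sel) == 0L)
    stop("no records match the requested selection", call. = FALSE)
  f <- factor(sel$recommendation, levels = OPTION_LEVELS)
  if (aggregate == "pooled") {
    p <- as.numeric(table(f)) / nrow(sel)
  } else {
    per_trial <- tapply(f, sel$trial_id,
                        function(x) as.numeric(table(x)) / length(x))
    p <- rowMeans(do.call(cbind, per_trial))
  }
  stats::setNames(p, OPTION_LEVELS)
}

#' Treatment inequity between patient arms
#'
#' For each arm the gap is `P(Option A) - P(Option C)` in percentage
#' points: how much more often clinicians recommend unsafe undertreatment
#' than guideline care. The inequity statistic is the Black female arm's
#' gap minus the white male arm's gap, so it is antisymmetric under arm
#' exchange and zero for identical option distributions.
#'
#' @inheritParams option_rates
#' @return A list of class `clinnet_inequity` with elements `gap` (named
#'   per-arm gaps, pp) and `inequity` (between-arm difference, pp).
#' @export
inequity <- function(records, round, condition = NULL,
                     aggregate = c("trial", "pooled")) {
  aggregate <- match.arg(aggregate)
  gap <- vapply(ARM_LEVELS, function(a) {
    sel <- filter_records(records, round, condition, a)
    if (nrow(sel) == 0L)
      stop("arm '", a, "' has no records in round ", round, call. = FALSE)
    r <- option_rates(sel, round, aggregate = aggregate)
    (r[["A"]] - r[["C"]]) * 100
  }, numeric(1))
  structure(list(gap = gap,
                 inequity = gap[["black_female"]] - gap[["white_male"]]),
            class = "clinnet_inequity")
}

#' @export
print.clinnet_inequity <- function(x, ...) {
  cat(sprintf("A-vs-C gap (pp): black_female %+.1f, white_male %+.1f\n",
              x$gap[["black_female"]], x$gap[["white_male"]]))
  cat(sprintf("Between-arm inequity: %+.1f pp\n", x$inequity))
  invisible(x)
}

#' Odds of unsafe undertreatment rather than guideline care
#'
#' `count(Option A) / count(Option C)` among the selected records. A zero
#' Option C count makes the odds undefined and raises an error unless the
#' Haldane-Anscombe `+0.5` correction is requested.
#'
#' @inheritParams option_rates
#' @param correction add 0.5 to both counts (for regression contexts).
#' @return A single nonnegative number.
#' @export
undertreatment_odds <- function(records, round, arm = NULL, condition = NULL,
                                correction = FALSE) {
  sel <- filter_records(records, round, condition, arm)
  if (nrow(sel) == 0L)
    stop("no records match the requested selection", call. = FALSE)
  n_a <- sum(sel$recommendation == "A")
  n_c <- sum(sel$recommendation == "C")
  if (correction) return((n_a + 0.5) / (n_c + 0.5))
  if (n_c == 0L)
    stop("odds undefined: no Option C recommendations in selection",
         call. = FALSE)
  n_a / n_c
}

# Cluster-robust (CR1) covariance for a fitted lm/glm given cluster labels.
cluster_vcov <- function(fit, clusters) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit, type = "response")
  w <- stats::weights(fit)
  if (is.null(w)) w <- rep(1, length(u))
  scores <- X * (w * u)
  g <- factor(clusters)
  G <- nlevels(g)
  meat <- crossprod(rowsum(scores, g))
  if (inherits(fit, "glm")) {
    W <- fit$weights  # IRLS weights
    bread <- solve(crossprod(X * sqrt(W)))
    scores <- X * stats::residuals(fit, type = "working") * W
    meat <- crossprod(rowsum(scores, g))
  } else {
    bread <- solve(crossprod(X))
  }
  n <- nrow(X); k <- ncol(X)
  adj <- G / (G - 1) * (n - 1) / (n - k)
  adj * bread %*% meat %*% bread
}

#' Revision coefficient
#'
#' The Pearson correlation between a clinician's initial absolute error
#' `x = |initial - anchor|` and the magnitude of their revision
#' `y = |final - initial|`. A positive value means less accurate clinicians
#' revise more, giving accurate clinicians greater de facto influence in the
#' network. The standard error is obtained from a cluster-robust (by trial)
#' OLS of `y` on `x` and transported to the correlation scale through
#' `r = b * sd(x) / sd(y)`, so `se(r) = se(b) * sd(x) / sd(y)`.
#'
#' @param initial,final paired estimate vectors (same clinicians).
#' @param clusters cluster labels (typically trial ids); a single shared
#'   label degrades gracefully to the classical OLS standard error.
#' @param anchor the risk anchor (default 16).
#' @return List with `r`, `se` (clustered, correlation scale), `slope`,
#'   `slope_se`, and `n`.
#' @export
#' @examples
#' revision_coefficient(c(16, 26, 36), c(16, 21, 26), clusters = c(1, 1, 1))
revision_coefficient <- function(initial, final, clusters,
                                 anchor = RISK_ANCHOR) {
  if (length(initial) != length(final) ||
      length(initial) != length(clusters))
    stop("initial, final and clusters must have equal length", call. = FALSE)
  if (length(initial) < 3L)
    stop("need at least 3 paired estimates", call. = FALSE)
  x <- abs(initial - anchor)
  y <- abs(final - initial)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in error or revision",
         call. = FALSE)
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  g <- factor(clusters)
  vc <- if (nlevels(g) > 1) cluster_vcov(fit, g) else stats::vcov(fit)
  slope_se <- sqrt(vc["x", "x"])
  list(r = r, se = slope_se * stats::sd(x) / stats::sd(y),
       slope = unname(stats::coef(fit)["x"]), slope_se = slope_se,
       n = length(x))
}

#' Recommendation improvement between two rounds
#'
#' Flags clinicians who were incorrect (per the correctness rule) at
#' `round_a` and correct at `round_b` -- e.g. switching from Option A, B or
#' D to Option C -- and reports the percentage-point change in the correct
#' rate. Clinicians missing either round (attrition) are excluded and
#' counted.
#'
#' @param records response-record data frame.
#' @param round_a,round_b the two rounds to compare (default 1 and 3).
#' @param rule a [correctness_rule()].
#' @return List with `improved` (named logical per clinician), `delta_pp`
#'   (change in correct rate, percentage points), `rate_a`, `rate_b`,
#'   `n_used` and `n_excluded`.
#' @export
improvement <- function(records, round_a = 1L, round_b = 3L,
                        rule = correctness_rule()) {
  a <- filter_records(records, round_a)
  b <- filter_records(records, round_b)
  common <- intersect(a$clinician_id, b$clinician_id)
  n_excluded <- length(union(a$clinician_id, b$clinician_id)) - length(common)
  if (length(common) == 0L)
    stop("no clinician has responses in both rounds", call. = FALSE)
  rec_a <- stats::setNames(a$recommendation, a$clinician_id)[common]
  rec_b <- stats::setNames(b$recommendation, b$clinician_id)[common]
  ok_a <- is_correct(rec_a, rule)
  ok_b <- is_correct(rec_b, rule)
  list(improved = stats::setNames(!ok_a & ok_b, common),
       delta_pp = (mean(ok_b) - mean(ok_a)) * 100,
       rate_a = mean(ok_a), rate_b = mean(ok_b),
       n_used = length(common), n_excluded = n_excluded)
}

#' Tidy per-cell metric table
#'
#' One row per (trial, condition, arm, round, metric): mean normalized
#' accuracy, per-option rates, correct rate under the supplied rule, and
#' the A-minus-C gap in percentage points. This is the tidy CSV emitted by
#' the analysis pipeline.
#'
#' @param records response-record data frame.
#' @param rule a [correctness_rule()].
#' @return A long-format data frame with columns `trial_id`, `condition`,
#'   `arm`, `round`, `metric`, `value`.
#' @export
metrics_table <- function(records, rule = correctness_rule()) {
  cells <- unique(records[c("trial_id", "condition", "arm", "round")])
  cells <- cells[order(cells$trial_id,
                       match(cells$condition, CONDITION_LEVELS),
                       match(cells$arm, ARM_LEVELS), cells$round), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sel <- records[records$trial_id == cell$trial_id &
                   records$condition == cell$condition &
                   records$arm == cell$arm &
                   records$round == cell$round, , drop = FALSE]
    rates <- as.numeric(table(factor(sel$recommendation,
                                     levels = OPTION_LEVELS))) / nrow(sel)
    vals <- c(accuracy_mean = mean(normalized_accuracy(sel$estimate)),
              stats::setNames(rates, paste0("rate_", OPTION_LEVELS)),
              correct_rate = mean(is_correct(sel$recommendation, rule)),
              gap_pp = (rates[1L] - rates[3L]) * 100)
    data.frame(cell, metric = names(vals), value = unname(vals),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
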