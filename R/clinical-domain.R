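# Clinical scoring for the standardized chest-pain case: HEART score
# arithmetic, the intermediate-band risk anchor, the four treatment options
# and the correctness rule used for compensation and sensitivity analyses.

ARM_LEVELS <- c("black_female", "white_male")
CONDITION_LEVELS <- c("network", "control")
OPTION_LEVELS <- c("A", "B", "C", "D")

# The risk anchor: most accurate 30-day MACE probability (in percent) for a
# HEART score in the intermediate 4-6 band, and the largest possible absolute
# error of an estimate on [0, 100] relative to that anchor.
RISK_ANCHOR <- 16
MAX_ABS_ERROR <- 84

#' The four treatment options of the standardized case
#'
#' Option A is unsafe undertreatment (low-dose aspirin, one-week follow-up),
#' Option B undertreatment (stress test in 2-3 days), Option C the
#' guideline-recommended treatment (full-dose aspirin and immediate emergency
#' department referral), and Option D overtreatment (urgent catheterization
#' without troponin confirmation).
#'
#' @return A data frame with columns `code`, `label` and `category`.
#' @export
#' @examples
#' treatment_options()
treatment_options <- function() {
  data.frame(
    code = OPTION_LEVELS,
    label = c(
      "Daily 81 mg aspirin; return to clinic in one week",
      "Daily 81 mg aspirin; stress test within 2-3 days",
      "Full-dose aspirin; referral to emergency department",
      "Full-dose aspirin; urgent cardiac catheterization"
    ),
    category = c("UNSAFE_UNDERTREATMENT", "UNDERTREATMENT",
                 "GUIDELINE", "OVERTREATMENT"),
    stringsAsFactors = FALSE
  )
}

#' HEART score components
#'
#' Builds the five-component HEART breakdown (History, ECG, Age, Risk
#' factors, Troponin), each scored 0-2. The troponin component may be absent
#' (`NA`), as when a case is scored before laboratory results are available;
#' an absent troponin contributes 0 points.
#'
#' @param history,ecg,age,risk_factors integers in 0-2.
#' @param troponin integer in 0-2, or `NA` when no troponin level is
#'   available.
#' @return An object of class `heart_components`.
#' @export
#' @examples
#' heart_components(history = 1, ecg = 1, age = 2, risk_factors = 1)
heart_components <- function(history, ecg, age, risk_factors,
                             troponin = NA_integer_) {
  comp <- list(history = history, ecg = ecg, age = age,
               risk_factors = risk_factors, troponin = troponin)
  for (nm in names(comp)) {
    x <- comp[[nm]]
    if (length(x) != 1L)
      stop("HEART component '", nm, "' must be a single value", call. = FALSE)
    if (nm == "troponin" && is.na(x)) next
    if (is.na(x) || !is.numeric(x) || x != as.integer(x) || x < 0 || x > 2)
      stop("HEART component '", nm, "' must be an integer in 0-2, got ",
           format(x), call. = FALSE)
    comp[[nm]] <- as.integer(x)
  }
  structure(comp, class = "heart_components")
}

#' Total HEART score
#'
#' Sums the present components; an absent troponin contributes 0, so the
#' attainable range is 0-8 without a troponin level and 0-10 with one.
#'
#' @param components a [heart_components()] object.
#' @return Integer total score.
#' @export
#' @examples
#' heart_score(heart_components(1, 1, 2, 1))  # 5, the standardized case
heart_score <- function(components) {
  if (!inherits(components, "heart_components"))
    stop("`components` must be built with heart_components()", call. = FALSE)
  vals <- unlist(components)
  sum(vals, na.rm = TRUE)
}

#' @export
print.heart_components <- function(x, ...) {
  vals <- unlist(x)
  cat("HEART components:",
      paste(names(x), ifelse(is.na(vals), "absent", vals), sep = "=",
            collapse = ", "),
      sprintf("(total %d)\n", heart_score(x)))
  invisible(x)
}

#' Risk band lookup table for HEART scores
#'
#' The intermediate band (scores 4-6) maps to a 16% 30-day risk of a major
#' adverse cardiac event; this band is canonical and cannot be overridden.
#' Risks for the low (0-3) and high (7-10) bands are configurable and default
#' to `NA` ("unspecified") so that no invented clinical number is presented
#' as ground truth.
#'
#' @param low_risk risk percent for scores 0-3, or `NA` (default).
#' @param high_risk risk percent for scores 7-10, or `NA` (default).
#' @return A data frame with columns `score_min`, `score_max`, `risk`.
#' @export
heart_risk_bands <- function(low_risk = NA_real_, high_risk = NA_real_) {
  for (x in list(low_risk, high_risk))
    if (!is.na(x) && (!is.numeric(x) || x < 0 || x > 100))
      stop("band risks must be percentages in [0, 100] or NA", call. = FALSE)
  data.frame(
    score_min = c(0L, 4L, 7L),
    score_max = c(3L, 6L, 10L),
    risk = c(as.numeric(low_risk), 16, as.numeric(high_risk))
  )
}

#' 30-day adverse-event risk for a HEART score
#'
#' @param score integer HEART score in 0-10.
#' @param bands a band table from [heart_risk_bands()]. Whatever the table
#'   contains, scores 4-6 always return 16.
#' @return Risk percent in `[0, 100]`, or `NA` for an unconfigured band.
#' @export
#' @examples
#' risk_for_score(5)   # 16
#' risk_for_score(2)   # NA: low band unspecified by default
risk_for_score <- function(score, bands = heart_risk_bands()) {
  if (length(score) != 1L || is.na(score) || !is.numeric(score) ||
      score != as.integer(score))
    stop("`score` must be a single integer", call. = FALSE)
  if (score < 0 || score > 10)
    stop("HEART score must be in 0-10, got ", score, call. = FALSE)
  if (score >= 4 && score <= 6) return(16.0)  # canonical, immutable band
  hit <- bands$score_min <= score & score <= bands$score_max
  if (!any(hit)) return(NA_real_)
  bands$risk[which(hit)[1L]]
}

#' Correctness rule for treatment recommendations
#'
#' The default rule accepts only Option C (the guideline-recommended
#' treatment); the sensitivity variant accepts Options B and C.
#'
#' @param accepted nonempty character subset of `c("A","B","C","D")`.
#' @return An object of class `correctness_rule`.
#' @export
#' @examples
#' correctness_rule()            # {C}
#' correctness_rule(c("B","C"))  # sensitivity variant
correctness_rule <- function(accepted = "C") {
  accepted <- unique(as.character(accepted))
  if (length(accepted) == 0L || !all(accepted %in% OPTION_LEVELS))
    stop("`accepted` must be a nonempty subset of {A,B,C,D}", call. = FALSE)
  structure(list(accepted = sort(accepted)), class = "correctness_rule")
}

#' @export
print.correctness_rule <- function(x, ...) {
  cat("Correctness rule: accepted options {",
      paste(x$accepted, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Is a recommendation correct under a rule?
#'
#' @param option character vector of option codes.
#' @param rule a [correctness_rule()].
#' @return Logical vector.
#' @export
is_correct <- function(option, rule = correctness_rule()) {
  if (!inherits(rule, "correctness_rule"))
    stop("`rule` must be a correctness_rule", call. = FALSE)
  option <- as.character(option)
  if (any(!option %in% OPTION_LEVELS))
    stop("unknown option code(s): ",
         paste(setdiff(option, OPTION_LEVELS), collapse = ", "),
         call. = FALSE)
  option %in% rule$accepted
}
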