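# Trial-level statistical framework: bootstrapped control groups, the
# trial-level observation table (7 trials x 4 condition-arm cells = 28 at
# the reference design), exact/approximate Wilcoxon tests, cluster-robust
# logistic regression, and the end-to-end analysis driver.

#' Bootstrap control clinicians into network-sized groups
#'
#' Control clinicians respond independently, so fewer are recruited per
#' trial (20 per arm vs 40 per network arm). For comparability with network
#' cells, each control condition-arm cell is resampled with replacement
#' into groups of `group_size` (default 40) and analysed at the group
#' level.
#'
#' @param records response records; only `condition == "control"` rows are
#'   used.
#' @param group_size clinicians per bootstrapped group (default 40).
#' @param n_groups groups per (trial, arm) cell (default 1).
#' @param seed integer seed; membership is deterministic given the seed.
#' @return A data frame with columns `group_id`, `trial_id`, `arm`,
#'   `clinician_id` (one row per draw, so clinicians may repeat).
#' @export
bootstrap_control_groups <- function(records, group_size = 40L,
                                     n_groups = 1L, seed = 1L) {
  ctl <- records[records$condition == "control", , drop = FALSE]
  if (nrow(ctl) == 0L)
    stop("no control records to bootstrap from", call. = FALSE)
  cells <- unique(ctl[c("trial_id", "arm")])
  cells <- cells[order(cells$trial_id, match(cells$arm, ARM_LEVELS)), ]
  with_seed(seed, {
    out <- lapply(seq_len(nrow(cells)), function(i) {
      tr <- cells$trial_id[i]; a <- cells$arm[i]
      pool <- unique(ctl$clinician_id[ctl$trial_id == tr & ctl$arm == a])
      do.call(rbind, lapply(seq_len(n_groups), function(g) {
        data.frame(
          group_id = sprintf("t%02d_%s_g%d", tr,
                             c(black_female = "bf", white_male = "wm")[[a]],
                             g),
          trial_id = tr, arm = a,
          clinician_id = pool[sample.int(length(pool), group_size,
                                         replace = TRUE)],
          stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, out)
  })
}

# Metrics for one multiset of clinicians within a cell: initial round and
# final round summaries. `ids` may contain repeats (bootstrap draws).
observe_members <- function(records, ids, rule, attrition) {
  r1 <- filter_records(records, 1L)
  rF <- filter_records(records, max(records$round))
  est1 <- stats::setNames(r1$estimate, r1$clinician_id)
  rec1 <- stats::setNames(r1$recommendation, r1$clinician_id)
  if (attrition == "locf") {
    lat <- latest_records(records)
    estF <- stats::setNames(lat$estimate, lat$clinician_id)
    recF <- stats::setNames(lat$recommendation, lat$clinician_id)
  } else {
    estF <- stats::setNames(rF$estimate, rF$clinician_id)
    recF <- stats::setNames(rF$recommendation, rF$clinician_id)
  }
  keep <- ids[ids %in% names(estF)]
  if (length(keep) == 0L)
    stop("no members with complete responses in cell", call. = FALSE)
  rates <- function(recs) {
    as.numeric(table(factor(recs, levels = OPTION_LEVELS))) / length(recs)
  }
  p1 <- rates(rec1[keep]); pF <- rates(recF[keep])
  data.frame(
    n = length(keep),
    acc_initial = mean(normalized_accuracy(est1[keep])),
    acc_final = mean(normalized_accuracy(estF[keep])),
    rate_A_initial = p1[1L], rate_B_initial = p1[2L],
    rate_C_initial = p1[3L], rate_D_initial = p1[4L],
    rate_A_final = pF[1L], rate_B_final = pF[2L],
    rate_C_final = pF[3L], rate_D_final = pF[4L],
    correct_initial = mean(is_correct(rec1[keep], rule)),
    correct_final = mean(is_correct(recF[keep], rule)),
    gap_initial_pp = (p1[1L] - p1[3L]) * 100,
    gap_final_pp = (pF[1L] - pF[3L]) * 100)
}

#' Build trial-level observations
#'
#' Aggregates records into one observation per (trial, condition, arm) --
#' the study's unit of inference (28 observations at the reference design).
#' Network cells use all their clinicians; control cells use the supplied
#' bootstrap groups (one observation per group). Attrition handling:
#' `"complete_case"` keeps only clinicians with a final-round response,
#' `"locf"` carries the last available response forward.
#'
#' @param records response-record data frame.
#' @param groups optional output of [bootstrap_control_groups()]; when
#'   `NULL`, control cells use their raw clinicians.
#' @param rule a [correctness_rule()].
#' @param attrition `"complete_case"` (default) or `"locf"`.
#' @return A data frame, one row per observation, with identifier columns
#'   `trial_id`, `condition`, `arm`, `group_id` and the metric columns of
#'   the observation.
#' @export
build_trial_observations <- function(records, groups = NULL,
                                     rule = correctness_rule(),
                                     attrition = c("complete_case", "locf")) {
  attrition <- match.arg(attrition)
  cells <- unique(records[c("trial_id", "condition", "arm")])
  cells <- cells[order(cells$trial_id,
                       match(cells$condition, CONDITION_LEVELS),
                       match(cells$arm, ARM_LEVELS)), ]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    tr <- cells$trial_id[i]; cond <- cells$condition[i]; a <- cells$arm[i]
    cell <- records[records$trial_id == tr & records$condition == cond &
                    records$arm == a, , drop = FALSE]
    if (cond == "control" && !is.null(groups)) {
      gsub <- groups[groups$trial_id == tr & groups$arm == a, , drop = FALSE]
      for (gid in unique(gsub$group_id)) {
        ids <- gsub$clinician_id[gsub$group_id == gid]
        obs <- observe_members(cell, ids, rule, attrition)
        rows[[length(rows) + 1L]] <-
          data.frame(trial_id = tr, condition = cond, arm = a,
                     group_id = gid, obs, stringsAsFactors = FALSE)
      }
    } else {
      ids <- unique(cell$clinician_id)
      obs <- observe_members(cell, ids, rule, attrition)
      rows[[length(rows) + 1L]] <-
        data.frame(trial_id = tr, condition = cond, arm = a,
                   group_id = NA_character_, obs, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- Wilcoxon tests -------------------------------------------------------

# Two-sided tail probability convention used throughout:
# p = min(1, 2 * min(P(T <= t), P(T >= t))).
two_sided_p <- function(cdf_le, cdf_ge) min(1, 2 * min(cdf_le, cdf_ge))

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares two sets of trial-level observations. When both samples have
#' fewer than 8 values the exact null distribution is obtained by
#' enumerating all assignments of the pooled (midrank-tied) ranks;
#' otherwise a tie-corrected normal approximation (without continuity
#' correction) is used. The two-sided p-value is twice the smaller tail,
#' capped at 1.
#'
#' @param a,b numeric vectors of observations.
#' @return List with `statistic` (Mann-Whitney U for sample `a`),
#'   `p.value`, and `exact` (logical).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p.value  # 0.1, the 3v3 minimum
rank_sum_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (n < 1L || m < 1L) stop("both samples must be nonempty", call. = FALSE)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(pooled)) == 1L) {
    warning("all values identical; p = 1")
    return(list(statistic = u, p.value = 1, exact = TRUE))
  }
  if (n < 8L && m < 8L) {
    combs <- utils::combn(n + m, n)
    offset <- n * (n + 1) / 2
    us <- colSums(matrix(rk[combs], nrow = n)) - offset
    p <- two_sided_p(mean(us <= u), mean(us >= u))
    return(list(statistic = u, p.value = p, exact = TRUE))
  }
  N <- n + m
  mu <- n * m / 2
  ties <- table(pooled)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z_le <- stats::pnorm(u, mu, sqrt(sigma2))
  p <- two_sided_p(z_le, 1 - z_le)
  list(statistic = u, p.value = p, exact = FALSE)
}

# Exact null distribution of the signed-rank statistic with (possibly tied,
# midrank) ranks: convolution over doubled ranks so everything is integer.
signed_rank_exact_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[s + 1] = #sign patterns with doubled sum s
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] +
      f[1L:(total + 1L - r)]
    f <- g
  }
  f <- f / sum(f)
  w2 <- as.integer(round(2 * w_plus))
  two_sided_p(sum(f[1L:(w2 + 1L)]), sum(f[(w2 + 1L):(total + 1L)]))
}

#' Wilcoxon signed-rank test
#'
#' Paired test on trial-level observations (e.g. initial vs final metric
#' per trial). Zero differences are dropped (Wilcoxon convention), ties get
#' midranks. The null distribution is exact (by convolution) for up to 25
#' nonzero differences, and a tie-corrected normal approximation beyond.
#'
#' @param x numeric vector: either paired differences (when `y` is `NULL`)
#'   or the first member of each pair.
#' @param y optional second member of each pair.
#' @return List with `statistic` (W+, the positive-rank sum), `p.value`,
#'   `n` (nonzero differences used), and `exact`.
#' @export
#' @examples
#' signed_rank_test(rep(1, 7))$p.value  # 2/128: all seven differences positive
signed_rank_test <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n = 0L, exact = TRUE))
  }
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  n <- length(d)
  if (n <= 25L) {
    p <- signed_rank_exact_p(rk, w_plus)
    return(list(statistic = w_plus, p.value = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z_le <- stats::pnorm(w_plus, mu, sqrt(sigma2))
  p <- two_sided_p(z_le, 1 - z_le)
  list(statistic = w_plus, p.value = p, n = n, exact = FALSE)
}

# ---- cluster-robust logistic regression -----------------------------------

# Ridge-penalized logistic IRLS, used as the separation fallback.
penalized_logit <- function(X, yv, lambda = 1e-2, maxit = 100L) {
  beta <- rep(0, ncol(X))
  P <- diag(lambda, ncol(X)); P[1L, 1L] <- 0  # do not shrink the intercept
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    score <- crossprod(X, yv - mu) - P %*% beta
    info <- crossprod(X * W, X) + P
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  list(beta = beta, info = info)
}

#' Logistic regression with trial-clustered standard errors
#'
#' Fits a binomial GLM and reports a CR1 cluster-robust sandwich
#' covariance, emitting odds ratios with 95% confidence intervals. Complete
#' or quasi-complete separation is detected (degenerate fitted
#' probabilities or runaway coefficients) and flagged; with
#' `on_separation = "penalize"` a weakly ridge-penalized fit is used
#' instead.
#'
#' @param formula model formula with a binary (logical or 0/1) response.
#' @param data data frame.
#' @param cluster name of the cluster column in `data` (default
#'   `"trial_id"`).
#' @param on_separation `"flag"` (default) or `"penalize"`.
#' @return A data frame of class `clinnet_logit`, one row per coefficient:
#'   `estimate`, `se_cluster`, `z`, `p`, `or`, `or_lo`, `or_hi`; attribute
#'   `separation` records whether separation was detected.
#' @export
clustered_logit <- function(formula, data, cluster = "trial_id",
                            on_separation = c("flag", "penalize")) {
  on_separation <- match.arg(on_separation)
  if (!cluster %in% names(data))
    stop("cluster column '", cluster, "' not found", call. = FALSE)
  if (anyNA(data[all.vars(formula)]))
    stop("model variables must not contain NA", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(formula, data = data, family = stats::binomial()))
  mu <- stats::fitted(fit)
  sep <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(stats::coef(fit)) > 15) ||
    !fit$converged
  cl <- data[[cluster]]
  if (sep && on_separation == "penalize") {
    mf <- stats::model.frame(formula, data)
    X <- stats::model.matrix(formula, mf)
    yv <- as.numeric(stats::model.response(mf))
    pen <- penalized_logit(X, yv)
    beta <- pen$beta
    mu <- stats::plogis(drop(X %*% beta))
    W <- mu * (1 - mu)
    bread <- solve(pen$info)
    scores <- X * (yv - mu)
    g <- factor(cl)
    meat <- crossprod(rowsum(scores, g))
    G <- nlevels(g); n <- nrow(X); k <- ncol(X)
    vc <- G / (G - 1) * (n - 1) / (n - k) * bread %*% meat %*% bread
    est <- beta
    names(est) <- colnames(X)
  } else {
    if (sep)
      warning("possible separation detected; coefficients may be unstable")
    vc <- cluster_vcov(fit, cl)
    est <- stats::coef(fit)
  }
  se <- sqrt(diag(vc))
  z <- est / se
  out <- data.frame(
    term = names(est), estimate = unname(est), se_cluster = unname(se),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
    or = unname(exp(est)),
    or_lo = unname(exp(est - 1.96 * se)),
    or_hi = unname(exp(est + 1.96 * se)),
    stringsAsFactors = FALSE)
  attr(out, "separation") <- sep
  class(out) <- c("clinnet_logit", "data.frame")
  out
}

#' Clustered choice models on response records
#'
#' Convenience wrapper around [clustered_logit()] for the recommendation
#' outcomes reported by the study: a binary outcome defined from the
#' records at one round (e.g. `~ recommendation == "C"`), optionally on a
#' restricted option set (e.g. only A and C responses for the
#' unsafe-vs-guideline contrast), regressed on record covariates with
#' trial-clustered errors.
#'
#' @param records response-record data frame.
#' @param outcome one-sided formula defining the binary outcome, evaluated
#'   in `records` (e.g. `~ recommendation == "C"`).
#' @param covariates one-sided formula of covariates (e.g. `~ arm`).
#' @param round round to analyse (default 1).
#' @param subset_options optional character vector restricting records to
#'   those recommendation codes.
#' @param ... passed to [clustered_logit()].
#' @return A `clinnet_logit` coefficient table.
#' @export
#' @examples
#' cfg <- generator_config(n_trials = 2, master_seed = 3)
#' rec <- simulate_study(cfg)
#' clustered_choice_model(rec, ~ recommendation == "C", ~ arm)
clustered_choice_model <- function(records, outcome, covariates = ~ arm,
                                   round = 1L, subset_options = NULL, ...) {
  sel <- filter_records(records, round)
  if (!is.null(subset_options))
    sel <- sel[sel$recommendation %in% subset_options, , drop = FALSE]
  if (nrow(sel) == 0L) stop("empty selection", call. = FALSE)
  sel$.y <- as.numeric(eval(outcome[[2L]], envir = sel))
  f <- stats::reformulate(attr(stats::terms(covariates), "term.labels"),
                          response = ".y")
  clustered_logit(f, sel, ...)
}

# ---- end-to-end analysis --------------------------------------------------

#' Analyse a study end to end
#'
#' Runs the full trial-level pipeline on a response-record table:
#' bootstraps control groups, builds the trial-level observation table,
#' computes the headline nonparametric contrasts (initial disparity in
#' guideline-care rates between arms; per-cell initial-to-final changes in
#' accuracy and guideline rates; initial and final inequity), the revision
#' coefficient among network clinicians, the improvement summary, and the
#' clustered odds-ratio contracts.
#'
#' @param records response-record data frame.
#' @param rule a [correctness_rule()].
#' @param group_size,n_groups,bootstrap_seed bootstrap settings for control
#'   groups.
#' @param attrition `"complete_case"` or `"locf"`.
#' @return A list of class `clinnet_analysis` with elements `observations`,
#'   `tests` (data frame of named contrasts with statistic, p, n),
#'   `revision`, `improvement_network`, `inequity`, `odds_ratios`, and
#'   `rule`.
#' @export
analyze_study <- function(records, rule = correctness_rule(),
                          group_size = 40L, n_groups = 1L,
                          bootstrap_seed = 1L,
                          attrition = c("complete_case", "locf")) {
  attrition <- match.arg(attrition)
  groups <- bootstrap_control_groups(records, group_size, n_groups,
                                     bootstrap_seed)
  obs <- build_trial_observations(records, groups, rule, attrition)

  tests <- list()
  add_test <- function(name, res, n) {
    tests[[length(tests) + 1L]] <<- data.frame(
      contrast = name, statistic = res$statistic, p = res$p.value, n = n,
      stringsAsFactors = FALSE)
  }
  wm <- obs[obs$arm == "white_male", ]
  bf <- obs[obs$arm == "black_female", ]
  add_test("initial_correct_rate_wm_vs_bf",
           rank_sum_test(wm$correct_initial, bf$correct_initial), nrow(obs))
  add_test("initial_gap_bf_vs_wm",
           rank_sum_test(bf$gap_initial_pp, wm$gap_initial_pp), nrow(obs))
  for (cond in CONDITION_LEVELS) {
    for (a in ARM_LEVELS) {
      cell <- obs[obs$condition == cond & obs$arm == a, ]
      add_test(paste0("accuracy_change_", cond, "_", a),
               signed_rank_test(cell$acc_final, cell$acc_initial),
               nrow(cell))
      add_test(paste0("correct_rate_change_", cond, "_", a),
               signed_rank_test(cell$correct_final, cell$correct_initial),
               nrow(cell))
    }
    sub <- obs[obs$condition == cond, ]
    add_test(paste0("final_correct_rate_wm_vs_bf_", cond),
             rank_sum_test(sub$correct_final[sub$arm == "white_male"],
                           sub$correct_final[sub$arm == "black_female"]),
             nrow(sub))
    add_test(paste0("final_gap_bf_vs_wm_", cond),
             rank_sum_test(sub$gap_final_pp[sub$arm == "black_female"],
                           sub$gap_final_pp[sub$arm == "white_male"]),
             nrow(sub))
  }
  tests <- do.call(rbind, tests)

  net <- records[records$condition == "network", ]
  net1 <- filter_records(net, 1L)
  netF <- filter_records(net, max(net$round))
  common <- intersect(net1$clinician_id, netF$clinician_id)
  e1 <- stats::setNames(net1$estimate, net1$clinician_id)[common]
  eF <- stats::setNames(netF$estimate, netF$clinician_id)[common]
  cl <- stats::setNames(net1$trial_id, net1$clinician_id)[common]
  revision <- tryCatch(revision_coefficient(e1, eF, cl),
                       error = function(e) NULL)

  ors <- list(
    initial_guideline_by_arm = clustered_choice_model(
      records, ~ recommendation == "C", ~ arm),
    initial_unsafe_vs_guideline_by_arm = tryCatch(
      clustered_choice_model(records, ~ recommendation == "A", ~ arm,
                             subset_options = c("A", "C")),
      error = function(e) NULL))

  structure(list(
    observations = obs,
    tests = tests,
    revision = revision,
    improvement_network = improvement(net, 1L, max(net$round), rule),
    inequity = list(
      initial = inequity(records, 1L),
      final_control = inequity(records, max(records$round),
                               condition = "control"),
      final_network = inequity(records, max(records$round),
                               condition = "network")),
    odds_ratios = ors,
    rule = rule,
    attrition = attrition), class = "clinnet_analysis")
}

#' @export
print.clinnet_analysis <- function(x, ...) {
  cat("Clinician network study analysis\n")
  cat(sprintf("  %d trial-level observations; correctness rule {%s}\n",
              nrow(x$observations), paste(x$rule$accepted, collapse = ",")))
  if (!is.null(x$revision))
    cat(sprintf("  Revision coefficient r = %.2f (SE %.2f, clustered)\n",
                x$revision$r, x$revision$se))
  cat(sprintf("  Initial inequity %+.1f pp; final: network %+.1f pp, control %+.1f pp\n",
              x$inequity$initial$inequity,
              x$inequity$final_network$inequity,
              x$inequity$final_control$inequity))
  cat("  Contrasts:\n")
  for (i in seq_len(nrow(x$tests)))
    cat(sprintf("    %-38s p = %.3f (n = %d)\n", x$tests$contrast[i],
                x$tests$p[i], x$tests$n[i]))
  invisible(x)
}

#' Re-run the analysis under an alternate correctness rule
#'
#' Executes the full pipeline under both the default rule (Option C only)
#' and an alternate rule (by default the sensitivity variant accepting
#' Options B and C) and returns both analyses for side-by-side comparison.
#'
#' @param records response-record data frame.
#' @param rule the alternate [correctness_rule()].
#' @param ... passed to [analyze_study()].
#' @return List with elements `default` and `sensitivity`, each a
#'   `clinnet_analysis`.
#' @export
sensitivity_reanalysis <- function(records,
                                   rule = correctness_rule(c("B", "C")),
                                   ...) {
  list(default = analyze_study(records, rule = correctness_rule(), ...),
       sensitivity = analyze_study(records, rule = rule, ...))
}
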