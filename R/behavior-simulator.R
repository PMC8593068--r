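# Agent-based generator of clinician responses for the three-round
# standardized-patient experiment. Round 1 draws independent estimates and
# recommendations per arm; rounds 2-3 apply DeGroot-style belief revision
# toward the neighbour mean in the network condition (with an
# error-dependent adoption weight, so less accurate clinicians revise more)
# and small-noise independent reflection with an acuity drift in the control
# condition.

#' Per-arm configuration of the response generator
#'
#' @param estimate_mean,estimate_sd parameters of the truncated-normal
#'   distribution (support `[0, 100]`) of initial probability estimates.
#'   `estimate_sd = 0` gives a point mass at `estimate_mean`.
#' @param choice_probs named probability vector over options A-D for the
#'   initial recommendation.
#' @return A list of class `arm_config`.
#' @export
arm_config <- function(estimate_mean, estimate_sd, choice_probs) {
  if (!is.numeric(estimate_mean) || length(estimate_mean) != 1L ||
      estimate_mean < 0 || estimate_mean > 100)
    stop("`estimate_mean` must be in [0, 100]", call. = FALSE)
  if (!is.numeric(estimate_sd) || length(estimate_sd) != 1L || estimate_sd < 0)
    stop("`estimate_sd` must be >= 0", call. = FALSE)
  choice_probs <- unlist(choice_probs)
  if (length(choice_probs) != 4L)
    stop("`choice_probs` must have 4 entries (A,B,C,D)", call. = FALSE)
  if (is.null(names(choice_probs))) names(choice_probs) <- OPTION_LEVELS
  if (!setequal(names(choice_probs), OPTION_LEVELS))
    stop("`choice_probs` must be named A,B,C,D", call. = FALSE)
  choice_probs <- choice_probs[OPTION_LEVELS]
  if (any(choice_probs < 0 | choice_probs > 1))
    stop("choice probabilities must be in [0, 1]", call. = FALSE)
  if (abs(sum(choice_probs) - 1) > 1e-9)
    stop("choice probabilities must sum to 1 (within 1e-9)", call. = FALSE)
  structure(list(estimate_mean = estimate_mean, estimate_sd = estimate_sd,
                 choice_probs = choice_probs),
            class = "arm_config")
}

# Reference initial option distributions: pooled initial rates for A and C
# are taken from the study design (Black female 29.9% A / 14.1% C; white
# male 23.4% A / 21.4% C); the remaining mass, whose split is not reported,
# is divided 2:1 between B (undertreatment) and D (overtreatment).
reference_choice_probs <- function(arm) {
  if (arm == "black_female") {
    rem <- 1 - 0.299 - 0.141
    c(A = 0.299, B = rem * 2 / 3, C = 0.141, D = rem / 3)
  } else {
    rem <- 1 - 0.234 - 0.214
    c(A = 0.234, B = rem * 2 / 3, C = 0.214, D = rem / 3)
  }
}

#' Full configuration of the synthetic-study generator
#'
#' Defaults encode the reference experimental design: 7 trials, each with
#' 40 clinicians per network arm and 20 per control arm (120 clinicians per
#' trial, randomized 2:1 network:control and then 1:1 between the two
#' patient-actor arms), a shared 4-regular communication network, three
#' response rounds, and full completion.
#'
#' @param n_trials number of independent trials (reference 7).
#' @param n_network clinicians per network condition-arm (reference 40).
#' @param n_control clinicians per control condition-arm (reference 20).
#' @param degree uniform degree of the communication network (reference 4).
#' @param arms named list (`black_female`, `white_male`) of [arm_config()]s.
#' @param choice_model list with `slope` (log-weight bonus for Option C per
#'   unit of normalized accuracy of the revised estimate), per-arm
#'   `intercepts`, and `switch_prob` (probability that a clinician
#'   reconsiders their recommendation in a revision round).
#' @param revision list with `alpha`, `beta`, `noise_sd`: the adoption
#'   weight on the neighbour mean is `clip(alpha + beta * |own - 16| / 84,
#'   0, 1)`, so `beta > 0` makes less accurate clinicians revise more.
#' @param control list with `drift_prob` (per-round probability of stepping
#'   one option toward higher acuity, A->B->C->D) and `noise_sd` for
#'   estimate jitter under independent reflection.
#' @param completion_prob probability that a clinician completes rounds 2-3
#'   (reference attrition setting 0.86; default 1).
#' @param master_seed integer; all randomness derives from it.
#' @param anchor,max_error the risk anchor (16) and maximal absolute error
#'   (84) used for accuracy-dependent behaviour.
#' @return A validated list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(master_seed = 42)
#' cfg$arms$black_female$choice_probs
generator_config <- function(
    n_trials = 7L,
    n_network = 40L,
    n_control = 20L,
    degree = 4L,
    arms = list(
      black_female = arm_config(30, 20, reference_choice_probs("black_female")),
      white_male   = arm_config(30, 20, reference_choice_probs("white_male"))
    ),
    choice_model = list(slope = 3,
                        intercepts = c(black_female = 0, white_male = 0),
                        switch_prob = 0.3),
    revision = list(alpha = 0.1, beta = 0.55, noise_sd = 3),
    control = list(drift_prob = 0.05, noise_sd = 3),
    completion_prob = 1.0,
    master_seed = 1L,
    anchor = RISK_ANCHOR,
    max_error = MAX_ABS_ERROR) {
  cfg <- list(n_trials = as.integer(n_trials),
              n_network = as.integer(n_network),
              n_control = as.integer(n_control),
              degree = as.integer(degree),
              arms = arms, choice_model = choice_model,
              revision = revision, control = control,
              completion_prob = completion_prob,
              master_seed = as.integer(master_seed),
              anchor = anchor, max_error = max_error)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_trials >= 1L, cfg$n_network >= 2L, cfg$n_control >= 1L)
  if (!setequal(names(cfg$arms), ARM_LEVELS))
    stop("`arms` must have entries black_female and white_male",
         call. = FALSE)
  for (a in ARM_LEVELS)
    if (!inherits(cfg$arms[[a]], "arm_config"))
      stop("arm '", a, "' must be built with arm_config()", call. = FALSE)
  cm <- cfg$choice_model
  if (!all(c("slope", "intercepts", "switch_prob") %in% names(cm)))
    stop("choice_model needs slope, intercepts, switch_prob", call. = FALSE)
  if (cm$switch_prob < 0 || cm$switch_prob > 1)
    stop("switch_prob must be in [0, 1]", call. = FALSE)
  if (!all(ARM_LEVELS %in% names(cm$intercepts)))
    stop("choice_model$intercepts must be named per arm", call. = FALSE)
  rv <- cfg$revision
  if (!all(c("alpha", "beta", "noise_sd") %in% names(rv)) || rv$noise_sd < 0)
    stop("revision needs alpha, beta and noise_sd >= 0", call. = FALSE)
  ct <- cfg$control
  if (!all(c("drift_prob", "noise_sd") %in% names(ct)) ||
      ct$drift_prob < 0 || ct$drift_prob > 1 || ct$noise_sd < 0)
    stop("control needs drift_prob in [0,1] and noise_sd >= 0", call. = FALSE)
  if (cfg$completion_prob < 0 || cfg$completion_prob > 1)
    stop("completion_prob must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

# Truncated-normal sampler on [lo, hi] by inverse-CDF; sd = 0 degenerates to
# a point mass at the (clipped) mean.
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(rep(clip(mean, lo, hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Multinomial recommendation draw for revision rounds: option weights are
# the arm's baseline probabilities, with Option C's weight scaled by
# exp(intercept + slope * accuracy) where accuracy = 1 - |estimate - 16|/84.
draw_choices <- function(p0, intercept, slope, acc) {
  n <- length(acc)
  w <- matrix(p0, nrow = n, ncol = 4L, byrow = TRUE)
  w[, 3L] <- w[, 3L] * exp(intercept + slope * acc)
  w <- w / rowSums(w)
  cw <- t(apply(w, 1L, cumsum))
  u <- stats::runif(n)
  idx <- rowSums(u > cw) + 1L
  OPTION_LEVELS[idx]
}

new_response_records <- function(trial_id, condition, arm, clinician_id,
                                 round, estimate, recommendation,
                                 network_position, completed) {
  data.frame(trial_id = as.integer(trial_id), condition = condition,
             arm = arm, clinician_id = clinician_id,
             round = as.integer(round), estimate = estimate,
             recommendation = recommendation,
             network_position = as.integer(network_position),
             completed = as.integer(completed), stringsAsFactors = FALSE)
}

#' Draw round-1 responses for one condition-arm cell
#'
#' Estimates are i.i.d. truncated normal on `[0, 100]`; recommendations are
#' i.i.d. from the arm's initial option distribution. In the network
#' condition each clinician is assigned a random node of the shared
#' topology.
#'
#' @param cfg a [generator_config()].
#' @param trial_id integer trial index.
#' @param condition `"network"` or `"control"`.
#' @param arm `"black_female"` or `"white_male"`.
#' @param seed integer seed for this cell.
#' @return A data frame of round-1 response records.
#' @export
draw_initial_responses <- function(cfg, trial_id, condition, arm, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  condition <- match.arg(condition, CONDITION_LEVELS)
  arm <- match.arg(arm, ARM_LEVELS)
  acfg <- cfg$arms[[arm]]
  n <- if (condition == "network") cfg$n_network else cfg$n_control
  with_seed(seed, {
    est <- rtrunc_norm(n, acfg$estimate_mean, acfg$estimate_sd)
    rec <- OPTION_LEVELS[sample.int(4L, n, replace = TRUE,
                                    prob = acfg$choice_probs)]
    pos <- if (condition == "network") sample.int(n) else rep(NA_integer_, n)
    ids <- sprintf("t%02d_%s_%s_%02d", trial_id,
                   c(network = "net", control = "ctl")[[condition]],
                   c(black_female = "bf", white_male = "wm")[[arm]],
                   seq_len(n))
    new_response_records(trial_id, condition, arm, ids, 1L, est, rec, pos, 1L)
  })
}

# Latest available record per clinician (last-observation-carried-forward).
latest_records <- function(prior_records) {
  prior <- prior_records[order(prior_records$round), , drop = FALSE]
  prior[!duplicated(prior$clinician_id, fromLast = TRUE), , drop = FALSE]
}

#' Network-condition revision round
#'
#' Each active (non-attrited) clinician sees the mean estimate of their
#' non-attrited neighbours (most recent available responses) and moves
#' toward it with adoption weight `w = clip(alpha + beta * |own - 16| / 84,
#' 0, 1)`: accurate clinicians revise little, inaccurate clinicians revise a
#' lot, which is the mechanism behind a positive revision coefficient. The
#' revised recommendation is redrawn (with probability `switch_prob`) from a
#' choice model whose Option C weight grows with the accuracy of the revised
#' estimate. A clinician with no available neighbour keeps their own
#' estimate.
#'
#' @param cfg a [generator_config()].
#' @param topology the shared `egal_topology`.
#' @param prior_records all records of earlier rounds for one network
#'   condition-arm cell.
#' @param seed integer seed for this round.
#' @return Data frame of next-round records for active clinicians.
#' @export
revise_network <- function(cfg, topology, prior_records, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!inherits(topology, "egal_topology"))
    stop("network revision requires a topology", call. = FALSE)
  if (any(prior_records$condition != "network"))
    stop("prior_records must come from a network condition", call. = FALSE)
  latest <- latest_records(prior_records)
  active <- latest[latest$completed == 1L, , drop = FALSE]
  next_round <- max(prior_records$round) + 1L

  est_by_node <- rep(NA_real_, topology$n)
  est_by_node[active$network_position] <- active$estimate

  arm <- active$arm[1L]
  rv <- cfg$revision
  cm <- cfg$choice_model
  with_seed(seed, {
    own <- active$estimate
    nm <- vapply(active$network_position, function(p) {
      vals <- est_by_node[topology$adj[[p]]]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) NA_real_ else mean(vals)
    }, numeric(1))
    w <- clip(rv$alpha + rv$beta * abs(own - cfg$anchor) / cfg$max_error, 0, 1)
    w[is.na(nm)] <- 0
    nm[is.na(nm)] <- own[is.na(nm)]
    noise <- if (rv$noise_sd > 0) stats::rnorm(nrow(active), 0, rv$noise_sd)
             else 0
    est <- clip((1 - w) * own + w * nm + noise, 0, 100)
    acc <- 1 - abs(est - cfg$anchor) / cfg$max_error
    rec <- active$recommendation
    reconsider <- stats::runif(nrow(active)) < cm$switch_prob
    if (any(reconsider)) {
      rec[reconsider] <- draw_choices(
        cfg$arms[[arm]]$choice_probs, cm$intercepts[[arm]], cm$slope,
        acc[reconsider])
    }
    new_response_records(active$trial_id, active$condition, active$arm,
                         active$clinician_id, next_round, est, rec,
                         active$network_position, 1L)
  })
}

#' Control-condition revision round
#'
#' Independent reflection: each active clinician's estimate is jittered by
#' zero-mean noise (clipped to `[0, 100]`), and with probability
#' `drift_prob` their recommendation steps one option toward higher acuity
#' (A to B, B to C, C to D; D stays D) -- the systematic acuity drift seen
#' under repeated individual reflection.
#'
#' @inheritParams revise_network
#' @param prior_records earlier rounds for one control condition-arm cell.
#' @return Data frame of next-round records for active clinicians.
#' @export
revise_control <- function(cfg, prior_records, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  latest <- latest_records(prior_records)
  active <- latest[latest$completed == 1L, , drop = FALSE]
  next_round <- max(prior_records$round) + 1L
  ct <- cfg$control
  step_up <- c(A = "B", B = "C", C = "D", D = "D")
  with_seed(seed, {
    noise <- if (ct$noise_sd > 0) stats::rnorm(nrow(active), 0, ct$noise_sd)
             else 0
    est <- clip(active$estimate + noise, 0, 100)
    rec <- active$recommendation
    drift <- stats::runif(nrow(active)) < ct$drift_prob
    rec[drift] <- step_up[rec[drift]]
    new_response_records(active$trial_id, active$condition, active$arm,
                         active$clinician_id, next_round, est, rec,
                         active$network_position, 1L)
  })
}

#' Simulate a complete multi-trial study
#'
#' Generates one shared communication topology from the master seed (the
#' same topology is used across all trials), then for each trial and each of
#' the four condition-arm cells draws round-1 responses, applies attrition
#' (each clinician independently completes rounds 2-3 with probability
#' `completion_prob`; attrited clinicians keep only their round-1 record,
#' flagged `completed = 0`), and runs two revision rounds. With the
#' reference configuration this yields `7 * 120 = 840` distinct clinicians.
#'
#' @param cfg a [generator_config()].
#' @return A data frame of response records (one row per clinician-round),
#'   ordered by trial, condition, arm, round, clinician. Identical `cfg`
#'   yields an identical table.
#' @export
#' @examples
#' cfg <- generator_config(n_trials = 1, master_seed = 7)
#' rec <- simulate_study(cfg)
#' length(unique(rec$clinician_id))  # 120
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  topology <- make_egalitarian_network(cfg$n_network, cfg$degree,
                                       derive_seed(cfg$master_seed, 7919L))
  out <- vector("list", cfg$n_trials * 4L)
  i <- 0L
  for (trial in seq_len(cfg$n_trials)) {
    for (ci in seq_along(CONDITION_LEVELS)) {
      condition <- CONDITION_LEVELS[ci]
      for (ai in seq_along(ARM_LEVELS)) {
        arm <- ARM_LEVELS[ai]
        recs <- draw_initial_responses(
          cfg, trial, condition, arm,
          derive_seed(cfg$master_seed, trial, ci, ai, 1L))
        if (cfg$completion_prob < 1) {
          done <- with_seed(derive_seed(cfg$master_seed, trial, ci, ai, 99L),
                            stats::runif(nrow(recs)) < cfg$completion_prob)
          recs$completed <- as.integer(done)
        }
        for (round in 2:3) {
          seed_r <- derive_seed(cfg$master_seed, trial, ci, ai, round)
          nxt <- if (condition == "network")
            revise_network(cfg, topology, recs, seed_r)
          else revise_control(cfg, recs, seed_r)
          recs <- rbind(recs, nxt)
        }
        i <- i + 1L
        out[[i]] <- recs
      }
    }
  }
  all <- do.call(rbind, out)
  all <- all[order(all$trial_id,
                   match(all$condition, CONDITION_LEVELS),
                   match(all$arm, ARM_LEVELS),
                   all$round, all$clinician_id), , drop = FALSE]
  rownames(all) <- NULL
  attr(all, "topology") <- topology
  all
}

#' Calibrate the Option C intercept of the revision choice model
#'
#' Solves, by bisection, for the per-arm intercept that makes the expected
#' post-revision Option C probability (averaged over a sample of accuracy
#' values) equal a target marginal rate.
#'
#' @param p0 baseline option probabilities (named A-D).
#' @param slope accuracy slope of the choice model.
#' @param acc numeric vector of normalized accuracies at which the model is
#'   evaluated (e.g. the accuracies of revised estimates).
#' @param target desired mean Option C probability, strictly in (0, 1).
#' @return The intercept (a single numeric).
#' @export
calibrate_choice_intercept <- function(p0, slope, acc, target) {
  stopifnot(target > 0, target < 1, p0[["C"]] > 0)
  p_c <- function(eta) {
    wc <- p0[["C"]] * exp(eta + slope * acc)
    mean(wc / (wc + sum(p0[c("A", "B", "D")])))
  }
  lo <- -20; hi <- 20
  if (p_c(lo) > target || p_c(hi) < target)
    stop("target rate not attainable within intercept bounds", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (p_c(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
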