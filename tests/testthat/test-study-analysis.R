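# Enumeration oracles live in helper-oracles.R.

test_that("rank-sum test matches its exact enumeration oracle (n <= 6)", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p.value, 0.1)
  expect_warning(res <- rank_sum_test(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(res$p.value, 1)
  set.seed(61)
  for (i in 1:40) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    # integer draws force ties often
    a <- sample(1:6, n, replace = TRUE)
    b <- sample(1:6, m, replace = TRUE)
    if (length(unique(c(a, b))) == 1L) next
    expect_equal(rank_sum_test(a, b)$p.value, oracle_rank_sum_p(a, b),
                 info = paste("a =", paste(a, collapse = ","),
                              "b =", paste(b, collapse = ",")))
  }
})

test_that("rank-sum agrees with stats::wilcox.test on tie-free data", {
  set.seed(62)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(6, 0.5)
    expect_equal(rank_sum_test(a, b)$p.value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # large-sample branch tracks the normal approximation closely
  a <- rnorm(20); b <- rnorm(25, 0.4)
  got <- rank_sum_test(a, b)
  expect_false(got$exact)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(got$p.value, ref, tolerance = 1e-10)
})

test_that("signed-rank test matches sign-enumeration oracle (n <= 10)", {
  # all seven differences positive: the smallest attainable two-sided p
  res <- signed_rank_test(rep(1, 7))
  expect_equal(res$p.value, 2 / 128)
  expect_equal(res$statistic, 28)
  expect_warning(res0 <- signed_rank_test(rep(0, 5)), "zero")
  expect_equal(res0$p.value, 1)
  set.seed(63)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- sample(-4:4, n, replace = TRUE)
    if (all(d == 0)) next
    expect_equal(signed_rank_test(d)$p.value, oracle_signed_rank_p(d),
                 info = paste("d =", paste(d, collapse = ",")))
  }
  # paired interface
  x <- c(3, 5, 9); y <- c(1, 2, 3)
  expect_equal(signed_rank_test(x, y)$p.value,
               oracle_signed_rank_p(x - y))
})

test_that("bootstrap groups are deterministic, sized, and cell-sourced", {
  rec <- simulate_study(small_cfg(master_seed = 14))
  g1 <- bootstrap_control_groups(rec, group_size = 40, seed = 3)
  g2 <- bootstrap_control_groups(rec, group_size = 40, seed = 3)
  expect_identical(g1, g2)
  g3 <- bootstrap_control_groups(rec, group_size = 40, seed = 4)
  expect_false(identical(g1, g3))
  # 2 trials x 2 arms, one group of 40 each
  expect_equal(nrow(g1), 2 * 2 * 40)
  for (i in seq_len(nrow(g1))) {
    src <- rec[rec$clinician_id == g1$clinician_id[i], ][1, ]
    expect_equal(src$condition, "control")
    expect_equal(src$trial_id, g1$trial_id[i])
    expect_equal(src$arm, g1$arm[i])
  }
  expect_error(bootstrap_control_groups(rec[rec$condition == "network", ]),
               "no control records")
})

test_that("a degenerate one-clinician pool yields 40 copies, and group means
           concentrate on the pool mean", {
  rec <- simulate_study(small_cfg(master_seed = 15))
  ctl_bf1 <- rec[rec$condition == "control" & rec$arm == "black_female" &
                 rec$trial_id == 1 & rec$round == 1, ]
  solo <- rec[rec$clinician_id == ctl_bf1$clinician_id[1], ]
  g <- bootstrap_control_groups(solo, group_size = 40, seed = 1)
  expect_equal(nrow(g), 40)
  expect_equal(unique(g$clinician_id), solo$clinician_id[1])

  # bootstrap consistency: mean of many group means ~ pool mean
  pool <- ctl_bf1$estimate
  groups <- bootstrap_control_groups(
    rec[rec$trial_id == 1 & rec$arm == "black_female", ],
    group_size = 40, n_groups = 200, seed = 5)
  ests <- setNames(ctl_bf1$estimate, ctl_bf1$clinician_id)
  gm <- tapply(ests[groups$clinician_id], groups$group_id, mean)
  # se of the mean of 200 group means ~ sd(pool)/sqrt(40*200); 1 is >5 se
  expect_lt(abs(mean(gm) - mean(pool)), 1)
})

test_that("trial observations have the design's count and oracle means", {
  cfg <- generator_config(master_seed = 16)
  rec <- simulate_study(cfg)
  groups <- bootstrap_control_groups(rec, seed = 2)
  obs <- build_trial_observations(rec, groups)
  expect_equal(nrow(obs), 28)  # 7 trials x 4 condition-arm cells
  one <- build_trial_observations(simulate_study(small_cfg(master_seed = 1)))
  expect_equal(nrow(one), 8)  # 2 trials x 4 cells

  # accuracy mean equals a brute-force recomputation for a network cell
  cell <- rec[rec$condition == "network" & rec$arm == "white_male" &
              rec$trial_id == 3, ]
  row <- obs[obs$condition == "network" & obs$arm == "white_male" &
             obs$trial_id == 3, ]
  expect_equal(row$acc_initial,
               mean(1 - abs(cell$estimate[cell$round == 1] - 16) / 84))
  expect_equal(row$acc_final,
               mean(1 - abs(cell$estimate[cell$round == 3] - 16) / 84))
  # and for a bootstrapped control cell, honouring multiplicity
  gsel <- groups[groups$trial_id == 2 & groups$arm == "black_female", ]
  ctl <- rec[rec$condition == "control" & rec$trial_id == 2 &
             rec$arm == "black_female" & rec$round == 1, ]
  est <- setNames(ctl$estimate, ctl$clinician_id)
  row2 <- obs[obs$condition == "control" & obs$arm == "black_female" &
              obs$trial_id == 2, ]
  expect_equal(row2$acc_initial,
               mean(1 - abs(est[gsel$clinician_id] - 16) / 84))
})

test_that("attrition handling: complete-case drops, locf carries forward", {
  cfg <- small_cfg(completion_prob = 0.7, master_seed = 44)
  rec <- simulate_study(cfg)
  cc <- build_trial_observations(rec, attrition = "complete_case")
  lo <- build_trial_observations(rec, attrition = "locf")
  n_complete <- sum(tapply(rec$round, rec$clinician_id, max) == 3)
  expect_equal(sum(cc$n), n_complete)
  expect_equal(sum(lo$n), length(unique(rec$clinician_id)))
})

test_that("clustered logistic regression recovers a known log-odds slope", {
  set.seed(91)
  n <- 840
  g <- rep(1:7, each = 120)
  x <- rnorm(n)
  beta <- 0.8
  y <- rbinom(n, 1, plogis(-0.5 + beta * x))
  d <- data.frame(.y = y, x = x, trial_id = g)
  fit <- clustered_logit(.y ~ x, d)
  expect_equal(fit$estimate[fit$term == "x"], beta, tolerance = 0.25)
  lo <- fit$or_lo[fit$term == "x"]; hi <- fit$or_hi[fit$term == "x"]
  expect_true(exp(beta) >= lo && exp(beta) <= hi)

  # a covariate independent of the outcome recovers OR ~ 1 within its CI
  d$z <- rnorm(n)
  fit0 <- clustered_logit(.y ~ z, d)
  expect_true(fit0$or_lo[fit0$term == "z"] <= 1 &&
              fit0$or_hi[fit0$term == "z"] >= 1)
})

test_that("clustered SE exceeds classical SE under intra-cluster correlation", {
  set.seed(92)
  n <- 700
  g <- rep(1:7, each = 100)
  re <- rnorm(7, 0, 1.5)[g]
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 * x + re))
  d <- data.frame(.y = y, x = 1 * (x > 0), trial_id = g)
  fit <- clustered_logit(.y ~ x, d)
  classical <- sqrt(diag(vcov(glm(.y ~ x, binomial, d))))
  expect_gt(fit$se_cluster[fit$term == "(Intercept)"],
            classical["(Intercept)"])
})

test_that("separation is flagged and the penalized fallback tames it", {
  d <- data.frame(.y = c(rep(0, 10), rep(1, 10)),
                  x = c(rep(0, 10), rep(1, 10)),
                  trial_id = rep(1:5, 4))
  expect_warning(fit <- clustered_logit(.y ~ x, d), "separation")
  expect_true(attr(fit, "separation"))
  fit2 <- clustered_logit(.y ~ x, d, on_separation = "penalize")
  expect_true(attr(fit2, "separation"))
  expect_lt(abs(fit2$estimate[fit2$term == "x"]), 15)
})

test_that("clustered_choice_model restricts samples and finds built-in bias", {
  # arms generated with very different guideline rates: the white-male OR
  # for recommending C must exceed 1 and be detected
  cfg <- generator_config(
    n_trials = 7, master_seed = 18,
    arms = list(
      black_female = arm_config(30, 20, c(A = .35, B = .35, C = .10, D = .20)),
      white_male   = arm_config(30, 20, c(A = .20, B = .30, C = .30, D = .20))))
  rec <- simulate_study(cfg)
  fit <- clustered_choice_model(rec, ~ recommendation == "C", ~ arm)
  or_wm <- fit$or[fit$term == "armwhite_male"]
  true_or <- (.30 / .70) / (.10 / .90)
  expect_gt(or_wm, 1)
  expect_true(fit$or_lo[fit$term == "armwhite_male"] <= true_or &&
              fit$or_hi[fit$term == "armwhite_male"] >= true_or)
  restricted <- clustered_choice_model(rec, ~ recommendation == "A", ~ arm,
                                       subset_options = c("A", "C"))
  expect_equal(nrow(restricted), 2)
})

test_that("sensitivity reanalysis obeys rule monotonicity", {
  rec <- simulate_study(small_cfg(master_seed = 19))
  out <- sensitivity_reanalysis(rec, bootstrap_seed = 7)
  # {C} run is identical to the default analysis
  base <- analyze_study(rec, bootstrap_seed = 7)
  expect_equal(out$default$observations, base$observations)
  # {B,C} correct rates dominate {C} correct rates everywhere
  expect_true(all(out$sensitivity$observations$correct_initial >=
                  out$default$observations$correct_initial))
  expect_true(all(out$sensitivity$observations$correct_final >=
                  out$default$observations$correct_final))
  # degenerate all-B data: 0 under {C}, 1 under {B,C}
  allB <- mk_records(estimate = rep(50, 6), recommendation = rep("B", 6))
  expect_equal(mean(is_correct(allB$recommendation, correctness_rule())), 0)
  expect_equal(mean(is_correct(allB$recommendation,
                               correctness_rule(c("B", "C")))), 1)
})

test_that("analyze_study is deterministic end to end under a fixed seed", {
  rec <- simulate_study(small_cfg(master_seed = 20))
  a1 <- analyze_study(rec, bootstrap_seed = 20)
  a2 <- analyze_study(rec, bootstrap_seed = 20)
  expect_equal(a1$observations, a2$observations)
  expect_equal(a1$tests, a2$tests)
  expect_equal(a1$revision$r, a2$revision$r)
})
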