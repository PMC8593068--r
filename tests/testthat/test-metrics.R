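test_that("normalized accuracy matches the min-max formula", {
  expect_equal(normalized_accuracy(16), 1.0)
  expect_equal(normalized_accuracy(100), 0.0)
  expect_equal(normalized_accuracy(0), 1 - 16 / 84)
  expect_error(normalized_accuracy(150), "\\[0, 100\\]")
  expect_error(normalized_accuracy(-1), "\\[0, 100\\]")
})

test_that("normalized accuracy is affine in |error|, bounded, peaked at 16", {
  est <- seq(0, 100, by = 0.5)
  acc <- normalized_accuracy(est)
  expect_true(all(acc >= 0 & acc <= 1))
  expect_equal(acc, 1 - abs(est - 16) / 84)
  expect_equal(est[which.max(acc)], 16)
  expect_equal(sum(acc == 1), 1L)
})

test_that("option rates sum to one and honour trial-then-grand averaging", {
  rec <- mk_records(estimate = rep(50, 4),
                    recommendation = c("A", "A", "C", "C"))
  expect_equal(option_rates(rec, 1),
               c(A = .5, B = 0, C = .5, D = 0))
  allC <- mk_records(estimate = rep(50, 3), recommendation = rep("C", 3))
  expect_equal(option_rates(allC, 1), c(A = 0, B = 0, C = 1, D = 0))

  # two trials with A-rates 0.2 (n=5) and 0.4 (n=20): the trial-then-grand
  # mean is 0.3, whereas pooling the 25 records gives 0.36
  t1 <- mk_records(trial = 1, estimate = rep(50, 5),
                   recommendation = c("A", rep("B", 4)))
  t2 <- mk_records(trial = 2, estimate = rep(50, 20),
                   recommendation = c(rep("A", 8), rep("B", 12)))
  both <- rbind(t1, t2)
  expect_equal(option_rates(both, 1)[["A"]], 0.3)
  expect_equal(option_rates(both, 1, aggregate = "pooled")[["A"]], 0.36)
})

test_that("option rates are order-invariant and reject empty selections", {
  set.seed(8)
  rec <- mk_records(trial = rep(1:3, each = 10), estimate = rep(50, 30),
                    recommendation = sample(c("A", "B", "C", "D"), 30,
                                            replace = TRUE))
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(option_rates(rec, 1), option_rates(shuffled, 1))
  expect_equal(sum(option_rates(rec, 1)), 1)
  expect_error(option_rates(rec, 3), "no records")
})

test_that("inequity reproduces the percentage-point arithmetic", {
  # one arm at printed pooled rates 29.9% A / 14.1% C -> 15.8 pp gap;
  # the other at 23.4% / 21.4% -> 2.0 pp; inequity 13.8 pp
  bf <- mk_records(arm = "black_female", estimate = rep(50, 1000),
                   recommendation = c(rep("A", 299), rep("C", 141),
                                      rep("B", 560)))
  wm <- mk_records(arm = "white_male", estimate = rep(50, 1000),
                   recommendation = c(rep("A", 234), rep("C", 214),
                                      rep("B", 552)))
  iq <- inequity(rbind(bf, wm), 1)
  expect_equal(iq$gap[["black_female"]], 15.8)
  expect_equal(iq$gap[["white_male"]], 2.0)
  expect_equal(iq$inequity, 13.8)
})

test_that("inequity is antisymmetric under arm exchange and zero at parity", {
  set.seed(12)
  recs <- sample(c("A", "B", "C", "D"), 40, replace = TRUE)
  bf <- mk_records(arm = "black_female", estimate = rep(50, 40),
                   recommendation = recs)
  wm <- mk_records(arm = "white_male", estimate = rep(50, 40),
                   recommendation = rev(recs))
  expect_equal(inequity(rbind(bf, wm), 1)$inequity, 0)

  wm2 <- mk_records(arm = "white_male", estimate = rep(50, 40),
                    recommendation = sample(c("A", "C"), 40, replace = TRUE))
  iq <- inequity(rbind(bf, wm2), 1)
  swapped <- rbind(transform(bf, arm = "white_male"),
                   transform(wm2, arm = "black_female"))
  expect_equal(inequity(swapped, 1)$inequity, -iq$inequity)
  expect_error(inequity(bf, 1), "white_male")
})

test_that("undertreatment odds are the A/C count ratio", {
  rec <- mk_records(estimate = rep(50, 20),
                    recommendation = c(rep("A", 10), rep("C", 10)))
  expect_equal(undertreatment_odds(rec, 1), 1.0)
  rec2 <- mk_records(estimate = rep(50, 45),
                     recommendation = c(rep("A", 30), rep("C", 15)))
  expect_equal(undertreatment_odds(rec2, 1), 2.0)
  set.seed(4)
  for (i in 1:20) {
    recs <- sample(c("A", "B", "C", "D"), 60, replace = TRUE)
    rec3 <- mk_records(estimate = rep(50, 60), recommendation = recs)
    expect_equal(undertreatment_odds(rec3, 1),
                 sum(recs == "A") / sum(recs == "C"))
  }
  noC <- mk_records(estimate = rep(50, 5), recommendation = rep("A", 5))
  expect_error(undertreatment_odds(noC, 1), "undefined")
  expect_equal(undertreatment_odds(noC, 1, correction = TRUE), 5.5 / 0.5)
})

test_that("revision coefficient equals textbook Pearson", {
  # perfect proportionality
  out <- revision_coefficient(initial = c(16, 26, 36), final = c(16, 21, 26),
                              clusters = rep(1, 3))
  expect_equal(out$r, 1)
  # brute-force sum-formula oracle on a random 20-pair sample
  set.seed(21)
  init <- runif(20, 16, 100)
  fin <- init - 0.4 * (init - 16) + rnorm(20, 0, 3)
  x <- abs(init - 16); y <- abs(fin - init)
  n <- 20
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  est <- revision_coefficient(init, fin, clusters = rep(1:4, each = 5))
  expect_equal(est$r, r_oracle, tolerance = 1e-12)
  expect_true(est$se > 0)
  # zero variance is an error, not a number
  expect_error(revision_coefficient(c(20, 20, 20), c(25, 25, 25), 1:3),
               "zero variance")
})

test_that("clustered SE of the revision slope reacts to intra-cluster correlation", {
  set.seed(77)
  g <- rep(1:7, each = 60)
  cluster_shift <- rnorm(7, 0, 8)[g]
  x <- runif(420, 0, 84)
  y <- 0.5 * x + cluster_shift + rnorm(420, 0, 4)
  init <- 16 + x
  fin <- init - y  # y > 0 for nearly all rows; sign is irrelevant to |.|
  out <- revision_coefficient(init, fin, clusters = g)
  fit <- lm(abs(fin - init) ~ abs(init - 16))
  classical <- sqrt(diag(vcov(fit)))[2]
  expect_gt(out$slope_se, classical)
})

test_that("improvement flags A->C switches and reports the rate delta", {
  r1 <- mk_records(estimate = rep(50, 4),
                   recommendation = c("A", "C", "B", "D"), round = 1)
  r3 <- mk_records(estimate = rep(50, 4),
                   recommendation = c("C", "C", "B", "C"), round = 3)
  out <- improvement(rbind(r1, r3))
  expect_equal(unname(out$improved), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$delta_pp, 50)  # 25% -> 75% correct
  # clinicians missing the final round are excluded and counted
  r3b <- r3[1:3, ]
  out2 <- improvement(rbind(r1, r3b))
  expect_equal(out2$n_used, 3)
  expect_equal(out2$n_excluded, 1)
  # a 14% -> 27% shift is a +13 pp delta
  n <- 100
  r1c <- mk_records(estimate = rep(50, n),
                    recommendation = c(rep("C", 14), rep("A", 86)), round = 1)
  r3c <- mk_records(estimate = rep(50, n),
                    recommendation = c(rep("C", 27), rep("A", 73)), round = 3)
  expect_equal(improvement(rbind(r1c, r3c))$delta_pp, 13)
})

test_that("metrics_table is tidy and consistent with direct computation", {
  rec <- simulate_study(small_cfg(master_seed = 9))
  tab <- metrics_table(rec)
  expect_equal(names(tab), c("trial_id", "condition", "arm", "round",
                             "metric", "value"))
  # 2 trials x 4 cells x 3 rounds x 7 metrics
  expect_equal(nrow(tab), 2 * 4 * 3 * 7)
  cell <- rec[rec$trial_id == 1 & rec$condition == "network" &
              rec$arm == "black_female" & rec$round == 1, ]
  got <- tab$value[tab$trial_id == 1 & tab$condition == "network" &
                   tab$arm == "black_female" & tab$round == 1 &
                   tab$metric == "accuracy_mean"]
  expect_equal(got, mean(1 - abs(cell$estimate - 16) / 84))
})
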