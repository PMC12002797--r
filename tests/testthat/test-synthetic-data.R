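test_that("normative stimulus tables honour the configured structure", {
  cfg <- cohort_config()
  stim <- generate_normative_stimuli(64, cfg, seed = 1)
  expect_equal(nrow(stim), 64)
  for (col in c("merit_prop", "need_prop", "control_prop")) {
    expect_true(all(stim[[col]] >= 0 & stim[[col]] <= 1))
  }
  for (col in c("merit_c", "need_c", "control_c")) {
    expect_lt(abs(mean(stim[[col]])), 1e-12)
  }
  # the requested merit-need evidence correlation is realized on average
  rhos <- vapply(1:6, function(s) {
    st <- generate_normative_stimuli(64, cfg, seed = s)
    cor(st$merit_prop, st$need_prop)
  }, numeric(1))
  expect_lt(abs(mean(rhos) - cfg$stimuli$merit_need_corr), 0.15)
  expect_error(generate_normative_stimuli(1, cfg), class = "socialddm_input_error")
  expect_error(generate_normative_stimuli(
    16, cohort_config(stimuli = list(merit_need_corr = 1.2))))
})

test_that("perception datasets have the task's design and are reproducible", {
  cfg <- cohort_config()
  stim <- generate_normative_stimuli(64, cfg, seed = 2)
  truth <- generate_perception_truth(2, cfg, seed = 3)
  d1 <- generate_perception_dataset(truth, stim, cfg, seed = 4)
  d2 <- generate_perception_dataset(truth, stim, cfg, seed = 4)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 2 * 192)
  counts <- table(d1$subject_id, d1$condition)
  expect_true(all(counts == 64))
  expect_true(all(is.na(d1$rt) | d1$rt <= cfg$perception$response_window))
})

test_that("a high-sensitivity subject tracks the merit evidence gradient", {
  cfg <- cohort_config()
  stim <- generate_normative_stimuli(64, cfg, seed = 5)
  S <- matrix(0, 3, 3)
  S[1, 1] <- 8
  truth <- tibble::tibble(
    subject_id = "s001",
    params = list(perception_params(
      bias = c(merit = 0, need = 0, control = 0), S = S,
      a = c(merit = 1.5, need = 1.5, control = 1.5),
      ndt = c(merit = 0.3, need = 0.3, control = 0.3),
      z = c(merit = 0.5, need = 0.5, control = 0.5))))
  d <- generate_perception_dataset(truth, stim, cfg, seed = 6)
  d <- d[d$condition == "merit" & !is.na(d$response), ]
  ev <- stim$merit_c[match(d$stimulus_id, stim$stimulus_id)]
  qs <- cut(ev, quantile(ev, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE)
  yes_rate <- tapply(d$response == "yes", qs, mean)
  expect_true(all(diff(yes_rate) > 0))
})

test_that("the altruism design reproduces the printed task constants", {
  des <- generate_altruism_design(seed = 7)
  expect_equal(nrow(des), 300)
  expect_equal(as.integer(table(des$run)), rep(60L, 5))
  expect_equal(sort(as.integer(table(des$partner_merit))), rep(100L, 3))
  # 20 consecutive trials per partner within each run
  blocks <- unique(des[c("run", "block", "partner_merit")])
  expect_equal(nrow(blocks), 15)
  expect_true(all(table(des$run, des$block) == 20))
  # need split 50/50 within partner
  expect_true(all(table(des$partner_merit, des$need_level) == 50))
  # cue jitter bands and offer ranges
  high <- des$need_cue_pct[des$need_level == "high"]
  low <- des$need_cue_pct[des$need_level == "low"]
  expect_true(all(high >= 76 & high <= 84))
  expect_true(all(low >= 16 & low <= 24))
  expect_true(all(des$offer_self >= 5 & des$offer_self <= 35))
  expect_true(all(des$offer_other >= 5 & des$offer_other <= 35))
  # trade-off proposals dominate the grid
  tradeoff <- (des$offer_self > 20 & des$offer_other < 20) |
    (des$offer_self < 20 & des$offer_other > 20)
  expect_gt(mean(tradeoff), 0.6)
})

test_that("altruism datasets follow the generating preferences", {
  cfg <- cohort_config()
  selfish <- tibble::tibble(
    subject_id = "s001",
    params = list(altruism_params(
      weights = c(w0 = 0, self = 8, other = 0, fairness = 0),
      delta = matrix(0, 4, 3), a = 1.5, ndt = 0.4, z = 0.5)))
  d <- generate_altruism_dataset(selfish, seed = 8)
  gains <- d[!is.na(d$response) & d$offer_self > 22, ]
  expect_gt(mean(gains$response == "accept"), 0.95)
  d2 <- generate_altruism_dataset(selfish, seed = 8)
  expect_identical(d, d2)
})

test_that("need-coupled other-regard raises generosity under high need", {
  cfg <- cohort_config()
  delta <- matrix(0, 4, 3, dimnames = list(c("w0", "self", "other", "fairness"),
                                           c("merit_high", "merit_low", "need_high")))
  delta["other", "need_high"] <- 0.6
  delta["self", "need_high"] <- -0.4
  truth <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:6),
    params = replicate(6, altruism_params(
      weights = c(w0 = 0, self = 1, other = 0.15, fairness = 0.4),
      delta = delta, a = 1.8, ndt = 0.4, z = 0.5), simplify = FALSE))
  d <- generate_altruism_dataset(truth, seed = 9)
  tab <- generosity_fractions(d)
  cells <- tab[tab$merit != "all", ]
  by_need <- tapply(cells$fraction, cells$need, mean)
  expect_gt(by_need[["high"]], by_need[["low"]])
})

test_that("the synthetic rTPJ covariate has the configured coupling", {
  set.seed(10)
  s <- rnorm(44, 2.84, 1.02)
  r0 <- generate_neural_covariate(s, coupling = 1, noise_sd = 0, seed = 11)
  expect_equal(cor(r0, s, method = "spearman"), 1)
  # zero coupling: mostly small correlations at n = 25
  small <- vapply(1:10, function(i) {
    cor(generate_neural_covariate(rnorm(25), coupling = 0, noise_sd = 1,
                                  seed = i), rnorm(25))
  }, numeric(1))
  expect_gte(mean(abs(small) < 0.3), 0.8)
  # default coupling: detectable at the perception-task sample size
  detect <- vapply(1:10, function(i) {
    set.seed(i)
    sm <- rnorm(44, 2.84, 1.02)
    rt <- generate_neural_covariate(sm, coupling = 1, noise_sd = 1)
    cor.test(sm, rt)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.8)
  expect_error(generate_neural_covariate(s, coupling = -1),
               class = "socialddm_domain_error")
})

test_that("linked cohorts carry the cross-task structure end to end", {
  cfg <- cohort_config()
  cohort <- generate_linked_cohort(40, cfg, seed = 12)
  expect_equal(nrow(cohort$perception_truth), 40)
  expect_equal(nrow(cohort$altruism_truth), 40)
  expect_true(all(cohort$subjects$inter_task_delay_days >= 27 &
                    cohort$subjects$inter_task_delay_days <= 663))
  # couplings present in the generating truth
  expect_gt(cor(cohort$perception_truth$S_merit,
                cohort$altruism_truth$dw_other_merit, method = "spearman"), 0.2)
  expect_lt(cor(cohort$perception_truth$S_merit,
                cohort$altruism_truth$dw_self_merit, method = "spearman"), -0.2)
  expect_gt(cor(cohort$perception_truth$S_merit,
                cohort$subjects$rtpj_beta), 0.2)
})
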