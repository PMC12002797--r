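make_alt_params <- function(weights = c(w0 = 0, self = 1, other = 0.3,
                                        fairness = 0.4),
                            delta = matrix(0, 4, 3), a = 1.8, ndt = 0.4,
                            z = 0.5) {
  altruism_params(weights = weights, delta = delta, a = a, ndt = ndt, z = z)
}

test_that("attributes follow the rescaled-difference definitions", {
  # the task's own worked proposal
  at <- compute_attributes(13, 35)
  expect_equal(at$self, -0.7)
  expect_equal(at$other, 1.5)
  expect_equal(at$fairness, -2.2)
  expect_equal(unlist(compute_attributes(20, 20)), c(self = 0, other = 0, fairness = 0))
  at2 <- compute_attributes(35, 5)
  expect_equal(unlist(at2), c(self = 1.5, other = -1.5, fairness = -3.0))
  expect_error(compute_attributes(-1, 10), class = "socialddm_domain_error")
})

test_that("fairness is non-positive with equality iff payoffs match", {
  set.seed(7)
  os <- sample(5:35, 200, replace = TRUE)
  oo <- sample(5:35, 200, replace = TRUE)
  at <- compute_attributes(os, oo)
  expect_true(all(at$fairness <= 0))
  expect_identical(at$fairness == 0, os == oo)
  expect_equal(at$fairness, -abs(at$other - at$self))
})

test_that("condition weights compose linearly from baselines and deltas", {
  p0 <- make_alt_params()
  for (m in c("high", "unknown", "low")) {
    for (n in c("high", "low")) {
      expect_equal(condition_weights(p0, m, n), p0$weights)
    }
  }
  d <- matrix(0, 4, 3)
  d[3, 3] <- 0.3  # other-regard rises under high need
  p <- make_alt_params(weights = c(w0 = 0, self = 1, other = 0.22, fairness = 0.4),
                       delta = d)
  expect_equal(condition_weights(p, "high", "high")[["other"]], 0.52)
  expect_equal(condition_weights(p, "low", "high")[["other"]], 0.52)
  expect_equal(condition_weights(p, "unknown", "low")[["other"]], 0.22)

  set.seed(11)
  pr <- make_alt_params(delta = matrix(rnorm(12, 0, 0.3), 4, 3))
  diff_need <- condition_weights(pr, "high", "high") -
    condition_weights(pr, "high", "low")
  expect_equal(unname(diff_need), unname(pr$delta[, "need_high"]))
  expect_error(condition_weights(pr, "medium", "low"),
               class = "socialddm_domain_error")
})

test_that("value drift matches the reported overall weights on a worked trial", {
  w <- c(w0 = 0, self = 0.97, other = 0.22, fairness = 0.35)
  at <- compute_attributes(31, 14)
  expect_equal(unlist(at), c(self = 1.1, other = -0.6, fairness = -1.7))
  expect_equal(altruism_drift(w, at), 0.97 * 1.1 - 0.22 * 0.6 - 0.35 * 1.7)
  expect_equal(altruism_drift(w, at), 0.34, tolerance = 1e-12)
  expect_equal(altruism_drift(c(w0 = 0, self = 0, other = 0, fairness = 0), at), 0)
  # at the default offer only the value constant remains
  expect_equal(altruism_drift(c(w0 = 0.7, self = 2, other = 2, fairness = 2),
                              compute_attributes(20, 20)), 0.7)
})

test_that("change scores match explicit condition-weight differencing", {
  d <- matrix(0, 4, 3, dimnames = list(c("w0", "self", "other", "fairness"),
                                       c("merit_high", "merit_low", "need_high")))
  d["other", "merit_high"] <- 0.2
  d["other", "merit_low"] <- -0.1
  p <- make_alt_params(delta = d)
  cs <- change_scores(p)
  expect_equal(cs$dw_other_merit, 0.3)

  p0 <- make_alt_params()
  cs0 <- change_scores(p0)
  expect_true(all(unlist(cs0[1:6]) == 0))
  expect_equal(cs0$overall_w_self, p0$weights[["self"]])

  set.seed(13)
  pr <- make_alt_params(delta = matrix(rnorm(12, 0, 0.3), 4, 3))
  tb <- condition_weight_table(pr)
  explicit_merit <- mean(tb$other[tb$merit == "high"]) -
    mean(tb$other[tb$merit == "low"])
  explicit_need <- mean(tb$self[tb$need == "high"]) -
    mean(tb$self[tb$need == "low"])
  cs_r <- change_scores(pr)
  expect_equal(cs_r$dw_other_merit, explicit_merit, tolerance = 1e-12)
  expect_equal(cs_r$dw_self_need, explicit_need, tolerance = 1e-12)
  expect_equal(cs_r$overall_w_fairness, mean(tb$fairness), tolerance = 1e-12)
})

test_that("all 19 parameters round-trip through JSON", {
  set.seed(17)
  p <- make_alt_params(weights = setNames(rnorm(4), c("w0", "self", "other", "fairness")),
                       delta = matrix(rnorm(12, 0, 0.3), 4, 3),
                       a = 2.1, ndt = 0.45, z = 0.55)
  path <- withr::local_tempfile(fileext = ".json")
  write_altruism_params(p, path)
  q <- read_altruism_params(path)
  expect_equal(q$weights, p$weights, tolerance = 1e-12)
  expect_equal(q$delta, p$delta, tolerance = 1e-12)
  expect_equal(c(q$a, q$ndt, q$z), c(p$a, p$ndt, p$z), tolerance = 1e-12)
})

test_that("the fitted likelihood dominates the generating parameters", {
  cfg <- cohort_config()
  truth <- generate_altruism_truth(1, cfg, seed = 51)
  trials <- generate_altruism_dataset(truth, seed = 52)
  set.seed(53)
  fit <- suppressWarnings(fit_altruism_subject(trials, restarts = 2))
  nll <- socialddm:::altruism_nll_factory(trials[!is.na(trials$response), ])
  expect_gte(fit$loglik + 1e-6,
             -nll(socialddm:::altruism_theta_pack(truth$params[[1]])))
  expect_s3_class(fit$params, "altruism_params")
  td <- tidy(fit)
  expect_equal(nrow(td), 19)
  expect_equal(glance(fit)$n_parameters, 19L)
})

test_that("an empty merit x need cell is an explicit error naming the cell", {
  cfg <- cohort_config()
  truth <- generate_altruism_truth(1, cfg, seed = 61)
  trials <- generate_altruism_dataset(truth, seed = 62)
  dropped <- trials[!(trials$partner_merit == "high" & trials$need_level == "low"), ]
  expect_error(suppressWarnings(fit_altruism_subject(dropped)),
               regexp = "\\(high, low\\)", class = "socialddm_input_error")
})
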