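make_params <- function(bias = c(merit = 0, need = 0, control = 0),
                        S = diag(3), a = rep(1.5, 3), ndt = rep(0.3, 3),
                        z = rep(0.5, 3)) {
  perception_params(bias = bias, S = S,
                    a = setNames(a, c("merit", "need", "control")),
                    ndt = setNames(ndt, c("merit", "need", "control")),
                    z = setNames(z, c("merit", "need", "control")))
}

test_that("stimulus centering gives exactly zero-mean evidence columns", {
  set.seed(5)
  raw <- tibble::tibble(stimulus_id = paste0("i", 1:10),
                        merit_prop = runif(10), need_prop = runif(10),
                        control_prop = runif(10))
  cen <- center_stimuli(raw)
  expect_lt(abs(mean(cen$merit_c)), 1e-12)
  expect_lt(abs(mean(cen$need_c)), 1e-12)
  expect_lt(abs(mean(cen$control_c)), 1e-12)
  expect_named(attr(cen, "evidence_means"),
               c("merit_prop", "need_prop", "control_prop"))
  expect_error(center_stimuli(raw[-1]), class = "socialddm_input_error")
  raw$merit_prop[1] <- 1.2
  expect_error(center_stimuli(raw), class = "socialddm_input_error")
})

test_that("drift composes bias and sensitivity-weighted evidence", {
  stim <- tibble::tibble(stimulus_id = "x", merit_c = 0.20, need_c = -0.1,
                         control_c = 0.05)
  # zero sensitivities: drift equals the condition bias
  p <- make_params(bias = c(merit = 0.33, need = 0, control = 0), S = matrix(0, 3, 3))
  expect_equal(perception_drift(p, stim, "merit"), 0.33)
  # single task-relevant sensitivity times centered evidence
  S <- matrix(0, 3, 3)
  S[1, 1] <- 2.84
  p2 <- make_params(S = S)
  expect_equal(perception_drift(p2, stim, "merit"), 2.84 * 0.20)
  # everything zero
  p3 <- make_params(S = matrix(0, 3, 3))
  expect_equal(perception_drift(p3, stim, "merit"), 0)
  expect_error(perception_drift(p3, stim, "maximal"),
               class = "socialddm_domain_error")
})

test_that("bias/sensitivity extraction is a pure projection", {
  S <- matrix(0.1, 3, 3)
  S[1, 1] <- 2.0
  p <- make_params(bias = c(merit = 0.2, need = -0.17, control = 0.05), S = S)
  s <- extract_bias_sensitivity(p)
  expect_equal(s$S_merit, 2.0)
  expect_equal(s$Bias_need, -0.17)
  expect_equal(ncol(s), 6)
})

test_that("all 21 parameters round-trip through JSON to 1e-12", {
  set.seed(8)
  p <- make_params(bias = rnorm(3), S = matrix(rnorm(9), 3),
                   a = runif(3, 0.5, 3), ndt = runif(3, 0.1, 0.5),
                   z = runif(3, 0.2, 0.8))
  names(p$bias) <- c("merit", "need", "control")
  path <- withr::local_tempfile(fileext = ".json")
  write_perception_params(p, path, meta = list(seed = 8))
  q <- read_perception_params(path)
  expect_equal(q$bias, p$bias, tolerance = 1e-12)
  expect_equal(q$S, p$S, tolerance = 1e-12)
  expect_equal(q$a, p$a, tolerance = 1e-12)
  expect_equal(q$ndt, p$ndt, tolerance = 1e-12)
  expect_equal(q$z, p$z, tolerance = 1e-12)
})

test_that("task-relevance check flags non-dominant diagonals", {
  S <- matrix(0.1, 3, 3)
  diag(S) <- c(3, 3, 4)
  expect_true(all(task_relevance_check(make_params(S = S))$task_relevant_dominant))
  S2 <- S
  S2[1, 2] <- 5  # need evidence dominates in merit blocks
  chk <- task_relevance_check(make_params(S = S2))
  expect_false(chk$task_relevant_dominant[chk$condition == "merit"])
  expect_true(all(chk$task_relevant_dominant[chk$condition != "merit"]))
})

test_that("model likelihood equals an independent wfpt recomputation", {
  cfg <- cohort_config()
  stim <- generate_normative_stimuli(16, cfg, seed = 21)
  truth <- generate_perception_truth(1, cfg, seed = 22)
  trials <- generate_perception_dataset(truth, stim, cfg, seed = 23)
  trials <- trials[!is.na(trials$response), ]
  p <- truth$params[[1]]
  # module-internal objective
  ll_model <- 0
  ll_oracle <- 0
  for (cond in c("merit", "need", "control")) {
    tr <- trials[trials$condition == cond, ]
    ev <- as.matrix(stim[match(tr$stimulus_id, stim$stimulus_id),
                         c("merit_c", "need_c", "control_c")])
    nll <- socialddm:::perception_nll_factory(ev, tr$response == "yes", tr$rt)
    theta <- c(p$bias[[cond]], p$S[cond, ], p$a[[cond]], p$ndt[[cond]],
               p$z[[cond]])
    ll_model <- ll_model - nll(theta)
    # independent route: per-trial wfpt at explicitly assembled drifts
    for (i in seq_len(nrow(tr))) {
      srow <- stim[stim$stimulus_id == tr$stimulus_id[i], ]
      v <- p$bias[[cond]] + p$S[cond, "merit"] * srow$merit_c +
        p$S[cond, "need"] * srow$need_c + p$S[cond, "control"] * srow$control_c
      spec <- ddm_spec(v, p$a[[cond]], p$z[[cond]], p$ndt[[cond]])
      ll_oracle <- ll_oracle +
        ddm_wfpt_density(tr$rt[i], ifelse(tr$response[i] == "yes", "upper", "lower"),
                         spec, log = TRUE)
    }
  }
  expect_equal(ll_model, ll_oracle, tolerance = 1e-8)
})

test_that("sensitivity is identified separately from bias on a toy stimulus set", {
  stim <- tibble::tibble(stimulus_id = c("lo", "hi"), merit_c = c(-0.3, 0.3),
                         need_c = 0, control_c = 0)
  S <- matrix(0, 3, 3)
  S[1, 1] <- 2
  p <- make_params(S = S)
  p_scaled <- make_params(S = 2 * S)
  v1 <- perception_drift(p, stim, "merit")
  v2 <- perception_drift(p_scaled, stim, "merit")
  p_yes_1 <- ddm_choice_probability(v1, a = 1.5, w = 0.5)
  p_yes_2 <- ddm_choice_probability(v2, a = 1.5, w = 0.5)
  # scaling S changes the SPREAD of predicted choice rates across stimuli,
  # which no bias shift can mimic (bias moves both stimuli the same way)
  expect_gt(diff(p_yes_2), diff(p_yes_1))
})

test_that("fitting is invariant to dataset duplication and errors on scarcity", {
  cfg <- cohort_config()
  stim <- generate_normative_stimuli(32, cfg, seed = 31)
  truth <- generate_perception_truth(1, cfg, seed = 32)
  trials <- generate_perception_dataset(truth, stim, cfg, seed = 33)
  set.seed(1)
  f1 <- suppressWarnings(fit_perception_subject(trials, stim, restarts = 2))
  set.seed(1)
  f2 <- suppressWarnings(
    fit_perception_subject(dplyr::bind_rows(trials, trials), stim, restarts = 2))
  expect_equal(f2$params$S, f1$params$S, tolerance = 0.05)
  expect_equal(f2$params$bias, f1$params$bias, tolerance = 0.05)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 0.01)

  few <- trials[trials$condition != "need" | seq_len(nrow(trials)) %in% 1:5, ]
  expect_error(fit_perception_subject(few[few$condition == "need", ] |>
                                        dplyr::bind_rows(few), stim),
               class = "socialddm_input_error")
})

test_that("tidy and glance summarize a perception fit", {
  cfg <- cohort_config()
  stim <- generate_normative_stimuli(32, cfg, seed = 41)
  truth <- generate_perception_truth(1, cfg, seed = 42)
  trials <- generate_perception_dataset(truth, stim, cfg, seed = 43)
  f <- suppressWarnings(fit_perception_subject(trials, stim, restarts = 2))
  td <- tidy(f)
  expect_equal(nrow(td), 21)
  expect_true(all(c("term", "estimate") %in% names(td)))
  g <- glance(f)
  expect_equal(g$n_parameters, 21L)
  expect_true(is.finite(g$logLik))
})
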