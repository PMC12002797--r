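#' Cohort configuration for the synthetic generators
#'
#' Group-level means and SDs of every subject-level parameter of both
#' behavioural models, evidence-distribution settings for the normative
#' stimulus table, cross-parameter couplings, and the inter-task delay range.
#' Defaults emulate the reported group statistics of the study the package
#' models: task-relevant sensitivities 2.84 +/- 1.02 (merit), 3.28 +/- 0.75
#' (need), 4.40 +/- 0.69 (control); biases 0.33 +/- 0.47, -0.17 +/- 0.39,
#' 0.09 +/- 0.36 with a 0.73 merit-need bias correlation; overall attribute
#' weights near 0.97 (self), 0.22 (other), 0.35 (fairness). Values not
#' reported (off-diagonal sensitivities, change-parameter means, DDM
#' thresholds and timing) are field-typical defaults documented in the
#' methods vignette. Every entry can be overridden.
#'
#' @param ... Named overrides merged into the default list (one level deep).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    perception = list(
      S_mean = matrix(c(2.84, 0.50, 0.50,
                        0.50, 3.28, 0.50,
                        0.50, 0.50, 4.40),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(perception_conditions, evidence_dims)),
      S_sd = matrix(c(1.02, 0.30, 0.30,
                      0.30, 0.75, 0.30,
                      0.30, 0.30, 0.69),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(perception_conditions, evidence_dims)),
      bias_mean = c(merit = 0.33, need = -0.17, control = 0.09),
      bias_sd = c(merit = 0.47, need = 0.39, control = 0.36),
      bias_merit_need_corr = 0.73,
      a_mean = 1.5, a_sd = 0.25,
      ndt_mean = 0.35, ndt_sd = 0.05,
      z_mean = 0.5, z_sd = 0.05,
      response_window = 2.0
    ),
    altruism = list(
      # baselines at the reference condition (unknown merit, low need),
      # chosen so the implied overall (6-cell mean) weights sit near the
      # reported overall means
      weights_mean = c(w0 = 0, self = 1.05, other = 0.12, fairness = 0.43),
      weights_sd = c(w0 = 0.30, self = 0.75, other = 0.49, fairness = 0.36),
      delta_mean = matrix(c(0.05, -0.05, 0.05,
                            -0.15, 0.15, -0.15,
                            0.15, -0.15, 0.20,
                            0.10, -0.10, -0.15),
                          nrow = 4, byrow = TRUE,
                          dimnames = list(weight_names, delta_names)),
      # heterogeneity of the change parameters must be substantially larger
      # than their estimation noise for observed change-score correlations of
      # ~0.9 with behavioural generosity changes to be possible at n ~ 28
      delta_sd = matrix(0.30, nrow = 4, ncol = 3,
                        dimnames = list(weight_names, delta_names)),
      a_mean = 1.8, a_sd = 0.3,
      ndt_mean = 0.5, ndt_sd = 0.08,
      z_mean = 0.5, z_sd = 0.05
    ),
    stimuli = list(
      prop_mean = c(merit = 0.567, need = 0.487, control = 0.549),
      # merit must be inferred indirectly from abstract cues, so raters
      # disagree moderately; need is signalled directly and concretely per
      # image and the factual control judgment is near-unanimous, giving
      # strongly bimodal (U-shaped) proportion distributions for those two
      concentration = c(merit = 2, need = 0.8, control = 0.5),
      merit_need_corr = 0.3
    ),
    coupling = list(
      # fraction of each coupled parameter's SD driven by standardized
      # perception scores (merit sensitivity -> merit change parameters;
      # merit bias -> baseline other-regard)
      s_merit_delta = 0.6,
      bias_merit_wother = 0.6,
      rtpj = 1, rtpj_noise_sd = 1
    ),
    delay_days = c(27, 663)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      overrides[[nm]]
    }
  }
  stopifnot(abs(cfg$stimuli$merit_need_corr) < 1)
  structure(cfg, class = c("cohort_config", "list"))
}

#' Generate a normative stimulus table
#'
#' Per image, "yes" proportions on the three judgment dimensions, drawn from
#' Beta marginals (configurable means and concentration) with a Gaussian
#' copula inducing the configured merit-need evidence correlation; control
#' evidence is independent. Deterministic per seed.
#'
#' @param n_images Number of images (default 64, the task's stimulus-set
#'   size).
#' @param config A [cohort_config()].
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return Tibble with `stimulus_id`, `merit_prop`, `need_prop`,
#'   `control_prop`, already centered via [center_stimuli()].
#' @export
generate_normative_stimuli <- function(n_images = 64, config = cohort_config(),
                                       seed = NULL) {
  if (n_images < 2) abort("need at least 2 images.", class = "socialddm_input_error")
  if (!is.null(seed)) set.seed(seed)
  sc <- config$stimuli
  rho <- sc$merit_need_corr
  if (abs(rho) >= 1) abort("infeasible merit-need correlation.",
                           class = "socialddm_input_error")
  z1 <- rnorm(n_images)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_images)
  kappa <- rep_len(sc$concentration, 3)
  names(kappa) <- evidence_dims
  to_beta <- function(z, mu, k) stats::qbeta(pnorm(z), mu * k, (1 - mu) * k)
  center_stimuli(tibble::tibble(
    stimulus_id = sprintf("img%03d", seq_len(n_images)),
    merit_prop = to_beta(z1, sc$prop_mean[["merit"]], kappa[["merit"]]),
    need_prop = to_beta(z2, sc$prop_mean[["need"]], kappa[["need"]]),
    control_prop = to_beta(rnorm(n_images), sc$prop_mean[["control"]],
                           kappa[["control"]])
  ))
}

# truncated-normal helper for parameters with hard domains
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  pmin(pmax(rnorm(n, mean, sd), lower), upper)
}

#' Draw subject-level perception parameters for a cohort
#'
#' Independent Normal draws per parameter at the configured means/SDs, except
#' the merit and need biases, which are drawn jointly with the configured
#' correlation. Domain-bounded parameters (`a`, `ndt`, `z`) are truncated to
#' their valid ranges.
#'
#' @param n_subjects Number of subjects.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, a `params` list-column of
#'   [perception_params()], and the flattened task-relevant truths.
#' @export
generate_perception_truth <- function(n_subjects, config = cohort_config(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pc <- config$perception
  rho <- pc$bias_merit_need_corr
  zb1 <- rnorm(n_subjects)
  zb2 <- rho * zb1 + sqrt(1 - rho^2) * rnorm(n_subjects)
  bias_merit <- pc$bias_mean[["merit"]] + pc$bias_sd[["merit"]] * zb1
  bias_need <- pc$bias_mean[["need"]] + pc$bias_sd[["need"]] * zb2
  bias_control <- rnorm(n_subjects, pc$bias_mean[["control"]], pc$bias_sd[["control"]])
  params <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    S <- matrix(rnorm(9, pc$S_mean, pc$S_sd), nrow = 3,
                dimnames = dimnames(pc$S_mean))
    params[[i]] <- perception_params(
      bias = c(merit = bias_merit[i], need = bias_need[i],
               control = bias_control[i]),
      S = S,
      a = setNames(rnorm_trunc(3, pc$a_mean, pc$a_sd, 0.4, 4), perception_conditions),
      ndt = setNames(rnorm_trunc(3, pc$ndt_mean, pc$ndt_sd, 0.1, 1), perception_conditions),
      z = setNames(rnorm_trunc(3, pc$z_mean, pc$z_sd, 0.1, 0.9), perception_conditions)
    )
  }
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("s%03d", seq_len(n_subjects)),
                   params = params),
    dplyr::bind_rows(purrr::map(params, extract_bias_sensitivity))
  )
}

#' Simulate a perception-task dataset
#'
#' Per subject, each stimulus is judged once per condition (64 x 3 = 192
#' trials under the default design): the drift follows the subject's true
#' parameters on the centered normative evidence, and choices/RTs come from
#' the diffusion simulator. Trials whose RT exceeds the response window (2 s
#' by default), and non-converged paths, are marked missing but kept.
#'
#' @param truth A [generate_perception_truth()] tibble.
#' @param stimuli A centered stimulus table.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param dt Simulation step (s), default 1e-3.
#' @return Tibble of trials: `subject_id`, `stimulus_id`, `condition`,
#'   `response` (`"yes"`/`"no"`/`NA`), `rt` (s, `NA` when missing).
#' @export
generate_perception_dataset <- function(truth, stimuli,
                                        config = cohort_config(), seed = NULL,
                                        dt = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  window <- config$perception$response_window
  out <- purrr::map2(truth$subject_id, truth$params, function(sid, p) {
    purrr::map(perception_conditions, function(cond) {
      v <- perception_drift(p, stimuli, cond)
      spec <- ddm_spec(v = 0, a = p$a[[cond]], w = p$z[[cond]],
                       ndt = p$ndt[[cond]])
      sim <- ddm_simulate(nrow(stimuli), spec, v = v, dt = dt)
      miss <- !sim$converged | sim$rt > window
      tibble::tibble(
        subject_id = sid, stimulus_id = stimuli$stimulus_id, condition = cond,
        response = ifelse(miss, NA_character_,
                          ifelse(sim$boundary == "upper", "yes", "no")),
        rt = ifelse(miss, NA_real_, sim$rt)
      )
    })
  })
  dplyr::bind_rows(out)
}

#' Generate the altruism-task trial design
#'
#' One subject's design: 300 trials in 5 runs; each run holds three blocks of
#' 20 consecutive trials, one block per partner, so each partner contributes
#' 100 trials. Within each block need is high on half the trials and low on
#' the other half in random order; the need cue is 80 (high) or 20 (low) plus
#' symmetric uniform jitter on \[-4, +4\] percentage points. Base proposals
#' are drawn from a $5-$31 grid concentrated in the trade-off quadrants
#' (one player above, the other below the $20 default) and jittered by $0-$4,
#' so realised offers span $5-$35.
#'
#' @param seed Integer seed.
#' @param partner_order Character vector of the three partner merit levels in
#'   block order (rotated across runs); default `c("high", "unknown", "low")`.
#'   Rotate across subjects to counterbalance.
#' @param quadrant_probs Probabilities of the (self-favouring, other-favouring,
#'   both-above, both-below) base-proposal quadrants.
#' @return Tibble of 300 rows: `trial`, `run`, `block`, `partner_merit`,
#'   `need_level`, `need_cue_pct`, `offer_self`, `offer_other`.
#' @export
generate_altruism_design <- function(seed = NULL,
                                     partner_order = c("high", "unknown", "low"),
                                     quadrant_probs = c(0.4, 0.4, 0.1, 0.1)) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(setequal(partner_order, merit_levels),
            length(quadrant_probs) == 4, abs(sum(quadrant_probs) - 1) < 1e-8)
  low_band <- 5:15
  high_band <- 21:31
  draw_offers <- function(n) {
    quad <- sample.int(4, n, replace = TRUE, prob = quadrant_probs)
    self_base <- ifelse(quad %in% c(1, 3), sample(high_band, n, replace = TRUE),
                        sample(low_band, n, replace = TRUE))
    other_base <- ifelse(quad %in% c(2, 3), sample(high_band, n, replace = TRUE),
                         sample(low_band, n, replace = TRUE))
    tibble::tibble(offer_self = self_base + sample(0:4, n, replace = TRUE),
                   offer_other = other_base + sample(0:4, n, replace = TRUE))
  }
  runs <- purrr::map(1:5, function(r) {
    # rotate partner order across runs so block position is balanced
    order_r <- partner_order[((seq_len(3) + r - 2) %% 3) + 1]
    blocks <- purrr::map(1:3, function(b) {
      need <- sample(rep(need_levels, each = 10))
      dplyr::bind_cols(
        tibble::tibble(
          run = r, block = b, partner_merit = order_r[b], need_level = need,
          need_cue_pct = ifelse(need == "high", 80, 20) + runif(20, -4, 4)
        ),
        draw_offers(20)
      )
    })
    dplyr::bind_rows(blocks)
  })
  out <- dplyr::bind_rows(runs)
  out$trial <- seq_len(nrow(out))
  dplyr::relocate(out, "trial")
}

#' Draw subject-level altruism parameters for a cohort
#'
#' Independent truncated-Normal draws at the configured means/SDs. When
#' standardized perception scores are supplied, the merit change parameters
#' for other- and self-regard couple to merit sensitivity (positively for
#' other-regard: more sensitive perceivers discriminate more by merit) and
#' the baseline other-regard weight couples to merit bias, each coupling
#' expressed as a fraction of that parameter's SD.
#'
#' @param n_subjects Number of subjects.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param s_merit_z,bias_merit_z Optional standardized perception scores of
#'   length `n_subjects` enabling the cross-task couplings.
#' @return Tibble with `subject_id`, a `params` list-column of
#'   [altruism_params()], and the flattened true change scores from
#'   [change_scores()].
#' @export
generate_altruism_truth <- function(n_subjects, config = cohort_config(),
                                    seed = NULL, s_merit_z = NULL,
                                    bias_merit_z = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ac <- config$altruism
  cp <- config$coupling
  params <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    w <- rnorm(4, ac$weights_mean, ac$weights_sd)
    names(w) <- weight_names
    d <- matrix(rnorm(12, ac$delta_mean, ac$delta_sd), nrow = 4,
                dimnames = dimnames(ac$delta_mean))
    if (!is.null(s_merit_z)) {
      lam <- cp$s_merit_delta
      res <- sqrt(max(0, 1 - lam^2))
      d["other", "merit_high"] <- ac$delta_mean["other", "merit_high"] +
        ac$delta_sd["other", "merit_high"] * (lam * s_merit_z[i] + res * rnorm(1))
      d["other", "merit_low"] <- ac$delta_mean["other", "merit_low"] -
        ac$delta_sd["other", "merit_low"] * (lam * s_merit_z[i] - res * rnorm(1))
      d["self", "merit_high"] <- ac$delta_mean["self", "merit_high"] -
        ac$delta_sd["self", "merit_high"] * (lam * s_merit_z[i] - res * rnorm(1))
      d["self", "merit_low"] <- ac$delta_mean["self", "merit_low"] +
        ac$delta_sd["self", "merit_low"] * (lam * s_merit_z[i] + res * rnorm(1))
    }
    if (!is.null(bias_merit_z)) {
      lam <- cp$bias_merit_wother
      res <- sqrt(max(0, 1 - lam^2))
      w["other"] <- ac$weights_mean[["other"]] +
        ac$weights_sd[["other"]] * (lam * bias_merit_z[i] + res * rnorm(1))
    }
    params[[i]] <- altruism_params(
      weights = w, delta = d,
      a = rnorm_trunc(1, ac$a_mean, ac$a_sd, 0.5, 4),
      ndt = rnorm_trunc(1, ac$ndt_mean, ac$ndt_sd, 0.1, 1),
      z = rnorm_trunc(1, ac$z_mean, ac$z_sd, 0.1, 0.9)
    )
  }
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("s%03d", seq_len(n_subjects)),
                   params = params),
    dplyr::bind_rows(purrr::map(params, change_scores))
  )
}

#' Simulate an altruism-task dataset
#'
#' Per subject, condition weights follow from the subject's true parameters,
#' the drift from the trial's attributes, and choices/RTs from the diffusion
#' simulator (accept = upper boundary). Each subject receives a fresh design
#' draw with the partner-block order rotated across subjects
#' (counterbalancing), unless a fixed `design` is supplied.
#'
#' @param truth A [generate_altruism_truth()] tibble.
#' @param design Optional fixed design from [generate_altruism_design()]
#'   applied to every subject; by default each subject gets their own draw.
#' @param seed Integer seed.
#' @param dt Simulation step (s), default 1e-3.
#' @return Tibble of trials: `subject_id`, `run`, `partner_merit`,
#'   `need_level`, `need_cue_pct`, `offer_self`, `offer_other`, `response`,
#'   `rt`.
#' @export
generate_altruism_dataset <- function(truth, design = NULL, seed = NULL,
                                      dt = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map2(seq_len(nrow(truth)), truth$params, function(i, p) {
    des <- if (is.null(design)) {
      generate_altruism_design(
        partner_order = merit_levels[((seq_len(3) + i - 2) %% 3) + 1])
    } else {
      design
    }
    wt <- condition_weight_table(p)
    des2 <- dplyr::left_join(des, wt, by = c("partner_merit" = "merit",
                                             "need_level" = "need"))
    attrs <- compute_attributes(des2$offer_self, des2$offer_other)
    v <- des2$w0 + des2$self * attrs$self + des2$other * attrs$other +
      des2$fairness * attrs$fairness
    spec <- ddm_spec(v = 0, a = p$a, w = p$z, ndt = p$ndt)
    sim <- ddm_simulate(nrow(des2), spec, v = v, dt = dt)
    tibble::tibble(
      subject_id = truth$subject_id[i],
      run = des2$run, partner_merit = des2$partner_merit,
      need_level = des2$need_level, need_cue_pct = des2$need_cue_pct,
      offer_self = des2$offer_self, offer_other = des2$offer_other,
      response = ifelse(sim$converged,
                        ifelse(sim$boundary == "upper", "accept", "reject"),
                        NA_character_),
      rt = ifelse(sim$converged, sim$rt, NA_real_)
    )
  })
  dplyr::bind_rows(out)
}

#' Synthetic rTPJ covariate
#'
#' A per-subject scalar standing in for merit-inference-evoked right
#' temporoparietal-junction activation, generated as
#' `coupling * standardize(S_merit) + Normal(0, noise_sd)`.
#'
#' @param s_merit True (or fitted) merit-sensitivity vector.
#' @param coupling Non-negative coupling strength.
#' @param noise_sd Noise SD.
#' @param seed Integer seed.
#' @return Numeric vector, one value per subject.
#' @export
generate_neural_covariate <- function(s_merit, coupling = 1, noise_sd = 1,
                                      seed = NULL) {
  if (coupling < 0) abort("`coupling` must be >= 0.", class = "socialddm_domain_error")
  if (!is.null(seed)) set.seed(seed)
  z <- if (sd(s_merit) > 0) (s_merit - mean(s_merit)) / sd(s_merit) else s_merit * 0
  coupling * z + rnorm(length(s_merit), 0, noise_sd)
}

#' Generate a fully linked synthetic cohort
#'
#' Draws a cohort with the cross-task statistical structure the linking
#' analyses assume: perception parameters at the configured group moments,
#' altruism parameters with merit change parameters coupled to merit
#' sensitivity and baseline other-regard coupled to merit bias, a synthetic
#' rTPJ covariate coupled to merit sensitivity, and an inter-task delay drawn
#' uniformly over the configured range (27-663 days by default).
#'
#' @param n_subjects Number of subjects.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List with `perception_truth`, `altruism_truth`, and `subjects`
#'   (tibble with `subject_id`, `rtpj_beta`, `inter_task_delay_days`).
#' @export
generate_linked_cohort <- function(n_subjects, config = cohort_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- generate_perception_truth(n_subjects, config)
  sz <- (per$S_merit - mean(per$S_merit)) / sd(per$S_merit)
  bz <- (per$Bias_merit - mean(per$Bias_merit)) / sd(per$Bias_merit)
  alt <- generate_altruism_truth(n_subjects, config, s_merit_z = sz,
                                 bias_merit_z = bz)
  rtpj <- generate_neural_covariate(per$S_merit, config$coupling$rtpj,
                                    config$coupling$rtpj_noise_sd)
  delay <- runif(n_subjects, config$delay_days[1], config$delay_days[2])
  list(
    perception_truth = per,
    altruism_truth = alt,
    subjects = tibble::tibble(subject_id = per$subject_id, rtpj_beta = rtpj,
                              inter_task_delay_days = delay)
  )
}
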