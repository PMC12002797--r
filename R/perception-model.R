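#' Mean-center a normative stimulus table
#'
#' The normative table carries, per image, the proportion of "yes" responses
#' from an independent rater sample on each judgment dimension (merit, need,
#' control). Model drifts are built from the dataset-wide mean-centered
#' proportions; centering is computed over the full stimulus set and stored
#' with the table so fits are reproducible.
#'
#' @param stimuli Data frame with columns `stimulus_id`, `merit_prop`,
#'   `need_prop`, `control_prop`, each proportion in \[0, 1\].
#' @return The input as a tibble with added centered columns `merit_c`,
#'   `need_c`, `control_c` and an attribute `evidence_means` recording the
#'   subtracted means.
#' @export
center_stimuli <- function(stimuli) {
  cols <- c("merit_prop", "need_prop", "control_prop")
  missing_cols <- setdiff(c("stimulus_id", cols), names(stimuli))
  if (length(missing_cols) > 0) {
    abort(paste0("stimulus table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "socialddm_input_error")
  }
  props <- as.matrix(stimuli[cols])
  if (any(props < 0 | props > 1)) {
    abort("normative proportions must lie in [0, 1].",
          class = "socialddm_input_error")
  }
  mu <- colMeans(props)
  out <- tibble::as_tibble(stimuli)
  out$merit_c <- props[, 1] - mu[1]
  out$need_c <- props[, 2] - mu[2]
  out$control_c <- props[, 3] - mu[3]
  attr(out, "evidence_means") <- setNames(as.numeric(mu), cols)
  out
}

perception_conditions <- c("merit", "need", "control")
evidence_dims <- c("merit", "need", "control")

#' Construct a subject-level perception parameter set
#'
#' The social-perception model describes each speeded yes/no judgment as
#' evidence accumulation whose drift combines a condition-specific evidence
#' bias with sensitivity-weighted normative evidence on all three dimensions:
#' `v = Bias_c + S[c, merit] * Merit + S[c, need] * Need + S[c, control] * Control`.
#' Each judged condition additionally has its own boundary separation,
#' non-decision time, and start fraction.
#'
#' @param bias Named numeric of length 3 (`merit`, `need`, `control`):
#'   evidence biases.
#' @param S 3x3 numeric matrix of sensitivities; rows index the judged
#'   condition, columns the evidence dimension.
#' @param a,ndt,z Named numerics of length 3 per condition: boundary
#'   separation (> 0), non-decision time (>= 0), start fraction in (0, 1).
#' @return An object of class `perception_params`.
#' @export
perception_params <- function(bias, S, a, ndt, z) {
  S <- as.matrix(S)
  dimnames(S) <- list(perception_conditions, evidence_dims)
  by_cond <- function(x) {
    if (!is.null(names(x))) x <- x[perception_conditions]
    setNames(as.numeric(x), perception_conditions)
  }
  bias <- by_cond(bias)
  a <- by_cond(a)
  ndt <- by_cond(ndt)
  z <- by_cond(z)
  if (any(!is.finite(c(bias, S, a, ndt, z)))) {
    abort("all perception parameters must be finite.", class = "socialddm_domain_error")
  }
  if (any(a <= 0) || any(ndt < 0) || any(z <= 0) || any(z >= 1)) {
    abort("need a > 0, ndt >= 0, 0 < z < 1 in every condition.",
          class = "socialddm_domain_error")
  }
  structure(list(bias = bias, S = S, a = a, ndt = ndt, z = z),
            class = "perception_params")
}

#' @export
print.perception_params <- function(x, ...) {
  cat("<perception_params>\n  bias:", sprintf("%s=%.3f", names(x$bias), x$bias), "\n")
  cat("  S (judged x evidence):\n")
  print(round(x$S, 3))
  cat("  a:  ", sprintf("%s=%.3f", names(x$a), x$a), "\n")
  cat("  ndt:", sprintf("%s=%.3f", names(x$ndt), x$ndt), "\n")
  cat("  z:  ", sprintf("%s=%.3f", names(x$z), x$z), "\n")
  invisible(x)
}

#' Drift rates for perception trials
#'
#' Evaluates `v = Bias_condition + sum_dim S[condition, dim] * evidence_dim`
#' on mean-centered stimulus evidence.
#'
#' @param params A [perception_params()] object.
#' @param stimuli A centered stimulus table from [center_stimuli()] (or any
#'   data frame with `merit_c`, `need_c`, `control_c` columns), one row per
#'   trial/stimulus.
#' @param condition Judged condition, one of `"merit"`, `"need"`,
#'   `"control"` (scalar).
#' @return Numeric drift vector, one element per stimulus row.
#' @export
perception_drift <- function(params, stimuli, condition) {
  stopifnot(inherits(params, "perception_params"))
  if (!condition %in% perception_conditions) {
    abort(paste0("unknown condition: ", condition), class = "socialddm_domain_error")
  }
  if (!all(c("merit_c", "need_c", "control_c") %in% names(stimuli))) {
    abort("stimuli must carry centered evidence columns; see center_stimuli().",
          class = "socialddm_input_error")
  }
  ev <- cbind(stimuli$merit_c, stimuli$need_c, stimuli$control_c)
  drop(params$bias[condition] + ev %*% params$S[condition, ])
}

# bounds used by the per-condition optimizer
perception_bounds <- function(min_rt) {
  list(
    lower = c(bias = -5, s_merit = -10, s_need = -10, s_control = -10,
              a = 0.3, ndt = 0.05, z = 0.05),
    upper = c(bias = 5, s_merit = 10, s_need = 10, s_control = 10,
              a = 5, ndt = max(0.06, min_rt - 0.01), z = 0.95)
  )
}

# negative log-likelihood closure for one condition's trials
perception_nll_factory <- function(ev, yes, rt, prior = NULL) {
  n <- length(rt)
  function(theta) {
    v <- theta[1] + drop(ev %*% theta[2:4])
    ll <- sum(pmax(cpp_wfpt_logdensity(rt, yes, v, rep.int(theta[5], n),
                                       rep.int(theta[7], n),
                                       rep.int(theta[6], n), 1, 1e-7), -1e10))
    if (!is.null(prior)) {
      ll <- ll + sum(dnorm(theta, prior$mean, prior$sd, log = TRUE))
    }
    if (!is.finite(ll)) 1e12 else -ll
  }
}

fit_one_condition <- function(ev, yes, rt, restarts, prior = NULL) {
  nll <- perception_nll_factory(ev, yes, rt, prior)
  b <- perception_bounds(min(rt))
  # data-driven start: under w = 0.5 the asymptotic accept rate is
  # logistic(v * a / sigma^2), so logistic-regression coefficients on the
  # centered evidence approximate (bias, S) * a
  a0 <- 1.5
  start <- c(bias = 0, s_merit = 0, s_need = 0, s_control = 0, a = a0,
             ndt = min(0.3, 0.8 * min(rt)), z = 0.5)
  co <- tryCatch(
    coef(suppressWarnings(glm(yes ~ ev, family = binomial()))),
    error = function(e) rep(0, 4)
  )
  co[!is.finite(co)] <- 0
  start[1:4] <- pmin(pmax(co / a0, b$lower[1:4] * 0.9), b$upper[1:4] * 0.9)

  starts <- list(start)
  if (restarts > 1) {
    for (i in seq_len(restarts - 1)) {
      jit <- start
      jit[1:4] <- start[1:4] + rnorm(4, 0, 1)
      jit[5] <- runif(1, 0.8, 3)
      jit[6] <- runif(1, b$lower[6], b$upper[6])
      jit[7] <- runif(1, 0.3, 0.7)
      starts[[i + 1]] <- pmin(pmax(jit, b$lower + 1e-6), b$upper - 1e-6)
    }
  }
  fits <- lapply(starts, function(s) {
    tryCatch(
      optim(s, nll, method = "L-BFGS-B", lower = b$lower, upper = b$upper,
            control = list(maxit = 400, factr = 1e8)),
      error = function(e) list(value = Inf, par = s, convergence = 99L)
    )
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  list(par = best$par, loglik = -best$value,
       converged = best$convergence == 0L,
       n_converged = sum(vapply(fits, `[[`, integer(1), "convergence") == 0L))
}

#' Fit the social-perception model to one subject
#'
#' Maximum-likelihood estimation of the full per-subject parameter set (three
#' evidence biases, the 3x3 sensitivity matrix, and per-condition boundary
#' separation, non-decision time and start fraction) from yes/no choices and
#' response times. The likelihood factorises over the three judged
#' conditions, so each condition's seven parameters are estimated by
#' independent bounded L-BFGS-B runs with multi-start (the first start is
#' data-driven via a logistic-regression projection of choices on evidence;
#' the rest are jittered). "yes" maps to the upper boundary. Responses
#' missing or beyond the response window are excluded from the likelihood.
#'
#' @param trials Data frame with columns `stimulus_id`, `condition`,
#'   `response` (`"yes"`/`"no"`, `NA` allowed), `rt` (s, `NA` allowed).
#' @param stimuli Centered stimulus table from [center_stimuli()].
#' @param restarts Number of optimizer starts per condition (default 8).
#' @param min_trials Minimum usable trials required per condition (default 20).
#' @param prior Optional shrinkage prior: list of `mean` and `sd` vectors of
#'   length 7 (bias, S triplet, a, ndt, z) per condition, as produced by the
#'   two-stage empirical-Bayes mode of [fit_perception()].
#' @return An object of class `perception_fit`: list with `params`
#'   ([perception_params()]), `loglik`, `converged`, `n_trials`, and a
#'   per-condition diagnostics tibble.
#' @export
fit_perception_subject <- function(trials, stimuli, restarts = 8,
                                   min_trials = 20, prior = NULL) {
  stopifnot(all(c("stimulus_id", "condition", "response", "rt") %in% names(trials)))
  usable <- trials[!is.na(trials$response) & !is.na(trials$rt) & trials$rt > 0, ]
  idx <- match(usable$stimulus_id, stimuli$stimulus_id)
  if (anyNA(idx)) {
    abort("trials reference stimulus ids absent from the normative table.",
          class = "socialddm_input_error")
  }
  ev_all <- cbind(stimuli$merit_c, stimuli$need_c, stimuli$control_c)[idx, , drop = FALSE]

  res <- list()
  for (cond in perception_conditions) {
    sel <- usable$condition == cond
    if (sum(sel) < min_trials) {
      abort(sprintf("condition '%s' has %d usable trials; need at least %d.",
                    cond, sum(sel), min_trials),
            class = "socialddm_input_error")
    }
    res[[cond]] <- fit_one_condition(
      ev_all[sel, , drop = FALSE],
      usable$response[sel] == "yes",
      usable$rt[sel],
      restarts = restarts,
      prior = if (is.null(prior)) NULL else prior[[cond]]
    )
  }
  par_mat <- vapply(res, `[[`, numeric(7), "par")  # 7 x 3
  params <- perception_params(
    bias = setNames(par_mat[1, ], perception_conditions),
    S = t(par_mat[2:4, ]),
    a = setNames(par_mat[5, ], perception_conditions),
    ndt = setNames(par_mat[6, ], perception_conditions),
    z = setNames(par_mat[7, ], perception_conditions)
  )
  diagnostics <- tibble::tibble(
    condition = perception_conditions,
    loglik = vapply(res, `[[`, numeric(1), "loglik"),
    converged = vapply(res, `[[`, logical(1), "converged"),
    n_starts_converged = vapply(res, `[[`, integer(1), "n_converged"),
    n_trials = vapply(perception_conditions,
                      function(cc) sum(usable$condition == cc), integer(1))
  )
  if (!all(diagnostics$converged)) {
    warn(paste0("perception fit did not converge for condition(s): ",
                paste(diagnostics$condition[!diagnostics$converged], collapse = ", ")))
  }
  structure(list(params = params,
                 loglik = sum(diagnostics$loglik),
                 converged = all(diagnostics$converged),
                 n_trials = nrow(usable),
                 diagnostics = diagnostics),
            class = "perception_fit")
}

#' @export
print.perception_fit <- function(x, ...) {
  cat(sprintf("<perception_fit> loglik = %.2f over %d trials; converged: %s\n",
              x$loglik, x$n_trials, x$converged))
  print(x$params)
  invisible(x)
}

#' Fit the perception model across a cohort
#'
#' Per-subject maximum likelihood by default. With `shrinkage = TRUE` a
#' two-stage empirical-Bayes scheme is used: first-stage MLEs provide
#' hyper-means and hyper-SDs for every parameter, and each subject is then
#' refitted under independent Normal priors with those moments (MAP). This
#' approximates hierarchical pooling without a full hierarchical sampler.
#'
#' @param trials Data frame with `subject_id` plus the columns of
#'   [fit_perception_subject()].
#' @param stimuli Centered stimulus table.
#' @param shrinkage Use the two-stage empirical-Bayes MAP mode?
#' @inheritParams fit_perception_subject
#' @return A tibble, one row per subject, with a `fit` list-column of
#'   `perception_fit` objects, the task-relevant summaries from
#'   [extract_bias_sensitivity()], `loglik` and `converged`.
#' @export
fit_perception <- function(trials, stimuli, restarts = 8, min_trials = 20,
                           shrinkage = FALSE) {
  split_trials <- split(tibble::as_tibble(trials), trials$subject_id)
  fits <- purrr::map(split_trials, fit_perception_subject, stimuli = stimuli,
                     restarts = restarts, min_trials = min_trials)
  if (shrinkage) {
    prior <- perception_hyper_prior(fits)
    fits <- purrr::map(split_trials, fit_perception_subject, stimuli = stimuli,
                       restarts = restarts, min_trials = min_trials,
                       prior = prior)
  }
  summaries <- purrr::map(fits, function(f) extract_bias_sensitivity(f$params))
  dplyr::bind_cols(
    tibble::tibble(subject_id = names(split_trials), fit = unname(fits)),
    dplyr::bind_rows(summaries),
    tibble::tibble(
      loglik = purrr::map_dbl(fits, "loglik"),
      converged = purrr::map_lgl(fits, "converged")
    )
  )
}

# per-condition Normal hyper-priors from first-stage MLEs; SDs are floored so
# a degenerate first stage cannot pin parameters
perception_hyper_prior <- function(fits) {
  prior <- list()
  for (cond in perception_conditions) {
    mat <- vapply(fits, function(f) {
      p <- f$params
      c(p$bias[cond], p$S[cond, ], p$a[cond], p$ndt[cond], p$z[cond])
    }, numeric(7))
    prior[[cond]] <- list(mean = rowMeans(mat),
                          sd = pmax(apply(mat, 1, sd), 0.1))
  }
  prior
}

#' Task-relevant bias and sensitivity summaries
#'
#' Pure projection of the fitted parameter set onto the scalars used in the
#' individual-differences analyses: the diagonal (task-relevant)
#' sensitivities and the three evidence biases.
#'
#' @param params A [perception_params()] object (or a `perception_fit`).
#' @return One-row tibble with `S_merit`, `S_need`, `S_control`,
#'   `Bias_merit`, `Bias_need`, `Bias_control`.
#' @export
extract_bias_sensitivity <- function(params) {
  if (inherits(params, "perception_fit")) params <- params$params
  stopifnot(inherits(params, "perception_params"))
  tibble::tibble(
    S_merit = params$S["merit", "merit"],
    S_need = params$S["need", "need"],
    S_control = params$S["control", "control"],
    Bias_merit = params$bias[["merit"]],
    Bias_need = params$bias[["need"]],
    Bias_control = params$bias[["control"]]
  )
}

#' Check task-relevant dominance of the sensitivity matrix
#'
#' For each judged condition, reports whether the task-relevant sensitivity
#' exceeds both task-irrelevant ones (`S[c, c] > S[c, d]` for all `d != c`).
#'
#' @inheritParams extract_bias_sensitivity
#' @return Tibble with columns `condition` and `task_relevant_dominant`.
#' @export
task_relevance_check <- function(params) {
  if (inherits(params, "perception_fit")) params <- params$params
  stopifnot(inherits(params, "perception_params"))
  dominant <- vapply(perception_conditions, function(cond) {
    s <- params$S[cond, ]
    all(s[cond] > s[setdiff(evidence_dims, cond)])
  }, logical(1))
  tibble::tibble(condition = perception_conditions,
                 task_relevant_dominant = unname(dominant))
}

#' Serialize perception parameters to JSON
#'
#' All 21 parameters are written as decimal text at full double precision and
#' round-trip within 1e-12; optional fit metadata (seed, restarts, loglik) is
#' stored alongside.
#'
#' @param params A [perception_params()] object.
#' @param path Output file path.
#' @param meta Optional named list of metadata.
#' @return `path`, invisibly.
#' @export
write_perception_params <- function(params, path, meta = NULL) {
  stopifnot(inherits(params, "perception_params"))
  payload <- list(
    bias = as.list(params$bias),
    S = lapply(perception_conditions, function(cond) as.list(params$S[cond, ])),
    a = as.list(params$a), ndt = as.list(params$ndt), z = as.list(params$z)
  )
  names(payload$S) <- perception_conditions
  if (!is.null(meta)) payload$meta <- meta
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_perception_params
#' @export
read_perception_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- do.call(rbind, lapply(perception_conditions, function(cond) {
    unlist(x$S[[cond]])[evidence_dims]
  }))
  perception_params(bias = unlist(x$bias), S = S, a = unlist(x$a),
                    ndt = unlist(x$ndt), z = unlist(x$z))
}

#' @export
tidy.perception_fit <- function(x, ...) {
  p <- x$params
  dplyr::bind_rows(
    tibble::tibble(term = paste0("Bias_", perception_conditions),
                   condition = perception_conditions,
                   estimate = unname(p$bias)),
    tidyr::crossing(condition = perception_conditions, dim = evidence_dims) |>
      dplyr::mutate(term = paste0("S_", .data$dim, "|", .data$condition),
                    estimate = purrr::map2_dbl(.data$condition, .data$dim,
                                               function(i, j) p$S[i, j])) |>
      dplyr::select("term", "condition", "estimate"),
    tibble::tibble(term = c(paste0("a_", perception_conditions),
                            paste0("ndt_", perception_conditions),
                            paste0("z_", perception_conditions)),
                   condition = rep(perception_conditions, 3),
                   estimate = c(unname(p$a), unname(p$ndt), unname(p$z)))
  )
}

#' @export
glance.perception_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 n_trials = x$n_trials, n_parameters = 21L)
}
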