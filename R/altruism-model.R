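#' Trial attributes of a proposed allocation
#'
#' Maps a proposal's payoffs onto the three value attributes of the
#' altruistic-choice model: payoff changes relative to the constant default
#' allocation, rescaled by 10, and a non-positive fairness term.
#' `Self = (offer_self - default) / 10`, `Other = (offer_other - default) / 10`,
#' `Fairness = -|Other - Self|` (computed on the rescaled differences).
#'
#' @param offer_self,offer_other Proposed payoffs in dollars (vectorised).
#' @param default Default payoff each player keeps if the proposal is
#'   rejected (default $20).
#' @return Tibble with columns `self`, `other`, `fairness`.
#' @examples
#' compute_attributes(13, 35)  # self -0.7, other 1.5, fairness -2.2
#' @export
compute_attributes <- function(offer_self, offer_other, default = 20) {
  if (any(!is.finite(offer_self)) || any(!is.finite(offer_other)) ||
      any(offer_self < 0) || any(offer_other < 0)) {
    abort("offers must be finite and non-negative.", class = "socialddm_domain_error")
  }
  self <- (offer_self - default) / 10
  other <- (offer_other - default) / 10
  tibble::tibble(self = self, other = other, fairness = -abs(other - self))
}

merit_levels <- c("high", "unknown", "low")
need_levels <- c("high", "low")
weight_names <- c("w0", "self", "other", "fairness")
delta_names <- c("merit_high", "merit_low", "need_high")

#' Construct a subject-level altruism parameter set
#'
#' The altruistic-choice model accumulates value evidence
#' `V = w0 + w_self * Self + w_other * Other + w_fairness * Fairness` toward
#' accept (upper) or reject (lower) boundaries. Each of the four weights has
#' a baseline (at the reference condition: unknown merit, low need) and three
#' additive change parameters: the effects of raising merit to high, lowering
#' it to low, and raising need to high. `a`, `ndt` and `z` are shared across
#' the six merit-by-need conditions.
#'
#' @param weights Named numeric of length 4 (`w0`, `self`, `other`,
#'   `fairness`): baseline weights.
#' @param delta 4x3 numeric matrix of change parameters; rows are the four
#'   weights, columns `merit_high`, `merit_low`, `need_high`.
#' @param a Boundary separation (> 0).
#' @param ndt Non-decision time (>= 0).
#' @param z Start fraction in (0, 1).
#' @return An object of class `altruism_params`.
#' @export
altruism_params <- function(weights, delta, a, ndt, z) {
  delta <- as.matrix(delta)
  dimnames(delta) <- list(weight_names, delta_names)
  if (!is.null(names(weights))) weights <- weights[weight_names]
  weights <- setNames(as.numeric(weights), weight_names)
  if (any(!is.finite(c(weights, delta, a, ndt, z)))) {
    abort("all altruism parameters must be finite.", class = "socialddm_domain_error")
  }
  if (a <= 0 || ndt < 0 || z <= 0 || z >= 1) {
    abort("need a > 0, ndt >= 0, 0 < z < 1.", class = "socialddm_domain_error")
  }
  structure(list(weights = weights, delta = delta, a = a, ndt = ndt, z = z),
            class = "altruism_params")
}

#' @export
print.altruism_params <- function(x, ...) {
  cat("<altruism_params>\n  baseline weights:",
      sprintf("%s=%.3f", names(x$weights), x$weights), "\n")
  cat("  change parameters:\n")
  print(round(x$delta, 3))
  cat(sprintf("  a=%.3f, ndt=%.3f, z=%.3f\n", x$a, x$ndt, x$z))
  invisible(x)
}

#' Condition-resolved attribute weights
#'
#' Weights for a merit-by-need cell compose linearly from the baselines and
#' change parameters; the reference condition (unknown merit, low need)
#' returns the baselines. There is no merit-by-need interaction term.
#'
#' @param params An [altruism_params()] object.
#' @param merit `"high"`, `"unknown"`, or `"low"`.
#' @param need `"high"` or `"low"`.
#' @return Named numeric of length 4 (`w0`, `self`, `other`, `fairness`).
#' @export
condition_weights <- function(params, merit, need) {
  stopifnot(inherits(params, "altruism_params"))
  if (!merit %in% merit_levels) {
    abort(paste0("unknown merit level: ", merit), class = "socialddm_domain_error")
  }
  if (!need %in% need_levels) {
    abort(paste0("unknown need level: ", need), class = "socialddm_domain_error")
  }
  w <- params$weights
  if (merit == "high") w <- w + params$delta[, "merit_high"]
  if (merit == "low") w <- w + params$delta[, "merit_low"]
  if (need == "high") w <- w + params$delta[, "need_high"]
  w
}

#' All six condition-resolved weight vectors
#'
#' @inheritParams condition_weights
#' @return Tibble with columns `merit`, `need`, `w0`, `self`, `other`,
#'   `fairness` (6 rows).
#' @export
condition_weight_table <- function(params) {
  grid <- tidyr::crossing(merit = merit_levels, need = need_levels)
  ws <- purrr::map2(grid$merit, grid$need,
                    function(m, n) condition_weights(params, m, n))
  dplyr::bind_cols(grid, dplyr::bind_rows(purrr::map(ws, as.list)))
}

#' Drift rate for altruism trials
#'
#' `v = w0 + w_self * Self + w_other * Other + w_fairness * Fairness`;
#' accept maps to the upper boundary.
#'
#' @param weights Named numeric of length 4 as returned by
#'   [condition_weights()].
#' @param attrs Attribute tibble from [compute_attributes()] (columns `self`,
#'   `other`, `fairness`).
#' @return Numeric drift vector, one element per attribute row.
#' @export
altruism_drift <- function(weights, attrs) {
  weights[["w0"]] + weights[["self"]] * attrs$self +
    weights[["other"]] * attrs$other + weights[["fairness"]] * attrs$fairness
}

# 19-parameter vector layout used by the optimizer
altruism_theta_pack <- function(params) {
  c(params$weights, as.numeric(params$delta), params$a, params$ndt, params$z)
}

altruism_theta_unpack <- function(theta) {
  altruism_params(
    weights = setNames(theta[1:4], weight_names),
    delta = matrix(theta[5:16], nrow = 4,
                   dimnames = list(weight_names, delta_names)),
    a = theta[17], ndt = theta[18], z = theta[19]
  )
}

altruism_nll_factory <- function(trials) {
  attrs <- compute_attributes(trials$offer_self, trials$offer_other)
  X <- cbind(1, attrs$self, attrs$other, attrs$fairness)  # n x 4
  Xmh <- X * (trials$partner_merit == "high")
  Xml <- X * (trials$partner_merit == "low")
  Xnh <- X * (trials$need_level == "high")
  upper <- trials$response == "accept"
  rt <- trials$rt
  n <- length(rt)
  function(theta, prior = NULL) {
    v <- drop(X %*% theta[1:4] + Xmh %*% theta[5:8] + Xml %*% theta[9:12] +
                Xnh %*% theta[13:16])
    ll <- sum(pmax(cpp_wfpt_logdensity(rt, upper, v, rep.int(theta[17], n),
                                       rep.int(theta[19], n),
                                       rep.int(theta[18], n), 1, 1e-7), -1e10))
    if (!is.null(prior)) ll <- ll + sum(dnorm(theta, prior$mean, prior$sd, log = TRUE))
    if (!is.finite(ll)) 1e12 else -ll
  }
}

altruism_bounds <- function(min_rt) {
  list(lower = c(rep(-10, 4), rep(-5, 12), 0.3, 0.05, 0.05),
       upper = c(rep(10, 4), rep(5, 12), 5, max(0.06, min_rt - 0.01), 0.95))
}

#' Fit the altruistic-choice model to one subject
#'
#' Maximum-likelihood estimation of the 19 parameters (4 baseline weights, 12
#' change parameters, shared `a`, `ndt`, `z`) from accept/reject choices and
#' response times, via bounded L-BFGS-B with multi-start. The first start is
#' data-driven (logistic regression of choices on the attributes); the
#' remaining starts are jittered. Accept maps to the upper boundary.
#'
#' @param trials Data frame with columns `partner_merit`, `need_level`,
#'   `offer_self`, `offer_other`, `response` (`"accept"`/`"reject"`), `rt`.
#' @param restarts Number of optimizer starts (default 8).
#' @param min_trials_per_cell Warn if any merit-by-need cell has fewer usable
#'   trials than this (default 25); an empty cell is an error.
#' @param prior Optional shrinkage prior (list of `mean`, `sd` vectors of
#'   length 19), as used by the empirical-Bayes mode of [fit_altruism()].
#' @return An object of class `altruism_fit`: list with `params`
#'   ([altruism_params()]), `loglik`, `converged`, `n_trials`.
#' @export
fit_altruism_subject <- function(trials, restarts = 8, min_trials_per_cell = 25,
                                 prior = NULL) {
  needed <- c("partner_merit", "need_level", "offer_self", "offer_other",
              "response", "rt")
  stopifnot(all(needed %in% names(trials)))
  usable <- trials[!is.na(trials$response) & !is.na(trials$rt) & trials$rt > 0, ]
  cells <- table(factor(usable$partner_merit, merit_levels),
                 factor(usable$need_level, need_levels))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    abort(paste0("empty merit x need cell(s): ",
                 paste(sprintf("(%s, %s)", merit_levels[empty[, 1]],
                               need_levels[empty[, 2]]), collapse = ", ")),
          class = "socialddm_input_error")
  }
  if (any(cells < min_trials_per_cell)) {
    warn(sprintf("some merit x need cells have fewer than %d usable trials.",
                 min_trials_per_cell))
  }
  nll <- altruism_nll_factory(usable)
  b <- altruism_bounds(min(usable$rt))

  a0 <- 1.8
  attrs <- compute_attributes(usable$offer_self, usable$offer_other)
  co <- tryCatch(
    coef(suppressWarnings(glm((usable$response == "accept") ~ attrs$self +
                                attrs$other + attrs$fairness,
                              family = binomial()))),
    error = function(e) rep(0, 4)
  )
  co[!is.finite(co)] <- 0
  start <- c(pmin(pmax(co / a0, -8), 8), rep(0, 12), a0,
             min(0.4, 0.8 * min(usable$rt)), 0.5)

  starts <- list(start)
  if (restarts > 1) {
    for (i in seq_len(restarts - 1)) {
      jit <- start
      jit[1:4] <- start[1:4] + rnorm(4, 0, 0.5)
      jit[5:16] <- rnorm(12, 0, 0.2)
      jit[17] <- runif(1, 0.8, 3)
      jit[18] <- runif(1, b$lower[18], b$upper[18])
      jit[19] <- runif(1, 0.35, 0.65)
      starts[[i + 1]] <- pmin(pmax(jit, b$lower + 1e-6), b$upper - 1e-6)
    }
  }
  fits <- lapply(starts, function(s) {
    tryCatch(
      optim(s, nll, prior = prior, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(maxit = 500, factr = 1e8)),
      error = function(e) list(value = Inf, par = s, convergence = 99L)
    )
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  converged <- best$convergence == 0L
  if (!converged) warn("altruism fit did not converge from any start.")
  structure(list(params = altruism_theta_unpack(unname(best$par)),
                 loglik = -best$value,
                 converged = converged,
                 n_trials = nrow(usable)),
            class = "altruism_fit")
}

#' @export
print.altruism_fit <- function(x, ...) {
  cat(sprintf("<altruism_fit> loglik = %.2f over %d trials; converged: %s\n",
              x$loglik, x$n_trials, x$converged))
  print(x$params)
  invisible(x)
}

#' Fit the altruism model across a cohort
#'
#' Per-subject maximum likelihood by default; `shrinkage = TRUE` adds the
#' same two-stage empirical-Bayes MAP refit used by [fit_perception()].
#'
#' @param trials Data frame with `subject_id` plus the columns of
#'   [fit_altruism_subject()].
#' @inheritParams fit_altruism_subject
#' @param shrinkage Use the two-stage empirical-Bayes MAP mode?
#' @return A tibble, one row per subject, with a `fit` list-column, the
#'   change scores and overall weights from [change_scores()], `loglik` and
#'   `converged`.
#' @export
fit_altruism <- function(trials, restarts = 8, min_trials_per_cell = 25,
                         shrinkage = FALSE) {
  split_trials <- split(tibble::as_tibble(trials), trials$subject_id)
  fits <- purrr::map(split_trials, fit_altruism_subject, restarts = restarts,
                     min_trials_per_cell = min_trials_per_cell)
  if (shrinkage) {
    mat <- vapply(fits, function(f) altruism_theta_pack(f$params), numeric(19))
    prior <- list(mean = rowMeans(mat), sd = pmax(apply(mat, 1, sd), 0.1))
    fits <- purrr::map(split_trials, fit_altruism_subject, restarts = restarts,
                       min_trials_per_cell = min_trials_per_cell, prior = prior)
  }
  dplyr::bind_cols(
    tibble::tibble(subject_id = names(split_trials), fit = unname(fits)),
    dplyr::bind_rows(purrr::map(fits, function(f) change_scores(f$params))),
    tibble::tibble(
      loglik = purrr::map_dbl(fits, "loglik"),
      converged = purrr::map_lgl(fits, "converged")
    )
  )
}

#' Change scores and overall weights
#'
#' Per-attribute condition differences of the condition-resolved weights:
#' the merit change is high-minus-low merit (`delta_merit_high -
#' delta_merit_low`), the need change is high-minus-low need
#' (`delta_need_high`). The overall weight is the unweighted mean over the
#' six merit-by-need cells.
#'
#' @param params An [altruism_params()] object (or an `altruism_fit`).
#' @return One-row tibble with `dw_self_merit`, `dw_other_merit`,
#'   `dw_fairness_merit`, `dw_self_need`, `dw_other_need`,
#'   `dw_fairness_need`, `overall_w0`, `overall_w_self`, `overall_w_other`,
#'   `overall_w_fairness`.
#' @export
change_scores <- function(params) {
  if (inherits(params, "altruism_fit")) params <- params$params
  stopifnot(inherits(params, "altruism_params"))
  d <- params$delta
  overall <- params$weights + (d[, "merit_high"] + d[, "merit_low"]) / 3 +
    d[, "need_high"] / 2
  tibble::tibble(
    dw_self_merit = d["self", "merit_high"] - d["self", "merit_low"],
    dw_other_merit = d["other", "merit_high"] - d["other", "merit_low"],
    dw_fairness_merit = d["fairness", "merit_high"] - d["fairness", "merit_low"],
    dw_self_need = d["self", "need_high"],
    dw_other_need = d["other", "need_high"],
    dw_fairness_need = d["fairness", "need_high"],
    overall_w0 = overall[["w0"]],
    overall_w_self = overall[["self"]],
    overall_w_other = overall[["other"]],
    overall_w_fairness = overall[["fairness"]]
  )
}

#' Serialize altruism parameters to JSON
#'
#' The 19 named parameters round-trip at full double precision; optional fit
#' metadata is stored alongside.
#'
#' @param params An [altruism_params()] object.
#' @param path Output file path.
#' @param meta Optional named list of metadata.
#' @return `path`, invisibly.
#' @export
write_altruism_params <- function(params, path, meta = NULL) {
  stopifnot(inherits(params, "altruism_params"))
  payload <- list(
    weights = as.list(params$weights),
    delta = lapply(weight_names, function(wn) as.list(params$delta[wn, ])),
    a = params$a, ndt = params$ndt, z = params$z
  )
  names(payload$delta) <- weight_names
  if (!is.null(meta)) payload$meta <- meta
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_altruism_params
#' @export
read_altruism_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  delta <- do.call(rbind, lapply(weight_names, function(wn) {
    unlist(x$delta[[wn]])[delta_names]
  }))
  altruism_params(weights = unlist(x$weights), delta = delta,
                  a = x$a, ndt = x$ndt, z = x$z)
}

#' @export
tidy.altruism_fit <- function(x, ...) {
  p <- x$params
  dplyr::bind_rows(
    tibble::tibble(term = paste0("w_", weight_names), type = "baseline",
                   estimate = unname(p$weights)),
    tidyr::crossing(wn = weight_names, dn = delta_names) |>
      dplyr::mutate(term = paste0("delta_", .data$dn, "(w_", .data$wn, ")"),
                    type = "change",
                    estimate = purrr::map2_dbl(.data$wn, .data$dn,
                                               function(i, j) p$delta[i, j])) |>
      dplyr::select("term", "type", "estimate"),
    tibble::tibble(term = c("a", "ndt", "z"), type = "ddm",
                   estimate = c(p$a, p$ndt, p$z))
  )
}

#' @export
glance.altruism_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 n_trials = x$n_trials, n_parameters = 19L)
}
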