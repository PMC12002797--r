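#' Mixed-effects logistic regression of generous choice
#'
#' Fits `generous ~ 1 + need + merit + need:merit + (1 | subject)` with a
#' logistic link and a participant random intercept (Laplace-approximated
#' marginal likelihood via `lme4::glmer`). Reference levels are low need and
#' low merit. Reports fixed effects with Wald 95% CIs, the random-intercept
#' SD, Nakagawa marginal/conditional pseudo-R², and likelihood-ratio tests of
#' the full model against (i) the intercept-plus-random-effect null and (ii)
#' the main-effects-only model.
#'
#' @param trials Data frame with `subject_id`, `partner_merit`, `need_level`,
#'   `offer_self`, `offer_other`, `response` (unclassifiable trials are
#'   dropped), or an already-classified 0/1 column `generous`.
#' @return An object of class `generosity_glmm`: list with `fixed` (tidy
#'   tibble of estimates, SEs, CIs, z, p), `ranef_sd`, `r_squared` (marginal
#'   and conditional), `lrt_null`, `lrt_interaction`, `separation_flag`, and
#'   the fitted `lme4` models.
#' @export
fit_generosity_glmm <- function(trials) {
  tr <- tibble::as_tibble(trials)
  if (!"generous" %in% names(tr)) {
    tr$generous <- classify_generous(tr$response, tr$offer_self, tr$offer_other)
  }
  tr <- tr[!is.na(tr$generous), ]
  if (length(unique(tr$subject_id)) < 2) {
    abort("need at least 2 subjects.", class = "socialddm_input_error")
  }
  if (!all(need_levels %in% tr$need_level) || !all(merit_levels %in% tr$partner_merit)) {
    abort("both need levels and all three merit levels must be present.",
          class = "socialddm_input_error")
  }
  tr$need <- factor(tr$need_level, levels = c("low", "high"))
  tr$merit <- factor(tr$partner_merit, levels = c("low", "unknown", "high"))
  tr$subject_id <- factor(tr$subject_id)

  full <- lme4::glmer(generous ~ need * merit + (1 | subject_id),
                      data = tr, family = binomial())
  main <- lme4::glmer(generous ~ need + merit + (1 | subject_id),
                      data = tr, family = binomial())
  null <- lme4::glmer(generous ~ 1 + (1 | subject_id),
                      data = tr, family = binomial())

  fe <- lme4::fixef(full)
  se <- sqrt(diag(as.matrix(vcov(full))))
  separation <- any(abs(fe) > 10) || any(se > 10)
  if (separation) {
    warn(paste("possible complete separation detected; refitting fixed effects",
               "with cell-mean data augmentation (half a success and half a",
               "failure added per need x merit cell)."))
    aug <- tidyr::crossing(need = levels(tr$need), merit = levels(tr$merit),
                           generous = c(0L, 1L),
                           subject_id = levels(tr$subject_id)[1])
    aug$need <- factor(aug$need, levels(tr$need))
    aug$merit <- factor(aug$merit, levels(tr$merit))
    aug$subject_id <- factor(aug$subject_id, levels(tr$subject_id))
    w <- c(rep(1, nrow(tr)), rep(0.5, nrow(aug)))
    tr2 <- dplyr::bind_rows(tr[c("generous", "need", "merit", "subject_id")], aug)
    full <- suppressWarnings(
      lme4::glmer(generous ~ need * merit + (1 | subject_id), data = tr2,
                  family = binomial(), weights = w))
    fe <- lme4::fixef(full)
    se <- sqrt(diag(as.matrix(vcov(full))))
  }
  z <- fe / se
  fixed <- tibble::tibble(
    term = names(fe), estimate = unname(fe), std_error = unname(se),
    conf_low = unname(fe - qnorm(0.975) * se),
    conf_high = unname(fe + qnorm(0.975) * se),
    statistic = unname(z), p_value = unname(2 * pnorm(-abs(z)))
  )

  vc <- lme4::VarCorr(full)
  ranef_sd <- attr(vc$subject_id, "stddev")[[1]]
  # Nakagawa pseudo-R2 with the logistic distribution-specific variance
  var_f <- stats::var(drop(stats::model.matrix(full) %*% fe))
  var_r <- ranef_sd^2
  var_d <- pi^2 / 3
  r2 <- c(marginal = var_f / (var_f + var_r + var_d),
          conditional = (var_f + var_r) / (var_f + var_r + var_d))

  lrt <- function(big, small) {
    stat <- as.numeric(2 * (logLik(big) - logLik(small)))
    df <- attr(logLik(big), "df") - attr(logLik(small), "df")
    c(chisq = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
  }
  structure(list(
    fixed = fixed, ranef_sd = ranef_sd, r_squared = r2,
    lrt_null = lrt(full, null),
    lrt_interaction = lrt(full, main),
    separation_flag = separation,
    models = list(full = full, main = main, null = null)
  ), class = "generosity_glmm")
}

#' @export
print.generosity_glmm <- function(x, ...) {
  cat("<generosity_glmm> generous ~ need * merit + (1 | subject)\n")
  print(as.data.frame(x$fixed), digits = 3)
  cat(sprintf("random-intercept SD: %.3f | R2 marginal %.3f, conditional %.3f\n",
              x$ranef_sd, x$r_squared["marginal"], x$r_squared["conditional"]))
  cat(sprintf("LRT vs null: chisq(%d) = %.2f, p = %.3g\n",
              as.integer(x$lrt_null["df"]), x$lrt_null["chisq"], x$lrt_null["p_value"]))
  cat(sprintf("LRT interaction: chisq(%d) = %.2f, p = %.3g\n",
              as.integer(x$lrt_interaction["df"]), x$lrt_interaction["chisq"],
              x$lrt_interaction["p_value"]))
  invisible(x)
}

#' @export
tidy.generosity_glmm <- function(x, ...) x$fixed

#' @export
glance.generosity_glmm <- function(x, ...) {
  tibble::tibble(
    r2_marginal = x$r_squared[["marginal"]],
    r2_conditional = x$r_squared[["conditional"]],
    ranef_sd = x$ranef_sd,
    lrt_null_chisq = x$lrt_null[["chisq"]],
    lrt_null_p = x$lrt_null[["p_value"]],
    lrt_interaction_chisq = x$lrt_interaction[["chisq"]],
    lrt_interaction_p = x$lrt_interaction[["p_value"]],
    separation_flag = x$separation_flag
  )
}

#' Wilcoxon contrasts of condition-resolved weights
#'
#' Paired Wilcoxon signed-rank tests of each attribute weight between high
#' and low merit and between high and low need, Benjamini-Hochberg adjusted
#' over the six contrasts. The exact distribution is used for n <= 25
#' (without ties/zeros), the Normal approximation otherwise. A contrast whose
#' paired differences are all zero is undefined and reported with p = 1 and a
#' flag.
#'
#' @param altruism_fits A [fit_altruism()] cohort tibble (or any tibble with
#'   a `fit` list-column of `altruism_fit`/`altruism_params`).
#' @return Tibble with `attribute`, `contrast`, `statistic`, `p_value`,
#'   `p_adjusted`, `undefined`.
#' @export
weight_condition_contrasts <- function(altruism_fits) {
  tables <- purrr::map(altruism_fits$fit, function(f) {
    condition_weight_table(if (inherits(f, "altruism_fit")) f$params else f)
  })
  grid <- tidyr::crossing(attribute = c("self", "other", "fairness"),
                          contrast = c("merit", "need"))
  res <- purrr::pmap(grid, function(attribute, contrast) {
    pairs <- vapply(tables, function(tb) {
      if (contrast == "merit") {
        hi <- mean(tb[[attribute]][tb$merit == "high"])
        lo <- mean(tb[[attribute]][tb$merit == "low"])
      } else {
        hi <- mean(tb[[attribute]][tb$need == "high"])
        lo <- mean(tb[[attribute]][tb$need == "low"])
      }
      hi - lo
    }, numeric(1))
    if (all(pairs == 0)) {
      return(tibble::tibble(statistic = NA_real_, p_value = 1, undefined = TRUE))
    }
    n <- length(pairs)
    wt <- suppressWarnings(wilcox.test(pairs, exact = n <= 25, correct = TRUE))
    tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                   undefined = FALSE)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out[c("attribute", "contrast", "statistic", "p_value", "p_adjusted", "undefined")]
}

#' Spearman correlations with FDR correction within a family
#'
#' Rank correlations with midrank ties over a declared family of variable
#' pairs, each screened by [remove_outliers_3sd()] first (pairwise: a subject
#' flagged in either member of a pair is dropped for that pair). Two-tailed
#' p-values use the t approximation for n > 10 and the exact permutation
#' distribution for n <= 10 (when there are no ties); Benjamini-Hochberg
#' adjustment is applied within the family.
#'
#' @param data Data frame, one row per subject.
#' @param pairs List of length-2 character vectors naming the x/y columns of
#'   each correlation in the family.
#' @param screen_outliers Apply the 3-SD rule before correlating (default
#'   `TRUE`).
#' @return Tibble with `x`, `y`, `n`, `rho`, `p_value`, `p_adjusted`,
#'   `flag` (`"constant input"` when a member is constant).
#' @export
spearman_fdr <- function(data, pairs, screen_outliers = TRUE) {
  res <- purrr::map(pairs, function(pr) {
    x <- data[[pr[1]]]
    y <- data[[pr[2]]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (screen_outliers) {
      keep <- !(seq_along(x) %in% remove_outliers_3sd(x)$removed) &
        !(seq_along(y) %in% remove_outliers_3sd(y)$removed)
      x <- x[keep]; y <- y[keep]
    }
    n <- length(x)
    if (n < 5) {
      abort(sprintf("fewer than 5 complete observations for (%s, %s).",
                    pr[1], pr[2]), class = "socialddm_input_error")
    }
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(x = pr[1], y = pr[2], n = n, rho = NA_real_,
                            p_value = NA_real_, flag = "constant input"))
    }
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = n <= 10))
    tibble::tibble(x = pr[1], y = pr[2], n = n, rho = unname(ct$estimate),
                   p_value = ct$p.value, flag = NA_character_)
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out[c("x", "y", "n", "rho", "p_value", "p_adjusted", "flag")]
}

#' Remove 3-SD outliers
#'
#' Single-pass screen: values farther than three standard deviations from the
#' mean are removed, with mean and SD computed once on the full vector. A
#' zero-variance vector removes nothing.
#'
#' @param values Numeric vector, length >= 3.
#' @return List with `values` (kept), `removed` (integer indices into the
#'   input) and `n_removed`.
#' @export
remove_outliers_3sd <- function(values) {
  if (length(values) < 3) {
    abort("need at least 3 values.", class = "socialddm_input_error")
  }
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  removed <- if (is.na(s) || s == 0) integer(0) else {
    which(abs(values - m) > 3 * s)
  }
  list(values = if (length(removed)) values[-removed] else values,
       removed = removed, n_removed = length(removed))
}

#' Perception-to-action linking regression
#'
#' Ordinary least squares of a merit-related change score on perceptual merit
#' sensitivity and the rTPJ covariate:
#' `dw ~ 1 + S_merit + rTPJ`. Reports coefficients with SEs, 95% CIs,
#' t statistics and two-tailed p-values, the model R², and a likelihood-ratio
#' comparison against the intercept-only model. Predictors correlated beyond
#' |r| > 0.99 are flagged as collinear.
#'
#' @param dw Response vector (e.g. merit-related change in `w_other`).
#' @param s_merit Perceptual merit-sensitivity vector.
#' @param rtpj Neural covariate vector.
#' @return An object of class `linking_regression`: list with `coefficients`
#'   (tidy tibble), `r_squared`, `lrt` (chisq, df, p), `collinearity_flag`,
#'   and the `lm` fit.
#' @export
linking_regression <- function(dw, s_merit, rtpj) {
  stopifnot(length(dw) == length(s_merit), length(dw) == length(rtpj))
  if (anyNA(c(dw, s_merit, rtpj))) {
    abort("inputs must be screened: no missing values allowed.",
          class = "socialddm_input_error")
  }
  collinear <- abs(cor(s_merit, rtpj)) > 0.99
  if (collinear) warn("predictors are collinear (|r| > 0.99); estimates unstable.")
  df <- tibble::tibble(dw = dw, s_merit = s_merit, rtpj = rtpj)
  fit <- lm(dw ~ s_merit + rtpj, data = df)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(confint(fit))[rownames(sm$coefficients), , drop = FALSE]
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, 1]),
    std_error = unname(sm$coefficients[, 2]),
    conf_low = unname(ci[, 1]), conf_high = unname(ci[, 2]),
    statistic = unname(sm$coefficients[, 3]),
    p_value = unname(sm$coefficients[, 4])
  )
  null <- lm(dw ~ 1, data = df)
  stat <- as.numeric(2 * (logLik(fit) - logLik(null)))
  structure(list(
    coefficients = coefs, r_squared = sm$r.squared,
    lrt = c(chisq = stat, df = 2,
            p_value = pchisq(stat, 2, lower.tail = FALSE)),
    collinearity_flag = collinear, fit = fit
  ), class = "linking_regression")
}

#' @export
print.linking_regression <- function(x, ...) {
  cat("<linking_regression> dw ~ 1 + S_merit + rTPJ\n")
  print(as.data.frame(x$coefficients), digits = 3)
  cat(sprintf("R2 = %.3f; LRT vs intercept-only: chisq(2) = %.2f, p = %.3g\n",
              x$r_squared, x$lrt["chisq"], x$lrt["p_value"]))
  invisible(x)
}

#' @export
tidy.linking_regression <- function(x, ...) x$coefficients

#' @export
glance.linking_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, lrt_chisq = x$lrt[["chisq"]],
                 lrt_p = x$lrt[["p_value"]],
                 collinearity_flag = x$collinearity_flag)
}

#' Partial Spearman correlation
#'
#' Spearman correlation between the residuals of `x` and `y` after ordinary
#' least-squares regression of their midranks on the control's midranks. A
#' constant control reduces to the plain Spearman correlation (flagged).
#'
#' @param x,y,control Aligned numeric vectors, n >= 6.
#' @return Tibble with `rho`, `p_value`, `n`, `flag`.
#' @export
partial_spearman <- function(x, y, control) {
  n <- length(x)
  stopifnot(length(y) == n, length(control) == n)
  if (n < 6) abort("need n >= 6.", class = "socialddm_input_error")
  flag <- NA_character_
  if (sd(control) == 0) {
    flag <- "constant control; plain Spearman returned"
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    return(tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                          n = n, flag = flag))
  }
  rx <- rank(x); ry <- rank(y); rc <- rank(control)
  ex <- resid(lm(rx ~ rc))
  ey <- resid(lm(ry ~ rc))
  ct <- suppressWarnings(cor.test(ex, ey, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                 flag = flag)
}
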