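test_that("BH adjustment matches the brute-force definition", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
  expect_equal(bh_brute_force(p), rep(0.06, 6))
  expect_equal(p.adjust(p, method = "BH"), bh_brute_force(p))
  set.seed(4)
  for (i in 1:20) {
    pv <- runif(sample(3:12, 1))
    adj <- p.adjust(pv, method = "BH")
    expect_equal(adj, bh_brute_force(pv))
    # monotone in raw-p order and never below raw
    ord <- order(pv)
    expect_true(all(diff(adj[ord]) >= -1e-15))
    expect_true(all(adj >= pv - 1e-15))
  }
})

test_that("Spearman correlations hit the rank-formula oracle and extremes", {
  df <- tibble::tibble(x = c(3, 1, 4, 1.5, 9, 2.6),
                       y = c(2, 7, 1, 8, 2.8, 1.8),
                       x_mono = exp(c(3, 1, 4, 1.5, 9, 2.6)),
                       x_neg = -c(3, 1, 4, 1.5, 9, 2.6))
  res <- spearman_fdr(df, list(c("x", "y"), c("x", "x_mono"), c("x", "x_neg")),
                      screen_outliers = FALSE)
  expect_equal(res$rho[2], 1)
  expect_equal(res$rho[3], -1)
  expect_equal(res$rho[1], spearman_brute_force(df$x, df$y), tolerance = 1e-12)
  expect_equal(res$p_adjusted, p.adjust(res$p_value, "BH"))
  df$const <- 1
  flagged <- spearman_fdr(df, list(c("x", "const")), screen_outliers = FALSE)
  expect_equal(flagged$flag, "constant input")
})

test_that("3-SD screening is single-pass on full-vector moments", {
  v <- c(rep(0, 49), 100)
  out <- remove_outliers_3sd(v)
  expect_identical(out$removed, 50L)
  expect_equal(out$n_removed, 1)
  # brute-force z-score check
  expect_identical(out$removed, which(abs(v - mean(v)) > 3 * sd(v)))
  expect_equal(remove_outliers_3sd(rep(2, 10))$n_removed, 0)
  set.seed(6)
  tight <- runif(30, -1, 1)
  expect_equal(remove_outliers_3sd(tight)$n_removed, 0)
  expect_error(remove_outliers_3sd(c(1, 2)), class = "socialddm_input_error")
})

test_that("Wilcoxon contrasts find directional weight shifts and flag ties", {
  base <- altruism_params(weights = c(w0 = 0, self = 1, other = 0.2, fairness = 0.4),
                          delta = matrix(0, 4, 3), a = 1.8, ndt = 0.4, z = 0.5)
  # identical conditions in every subject: all tests undefined, p = 1
  flat <- tibble::tibble(fit = replicate(8, base, simplify = FALSE))
  res_flat <- weight_condition_contrasts(flat)
  expect_true(all(res_flat$undefined))
  expect_true(all(res_flat$p_value == 1))

  # every subject weighs self less under high merit
  set.seed(12)
  cohort <- tibble::tibble(fit = lapply(1:28, function(i) {
    d <- matrix(rnorm(12, 0, 0.02), 4, 3,
                dimnames = list(c("w0", "self", "other", "fairness"),
                                c("merit_high", "merit_low", "need_high")))
    d["self", "merit_high"] <- -abs(rnorm(1, 0.3, 0.05))
    d["self", "merit_low"] <- abs(rnorm(1, 0.3, 0.05))
    altruism_params(weights = c(w0 = 0, self = 1, other = 0.2, fairness = 0.4),
                    delta = d, a = 1.8, ndt = 0.4, z = 0.5)
  }))
  res <- weight_condition_contrasts(cohort)
  p_self_merit <- res$p_adjusted[res$attribute == "self" & res$contrast == "merit"]
  expect_lt(p_self_merit, 0.05)
})

test_that("signed-rank p-values match exact enumeration and are null-uniform", {
  set.seed(23)
  for (i in 1:5) {
    x <- rnorm(8)
    wt <- wilcox.test(x, exact = TRUE)
    expect_equal(wt$p.value, signed_rank_exact_p(x), tolerance = 1e-12)
  }
  pvals <- replicate(500, wilcox.test(rnorm(26), exact = FALSE,
                                      correct = TRUE)$p.value)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the generosity GLMM collapses to plain logistic without clustering", {
  set.seed(31)
  design <- generate_altruism_design()
  trials <- dplyr::bind_rows(lapply(1:12, function(i) {
    d <- design
    d$subject_id <- sprintf("s%02d", i)
    # no subject heterogeneity; mild need and merit effects on generosity
    eta <- -0.5 + 0.4 * (d$need_level == "high") +
      0.5 * (d$partner_merit == "high")
    d$generous <- rbinom(nrow(d), 1, plogis(eta))
    d
  }))
  fit <- fit_generosity_glmm(trials)
  ref <- glm(generous ~ factor(need_level, c("low", "high")) *
               factor(partner_merit, c("low", "unknown", "high")),
             data = trials, family = binomial())
  expect_lt(fit$ranef_sd, 0.05)
  expect_equal(unname(fit$fixed$estimate), unname(coef(ref)), tolerance = 1e-3)
  expect_true(all(c("marginal", "conditional") %in% names(fit$r_squared)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
})

test_that("the GLMM recovers a generating need effect with clustering", {
  set.seed(37)
  design <- generate_altruism_design()
  trials <- dplyr::bind_rows(lapply(1:25, function(i) {
    d <- design
    d$subject_id <- sprintf("s%02d", i)
    eta <- rnorm(1, -0.6, 0.8) + 0.4 * (d$need_level == "high") +
      0.6 * (d$partner_merit == "high") + 0.5 * (d$partner_merit == "unknown")
    d$generous <- rbinom(nrow(d), 1, plogis(eta))
    d
  }))
  fit <- fit_generosity_glmm(trials)
  b_need <- lme4::fixef(fit$models$main)[["needhigh"]]
  expect_lt(abs(b_need - 0.4), 0.2)
  expect_gt(fit$ranef_sd, 0.3)
  expect_lt(fit$lrt_null["p_value"], 0.001)
})

test_that("linking regression interpolates noiseless data and flags collinearity", {
  set.seed(41)
  s <- rnorm(25)
  r <- rnorm(25)
  dw <- 0.2 * s + 0.3 * r + 0.1
  fit <- linking_regression(dw, s, r)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$coefficients$estimate, c(0.1, 0.2, 0.3), tolerance = 1e-10)
  expect_false(fit$collinearity_flag)
  expect_warning(fit2 <- linking_regression(dw, s, 2 * s + 1e-9 * r),
                 regexp = "collinear")
  expect_true(fit2$collinearity_flag)
  expect_error(linking_regression(c(dw[-1], NA), s, r),
               class = "socialddm_input_error")
})

test_that("partial Spearman removes the control's contribution", {
  set.seed(43)
  ctrl <- rnorm(200)
  x <- rnorm(200)
  # fully explained response: partial association with x vanishes
  res0 <- partial_spearman(x, ctrl, ctrl)
  expect_lt(abs(res0$rho), 0.05)
  # identical variables stay perfectly associated
  res1 <- partial_spearman(x, x, ctrl)
  expect_equal(res1$rho, 1, tolerance = 1e-12)
  # an irrelevant control leaves the plain Spearman almost unchanged
  y <- 0.6 * x + 0.8 * rnorm(200)
  plain <- cor(x, y, method = "spearman")
  res2 <- partial_spearman(x, y, rnorm(200))
  expect_equal(res2$rho, plain, tolerance = 0.05)
  # constant control: flagged, reduces to plain Spearman
  res3 <- partial_spearman(x, y, rep(1, 200))
  expect_equal(res3$rho, plain, tolerance = 1e-12)
  expect_match(res3$flag, "constant control")
})
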