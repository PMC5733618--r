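test_that("AIC is the penalized deviance and reproduces printed cells", {
  expect_equal(aic(284.88, 2), 288.88)
  expect_equal(aic(253.88, 4), 261.88)
  expect_equal(aic(0, 0), 0)
  expect_error(aic(10, -1), "n_estimated")
  # linear in both arguments
  set.seed(11)
  x <- runif(5, 100, 400); k <- sample(0:8, 5, replace = TRUE)
  expect_equal(aic(x, k), x + 2 * k)
})

test_that("likelihood-ratio tests follow the chi-square recipe", {
  lrt <- likelihood_ratio_test(manual_fit("homogeneous_general", 193.78, 7),
                               manual_fit("general", 193.50, 8))
  expect_equal(lrt$chi2, 0.28)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p, pchisq(0.28, 1, lower.tail = FALSE))
  expect_equal(round(lrt$p, 2), 0.60)

  lrt2 <- likelihood_ratio_test(manual_fit("environmental", 204.44, 5),
                                manual_fit("general", 193.50, 8))
  expect_equal(lrt2$chi2, 10.94)
  expect_equal(lrt2$df, 3L)
  expect_equal(lrt2$p, 0.012, tolerance = 0.05)

  # identical fits: statistic zero, p = 1; better-fitting nested model floors
  same <- likelihood_ratio_test(manual_fit("a", 100, 2),
                                manual_fit("b", 100, 4))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  floored <- likelihood_ratio_test(manual_fit("a", 99.9, 2),
                                   manual_fit("b", 100, 4))
  expect_equal(floored$chi2, 0)

  expect_error(likelihood_ratio_test(manual_fit("a", 1, 4),
                                     manual_fit("b", 1, 4)), "nested")
  # p decreases in chi2 at fixed df
  ps <- vapply(c(1, 2, 5, 10), function(x)
    likelihood_ratio_test(manual_fit("a", 100 + x, 3),
                          manual_fit("b", 100, 5))$p, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("model comparison selects minimal AIC with parsimony tie-break", {
  fits <- list(manual_fit("general", 100, 8),
               manual_fit("m1", 104, 4),
               manual_fit("m2", 108, 2))   # AIC 116, 112, 112
  cmp <- compare_models(fits)
  expect_s3_class(cmp, "seg_comparison")
  expect_equal(best_model(cmp), "m2")      # tie broken by fewer parameters
  expect_equal(cmp$AIC, c(116, 112, 112))
  expect_equal(cmp$p_vs_general[1], NA_real_)
  expect_error(compare_models(fits, general_id = "nope"), "not among")
  pl <- ggplot2::autoplot(cmp)
  expect_s3_class(pl, "ggplot")
})

test_that("sporadic fits on singletons equal the analytic Bernoulli MLE", {
  set.seed(12)
  b_true <- -1.0
  n <- 2000
  aff <- runif(n) < susceptibility(b_true, 1)
  ped <- tibble::tibble(
    family_id = paste0("S", seq_len(n)), id = "1",
    father_id = NA_character_, mother_id = NA_character_,
    sex = "male", affection = ifelse(aff, "affected", "unaffected"),
    is_proband = FALSE)
  fit <- fit_model(ped, "sporadic_no_assoc", ascertainment = "none",
                   n_starts = 3, seed = 1)
  analytic <- qlogis(mean(aff))
  expect_true(fit$converged)
  expect_equal(fit$par_free[["beta"]], analytic, tolerance = 1e-3)
  expect_lt(abs(fit$par_free[["beta"]] - b_true), 0.15)
  # the fitted deviance equals the closed-form Bernoulli deviance
  expect_equal(fit$neg2lnL,
               -2 * sum(susceptibility(analytic, as.numeric(aff),
                                       log = TRUE)),
               tolerance = 1e-6)
})

test_that("refitting with an identical seed reproduces the fit bit for bit", {
  cfg <- sim_config(n_families = 6, min_affected = 2, seed = 31)
  ped <- simulate_study(cfg)
  f1 <- fit_model(ped, "dominant", n_starts = 4, seed = 9)
  f2 <- fit_model(ped, "dominant", n_starts = 4, seed = 9)
  expect_identical(f1$neg2lnL, f2$neg2lnL)
  expect_identical(f1$par_free, f2$par_free)
  expect_identical(unclass(f1$estimates), unclass(f2$estimates))
})

test_that("fits expose tidy() and glance() summaries", {
  cfg <- sim_config(n_families = 4, min_affected = 2, seed = 32)
  ped <- simulate_study(cfg)
  f <- fit_model(ped, "dominant", n_starts = 2, seed = 1)
  td <- tidy(f)
  expect_equal(nrow(td), 11)
  expect_true(all(c("beta_AA", "q_A", "tau_AB", "delta_SS") %in% td$term))
  expect_equal(td$estimate[td$term == "beta_AA"],
               td$estimate[td$term == "beta_AB"])
  expect_false(td$free[td$term == "tau_AA"])
  gl <- glance(f)
  expect_equal(gl$AIC, f$neg2lnL + 2 * f$n_estimated)
  expect_equal(gl$n_estimated, 4L)
})

test_that("the general fit is never worse than a nested fit on the same data", {
  cfg <- sim_config(n_families = 6, min_affected = 2, seed = 33)
  ped <- simulate_study(cfg)
  fd <- fit_model(ped, build_model_spec("dominant", assoc = "none"),
                  n_starts = 3, seed = 1)
  fg <- fit_model(ped, build_model_spec("general", assoc = "none"),
                  n_starts = 3, seed = 1,
                  start = c(beta_AA = fd$par_free[["beta_AAB"]],
                            beta_AB = fd$par_free[["beta_AAB"]],
                            beta_BB = fd$par_free[["beta_BB"]],
                            q_A = qlogis(fd$par_free[["q_A"]]),
                            tau_AA = 25, tau_AB = 0, tau_BB = -25))
  expect_lte(fg$neg2lnL, fd$neg2lnL + 1e-4)
})
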