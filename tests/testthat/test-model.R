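test_that("founder type frequencies are Hardy-Weinberg proportions", {
  expect_equal(unname(founder_type_probs(1)), c(1, 0, 0))
  expect_equal(unname(founder_type_probs(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(founder_type_probs(0.19)),
               c(0.0361, 0.3078, 0.6561))
  expect_error(founder_type_probs(1.2), "q_A")
  set.seed(1)
  for (q in runif(20)) expect_equal(sum(founder_type_probs(q)), 1)
})

test_that("offspring type distribution follows the transmission rule", {
  mend <- c(1, 0.5, 0)
  expect_equal(unname(offspring_type_probs("AA", "AA", mend)), c(1, 0, 0))
  expect_equal(unname(offspring_type_probs("AB", "AB", mend)),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(offspring_type_probs("AB", "AB", c(1, 0.999, 0))),
               c(0.998001, 0.001998, 0.000001))
  set.seed(2)
  for (r in 1:20) {
    tau <- runif(3)
    for (f in c("AA", "AB", "BB")) for (m in c("AA", "AB", "BB"))
      expect_equal(sum(offspring_type_probs(f, m, tau)), 1)
  }
})

test_that("the regressive logit adds association terms for realized relatives", {
  p2 <- seg_params(beta = rep(-1.58, 3),
                   delta = c(FM = 0, FO = 2.64, MO = 2.64, SS = 2.64))
  expect_equal(regressive_logit("AA", p2), -1.58)
  expect_equal(regressive_logit("AA", p2, aff_father = 1, aff_mother = 0),
               -1.58 + 2.64)
  expect_equal(regressive_logit("AA", p2, aff_father = NA, aff_mother = NA,
                                n_affected_preceding_sibs = 2),
               -1.58 + 2 * 2.64)
  p0 <- seg_params(beta = c(-1, 0, 1))
  for (u in c("AA", "AB", "BB"))
    expect_equal(regressive_logit(u, p0, aff_father = 1, aff_mother = 1,
                                  n_affected_preceding_sibs = 3),
                 p0$beta[[u]])
})

test_that("susceptibility is a stable logistic in both tails", {
  expect_equal(susceptibility(0, 1), 0.5)
  expect_equal(susceptibility(-1.58, 1), 1 / (1 + exp(1.58)))
  expect_equal(round(susceptibility(-1.58, 1), 4), 0.1708)
  expect_equal(susceptibility(-154.70, 1, log = TRUE), -154.70)
  expect_gt(susceptibility(-154.70, 1), 0)          # no underflow to exact 0? it is ~1e-68
  expect_equal(susceptibility(700, 0, log = TRUE), -700)
  th <- seq(-30, 30, length.out = 101)
  expect_equal(susceptibility(th, 1) + susceptibility(th, 0), rep(1, 101))
  expect_true(all(diff(susceptibility(th, 1)) > 0))  # strictly increasing
  expect_error(susceptibility(0, 2), "trait")
})

test_that("homogeneity constraint solves the stationarity equation", {
  for (q in c(0.1, 0.3, 0.7))
    expect_equal(as.numeric(homogeneity_tau_ab(q, 1, 0)), 0.5)
  expect_equal(as.numeric(homogeneity_tau_ab(0.4, 0.4, 0.4)), 0.4)
  expect_equal(as.numeric(homogeneity_tau_ab(0.3, 1, 0.1)), 0.161 / 0.42)
  # solved value satisfies the stationarity equation
  set.seed(3)
  for (r in 1:25) {
    q <- runif(1, 0.05, 0.95); ta <- runif(1); tb <- runif(1)
    t_ab <- as.numeric(homogeneity_tau_ab(q, ta, tb))
    expect_equal(q^2 * ta + 2 * q * (1 - q) * t_ab + (1 - q)^2 * tb, q)
  }
  expect_false(attr(homogeneity_tau_ab(0.05, 0, 1), "feasible"))
  expect_error(homogeneity_tau_ab(0, 1, 0), "strictly")
})

test_that("model specifications expose the expected free-parameter counts", {
  want <- c(sporadic_no_assoc = 1, sporadic_equal_assoc = 2,
            sporadic_parent_assoc = 3, sporadic_free_assoc = 4,
            general = 8, homogeneous_general = 7, environmental = 5,
            tau_ab_free = 6, codominant = 5, dominant = 4, recessive = 4,
            additive = 4, decreasing = 5, increasing = 5)
  for (id in names(want))
    expect_equal(build_model_spec(id)$n_free, unname(want[id]),
                 ignore_attr = TRUE, label = id)
  expect_error(build_model_spec("no_such_model"))
})

test_that("resolving any admissible free vector satisfies the model constraints", {
  set.seed(4)
  for (id in model_ids()) {
    m <- build_model_spec(id)
    for (r in 1:10) {
      w <- stats::setNames(
        m$free$lhs_lo + runif(m$n_free) * (m$free$lhs_hi - m$free$lhs_lo),
        m$free$name)
      res <- segfam:::resolve_model(m, w)
      p <- res$params
      expect_s3_class(p, "seg_params")
      expect_true(all(p$tau >= 0 & p$tau <= 1))
      expect_equal(p$delta[["FM"]], 0)
      switch(id,
        dominant = expect_equal(p$beta[["AA"]], p$beta[["AB"]]),
        recessive = expect_equal(p$beta[["AB"]], p$beta[["BB"]]),
        additive = expect_equal(p$beta[["AB"]],
                                (p$beta[["AA"]] + p$beta[["BB"]]) / 2),
        decreasing = expect_true(p$beta[["AA"]] >= p$beta[["AB"]] &&
                                   p$beta[["AB"]] >= p$beta[["BB"]]),
        increasing = expect_true(p$beta[["AA"]] <= p$beta[["AB"]] &&
                                   p$beta[["AB"]] <= p$beta[["BB"]]),
        environmental = expect_equal(unname(p$tau), rep(p$q_A, 3)),
        tau_ab_free = expect_equal(unname(p$tau[c(1, 3)]), c(1, 0)),
        homogeneous_general = if (res$penalty == 0)
          expect_equal(p$q_A^2 * p$tau[["AA"]] +
                         2 * p$q_A * (1 - p$q_A) * p$tau[["AB"]] +
                         (1 - p$q_A)^2 * p$tau[["BB"]], p$q_A,
                       tolerance = 1e-8),
        NULL)
      if (id %in% c("codominant", "dominant", "recessive", "additive",
                    "decreasing", "increasing"))
        expect_equal(unname(p$tau), c(1, 0.5, 0))
      if (startsWith(id, "sporadic"))
        expect_equal(length(unique(p$beta)), 1L)
      if (id %in% c("sporadic_equal_assoc", "general"))
        expect_equal(p$delta[["FO"]], p$delta[["MO"]])
    }
  }
})

test_that("Mendelian and environmental transmission are exactly homogeneous", {
  for (q in c(0.2, 0.5, 0.8)) {
    expect_equal(as.numeric(homogeneity_tau_ab(q, 1, 0)), 0.5)
    expect_equal(as.numeric(homogeneity_tau_ab(q, q, q)), q)
  }
})

test_that("parameter sets validate their ranges", {
  expect_error(seg_params(q_A = 1.5), "q_A")
  expect_error(seg_params(tau = c(1, 2, 0)), "tau")
  expect_error(seg_params(beta = c(Inf, 0, 0)), "finite")
})
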