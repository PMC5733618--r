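test_that("zero mate probability leaves exactly the founder couple", {
  set.seed(21)
  for (r in 1:5) expect_equal(nrow(simulate_structure(4, 3, 0, "F1")), 2)
  # a single-generation family is the couple regardless of mating
  set.seed(22)
  expect_equal(nrow(simulate_structure(1, 3, 1, "F1")), 2)
})

test_that("structure simulation is deterministic under a fixed seed", {
  set.seed(23); a <- simulate_structure(4, 2.2, 0.5, "F1")
  set.seed(23); b <- simulate_structure(4, 2.2, 0.5, "F1")
  expect_identical(a, b)
  expect_equal(nrow(validate_pedigree(a)), 0)
})

test_that("mean family size tracks the branching-process expectation", {
  # every mating (the founder couple included) happens with probability m
  # and yields a Poisson(s) sibship; non-final-generation children bring in
  # a founder spouse when they mate
  g <- 4; s <- 2.2; m <- 0.5
  births <- numeric(g); births[2] <- m * s
  if (g > 2) for (k in 3:g) births[k] <- births[k - 1] * m * s
  spouses <- m * births[2:(g - 1)]
  expected <- 2 + sum(births) + sum(spouses)
  set.seed(24)
  sizes <- replicate(2000, nrow(simulate_structure(g, s, m, "F")))
  expect_lt(abs(mean(sizes) - expected) / expected, 0.05)
})

test_that("type dropping matches the analytic type distributions", {
  trio <- make_trio()
  # fixation: q_A = 1 makes every founder AA, and with tau_AA = 1 the whole
  # pedigree is AA whatever the other transmission probabilities are
  set.seed(25)
  for (r in 1:5) {
    td <- drop_types(trio, 1, c(1, runif(2)))
    expect_equal(td$.true_type, rep("AA", 3))
  }
  # Mendelian segregation from AB x AB parents approaches (1/4, 1/2, 1/4)
  set.seed(26)
  n <- 4000
  kid <- character(n); keep <- logical(n)
  for (i in seq_len(n)) {
    td <- drop_types(trio, 0.5, c(1, 0.5, 0))
    keep[i] <- all(td$.true_type[1:2] == "AB")
    kid[i] <- td$.true_type[3]
  }
  kid <- kid[keep]
  freq <- table(factor(kid, levels = c("AA", "AB", "BB"))) / length(kid)
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / length(kid))
  expect_true(all(abs(as.numeric(freq) - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("environmental transmission makes offspring types independent of parents", {
  trio <- make_trio()
  q <- 0.4
  set.seed(27)
  n <- 3000
  par_type <- character(n); kid <- character(n)
  for (i in seq_len(n)) {
    td <- drop_types(trio, q, rep(q, 3))
    par_type[i] <- paste(td$.true_type[1], td$.true_type[2])
    kid[i] <- td$.true_type[3]
  }
  tab <- table(par_type, kid)
  tab <- tab[rowSums(tab) >= 30, , drop = FALSE]
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("phenotype simulation reproduces the regressive conditional law", {
  trio <- make_trio()
  truth <- seg_params(beta = rep(-1.58, 3),
                      delta = c(FM = 0, FO = 2.64, MO = 2.64, SS = 2.64))
  set.seed(28)
  n <- 6000
  father_aff <- logical(n); child_aff <- logical(n); mother_aff <- logical(n)
  for (i in seq_len(n)) {
    td <- drop_types(trio, 0.5, c(1, 0.5, 0))
    sp <- simulate_phenotypes(td, truth)
    father_aff[i] <- sp$affection[1] == "affected"
    mother_aff[i] <- sp$affection[2] == "affected"
    child_aff[i] <- sp$affection[3] == "affected"
  }
  # parents are founders: marginal prevalence logistic(-1.58)
  expect_lt(abs(mean(father_aff) - susceptibility(-1.58, 1)),
            3 * sqrt(0.17 * 0.83 / n))
  # child given affected father only: logistic(-1.58 + 2.64)
  sel <- father_aff & !mother_aff
  p_target <- susceptibility(-1.58 + 2.64, 1)
  expect_lt(abs(mean(child_aff[sel]) - p_target),
            3 * sqrt(p_target * (1 - p_target) / sum(sel)))
})

test_that("deterministic penetrance makes affection equal carrier status", {
  set.seed(29)
  ped <- random_pedigree(6, 30)
  truth <- seg_params(beta = c(500, 500, -500), q_A = 0.3)
  td <- drop_types(ped, 0.3, c(1, 0.5, 0))
  sp <- simulate_phenotypes(td, truth)
  expect_equal(sp$affection == "affected", sp$.true_type != "BB")
  # and an impossible trait never occurs
  none <- simulate_phenotypes(td, seg_params(beta = rep(-500, 3)))
  expect_true(all(none$affection == "unaffected"))
})

test_that("ascertained families obey the rule and carry one affected proband", {
  cfg <- sim_config(n_families = 5, seed = 41)
  ped <- simulate_study(cfg)
  fams <- split(ped, ped$family_id)
  expect_length(fams, 5)
  for (p in fams) {
    expect_equal(sum(p$is_proband), 1)
    expect_equal(p$affection[p$is_proband], "affected")
    expect_gte(sum(p$affection == "affected"), cfg$min_affected)
    expect_gte(nrow(p), cfg$min_members)
    expect_lte(nrow(p), cfg$max_members)
  }
  expect_equal(nrow(validate_pedigree(ped)), 0)
})

test_that("simulation is fully deterministic under the config seed", {
  cfg <- sim_config(n_families = 3, seed = 42)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("an unattainable ascertainment rule errors out", {
  cfg <- sim_config(n_families = 2,
                    truth = seg_params(beta = rep(-6, 3), q_A = 0.5),
                    min_affected = 5, seed = 43)
  expect_error(ascertain_families(cfg, max_tries = 300), "acceptance")
})
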