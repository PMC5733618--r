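test_that("a single affected founder with gamma = 0.5 has log-likelihood log(0.5)", {
  ped <- tibble::tibble(family_id = "S", id = "1", father_id = NA_character_,
                        mother_id = NA_character_, sex = "male",
                        affection = "affected", is_proband = TRUE)
  p <- seg_params(beta = c(0, 0, 0), q_A = 0.3)
  expect_equal(pedigree_loglik(ped, p)$loglik, log(0.5))
  expect_equal(brute_force_loglik(ped, p), log(0.5))
  # conditioning on the only datum gives zero
  expect_equal(pedigree_loglik(ped, p, "proband")$loglik, 0)
})

test_that("all-unknown phenotypes give log-likelihood zero for any model", {
  ped <- make_nuclear(4)
  ped$affection <- "unknown"
  set.seed(5)
  for (r in 1:5)
    expect_equal(pedigree_loglik(ped, random_params())$loglik, 0)
})

test_that("sporadic likelihood factorizes into independent logistic terms", {
  set.seed(6)
  for (r in 1:10) {
    sim <- random_phenotyped_pedigree(3, 12)
    ped <- sim$ped
    b <- runif(1, -3, 1)
    p <- seg_params(beta = rep(b, 3), q_A = 1)
    known <- ped$affection != "unknown"
    closed <- sum(susceptibility(b, as.numeric(ped$affection[known] ==
                                                 "affected"), log = TRUE))
    expect_equal(pedigree_loglik(ped, p)$loglik, closed)
    expect_equal(brute_force_loglik(ped, p), closed)
  }
})

test_that("peeling equals brute-force enumeration on random instances", {
  set.seed(7)
  for (r in 1:40) {
    sim <- random_phenotyped_pedigree(2, 11)
    d <- abs(pedigree_loglik(sim$ped, sim$params)$loglik -
               brute_force_loglik(sim$ped, sim$params))
    expect_lt(d, 1e-10)
  }
})

test_that("the likelihood is invariant to id relabeling", {
  set.seed(8)
  for (r in 1:5) {
    sim <- random_phenotyped_pedigree(4, 12)
    ped <- sim$ped
    relab <- stats::setNames(paste0("x", seq_len(nrow(ped))), ped$id)
    ped2 <- ped
    ped2$id <- relab[ped$id]
    ped2$father_id <- unname(relab[ped$father_id])
    ped2$mother_id <- unname(relab[ped$mother_id])
    expect_equal(pedigree_loglik(ped2, sim$params)$loglik,
                 pedigree_loglik(ped, sim$params)$loglik)
  }
})

test_that("ascertainment adjustment subtracts the proband marginal exactly", {
  set.seed(9)
  for (r in 1:10) {
    sim <- random_phenotyped_pedigree(3, 11, unknown_rate = 0)
    ped <- sim$ped
    aff <- which(ped$affection == "affected")
    if (!length(aff)) next
    ped$is_proband[sample(aff, 1)] <- TRUE
    adj <- pedigree_loglik(ped, sim$params, "proband")$loglik
    full <- pedigree_loglik(ped, sim$params, "none")$loglik
    masked <- ped
    masked$affection[!ped$is_proband] <- "unknown"
    denom <- pedigree_loglik(masked, sim$params, "none")$loglik
    expect_equal(adj, full - denom, tolerance = 1e-10)
    expect_equal(adj, brute_force_loglik(ped, sim$params, "proband"),
                 tolerance = 1e-10)
  }
})

test_that("a sporadic trio's adjusted likelihood reduces to the parents' closed form", {
  ped <- make_trio()
  b <- -0.7
  p <- seg_params(beta = rep(b, 3), q_A = 0.4)
  adj <- pedigree_loglik(ped, p, "proband")$loglik
  # child term cancels against the proband marginal
  expect_equal(adj, 2 * susceptibility(b, 0, log = TRUE))
})

test_that("proband ascertainment requires an affected proband everywhere", {
  ped <- make_trio(proband = c(FALSE, FALSE, FALSE))
  expect_error(pedigree_loglik(ped, seg_params(), "proband"), "proband")
})

test_that("sample -2lnL is additive over pedigrees", {
  p <- seg_params(beta = c(-1, -1, -1), q_A = 0.5)
  ped <- make_trio()
  one <- sample_neg2lnl(ped, p)
  two_fam <- dplyr::bind_rows(ped, dplyr::mutate(ped, family_id = "T2"))
  expect_equal(sample_neg2lnl(two_fam, p), 2 * one)
  expect_equal(one, -2 * sum(pedigree_loglik(ped, p)$loglik))
})

test_that("degenerate Mendelian limits collapse the type sum", {
  ped <- make_nuclear(3)
  ped$affection <- c("affected", "unaffected", "affected", "affected",
                     "unaffected")
  # q_A = 1: every member AA
  p1 <- seg_params(beta = c(-0.5, -2, -4), q_A = 1)
  t <- as.numeric(ped$affection == "affected")
  expect_equal(pedigree_loglik(ped, p1)$loglik,
               sum(susceptibility(-0.5, t, log = TRUE)))
  # q_A = 0: every member BB
  p0 <- seg_params(beta = c(-0.5, -2, -4), q_A = 0)
  expect_equal(pedigree_loglik(ped, p0)$loglik,
               sum(susceptibility(-4, t, log = TRUE)))
})

test_that("full-penetrance carrier trio matches the 27-term hand sum", {
  # carriers (AA/AB) always affected, BB never; all three members affected
  ped <- make_trio(affection = rep("affected", 3),
                   proband = c(FALSE, FALSE, TRUE))
  p <- seg_params(beta = c(500, 500, -500), q_A = 0.5)
  # by hand: all three must carry, so both parents are carrier types and the
  # child carries with the Mendelian non-BB probability
  hw <- founder_type_probs(0.5)
  carry <- 0
  for (uf in 1:2) for (um in 1:2) {
    pr <- offspring_type_probs(c("AA", "AB")[uf], c("AA", "AB")[um],
                               c(1, 0.5, 0))
    carry <- carry + hw[uf] * hw[um] * (pr[["AA"]] + pr[["AB"]])
  }
  hand <- log(unname(carry))
  expect_equal(pedigree_loglik(ped, p)$loglik, hand, tolerance = 1e-12)
  expect_equal(brute_force_loglik(ped, p), hand, tolerance = 1e-12)
})

test_that("oversized pedigrees are rejected by the enumeration oracle", {
  set.seed(10)
  ped <- random_pedigree(13, 30)
  expect_error(brute_force_loglik(ped, seg_params()), "12")
})
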