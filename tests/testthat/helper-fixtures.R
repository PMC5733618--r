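# fixtures and independent oracles shared across test files

make_trio <- function(affection = c("unaffected", "unaffected", "affected"),
                      proband = c(FALSE, FALSE, TRUE)) {
  tibble::tibble(
    family_id = "T1", id = c("1", "2", "3"),
    father_id = c(NA, NA, "1"), mother_id = c(NA, NA, "2"),
    sex = c("male", "female", "male"),
    affection = affection, is_proband = proband)
}

make_nuclear <- function(n_children = 3) {
  kids <- as.character(seq_len(n_children) + 2)
  tibble::tibble(
    family_id = "N1", id = c("1", "2", kids),
    father_id = c(NA, NA, rep("1", n_children)),
    mother_id = c(NA, NA, rep("2", n_children)),
    sex = c("male", "female", rep(c("male", "female"),
                                  length.out = n_children)),
    affection = "unaffected", is_proband = FALSE)
}

# grandparent couple, two married children, one grandchild each
make_three_gen <- function() {
  tibble::tibble(
    family_id = "G1",
    id = c("gf", "gm", "c1", "s1", "c2", "s2", "k1", "k2"),
    father_id = c(NA, NA, "gf", NA, "gf", NA, "c1", "s2"),
    mother_id = c(NA, NA, "gm", NA, "gm", NA, "s1", "c2"),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female"),
    affection = c("affected", "unaffected", "affected", "unaffected",
                  "unaffected", "unaffected", "affected", "affected"),
    is_proband = FALSE)
}

random_pedigree <- function(n_min = 2, n_max = 12, generations = NULL) {
  repeat {
    g <- if (is.null(generations)) sample(2:4, 1) else generations
    ped <- simulate_structure(g, stats::runif(1, 1.5, 2.5),
                              stats::runif(1, 0.3, 0.9), "R1")
    if (nrow(ped) >= n_min && nrow(ped) <= n_max) return(ped)
  }
}

random_params <- function(with_assoc = TRUE) {
  seg_params(
    beta = sort(stats::runif(3, -4, 2), decreasing = TRUE),
    q_A = stats::runif(1, 0.05, 0.95),
    tau = stats::runif(3),
    delta = if (with_assoc)
      c(FM = stats::runif(1, -1, 1), FO = stats::runif(1, -1, 2),
        MO = stats::runif(1, -1, 2), SS = stats::runif(1, -1, 2))
    else c(FM = 0, FO = 0, MO = 0, SS = 0))
}

random_phenotyped_pedigree <- function(n_min = 2, n_max = 12,
                                       unknown_rate = 0.15) {
  ped <- random_pedigree(n_min, n_max)
  p <- random_params()
  ped <- drop_types(ped, p$q_A, p$tau)
  ped <- simulate_phenotypes(ped, p)
  ped$affection[stats::runif(nrow(ped)) < unknown_rate] <- "unknown"
  list(ped = ped, params = p)
}

# Independent relationship-classification oracle: label each pair by the
# depth signature of its common ancestors (climbing parent paths), rather
# than by the adjacency-matrix products the package uses.
oracle_relationships <- function(ped) {
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  n <- nrow(ped)
  anc_depths <- function(i) {
    # named vector: minimal climb depth to each ancestor (including self = 0)
    d <- stats::setNames(0L, i)
    frontier <- i
    depth <- 0L
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- c(fa[frontier], mo[frontier])
      nxt <- nxt[!is.na(nxt)]
      nxt <- setdiff(nxt, as.integer(names(d)))
      if (length(nxt)) d <- c(d, stats::setNames(rep(depth, length(nxt)), nxt))
      frontier <- nxt
    }
    d
  }
  A <- lapply(seq_len(n), anc_depths)
  classify <- function(i, j) {
    ai <- A[[i]]; aj <- A[[j]]
    common <- intersect(names(ai), names(aj))
    if (!length(common)) return(NULL)
    di <- ai[common]; dj <- aj[common]
    has <- function(x, y) {
      if (x == y) sum(di == x & dj == y)
      else sum(di == x & dj == y) + sum(di == y & dj == x)
    }
    if (any((di == 0 & dj == 1) | (dj == 0 & di == 1))) return("parent_offspring")
    if (any((di == 0 & dj == 2) | (dj == 0 & di == 2))) return("grandparental")
    if (any(di == 0 | dj == 0)) return(NULL)          # deeper lineal
    if (has(1, 1) == 2) return("sib_sib")
    if (has(1, 2) == 2) return("avuncular")
    if (has(2, 2) == 2 && has(1, 1) == 0) return("cousin")
    NULL
  }
  out <- stats::setNames(rep(0L, length(REL_CLASSES_ORACLE)),
                         REL_CLASSES_ORACLE)
  conc <- out
  aff <- ped$affection == "affected"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cl <- classify(i, j)
    if (is.null(cl)) next
    out[cl] <- out[cl] + 1L
    if (aff[i] && aff[j]) conc[cl] <- conc[cl] + 1L
    if (cl == "sib_sib") {
      sx <- sort(c(ped$sex[i], ped$sex[j]))
      sub <- if (all(sx == "female")) "sister_sister"
             else if (all(sx == "male")) "brother_brother"
             else "sister_brother"
      out[sub] <- out[sub] + 1L
      if (aff[i] && aff[j]) conc[sub] <- conc[sub] + 1L
    }
  }
  list(pairs = out, concordant = conc)
}

REL_CLASSES_ORACLE <- c("parent_offspring", "sib_sib", "sister_sister",
                        "brother_brother", "sister_brother", "grandparental",
                        "avuncular", "cousin")

# warm start for the general model from a homogeneous-general fit
warm_general_start <- function(fh, assoc = "none") {
  w <- fh$par_working
  t_ab <- as.numeric(homogeneity_tau_ab(fh$par_free[["q_A"]],
                                        fh$par_free[["tau_AA"]],
                                        fh$par_free[["tau_BB"]]))
  t_ab <- min(max(t_ab, 1e-6), 1 - 1e-6)
  s <- c(w[["beta_AA"]], w[["beta_AB"]], w[["beta_BB"]], w[["q_A"]],
         w[["tau_AA"]], stats::qlogis(t_ab), w[["tau_BB"]])
  nm <- c("beta_AA", "beta_AB", "beta_BB", "q_A", "tau_AA", "tau_AB",
          "tau_BB")
  if (assoc == "equal") { s <- c(s, w[["delta"]]); nm <- c(nm, "delta") }
  stats::setNames(s, nm)
}
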