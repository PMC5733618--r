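#' Simulation configuration for ascertained multiplex families
#'
#' Bundles the generative conditions for the family simulator. Defaults
#' emulate the motivating ankylosing-spondylitis family study: nine extended
#' families of three to five generations averaging around 35 members,
#' ascertained through a single affected proband with at least five affected
#' members and at least fifteen members per family.
#'
#' @param n_families Number of ascertained families to produce.
#' @param generations Candidate generation counts; each family draws
#'   uniformly from this set.
#' @param mean_sibship Mean of the Poisson sibship-size distribution.
#' @param mate_probability Probability that a non-final-generation individual
#'   mates (spouses are unrelated founders).
#' @param truth A [seg_params()] object: the generating parameter values.
#' @param min_affected Minimum affected members for a family to be retained.
#' @param min_members,max_members Family-size range for retention (the upper
#'   cap emulates the practical limit on how large a recruitable extended
#'   family gets).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 9, generations = 3:5, mean_sibship = 2.8,
                       mate_probability = 0.65,
                       truth = seg_params(beta = c(-0.8, -0.8, -154.7),
                                          q_A = 0.17),
                       min_affected = 5, min_members = 15, max_members = 55,
                       seed = 1L) {
  stopifnot(n_families >= 1, all(generations >= 1), mean_sibship > 0,
            mate_probability >= 0, mate_probability <= 1,
            inherits(truth, "seg_params"), min_affected >= 0,
            min_members >= 0, max_members >= min_members)
  structure(list(n_families = n_families, generations = generations,
                 mean_sibship = mean_sibship,
                 mate_probability = mate_probability, truth = truth,
                 min_affected = min_affected, min_members = min_members,
                 max_members = max_members, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Expects top-level keys matching the arguments of [sim_config()], with
#' `truth` a mapping of `beta`, `q_A`, `tau`, `delta`.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- y$truth %||% list()
  truth <- seg_params(beta = tr$beta %||% c(-0.8, -0.8, -154.7),
                      q_A = tr$q_A %||% 0.17,
                      tau = tr$tau %||% c(1, 0.5, 0),
                      delta = unlist(tr$delta) %||% numeric(0))
  args <- y[setdiff(names(y), "truth")]
  do.call(sim_config, c(args, list(truth = truth)))
}

#' Simulate a pedigree structure (no phenotypes)
#'
#' Grows one family from a founder couple: each individual in a non-final
#' generation mates with probability `mate_probability` (the founder couple
#' included; an unrelated founder spouse is added for non-founders), and
#' each mating produces one Poisson(`mean_sibship`) sibship. With
#' `mate_probability = 0` the family is exactly the founder couple. Sexes
#' are assigned independently with probability one half; sex determines
#' nothing downstream (the model has no sex terms).
#'
#' @param generations Number of generations for this family.
#' @param mean_sibship Mean Poisson sibship size.
#' @param mate_probability Mating probability per individual per generation.
#' @param family_id Family identifier.
#' @return Pedigree tibble with `affection = "unknown"` throughout.
#' @export
simulate_structure <- function(generations = 4, mean_sibship = 2.8,
                               mate_probability = 0.65, family_id = "F1") {
  cap <- 512L
  father <- mother <- integer(cap)
  male <- logical(cap)
  father[1:2] <- 0L; mother[1:2] <- 0L
  male[1:2] <- c(TRUE, FALSE)
  n <- 2L
  couples_f <- integer(0); couples_m <- integer(0)
  if (generations > 1 && stats::runif(1) < mate_probability) {
    couples_f <- 1L; couples_m <- 2L
  }
  for (g in seq_len(generations - 1L)) {
    if (!length(couples_f)) break
    nkids <- stats::rpois(length(couples_f), mean_sibship)
    new_f <- new_m <- integer(0)
    for (ci in seq_along(couples_f)) {
      if (nkids[ci] == 0) next
      for (k in seq_len(nkids[ci])) {
        n <- n + 1L
        if (n + 1L > cap) {
          cap <- cap * 2L
          father <- c(father, integer(cap / 2)); mother <- c(mother, integer(cap / 2))
          male <- c(male, logical(cap / 2))
        }
        father[n] <- couples_f[ci]; mother[n] <- couples_m[ci]
        male[n] <- stats::runif(1) < 0.5
        kid <- n
        # members of the final generation never mate
        if (g + 1L < generations && stats::runif(1) < mate_probability) {
          n <- n + 1L
          father[n] <- 0L; mother[n] <- 0L
          male[n] <- !male[kid]
          if (male[kid]) { new_f <- c(new_f, kid); new_m <- c(new_m, n) }
          else { new_f <- c(new_f, n); new_m <- c(new_m, kid) }
        }
      }
    }
    couples_f <- new_f; couples_m <- new_m
  }
  idx <- seq_len(n)
  ids <- as.character(idx)
  fa <- father[idx]; mo <- mother[idx]
  father_id <- mother_id <- rep(NA_character_, n)
  father_id[fa > 0L] <- ids[fa[fa > 0L]]
  mother_id[mo > 0L] <- ids[mo[mo > 0L]]
  ped <- tibble::new_tibble(list(
    family_id = rep(family_id, n), id = ids,
    father_id = father_id, mother_id = mother_id,
    sex = ifelse(male[idx], "male", "female"),
    affection = rep("unknown", n),
    is_proband = rep(FALSE, n)), nrow = n)
  assign_birth_order(ped)
}

#' Drop latent types through a pedigree
#'
#' Founders draw their type from Hardy-Weinberg proportions at `q_A`;
#' each non-founder draws from the offspring distribution implied by the
#' parental types and the transmission probabilities `tau`
#' (genotype dropping, generalized to non-Mendelian `tau`).
#'
#' @param ped Pedigree tibble, rows ordered so parents precede children.
#' @param q_A Component-A frequency.
#' @param tau Transmission probabilities (AA, AB, BB).
#' @return `ped` with a `.true_type` column.
#' @export
drop_types <- function(ped, q_A, tau) {
  ped <- as_ped_tibble(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  pr_founder <- founder_type_probs(q_A)
  tau <- check_tau(tau)
  n <- nrow(ped)
  r <- stats::runif(n)
  u <- integer(n)                # 1 = AA, 2 = AB, 3 = BB
  cf <- pr_founder[1] + pr_founder[2]
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      u[i] <- 1L + (r[i] > pr_founder[1]) + (r[i] > cf)
    } else {
      if (u[fa[i]] == 0L || u[mo[i]] == 0L)
        stop("rows must be ordered parents-before-children", call. = FALSE)
      a <- tau[u[fa[i]]]; b <- tau[u[mo[i]]]
      p_aa <- a * b
      p_ab <- a * (1 - b) + (1 - a) * b
      u[i] <- 1L + (r[i] > p_aa) + (r[i] > p_aa + p_ab)
    }
  }
  ped$.true_type <- TYPES[u]
  ped
}

#' Simulate phenotypes under the regressive logistic model
#'
#' Processes members in row order (which must put spouses, parents and
#' earlier sibs before each individual, as the generator's output does) and
#' draws each affection status as Bernoulli with probability
#' \eqn{\gamma(\theta)}, where \eqn{\theta} is the regressive logit given
#' the member's latent type and the already-realized phenotypes of its
#' designated relatives.
#'
#' @param ped Pedigree tibble with a `.true_type` column (see
#'   [drop_types()]).
#' @param truth Generating [seg_params()].
#' @return `ped` with `affection` filled in (`"affected"`/`"unaffected"`).
#' @export
simulate_phenotypes <- function(ped, truth) {
  ped <- as_ped_tibble(ped)
  if (is.null(ped$.true_type)) stop("run drop_types() first", call. = FALSE)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  if (any(!is.na(fa) & fa > seq_len(nrow(ped))) ||
      any(!is.na(mo) & mo > seq_len(nrow(ped))))
    stop("rows must be ordered parents-before-children", call. = FALSE)
  n <- nrow(ped)
  aff <- logical(n)
  u <- match(ped$.true_type, TYPES)
  beta <- unname(truth$beta)
  d_fo <- truth$delta[["FO"]]; d_mo <- truth$delta[["MO"]]
  d_ss <- truth$delta[["SS"]]; d_fm <- truth$delta[["FM"]]
  # spouse = other parent of the first child (realized only if earlier row)
  spouse <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) next
    if (is.na(spouse[fa[i]])) spouse[fa[i]] <- mo[i]
    if (is.na(spouse[mo[i]])) spouse[mo[i]] <- fa[i]
  }
  # running count of affected earlier sibs per sibship
  sib_of <- ifelse(is.na(fa), NA_integer_,
                   match(paste(fa, mo), unique(paste(fa, mo)[!is.na(fa)])))
  n_aff_sib <- integer(max(sib_of, 1, na.rm = TRUE))
  r <- stats::runif(n)
  for (i in seq_len(n)) {
    th <- beta[u[i]]
    if (!is.na(fa[i])) {
      if (aff[fa[i]]) th <- th + d_fo
      if (aff[mo[i]]) th <- th + d_mo
      th <- th + d_ss * n_aff_sib[sib_of[i]]
    }
    if (d_fm != 0 && !is.na(spouse[i]) && spouse[i] < i && aff[spouse[i]])
      th <- th + d_fm
    aff[i] <- r[i] < stats::plogis(th)
    if (aff[i] && !is.na(sib_of[i]))
      n_aff_sib[sib_of[i]] <- n_aff_sib[sib_of[i]] + 1L
  }
  ped$affection <- ifelse(aff, "affected", "unaffected")
  ped
}

#' Simulate singly ascertained multiplex families
#'
#' Streams simulated families (structure, latent types, phenotypes) and
#' applies genuine single ascertainment: a candidate proband is drawn
#' uniformly from the family and the family enters the sample only if that
#' candidate is affected, so a family's acceptance probability is
#' proportional to its fraction of affected members and, given acceptance,
#' the proband is uniform among the affected. Conditioning the likelihood on
#' the proband's phenotype ([pedigree_loglik()] with
#' `ascertainment = "proband"`) is then the exact correction. Families must
#' additionally satisfy the rule thresholds (at least `min_affected`
#' affected members, size within `[min_members, max_members]`). Sampling
#' continues until `n_families` are accepted.
#'
#' @param config A [sim_config()].
#' @param max_tries Abort with an error after this many rejected families
#'   (the acceptance probability is effectively zero).
#' @return Pedigree tibble of accepted families (`F1`, `F2`, ...) with
#'   `.true_type` retained and one affected proband flagged per family.
#' @export
ascertain_families <- function(config, max_tries = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  out <- vector("list", config$n_families)
  accepted <- 0L
  tries <- 0
  while (accepted < config$n_families) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("ascertainment acceptance probability is ~0 after ", max_tries,
           " attempts; adjust the generating parameters or rule",
           call. = FALSE)
    gens <- if (length(config$generations) == 1) config$generations
            else sample(config$generations, 1)
    ped <- simulate_structure(gens, config$mean_sibship,
                              config$mate_probability,
                              family_id = paste0("F", accepted + 1L))
    if (nrow(ped) < config$min_members || nrow(ped) > config$max_members) next
    ped <- drop_types(ped, config$truth$q_A, config$truth$tau)
    ped <- simulate_phenotypes(ped, config$truth)
    pb <- sample.int(nrow(ped), 1)
    if (ped$affection[pb] != "affected") next
    if (sum(ped$affection == "affected") < config$min_affected) next
    ped$is_proband[pb] <- TRUE
    accepted <- accepted + 1L
    out[[accepted]] <- ped
  }
  dplyr::bind_rows(out)
}

#' Simulate a complete ascertained study sample
#'
#' Convenience wrapper around [ascertain_families()] returning the combined
#' pedigree tibble; the generating truth is attached as attribute `truth`.
#'
#' @param config A [sim_config()].
#' @param ... Passed to [ascertain_families()].
#' @return Pedigree tibble.
#' @export
simulate_study <- function(config = sim_config(), ...) {
  ped <- ascertain_families(config, ...)
  attr(ped, "truth") <- config$truth
  ped
}
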