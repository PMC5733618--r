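# Precompute the fitting-invariant structure of one family: parent indices,
# trait codes, regressive-term indicators, proband index. The regressive
# delta-terms involve only observed phenotypes, so everything except the
# parameter values is fixed here.
ped_struct <- function(p, covariate_names = character()) {
  n <- nrow(p)
  fa <- match(p$father_id, p$id)
  mo <- match(p$mother_id, p$id)
  trait <- dplyr::case_when(p$affection == "affected" ~ 1,
                            p$affection == "unaffected" ~ 0,
                            TRUE ~ NA_real_)
  aff <- !is.na(trait) & trait == 1
  z_f <- ifelse(!is.na(fa) & aff[replace(fa, is.na(fa), 1L)], 1, 0)
  z_m <- ifelse(!is.na(mo) & aff[replace(mo, is.na(mo), 1L)], 1, 0)
  # affected preceding full sibs
  n_sib <- integer(n)
  sibkey <- ifelse(is.na(fa), NA, paste(fa, mo))
  for (k in unique(sibkey[!is.na(sibkey)])) {
    idx <- which(!is.na(sibkey) & sibkey == k)
    idx <- idx[order(p$birth_order[idx])]
    n_sib[idx] <- cumsum(c(0, aff[idx][-length(idx)]))
  }
  # spouse = other parent of the first child (in file order)
  z_sp <- numeric(n)
  for (i in seq_len(n)) {
    ch <- which(fa == i | mo == i)
    if (!length(ch)) next
    other <- if (!is.na(fa[ch[1]]) && fa[ch[1]] == i) mo[ch[1]] else fa[ch[1]]
    if (!is.na(other) && aff[other]) z_sp[i] <- 1
  }
  X <- NULL
  if (length(covariate_names)) {
    miss <- setdiff(covariate_names, names(p))
    if (length(miss))
      stop("missing covariate columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    X <- as.matrix(p[, covariate_names, drop = FALSE])
  }
  pb <- which(p$is_proband)
  # Elston-Stewart-style elimination order: childless members first, then up
  # the descendant chains; married-in founders just before their partners so
  # joined scopes stay at most {individual, father, mother, spouse}
  depth <- rep(NA_integer_, n)
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progress <- FALSE
    for (i in todo) {
      ch <- which((!is.na(fa) & fa == i) | (!is.na(mo) & mo == i))
      if (!length(ch)) { depth[i] <- 0L; progress <- TRUE }
      else if (!anyNA(depth[ch])) {
        depth[i] <- 1L + max(depth[ch]); progress <- TRUE
      }
    }
    if (!progress) stop("pedigree contains a parent cycle", call. = FALSE)
  }
  elim <- order(depth, !is.na(fa), seq_len(n))
  list(n = n, family_id = p$family_id[1],
       father = ifelse(is.na(fa), 0L, fa), mother = ifelse(is.na(mo), 0L, mo),
       elim = elim,
       trait = trait, z_f = z_f, z_m = z_m, n_sib = n_sib, z_sp = z_sp,
       X = X, proband = if (length(pb)) pb[1] else NA_integer_)
}

ped_structs <- function(ped, covariate_names = character()) {
  lapply(ped_split(ped), ped_struct, covariate_names = covariate_names)
}

# flatten per-family structures into one set of concatenated arrays so a
# likelihood evaluation is a few vectorized operations plus one C++ call
combine_structs <- function(structs) {
  nm <- vapply(structs, `[[`, integer(1), "n")
  off <- cumsum(c(0L, nm[-length(nm)]))
  g <- function(field) unlist(lapply(structs, `[[`, field), use.names = FALSE)
  pb <- vapply(structs, `[[`, integer(1), "proband")
  trait <- g("trait")
  list(nm = nm, n_total = sum(nm), fa = g("father"), mo = g("mother"),
       el = g("elim"), z_f = g("z_f"), z_m = g("z_m"), n_sib = g("n_sib"),
       z_sp = g("z_sp"), trait = trait,
       trait_code = ifelse(is.na(trait), -1L, as.integer(trait)),
       zeros = numeric(sum(nm)),
       proband = pb, proband_global = off + pb,
       X = if (is.null(structs[[1]]$X)) NULL
           else do.call(rbind, lapply(structs, `[[`, "X")),
       family_id = vapply(structs, `[[`, character(1), "family_id"))
}

# trans[child + 3*(father-1) + 9*(mother-1)], child index fastest
transmission_flat <- function(tau) {
  af <- rep(tau, times = 3)
  am <- rep(tau, each = 3)
  as.numeric(rbind(af * am, af * (1 - am) + (1 - af) * am,
                   (1 - af) * (1 - am)))
}

peel_combined <- function(cb, params, ascertainment) {
  ascertain <- ascertainment == "proband"
  if (ascertain && anyNA(cb$proband))
    stop("ascertainment = 'proband' requires a proband in every family",
         call. = FALSE)
  assoc <- params$delta[["FO"]] * cb$z_f + params$delta[["MO"]] * cb$z_m +
    params$delta[["SS"]] * cb$n_sib + params$delta[["FM"]] * cb$z_sp
  xb <- if (length(params$xi)) drop(cb$X %*% params$xi) else cb$zeros
  peel_model_cpp(cb$nm, cb$fa, cb$mo, cb$el, cb$trait_code, assoc, xb,
                 cb$proband_global, unname(params$beta), params$q_A,
                 unname(params$tau), ascertain)
}

#' Exact pedigree log-likelihood under the regressive model
#'
#' Computes the natural-log likelihood of each family by exact summation over
#' the latent type assignments (Elston-Stewart peeling via variable
#' elimination): founders carry Hardy-Weinberg type priors, non-founders the
#' tau-transmission probabilities, and every member of known phenotype a
#' logistic penetrance whose logit includes the regressive
#' familial-association terms. Members of unknown affection contribute
#' transmission structure but no penetrance factor. With
#' `ascertainment = "proband"` the classical single-ascertainment correction
#' is applied: the log marginal probability that the proband is affected
#' (all other phenotypes set to unknown) is subtracted.
#'
#' @param ped Pedigree tibble (one or more families).
#' @param params A [seg_params()] object.
#' @param ascertainment `"none"` or `"proband"`. `"proband"` requires each
#'   family to have a designated, affected proband.
#' @return A tibble with columns `family_id` and `loglik`.
#' @seealso [brute_force_loglik()], [sample_neg2lnl()]
#' @export
pedigree_loglik <- function(ped, params, ascertainment = c("none", "proband")) {
  ascertainment <- match.arg(ascertainment)
  stopifnot(inherits(params, "seg_params"))
  ped <- as_ped_tibble(ped)
  diag <- validate_pedigree(ped)
  if (nrow(diag)) stop("invalid pedigree: ", diag$message[1], call. = FALSE)
  cb <- combine_structs(ped_structs(ped, names(params$xi) %||% character()))
  ll <- peel_combined(cb, params, ascertainment)
  if (any(!is.finite(ll) & !is.infinite(ll)))
    stop("non-finite likelihood; parameters: ",
         paste(deparse(unclass(params)), collapse = ""), call. = FALSE)
  tibble::tibble(family_id = cb$family_id, loglik = as.numeric(ll))
}

#' Brute-force pedigree log-likelihood by type enumeration
#'
#' Independent oracle for [pedigree_loglik()]: enumerates all `3^n` latent
#' type assignments of a single family (at most 12 members) and sums their
#' joint probabilities directly, using its own arithmetic for founder
#' priors, transmissions and regressive penetrances.
#'
#' @inheritParams pedigree_loglik
#' @return Log-likelihood (numeric scalar) of the single family in `ped`.
#' @export
brute_force_loglik <- function(ped, params,
                               ascertainment = c("none", "proband")) {
  ascertainment <- match.arg(ascertainment)
  ped <- as_ped_tibble(ped)
  if (length(unique(ped$family_id)) != 1)
    stop("brute_force_loglik takes a single family", call. = FALSE)
  n <- nrow(ped)
  if (n > 12) stop("pedigree too large for enumeration (> 12 members)",
                   call. = FALSE)
  if (ascertainment == "proband") {
    pb <- which(ped$is_proband)
    if (length(pb) != 1 || ped$affection[pb] != "affected")
      stop("proband ascertainment requires one affected proband",
           call. = FALSE)
    masked <- ped
    masked$affection[-pb] <- "unknown"
    return(brute_force_loglik(ped, params, "none") -
           brute_force_loglik(masked, params, "none"))
  }

  q <- params$q_A
  log_prior <- log(c(q^2, 2 * q * (1 - q), (1 - q)^2))
  tau <- params$tau
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  logp <- numeric(nrow(grid))
  for (i in seq_len(n)) {
    u <- grid[, i]
    if (is.na(fa[i])) {
      logp <- logp + log_prior[u]
    } else {
      a <- tau[grid[, fa[i]]]
      b <- tau[grid[, mo[i]]]
      pr <- cbind(a * b, a * (1 - b) + (1 - a) * b, (1 - a) * (1 - b))
      logp <- logp + log(pr[cbind(seq_len(nrow(grid)), u)])
    }
    if (ped$affection[i] == "unknown") next
    # regressive logit, recomputed from first principles
    th <- params$beta[u]
    aff <- function(id) !is.na(id) && ped$affection[id] == "affected"
    if (!is.na(fa[i]) && aff(fa[i])) th <- th + params$delta[["FO"]]
    if (!is.na(mo[i]) && aff(mo[i])) th <- th + params$delta[["MO"]]
    sibs <- which(!is.na(fa) & fa == fa[i] & mo == mo[i] &
                    ped$birth_order < ped$birth_order[i])
    th <- th + params$delta[["SS"]] *
      sum(ped$affection[sibs] == "affected")
    ch <- which(fa == i | mo == i)
    if (length(ch)) {
      other <- if (!is.na(fa[ch[1]]) && fa[ch[1]] == i) mo[ch[1]] else fa[ch[1]]
      if (aff(other)) th <- th + params$delta[["FM"]]
    }
    t_i <- if (ped$affection[i] == "affected") 1 else 0
    logp <- logp + susceptibility(th, t_i, log = TRUE)
  }
  m <- max(logp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(logp - m)))
}

#' Sample -2 log-likelihood
#'
#' Twice the negative sum of (ascertainment-adjusted) per-family
#' log-likelihoods, the quantity reported in segregation-analysis comparison
#' tables.
#'
#' @inheritParams pedigree_loglik
#' @return Numeric scalar.
#' @export
sample_neg2lnl <- function(ped, params, ascertainment = c("none", "proband")) {
  ascertainment <- match.arg(ascertainment)
  -2 * sum(pedigree_loglik(ped, params, ascertainment)$loglik)
}
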