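TYPES <- c("AA", "AB", "BB")

#' Parameter set for the regressive segregation model
#'
#' Bundles every parameter of the latent-type regressive logistic model: the
#' baseline susceptibility logits `beta` (one per type AA/AB/BB), the
#' component-A frequency `q_A` governing Hardy-Weinberg founder type
#' frequencies, the transmission probabilities `tau` (probability that a
#' parent of each type transmits component A), the familial-association
#' coefficients `delta` (spouse FM, father-offspring FO, mother-offspring MO,
#' sib-sib SS, on the logit scale), and covariate coefficients `xi`.
#'
#' @param beta Numeric length 3 (AA, AB, BB), susceptibility logits. Very
#'   negative values (e.g. -154.7) represent effectively-zero penetrance and
#'   are handled in log domain.
#' @param q_A Frequency of component A in founders, in `[0, 1]`.
#' @param tau Numeric length 3 in `[0, 1]`: transmission probabilities
#'   \eqn{\tau_{AA}, \tau_{AB}, \tau_{BB}}. Mendelian values are (1, 0.5, 0).
#' @param delta Named numeric: `FM`, `FO`, `MO`, `SS` association logits.
#' @param xi Named numeric vector of covariate coefficients (may be empty).
#' @return An object of class `seg_params` (a validated list).
#' @examples
#' seg_params(beta = c(-0.8, -0.8, -154.7), q_A = 0.17)
#' @export
seg_params <- function(beta = c(AA = 0, AB = 0, BB = 0),
                       q_A = 0.5,
                       tau = c(AA = 1, AB = 0.5, BB = 0),
                       delta = c(FM = 0, FO = 0, MO = 0, SS = 0),
                       xi = numeric(0)) {
  beta <- stats::setNames(as.numeric(beta), TYPES)
  tau <- stats::setNames(as.numeric(tau), TYPES)
  d <- c(FM = 0, FO = 0, MO = 0, SS = 0)
  if (length(delta)) {
    if (is.null(names(delta))) names(delta) <- names(d)[seq_along(delta)]
    d[names(delta)] <- as.numeric(delta)
  }
  stopifnot(length(beta) == 3, length(tau) == 3, length(q_A) == 1)
  if (anyNA(beta) || any(!is.finite(beta)))
    stop("beta must be finite", call. = FALSE)
  if (is.na(q_A) || q_A < 0 || q_A > 1)
    stop("q_A must be in [0, 1]", call. = FALSE)
  if (anyNA(tau) || any(tau < 0 | tau > 1))
    stop("tau values must be in [0, 1]", call. = FALSE)
  structure(list(beta = beta, q_A = q_A, tau = tau, delta = d,
                 xi = as.numeric(xi)),
            class = "seg_params")
}

#' @export
print.seg_params <- function(x, ...) {
  cat("<seg_params>\n")
  cat("  beta :", sprintf("%s=%.4g", TYPES, x$beta), "\n")
  cat("  q_A  :", format(x$q_A), "\n")
  cat("  tau  :", sprintf("%s=%.4g", TYPES, x$tau), "\n")
  cat("  delta:", sprintf("%s=%.4g", names(x$delta), x$delta), "\n")
  if (length(x$xi)) cat("  xi   :", format(x$xi), "\n")
  invisible(x)
}

#' Hardy-Weinberg founder type frequencies
#'
#' Founder types are drawn from Hardy-Weinberg proportions
#' \eqn{(q_A^2,\; 2 q_A (1 - q_A),\; (1 - q_A)^2)} for component frequency
#' `q_A`.
#'
#' @param q_A Frequency of component A, in `[0, 1]`.
#' @return Named numeric length 3 (AA, AB, BB), summing to 1.
#' @examples
#' founder_type_probs(0.19)
#' @export
founder_type_probs <- function(q_A) {
  if (!is.numeric(q_A) || length(q_A) != 1 || is.na(q_A) || q_A < 0 || q_A > 1)
    stop("q_A must be a single value in [0, 1]", call. = FALSE)
  c(AA = q_A^2, AB = 2 * q_A * (1 - q_A), BB = (1 - q_A)^2)
}

#' Offspring type distribution given parental types
#'
#' Each parent of type u transmits component A with probability
#' \eqn{\tau_u}; with `a`, `b` the paternal and maternal transmission
#' probabilities the offspring is AA with probability `a*b`, AB with
#' `a*(1-b) + (1-a)*b`, and BB with `(1-a)*(1-b)`.
#'
#' @param father_type,mother_type One of `"AA"`, `"AB"`, `"BB"`.
#' @param tau Numeric length 3 in `[0,1]`, transmission probabilities in
#'   (AA, AB, BB) order.
#' @return Named numeric length 3 summing to 1.
#' @examples
#' offspring_type_probs("AB", "AB", c(1, 0.5, 0)) # Punnett square
#' @export
offspring_type_probs <- function(father_type, mother_type, tau) {
  tau <- check_tau(tau)
  a <- tau[[match.arg(father_type, TYPES)]]
  b <- tau[[match.arg(mother_type, TYPES)]]
  c(AA = a * b, AB = a * (1 - b) + (1 - a) * b, BB = (1 - a) * (1 - b))
}

check_tau <- function(tau) {
  tau <- stats::setNames(as.numeric(tau), TYPES)
  if (anyNA(tau) || any(tau < 0 | tau > 1))
    stop("tau values must be in [0, 1]", call. = FALSE)
  tau
}

# 3x3x3 transmission array [child, father, mother]
transmission_array <- function(tau) {
  tau <- check_tau(tau)
  arr <- array(0, c(3, 3, 3), dimnames = list(TYPES, TYPES, TYPES))
  for (f in 1:3) for (m in 1:3) {
    a <- tau[f]; b <- tau[m]
    arr[, f, m] <- c(a * b, a * (1 - b) + (1 - a) * b, (1 - a) * (1 - b))
  }
  arr
}

#' Homogeneity-constrained heterozygote transmission probability
#'
#' The homogeneous general model requires the frequency of the transmitted
#' component to be stationary across generations:
#' \eqn{q_A^2 \tau_{AA} + 2 q_A (1-q_A) \tau_{AB} + (1-q_A)^2 \tau_{BB} = q_A}.
#' Solving for \eqn{\tau_{AB}} gives the constrained value. Values outside
#' `[0, 1]` are infeasible parameter points; the raw solution is still
#' returned with attribute `feasible = FALSE` so callers can penalise it.
#'
#' @param q_A Component-A frequency, strictly inside (0, 1).
#' @param tau_AA,tau_BB Transmission probabilities in `[0, 1]`.
#' @return The solved \eqn{\tau_{AB}} with logical attribute `feasible`.
#' @examples
#' homogeneity_tau_ab(0.3, 1, 0)   # Mendelian transmission: always 0.5
#' @export
homogeneity_tau_ab <- function(q_A, tau_AA, tau_BB) {
  if (q_A <= 0 || q_A >= 1)
    stop("q_A must be strictly inside (0, 1)", call. = FALSE)
  t_ab <- (q_A - q_A^2 * tau_AA - (1 - q_A)^2 * tau_BB) / (2 * q_A * (1 - q_A))
  attr(t_ab, "feasible") <- t_ab >= 0 && t_ab <= 1
  t_ab
}

#' Regressive logit of susceptibility
#'
#' The linear predictor \eqn{\theta} of an individual's susceptibility under
#' the regressive model: the baseline logit of the individual's latent type
#' plus association terms for each designated relative whose phenotype is
#' already realised (affected spouse, father, mother, and affected preceding
#' sibs), plus covariate effects. A relative that is absent or of unknown
#' status contributes no term.
#'
#' @param type `"AA"`, `"AB"` or `"BB"`.
#' @param params A [seg_params()] object.
#' @param aff_father,aff_mother,aff_spouse 1 if that relative is affected, 0
#'   if unaffected, `NA` if absent/unknown (term omitted).
#' @param n_affected_preceding_sibs Count of affected sibs earlier in birth
#'   order.
#' @param covariates Numeric vector matching `params$xi` (optional).
#' @return The logit \eqn{\theta} (numeric scalar).
#' @examples
#' p <- seg_params(beta = rep(-1.58, 3), delta = c(FM = 0, FO = 2.64, MO = 2.64, SS = 2.64))
#' regressive_logit("AA", p, aff_father = 1, aff_mother = 0)
#' @export
regressive_logit <- function(type, params,
                             aff_father = NA, aff_mother = NA,
                             n_affected_preceding_sibs = 0,
                             aff_spouse = NA, covariates = NULL) {
  stopifnot(inherits(params, "seg_params"))
  z <- function(a) if (is.na(a)) 0 else as.numeric(a)
  th <- params$beta[[match.arg(type, TYPES)]] +
    params$delta[["FO"]] * z(aff_father) +
    params$delta[["MO"]] * z(aff_mother) +
    params$delta[["SS"]] * n_affected_preceding_sibs +
    params$delta[["FM"]] * z(aff_spouse)
  if (length(params$xi)) {
    if (is.null(covariates) || length(covariates) != length(params$xi))
      stop("covariates must match length of params$xi", call. = FALSE)
    th <- th + sum(params$xi * covariates)
  }
  unname(th)
}

#' Susceptibility under the cumulative logistic model
#'
#' Probability of the observed trait value given the logit \eqn{\theta}:
#' \eqn{\gamma = e^\theta / (1 + e^\theta)} for an affected individual
#' (`trait = 1`) and \eqn{1 - \gamma} for an unaffected one. Evaluated in a
#' numerically stable form so logits as extreme as several hundred (boundary
#' fits) neither overflow nor underflow; use `log = TRUE` for the
#' log-probability.
#'
#' @param theta Logit(s) of susceptibility.
#' @param trait 0 (unaffected) or 1 (affected); recycled against `theta`.
#' @param log Return log-probability?
#' @return Probability (or log-probability) of the observed trait value.
#' @examples
#' susceptibility(0, 1)        # 0.5
#' susceptibility(-154.7, 1, log = TRUE)
#' @export
susceptibility <- function(theta, trait = 1, log = FALSE) {
  if (!all(trait %in% c(0, 1))) stop("trait must be 0 or 1", call. = FALSE)
  n <- max(length(theta), length(trait))
  theta <- rep_len(theta, n)
  trait <- rep_len(trait, n)
  lp <- ifelse(trait == 1,
               stats::plogis(theta, log.p = TRUE),
               stats::plogis(-theta, log.p = TRUE))
  if (log) lp else exp(lp)
}
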