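MODEL_IDS <- c("sporadic_no_assoc", "sporadic_equal_assoc",
               "sporadic_parent_assoc", "sporadic_free_assoc",
               "general", "homogeneous_general", "environmental",
               "tau_ab_free", "codominant", "dominant", "recessive",
               "additive", "decreasing", "increasing")

MODEL_LABELS <- c(
  sporadic_no_assoc = "Sporadic, no familial association",
  sporadic_equal_assoc = "Sporadic, equal familial association",
  sporadic_parent_assoc = "Sporadic, parent vs sib association",
  sporadic_free_assoc = "Sporadic, free familial association",
  general = "General transmission",
  homogeneous_general = "Homogeneous general",
  environmental = "Environmental (no transmission)",
  tau_ab_free = "Tau-AB-free (non-Mendelian)",
  codominant = "Mendelian codominant",
  dominant = "Mendelian dominant",
  recessive = "Mendelian recessive",
  additive = "Mendelian additive",
  decreasing = "Mendelian decreasing",
  increasing = "Mendelian increasing")

#' Available segregation model identifiers
#'
#' @return Character vector of model ids accepted by [build_model_spec()],
#'   in the conventional fitting order (four sporadic/association models,
#'   then the transmission models).
#' @export
model_ids <- function() MODEL_IDS

# working-scale metadata per parameter kind.
# beta/delta are optimized on their natural scale with box bounds;
# probabilities through a logit transform; monotone gaps as log drops.
KIND_META <- list(
  beta  = list(lower = -500, upper = 50,  lhs = c(-6, 2)),
  prob  = list(lower = -30,  upper = 30,  lhs = c(-2.5, 2.5)),
  delta = list(lower = -50,  upper = 50,  lhs = c(-1, 4)),
  gap   = list(lower = -30,  upper = 6.2, lhs = c(-2, 1.5))
)

free_tbl <- function(name, kind, start) {
  tibble::tibble(
    name = name, kind = kind, start = start,
    lower = vapply(kind, function(k) KIND_META[[k]]$lower, 0),
    upper = vapply(kind, function(k) KIND_META[[k]]$upper, 0),
    lhs_lo = vapply(kind, function(k) KIND_META[[k]]$lhs[1], 0),
    lhs_hi = vapply(kind, function(k) KIND_META[[k]]$lhs[2], 0)
  )
}

# natural-scale value of a working parameter
to_natural <- function(w, kind) {
  switch(kind, beta = w, delta = w, prob = stats::plogis(w), gap = exp(w))
}

assoc_free <- function(assoc) {
  switch(assoc,
         none = free_tbl(character(), character(), numeric()),
         equal = free_tbl("delta", "delta", 0.5),
         parent = free_tbl(c("delta_P", "delta_SS"), c("delta", "delta"),
                           c(0.5, 0.5)),
         free = free_tbl(c("delta_FO", "delta_MO", "delta_SS"),
                         rep("delta", 3), rep(0.5, 3)),
         stop("unknown association structure: ", assoc, call. = FALSE))
}

assoc_deltas <- function(assoc, nat) {
  switch(assoc,
         none = c(FM = 0, FO = 0, MO = 0, SS = 0),
         equal = c(FM = 0, FO = nat$delta, MO = nat$delta, SS = nat$delta),
         parent = c(FM = 0, FO = nat$delta_P, MO = nat$delta_P,
                    SS = nat$delta_SS),
         free = c(FM = 0, FO = nat$delta_FO, MO = nat$delta_MO,
                  SS = nat$delta_SS))
}

MENDELIAN_TAU <- c(AA = 1, AB = 0.5, BB = 0)

#' Build a named segregation model specification
#'
#' Returns the constraint set of one of the fourteen named models as a
#' `seg_model` object: which parameters are free (and on what optimizer
#' scale), and how a free-parameter vector resolves to a full
#' [seg_params()] set. The sporadic models (one susceptibility class, no
#' transmission) differ only in their familial-association structure; the
#' transmission models carry the association structure given by `assoc`
#' (default `"equal"`, i.e. \eqn{\delta_{FO} = \delta_{MO} = \delta_{SS}}).
#' The spouse association \eqn{\delta_{FM}} is fixed at 0 throughout.
#'
#' Free-parameter counts with `assoc = "equal"`: sporadic models 1-4,
#' dominant/recessive/additive 4, codominant/environmental/decreasing/
#' increasing 5, tau-AB-free 6, homogeneous general 7, general 8.
#'
#' @param model_id One of [model_ids()].
#' @param assoc Familial-association structure for the transmission models:
#'   `"equal"`, `"none"`, `"parent"` (FO = MO, SS separate) or `"free"`.
#' @return A `seg_model` object.
#' @examples
#' build_model_spec("dominant")
#' @export
build_model_spec <- function(model_id, assoc = "equal") {
  model_id <- match.arg(model_id, MODEL_IDS)
  assoc <- match.arg(assoc, c("equal", "none", "parent", "free"))

  beta3 <- function(b0 = -1) free_tbl(
    c("beta_AA", "beta_AB", "beta_BB"), rep("beta", 3), c(b0 + 0.5, b0, b0 - 2))
  qfree <- free_tbl("q_A", "prob", stats::qlogis(0.3))

  sporadic <- function(a) list(
    free = dplyr::bind_rows(free_tbl("beta", "beta", -1), assoc_free(a)),
    build = function(nat) list(
      params = seg_params(beta = rep(nat$beta, 3), q_A = 1,
                          tau = MENDELIAN_TAU, delta = assoc_deltas(a, nat)),
      penalty = 0))

  def <- switch(model_id,
    sporadic_no_assoc = sporadic("none"),
    sporadic_equal_assoc = sporadic("equal"),
    sporadic_parent_assoc = sporadic("parent"),
    sporadic_free_assoc = sporadic("free"),
    general = list(
      free = dplyr::bind_rows(beta3(), qfree,
        free_tbl(c("tau_AA", "tau_AB", "tau_BB"), rep("prob", 3),
                 stats::qlogis(c(0.9, 0.5, 0.1))), assoc_free(assoc)),
      build = function(nat) list(
        params = seg_params(beta = c(nat$beta_AA, nat$beta_AB, nat$beta_BB),
                            q_A = nat$q_A,
                            tau = c(nat$tau_AA, nat$tau_AB, nat$tau_BB),
                            delta = assoc_deltas(assoc, nat)),
        penalty = 0)),
    homogeneous_general = list(
      free = dplyr::bind_rows(beta3(), qfree,
        free_tbl(c("tau_AA", "tau_BB"), c("prob", "prob"),
                 stats::qlogis(c(0.9, 0.1))), assoc_free(assoc)),
      build = function(nat) {
        t_ab <- homogeneity_tau_ab(nat$q_A, nat$tau_AA, nat$tau_BB)
        viol <- max(0, t_ab - 1, -t_ab)
        list(params = seg_params(
               beta = c(nat$beta_AA, nat$beta_AB, nat$beta_BB),
               q_A = nat$q_A,
               tau = c(nat$tau_AA, min(1, max(0, t_ab)), nat$tau_BB),
               delta = assoc_deltas(assoc, nat)),
             penalty = 100 * viol + 1e4 * viol^2)
      }),
    environmental = list(
      free = dplyr::bind_rows(beta3(), qfree, assoc_free(assoc)),
      build = function(nat) list(
        params = seg_params(beta = c(nat$beta_AA, nat$beta_AB, nat$beta_BB),
                            q_A = nat$q_A, tau = rep(nat$q_A, 3),
                            delta = assoc_deltas(assoc, nat)),
        penalty = 0)),
    tau_ab_free = list(
      free = dplyr::bind_rows(beta3(), qfree,
        free_tbl("tau_AB", "prob", stats::qlogis(0.5)), assoc_free(assoc)),
      build = function(nat) list(
        params = seg_params(beta = c(nat$beta_AA, nat$beta_AB, nat$beta_BB),
                            q_A = nat$q_A, tau = c(1, nat$tau_AB, 0),
                            delta = assoc_deltas(assoc, nat)),
        penalty = 0)),
    codominant = list(
      free = dplyr::bind_rows(beta3(), qfree, assoc_free(assoc)),
      build = function(nat) list(
        params = seg_params(beta = c(nat$beta_AA, nat$beta_AB, nat$beta_BB),
                            q_A = nat$q_A, tau = MENDELIAN_TAU,
                            delta = assoc_deltas(assoc, nat)),
        penalty = 0)),
    dominant = list(
      free = dplyr::bind_rows(
        free_tbl(c("beta_AAB", "beta_BB"), c("beta", "beta"), c(-1, -3)),
        qfree, assoc_free(assoc)),
      build = function(nat) list(
        params = seg_params(beta = c(nat$beta_AAB, nat$beta_AAB, nat$beta_BB),
                            q_A = nat$q_A, tau = MENDELIAN_TAU,
                            delta = assoc_deltas(assoc, nat)),
        penalty = 0)),
    recessive = list(
      free = dplyr::bind_rows(
        free_tbl(c("beta_AA", "beta_ABB"), c("beta", "beta"), c(-1, -3)),
        qfree, assoc_free(assoc)),
      build = function(nat) list(
        params = seg_params(beta = c(nat$beta_AA, nat$beta_ABB, nat$beta_ABB),
                            q_A = nat$q_A, tau = MENDELIAN_TAU,
                            delta = assoc_deltas(assoc, nat)),
        penalty = 0)),
    additive = list(
      free = dplyr::bind_rows(
        free_tbl(c("beta_AA", "beta_BB"), c("beta", "beta"), c(-1, -3)),
        qfree, assoc_free(assoc)),
      build = function(nat) list(
        params = seg_params(
          beta = c(nat$beta_AA, (nat$beta_AA + nat$beta_BB) / 2, nat$beta_BB),
          q_A = nat$q_A, tau = MENDELIAN_TAU,
          delta = assoc_deltas(assoc, nat)),
        penalty = 0)),
    decreasing = list(
      free = dplyr::bind_rows(
        free_tbl("beta_AA", "beta", -0.5),
        free_tbl(c("gap_AB", "gap_BB"), c("gap", "gap"), c(0, 0)),
        qfree, assoc_free(assoc)),
      build = function(nat) {
        b_ab <- nat$beta_AA - nat$gap_AB
        b_bb <- b_ab - nat$gap_BB
        list(params = seg_params(
               beta = pmax(c(nat$beta_AA, b_ab, b_bb), -700),
               q_A = nat$q_A, tau = MENDELIAN_TAU,
               delta = assoc_deltas(assoc, nat)),
             penalty = 0)
      }),
    increasing = list(
      free = dplyr::bind_rows(
        free_tbl("beta_AA", "beta", -3),
        free_tbl(c("gap_AB", "gap_BB"), c("gap", "gap"), c(0, 0)),
        qfree, assoc_free(assoc)),
      build = function(nat) {
        b_ab <- nat$beta_AA + nat$gap_AB
        b_bb <- b_ab + nat$gap_BB
        list(params = seg_params(
               beta = pmin(c(nat$beta_AA, b_ab, b_bb), 500),
               q_A = nat$q_A, tau = MENDELIAN_TAU,
               delta = assoc_deltas(assoc, nat)),
             penalty = 0)
      })
  )

  structure(list(model_id = model_id,
                 label = MODEL_LABELS[[model_id]],
                 assoc = if (startsWith(model_id, "sporadic")) NA_character_
                         else assoc,
                 free = def$free,
                 build = def$build,
                 n_free = nrow(def$free)),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat("<seg_model>", x$model_id, "-", x$label, "\n")
  cat("  free parameters (", x$n_free, "): ",
      paste(x$free$name, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# resolve a working-scale vector to (seg_params, penalty)
resolve_model <- function(model, w) {
  stopifnot(inherits(model, "seg_model"), length(w) == model$n_free)
  nat <- as.list(mapply(to_natural, w, model$free$kind))
  names(nat) <- model$free$name
  model$build(nat)
}

# working-scale start vector
model_start <- function(model, prevalence = NULL) {
  s <- model$free$start
  if (!is.null(prevalence) && is.finite(prevalence)) {
    b0 <- stats::qlogis(min(max(prevalence, 0.02), 0.98))
    is_b <- model$free$kind == "beta"
    s[is_b] <- s[is_b] + b0 + 1   # defaults centred near -1
  }
  stats::setNames(s, model$free$name)
}
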