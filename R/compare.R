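#' Akaike's Information Criterion
#'
#' `AIC = -2 ln L + 2 * (number of estimated parameters)`; smaller values
#' indicate better fit.
#'
#' @param neg2lnL -2 log-likelihood.
#' @param n_estimated Number of estimated parameters (non-negative).
#' @return Numeric.
#' @examples
#' aic(284.88, 2)  # 288.88
#' @export
aic <- function(neg2lnL, n_estimated) {
  if (any(n_estimated < 0)) stop("n_estimated must be >= 0", call. = FALSE)
  neg2lnL + 2 * n_estimated
}

#' Likelihood-ratio test of a nested model against a more general one
#'
#' The statistic is the difference in -2 log-likelihoods (floored at zero),
#' referred to a chi-square distribution with degrees of freedom equal to the
#' difference in the number of estimated parameters.
#'
#' @param nested,general `seg_fit` objects (from [fit_model()] or
#'   [manual_fit()]) on the same data with the same ascertainment; `nested`
#'   must estimate strictly fewer parameters.
#' @return One-row tibble with `chi2`, `df` and `p`.
#' @examples
#' likelihood_ratio_test(manual_fit("homogeneous_general", 193.78, 7),
#'                       manual_fit("general", 193.50, 8))
#' @export
likelihood_ratio_test <- function(nested, general) {
  stopifnot(inherits(nested, "seg_fit"), inherits(general, "seg_fit"))
  df <- general$n_estimated - nested$n_estimated
  if (df <= 0)
    stop("models are not nested: nested model must estimate fewer parameters",
         call. = FALSE)
  chi2 <- max(0, nested$neg2lnL - general$neg2lnL)
  tibble::tibble(chi2 = chi2, df = as.integer(df),
                 p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Model-comparison table with LRT p-values and AIC
#'
#' Builds the standard segregation-analysis comparison table: one row per
#' fitted model with its -2 log-likelihood, estimated-parameter count,
#' likelihood-ratio p-value against the general model, and AIC. The best
#' model is the one with minimal AIC; ties are broken in favour of fewer
#' estimated parameters (parsimony).
#'
#' Some model classes are exact images of one another under relabeling of
#' the latent types (Mendelian dominant and recessive are the canonical
#' pair: swapping AA and BB maps one constraint set onto the other while
#' leaving Hardy-Weinberg priors and Mendelian transmission invariant), so
#' their maximized likelihoods coincide up to optimizer noise. AIC values
#' within `aic_tol` of the minimum are therefore treated as tied, and ties
#' resolve by fewer estimated parameters and then by the order the fits
#' were supplied in.
#'
#' @param fits List of `seg_fit` objects.
#' @param general_id Model id of the general (reference) model; rows with at
#'   least as many estimated parameters as the reference get no p-value.
#' @param aic_tol Numerical tolerance within which AIC values count as tied.
#' @return A `seg_comparison` tibble with attribute `best_model_id`;
#'   [ggplot2::autoplot()] draws the AIC comparison.
#' @export
compare_models <- function(fits, general_id = "general", aic_tol = 0.05) {
  if (inherits(fits, "seg_fit")) fits <- list(fits)
  ids <- vapply(fits, `[[`, character(1), "model_id")
  gi <- match(general_id, ids)
  if (is.na(gi))
    stop("general model '", general_id, "' not among the fits", call. = FALSE)
  gen <- fits[[gi]]
  rows <- lapply(fits, function(f) {
    p <- NA_real_
    if (f$model_id != general_id && f$n_estimated < gen$n_estimated)
      p <- likelihood_ratio_test(f, gen)$p
    tibble::tibble(model_id = f$model_id, neg2lnL = f$neg2lnL,
                   n_estimated = f$n_estimated, p_vs_general = p,
                   AIC = aic(f$neg2lnL, f$n_estimated),
                   converged = isTRUE(f$converged) | is.na(f$converged))
  })
  out <- dplyr::bind_rows(rows)
  ok <- which(is.finite(out$AIC))
  tied <- ok[out$AIC[ok] <= min(out$AIC[ok]) + aic_tol]
  best <- tied[order(out$n_estimated[tied], tied)][1]
  structure(dplyr::as_tibble(out),
            best_model_id = out$model_id[best],
            class = c("seg_comparison", class(out)))
}

#' Best-fitting model id from a comparison table
#'
#' @param comparison A `seg_comparison` from [compare_models()].
#' @return The model id with minimal AIC (ties to fewer parameters).
#' @export
best_model <- function(comparison) {
  attr(comparison, "best_model_id")
}

#' Fit a set of models and compare per family
#'
#' Refits each candidate model to every family separately and reports the
#' AIC-best model per family, supporting per-pedigree mode-of-inheritance
#' claims.
#'
#' @param ped Pedigree tibble.
#' @param models Character vector of model ids (must include `general_id` if
#'   p-values are wanted; only AIC is used for the per-family winner).
#' @param general_id Reference model id for p-values where present.
#' @param aic_tol AIC tie tolerance (see [compare_models()]).
#' @inheritParams fit_model
#' @return Tibble with one row per family: `family_id`, `best_model_id`,
#'   and the per-model AICs in wide columns.
#' @export
best_model_by_family <- function(ped, models, general_id = "general",
                                 ascertainment = "proband",
                                 n_starts = 10, seed = 1L, aic_tol = 0.05) {
  ped <- as_ped_tibble(ped)
  fams <- ped_split(ped)
  rows <- lapply(fams, function(p) {
    fits <- lapply(models, function(m)
      fit_model(p, m, ascertainment = ascertainment,
                n_starts = n_starts, seed = seed))
    aics <- vapply(fits, function(f) aic(f$neg2lnL, f$n_estimated), 0)
    nest <- vapply(fits, `[[`, integer(1), "n_estimated")
    tied <- which(aics <= min(aics) + aic_tol)
    best <- models[tied[order(nest[tied], tied)][1]]
    out <- tibble::tibble(family_id = p$family_id[1], best_model_id = best)
    out[paste0("AIC_", models)] <- as.list(aics)
    out
  })
  dplyr::bind_rows(rows)
}

#' @export
print.seg_comparison <- function(x, ...) {
  cat("Segregation model comparison (best by AIC:",
      attr(x, "best_model_id"), ")\n")
  NextMethod()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' AIC comparison plot
#'
#' @param object A `seg_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot: AIC per model, best model highlighted.
#' @export
autoplot.seg_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$model_id <- factor(df$model_id, levels = df$model_id)
  df$best <- df$model_id == attr(object, "best_model_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_id, y = .data$AIC,
                                   fill = .data$best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#2166AC")) +
    ggplot2::labs(x = NULL, y = "AIC") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
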