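#' Published model-comparison statistics from the motivating AS family study
#'
#' The -2 log-likelihoods, estimated-parameter counts and printed
#' p-values/AIC from the nine-family Chinese Han ankylosing-spondylitis
#' segregation study that motivates this package, as printed in its two
#' comparison tables. The `stage` column separates the
#' familial-association stage (four sporadic models) from the transmission
#' stage. Together with [manual_fit()] and [compare_models()] these allow
#' the study's model-comparison arithmetic to be replayed exactly; the raw
#' pedigrees themselves were never deposited.
#'
#' @return Tibble with columns `stage`, `model_id`, `neg2lnL`,
#'   `n_estimated`, `printed_p`, `printed_AIC`.
#' @export
published_model_stats <- function() {
  readr::read_tsv(system.file("extdata", "published_model_stats.tsv",
                              package = "segfam"),
                  col_types = "ccdicd")
}

#' Published sample composition of the motivating AS family study
#'
#' Individual counts by sex and relationship-pair counts (with
#' concordant-affected pairs) as tabulated by the nine-family
#' ankylosing-spondylitis study. The first rows are individual counts
#' (affected individuals); the relationship rows are pair counts
#' (concordant-affected pairs).
#'
#' @return Tibble with columns `group`, `n`, `n_affected_or_concordant`.
#' @export
study_sample_counts <- function() {
  readr::read_tsv(system.file("extdata", "study_sample_counts.tsv",
                              package = "segfam"),
                  col_types = "cii")
}

#' Replay a published model-comparison stage
#'
#' Rebuilds a [compare_models()] table from published `-2lnL` /
#' parameter-count rows (e.g. [published_model_stats()]), recomputing every
#' likelihood-ratio p-value and AIC from scratch.
#'
#' @param stats Tibble with columns `model_id`, `neg2lnL`, `n_estimated`.
#' @param general_id Reference model id present in `stats`.
#' @return A `seg_comparison` tibble.
#' @examples
#' stats <- dplyr::filter(published_model_stats(), stage == "transmission")
#' replay_comparison(stats, "general")
#' @export
replay_comparison <- function(stats, general_id = "general") {
  fits <- purrr::pmap(stats[c("model_id", "neg2lnL", "n_estimated")],
                      manual_fit)
  compare_models(fits, general_id = general_id)
}
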