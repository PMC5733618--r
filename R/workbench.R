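STAGE1_MODELS <- MODEL_IDS[1:4]
STAGE2_MODELS <- c("general", "homogeneous_general", "environmental",
                   "tau_ab_free", "codominant", "dominant", "recessive",
                   "additive", "decreasing")

assoc_of_sporadic <- c(sporadic_no_assoc = "none",
                       sporadic_equal_assoc = "equal",
                       sporadic_parent_assoc = "parent",
                       sporadic_free_assoc = "free")

#' Run the two-stage segregation analysis
#'
#' Stage 1 fits the four sporadic models (differing only in their
#' familial-association structure) and selects the structure by AIC with
#' parsimony tie-break. Stage 2 fits the transmission models carrying that
#' association structure and compares each against the general model by
#' likelihood-ratio test and AIC. A `--one-stage` style analysis (all
#' transmission models with a fixed structure) is available via
#' `one_stage = TRUE`.
#'
#' @param ped Pedigree tibble, or a PED file path.
#' @param probands Optional proband sidecar path (when `ped` is a path).
#' @param models Transmission-stage model ids (default: the nine
#'   transmission models, general through Mendelian decreasing; the selected
#'   sporadic model is added to the comparison automatically).
#' @param ascertainment `"proband"` or `"none"`.
#' @param one_stage Skip stage 1 and use `assoc` directly.
#' @param assoc Association structure when `one_stage = TRUE`.
#' @param out_dir Optional directory: comparison TSV/JSON, per-fit estimates
#'   and a manifest are written there.
#' @param seed Integer seed (multistart designs).
#' @param n_starts Optimizer starts per model.
#' @return List of class `seg_run`: `stage1` (comparison of sporadic
#'   models, unless `one_stage`), `assoc` (selected structure),
#'   `comparison` (stage-2 `seg_comparison`), `fits` (named list of
#'   `seg_fit`), `best_model_id`.
#' @export
run_fit <- function(ped, probands = NULL, models = STAGE2_MODELS,
                    ascertainment = "proband", one_stage = FALSE,
                    assoc = "equal", out_dir = NULL, seed = 1L,
                    n_starts = 20) {
  if (is.character(ped) && length(ped) == 1)
    ped <- read_ped(ped, probands = probands)
  ped <- as_ped_tibble(ped)

  stage1 <- NULL
  if (!one_stage) {
    s1_fits <- lapply(STAGE1_MODELS, function(m)
      fit_model(ped, m, ascertainment = ascertainment,
                n_starts = n_starts, seed = seed))
    stage1 <- compare_models(s1_fits, general_id = "sporadic_free_assoc")
    ok <- which(is.finite(stage1$AIC))
    pick <- stage1$model_id[ok][order(stage1$AIC[ok],
                                      stage1$n_estimated[ok])][1]
    assoc <- assoc_of_sporadic[[pick]]
  }
  if (!"general" %in% models)
    stop("the transmission stage requires the general model", call. = FALSE)
  fits <- lapply(models, function(m)
    fit_model(ped, build_model_spec(m, assoc = assoc),
              ascertainment = ascertainment, n_starts = n_starts,
              seed = seed))
  names(fits) <- models
  if (!isTRUE(fits[["general"]]$converged))
    warning("general model did not converge; comparisons are unreliable",
            call. = FALSE)
  # include the stage-1 winner row for reference, as comparison tables do
  if (!one_stage) {
    sp <- s1_fits[[match(names(assoc_of_sporadic)[assoc_of_sporadic == assoc],
                         STAGE1_MODELS)]]
    fits <- c(stats::setNames(list(sp), sp$model_id), fits)
  }
  comparison <- compare_models(fits, general_id = "general")

  out <- structure(list(stage1 = stage1, assoc = assoc,
                        comparison = comparison, fits = fits,
                        best_model_id = best_model(comparison),
                        seed = seed, ascertainment = ascertainment),
                   class = "seg_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.seg_run <- function(x, ...) {
  if (!is.null(x$stage1)) {
    cat("Stage 1 (familial association):\n")
    print(x$stage1)
    cat("Selected association structure:", x$assoc, "\n\n")
  }
  cat("Stage 2 (transmission models):\n")
  print(x$comparison)
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(run$comparison),
                   file.path(out_dir, "comparison.tsv"))
  if (!is.null(run$stage1))
    readr::write_tsv(tibble::as_tibble(run$stage1),
                     file.path(out_dir, "stage1.tsv"))
  ests <- lapply(run$fits, function(f) {
    g <- as.list(glance(f))
    g$estimates <- if (is.null(f$estimates)) NULL else unclass(f$estimates)
    g$boundary <- as.list(f$boundary)
    g
  })
  jsonlite::write_json(
    list(best_model_id = run$best_model_id, assoc = run$assoc,
         seed = run$seed, ascertainment = run$ascertainment, fits = ests),
    file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = run$seed, ascertainment = run$ascertainment,
                   assoc = run$assoc,
                   models = names(run$fits),
                   package_version = as.character(
                     utils::packageVersion("segfam")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Simulate a study dataset and write it to disk
#'
#' Runs [simulate_study()] and writes the PED file, the proband sidecar, a
#' truth table (member, latent type, susceptibility under the truth) and a
#' sample summary TSV. Two runs with the same configuration produce
#' byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return The simulated pedigree tibble, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  ped <- simulate_study(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ped(ped, file.path(out_dir, "families.ped"),
            probands = file.path(out_dir, "probands.txt"))
  th <- vapply(seq_len(nrow(ped)), function(i)
    regressive_logit(ped$.true_type[i], config$truth), 0)
  readr::write_tsv(
    tibble::tibble(family_id = ped$family_id, id = ped$id,
                   true_type = ped$.true_type,
                   baseline_gamma = susceptibility(th, 1)),
    file.path(out_dir, "truth.tsv"))
  readr::write_tsv(summarize_sample(ped), file.path(out_dir, "summary.tsv"))
  invisible(ped)
}
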