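REL_CLASSES <- c("parent_offspring", "sib_sib", "sister_sister",
                 "brother_brother", "sister_brother", "grandparental",
                 "avuncular", "cousin")

#' Count blood-relative pairs by relationship class
#'
#' Classifies every unordered pair of members of each family by blood
#' relationship through the parent graph and tallies totals and
#' concordant-affected pairs (both members affected; members of unknown
#' status never count as concordant). Classes are the standard consanguinity
#' classes: parent-offspring, full sibs (also decomposed by sex),
#' grandparent-grandchild (exactly two generations), avuncular (full sib of a
#' parent), and first cousins (children of full sibs). In-law pairs and more
#' distant relationships are ignored.
#'
#' @param ped Pedigree tibble (one or more families).
#' @return A tibble with columns `class`, `n_pairs`,
#'   `n_concordant_affected`, summed over families, with the sex-specific sib
#'   rows summing to `sib_sib`.
#' @export
count_relationship_pairs <- function(ped) {
  ped <- as_ped_tibble(ped)
  diag <- validate_pedigree(ped)
  if (nrow(diag))
    stop("invalid pedigree: ", diag$message[1], call. = FALSE)
  fams <- ped_split(ped)
  tot <- matrix(0L, length(REL_CLASSES), 2,
                dimnames = list(REL_CLASSES, c("pairs", "concordant")))
  for (p in fams) tot <- tot + count_pairs_one(p)
  tibble::tibble(class = REL_CLASSES,
                 n_pairs = as.integer(tot[, 1]),
                 n_concordant_affected = as.integer(tot[, 2]))
}

count_pairs_one <- function(p) {
  n <- nrow(p)
  fa <- match(p$father_id, p$id)
  mo <- match(p$mother_id, p$id)
  # parent indicator: P[i, j] TRUE if j is a parent of i
  P <- matrix(FALSE, n, n)
  ok <- !is.na(fa); P[cbind(which(ok), fa[ok])] <- TRUE
  ok <- !is.na(mo); P[cbind(which(ok), mo[ok])] <- TRUE
  # full sibs: same father and mother, both listed
  sibkey <- ifelse(is.na(fa), NA, paste(fa, mo))
  S <- !is.na(outer(sibkey, sibkey, "==")) & outer(sibkey, sibkey, "==")
  S[is.na(S)] <- FALSE
  diag(S) <- FALSE
  # grandparental: j is parent of a parent of i
  G <- (P %*% P) > 0
  # avuncular: j is full sib of a parent of i
  A <- (P %*% S) > 0
  # first cousins: a parent of i is a full sib of a parent of j
  C <- (P %*% S %*% t(P)) > 0

  aff <- p$affection == "affected"
  male <- p$sex == "male"
  up <- upper.tri(matrix(0, n, n))
  count <- function(M, restrict = TRUE) {
    M <- (M | t(M)) & up & restrict
    c(sum(M), sum(M & outer(aff, aff, "&")))
  }
  sib_ff <- outer(!male, !male, "&")
  sib_mm <- outer(male, male, "&")
  sib_fm <- outer(male, !male, "&") | outer(!male, male, "&")
  rbind(parent_offspring = count(P),
        sib_sib = count(S),
        sister_sister = count(S, sib_ff),
        brother_brother = count(S, sib_mm),
        sister_brother = count(S, sib_fm),
        grandparental = count(G),
        avuncular = count(A),
        cousin = count(C))
}

#' Summary statistics for a pedigree sample
#'
#' Sample-level descriptives in the style of a family-study "characteristics"
#' table: totals by sex, affected counts and percentages by sex (unknown
#' status members are excluded from the numerator but kept in the sex
#' denominators), pedigree-size mean and SD, and the generation-count range.
#'
#' @param ped Pedigree tibble with at least one family.
#' @return A one-row tibble.
#' @export
summarize_sample <- function(ped) {
  ped <- as_ped_tibble(ped)
  if (!nrow(ped)) stop("no pedigrees to summarize", call. = FALSE)
  fams <- ped_split(ped)
  sizes <- vapply(fams, nrow, integer(1))
  gens <- vapply(fams, function(p) max(generation_numbers(p)), integer(1))
  male <- ped$sex == "male"
  aff <- ped$affection == "affected"
  tibble::tibble(
    n_families = length(fams),
    n_members = nrow(ped),
    n_male = sum(male),
    n_female = sum(!male),
    n_affected = sum(aff),
    n_affected_male = sum(aff & male),
    n_affected_female = sum(aff & !male),
    pct_affected_male = 100 * sum(aff & male) / sum(male),
    pct_affected_female = 100 * sum(aff & !male) / sum(!male),
    male_female_affected_ratio = pct_affected_male / pct_affected_female,
    mean_size = mean(sizes),
    sd_size = stats::sd(sizes),
    min_generations = min(gens),
    max_generations = max(gens)
  )
}

#' Descriptives from published sample margins
#'
#' Computes the headline descriptive statistics (percent affected by sex,
#' male:female affected ratio, mean pedigree size) directly from tabulated
#' sample counts, for use when only a study's printed margins are available
#' rather than individual-level data.
#'
#' @param n_male,n_affected_male,n_female,n_affected_female,n_families Counts.
#' @return A one-row tibble with `pct_affected_male`, `pct_affected_female`,
#'   `male_female_affected_ratio` and `mean_size`.
#' @examples
#' sample_descriptives(169, 43, 146, 31, 9)
#' @export
sample_descriptives <- function(n_male, n_affected_male,
                                n_female, n_affected_female, n_families) {
  pm <- 100 * n_affected_male / n_male
  pf <- 100 * n_affected_female / n_female
  tibble::tibble(
    pct_affected_male = pm,
    pct_affected_female = pf,
    male_female_affected_ratio = pm / pf,
    mean_size = (n_male + n_female) / n_families
  )
}
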