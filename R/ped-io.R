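PED_COLS <- c("family_id", "id", "father_id", "mother_id", "sex",
              "affection", "is_proband", "birth_order")

#' Read pedigrees from a LINKAGE/PLINK PED-style file
#'
#' Parses a whitespace- or tab-delimited pre-makeped pedigree file with
#' columns `FID IID PAT MAT SEX PHENO [PROBAND] [COVARIATES...]`. Parent id
#' `0` denotes a founder; `SEX` is 1 = male, 2 = female; `PHENO` is
#' 2 = affected, 1 = unaffected, 0 or -9 = unknown. Probands can come from an
#' optional 7th 0/1 column (`proband_col = TRUE`) or a sidecar file with
#' `FID IID` per line (`probands=`). Birth order is assigned by file order
#' within each sibship (same family and parent couple).
#'
#' @param path Path to the PED file.
#' @param probands Optional path to a proband sidecar file (`FID IID` lines).
#' @param proband_col Is the 7th column a 0/1 proband flag?
#' @param covariate_names Optional names for trailing numeric covariate
#'   columns; defaults to `cov1`, `cov2`, ...
#' @param validate Run [validate_pedigree()] and error on violations?
#' @return A tibble with one row per individual and columns `family_id`,
#'   `id`, `father_id`, `mother_id`, `sex`, `affection`, `is_proband`,
#'   `birth_order`, plus any covariates. Rows keep file order.
#' @seealso [write_ped()], [validate_pedigree()]
#' @export
read_ped <- function(path, probands = NULL, proband_col = FALSE,
                     covariate_names = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty pedigree file: ", path, call. = FALSE)
    return(empty_pedigree())
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  min_cols <- 6L + as.integer(proband_col)
  bad <- which(nf < min_cols)
  if (length(bad))
    stop(sprintf("malformed line %d: expected at least %d fields, found %d",
                 bad[1], min_cols, nf[bad[1]]), call. = FALSE)
  if (length(unique(nf)) > 1)
    stop(sprintf("malformed line %d: ragged field count (%d vs %d)",
                 which(nf != nf[1])[1], nf[which(nf != nf[1])[1]], nf[1]),
         call. = FALSE)
  m <- do.call(rbind, fields)

  sex_raw <- m[, 5]
  if (!all(sex_raw %in% c("1", "2")))
    stop(sprintf("malformed line %d: SEX must be 1 or 2",
                 which(!sex_raw %in% c("1", "2"))[1]), call. = FALSE)
  ph_raw <- m[, 6]
  if (!all(ph_raw %in% c("2", "1", "0", "-9")))
    stop(sprintf("malformed line %d: PHENO must be 2, 1, 0 or -9",
                 which(!ph_raw %in% c("2", "1", "0", "-9"))[1]), call. = FALSE)

  ped <- tibble::tibble(
    family_id = m[, 1],
    id = m[, 2],
    father_id = dplyr::na_if(m[, 3], "0"),
    mother_id = dplyr::na_if(m[, 4], "0"),
    sex = dplyr::if_else(sex_raw == "1", "male", "female"),
    affection = dplyr::case_when(ph_raw == "2" ~ "affected",
                                 ph_raw == "1" ~ "unaffected",
                                 TRUE ~ "unknown"),
    is_proband = if (proband_col) m[, 7] == "1" else FALSE
  )
  ncov <- ncol(m) - 6L - as.integer(proband_col)
  if (ncov > 0) {
    cov <- m[, (ncol(m) - ncov + 1L):ncol(m), drop = FALSE]
    suppressWarnings(storage.mode(cov) <- "double")
    if (anyNA(cov))
      stop("non-numeric covariate value in PED file", call. = FALSE)
    colnames(cov) <- covariate_names %||% paste0("cov", seq_len(ncov))
    ped <- dplyr::bind_cols(ped, tibble::as_tibble(cov))
  }
  ped <- assign_birth_order(ped)
  if (!is.null(probands)) ped <- apply_probands(ped, probands)
  if (validate) {
    diag <- validate_pedigree(ped)
    if (nrow(diag))
      stop("invalid pedigree file: ", diag$message[1],
           sprintf(" (and %d more)", nrow(diag) - 1L)[nrow(diag) > 1],
           call. = FALSE)
  }
  ped
}

empty_pedigree <- function() {
  tibble::tibble(family_id = character(), id = character(),
                 father_id = character(), mother_id = character(),
                 sex = character(), affection = character(),
                 is_proband = logical(), birth_order = integer())
}

assign_birth_order <- function(ped) {
  key <- paste(ped$family_id, ped$father_id, ped$mother_id, sep = "\r")
  key[is.na(ped$father_id)] <- NA
  bo <- integer(nrow(ped))
  for (k in unique(key[!is.na(key)])) {
    idx <- which(!is.na(key) & key == k)
    bo[idx] <- seq_along(idx)
  }
  bo[is.na(key)] <- 1L
  ped$birth_order <- bo
  ped
}

apply_probands <- function(ped, path) {
  if (!file.exists(path)) stop("proband file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ped$is_proband <- FALSE
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) != 2)
      stop("proband sidecar lines must be 'FID IID'", call. = FALSE)
    hit <- ped$family_id == f[1] & ped$id == f[2]
    if (!any(hit))
      stop("proband ", f[2], " not found in family ", f[1], call. = FALSE)
    ped$is_proband[hit] <- TRUE
  }
  ped
}

#' Write pedigrees to a PED-style file
#'
#' Inverse of [read_ped()]: affection is written as 2/1/0, missing parents as
#' 0. A read-write-read cycle reproduces the pedigree tibble field for field.
#'
#' @param ped Pedigree tibble (see [read_ped()]).
#' @param path Output PED path.
#' @param probands Optional path for a proband sidecar file (`FID IID`).
#' @param proband_col Write the proband flag as a 7th column instead?
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, probands = NULL, proband_col = FALSE) {
  cov <- setdiff(names(ped), PED_COLS)
  cov <- cov[!startsWith(cov, ".")]
  out <- cbind(
    ped$family_id, ped$id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    ifelse(ped$sex == "male", "1", "2"),
    dplyr::case_when(ped$affection == "affected" ~ "2",
                     ped$affection == "unaffected" ~ "1",
                     TRUE ~ "0")
  )
  if (proband_col) out <- cbind(out, ifelse(ped$is_proband, "1", "0"))
  for (cc in cov) out <- cbind(out, format(ped[[cc]], trim = TRUE))
  writeLines(apply(out, 1, paste, collapse = "\t"), path)
  if (!is.null(probands)) {
    pb <- ped[ped$is_proband, c("family_id", "id")]
    writeLines(paste(pb$family_id, pb$id, sep = "\t"), probands)
  }
  invisible(path)
}

#' Structural validation of a pedigree tibble
#'
#' Checks the invariants the likelihood engine relies on: referenced parents
#' exist, fathers are male and mothers female, parents are both present or
#' both absent, ids are unique within a family, the parent graph is acyclic,
#' birth order is unique within each sibship, and each family has at most one
#' proband (single ascertainment) who, if present, is affected.
#'
#' @param ped Pedigree tibble.
#' @return A tibble of diagnostics (`family_id`, `id`, `rule`, `message`);
#'   zero rows when every invariant holds.
#' @export
validate_pedigree <- function(ped) {
  ped <- as_ped_tibble(ped)
  out <- list()
  add <- function(fid, id, rule, msg)
    out[[length(out) + 1L]] <<- tibble::tibble(
      family_id = fid, id = id, rule = rule, message = msg)

  for (fid in unique(ped$family_id)) {
    p <- ped[ped$family_id == fid, ]
    dup <- p$id[duplicated(p$id)]
    for (d in unique(dup))
      add(fid, d, "duplicate_id", paste0("duplicate id '", d,
                                         "' in family ", fid))
    half <- is.na(p$father_id) != is.na(p$mother_id)
    for (i in which(half))
      add(fid, p$id[i], "half_specified_parents",
          paste0("individual ", p$id[i], " has exactly one parent listed"))
    for (i in seq_len(nrow(p))) {
      for (side in c("father", "mother")) {
        pid <- p[[paste0(side, "_id")]][i]
        if (is.na(pid)) next
        j <- match(pid, p$id)
        if (is.na(j)) {
          add(fid, p$id[i], "missing_parent",
              paste0(side, " '", pid, "' of ", p$id[i], " not in family ", fid))
        } else {
          want <- if (side == "father") "male" else "female"
          if (p$sex[j] != want)
            add(fid, p$id[i], "parent_sex",
                paste0(side, " '", pid, "' of ", p$id[i], " is not ", want))
        }
      }
    }
    # cycle check via repeated founder stripping (Kahn)
    ids <- p$id
    fa <- match(p$father_id, ids); mo <- match(p$mother_id, ids)
    done <- rep(FALSE, nrow(p))
    parent_done <- function(idx) is.na(idx) | done[replace(idx, is.na(idx), 1L)]
    repeat {
      ready <- !done & parent_done(fa) & parent_done(mo)
      if (!any(ready)) break
      done[ready] <- TRUE
    }
    for (i in which(!done))
      add(fid, p$id[i], "cycle",
          paste0("individual ", p$id[i], " is their own ancestor"))
    # birth order unique within sibship
    sib <- paste(p$father_id, p$mother_id)
    for (k in unique(sib[!is.na(p$father_id)])) {
      idx <- which(sib == k & !is.na(p$father_id))
      if (anyDuplicated(p$birth_order[idx]))
        add(fid, p$id[idx[1]], "birth_order",
            paste0("duplicate birth_order in sibship of ", p$id[idx[1]]))
    }
    npb <- sum(p$is_proband)
    if (npb > 1)
      add(fid, NA_character_, "multiple_probands",
          paste0("family ", fid, " has ", npb, " probands"))
    if (npb == 1 && p$affection[p$is_proband][1] != "affected")
      add(fid, p$id[p$is_proband][1], "proband_unaffected",
          paste0("proband ", p$id[p$is_proband][1], " is not affected"))
  }
  if (!length(out))
    return(tibble::tibble(family_id = character(), id = character(),
                          rule = character(), message = character()))
  dplyr::bind_rows(out)
}

as_ped_tibble <- function(ped) {
  if (!is.data.frame(ped)) stop("ped must be a data frame", call. = FALSE)
  miss <- setdiff(setdiff(PED_COLS, "birth_order"), names(ped))
  if (length(miss))
    stop("pedigree is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ped <- tibble::as_tibble(ped)
  if (!"birth_order" %in% names(ped)) ped <- assign_birth_order(ped)
  ped
}

# split a multi-family tibble into a named list of per-family tibbles,
# preserving row order
ped_split <- function(ped) {
  ped <- as_ped_tibble(ped)
  split(ped, factor(ped$family_id, levels = unique(ped$family_id)))
}

# generation number: founders 1, child = max(parent generations) + 1
generation_numbers <- function(p) {
  fa <- match(p$father_id, p$id); mo <- match(p$mother_id, p$id)
  g <- ifelse(is.na(fa), 1L, NA_integer_)
  while (anyNA(g)) {
    todo <- which(is.na(g) & !is.na(g[fa]) & !is.na(g[mo]))
    if (!length(todo)) stop("cannot order pedigree (cycle?)", call. = FALSE)
    g[todo] <- pmax(g[fa[todo]], g[mo[todo]]) + 1L
  }
  g
}
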