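#' Mean arterial pressure from systolic and diastolic readings
#'
#' MAP summarises a blood-pressure reading as `(2 * DBP + SBP) / 3`,
#' weighting the diastolic phase double because the heart spends roughly
#' two thirds of the cardiac cycle in diastole.
#'
#' @param sbp,dbp Systolic and diastolic blood pressure in mmHg;
#'   vectorised. Requires `sbp >= dbp > 0`.
#' @return MAP in mmHg, same length as the inputs.
#' @examples
#' compute_map(120, 80)
#' @export
compute_map <- function(sbp, dbp) {
  if (!is.numeric(sbp) || !is.numeric(dbp) || length(sbp) != length(dbp)) {
    stop_invalid("`sbp` and `dbp` must be numeric vectors of equal length.")
  }
  ok <- is.na(sbp) | is.na(dbp)
  if (any(!ok & dbp <= 0)) {
    stop_invalid("Diastolic pressure must be positive.")
  }
  if (any(!ok & sbp < dbp)) {
    stop_invalid("Systolic pressure cannot be below diastolic pressure.")
  }
  (2 * dbp + sbp) / 3
}

#' Validate a pedigree table
#'
#' Checks that parent ids either reference individuals present in the
#' table or are the missing code `"0"`, and that the parent graph is
#' acyclic (no individual is its own ancestor).
#'
#' @param pedigree A tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`.
#' @return The pedigree, invisibly, or an error.
#' @export
validate_pedigree <- function(pedigree) {
  required <- c("family_id", "individual_id", "father_id", "mother_id")
  if (!is.data.frame(pedigree) || !all(required %in% names(pedigree))) {
    stop_invalid(paste0("`pedigree` must have columns: ",
                        paste(required, collapse = ", "), "."))
  }
  ids <- as.character(pedigree$individual_id)
  if (anyDuplicated(ids)) stop_invalid("Pedigree individual ids must be unique.")
  fa <- as.character(pedigree$father_id)
  mo <- as.character(pedigree$mother_id)
  ref <- c(fa, mo)
  bad <- ref != "0" & !(ref %in% ids)
  if (any(bad)) {
    stop_invalid(sprintf("Parent id '%s' does not reference any individual.",
                         ref[bad][1L]))
  }
  # acyclicity: iteratively peel individuals whose parents are resolved
  remaining <- setNames(rep(TRUE, length(ids)), ids)
  repeat {
    parent_in <- (fa != "0" & remaining[fa]) | (mo != "0" & remaining[mo])
    parent_in[is.na(parent_in)] <- FALSE
    peel <- remaining[ids] & !parent_in
    if (!any(peel)) break
    remaining[ids[peel]] <- FALSE
  }
  if (any(remaining)) {
    stop_invalid(sprintf("Pedigree contains a cycle involving '%s'.",
                         names(remaining)[remaining][1L]))
  }
  invisible(pedigree)
}

#' Break pedigrees into parent-offspring trios
#'
#' One trio per eligible offspring: both declared parents genotyped, and
#' the offspring both genotyped and phenotyped (non-missing MAP). An
#' individual may parent several trios and appear as offspring in at most
#' one; a nuclear family with k eligible siblings yields k trios.
#'
#' @param g A [genotype_matrix()].
#' @param pedigree A pedigree tibble ([read_ped_map()] format).
#' @param pheno A phenotype tibble with `individual_id` and `map_value`.
#' @return A `trio_set`: a tibble with columns `family_id`, `father`,
#'   `mother`, `offspring` (ids into `g`). May be empty.
#' @export
extract_trios <- function(g, pedigree, pheno) {
  validate_pedigree(pedigree)
  gen_ids <- individual_ids(g)
  phenotyped <- pheno$individual_id[!is.na(pheno$map_value)]
  fa <- as.character(pedigree$father_id)
  mo <- as.character(pedigree$mother_id)
  ids <- as.character(pedigree$individual_id)
  eligible <- fa != "0" & mo != "0" &
    fa %in% gen_ids & mo %in% gen_ids &
    ids %in% gen_ids & ids %in% phenotyped
  out <- tibble::tibble(
    family_id = as.character(pedigree$family_id)[eligible],
    father = fa[eligible],
    mother = mo[eligible],
    offspring = ids[eligible]
  )
  class(out) <- c("trio_set", class(out))
  out
}
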