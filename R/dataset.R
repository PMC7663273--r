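#' Eligibility fixpoint over a sparse interaction-index map
#'
#' A curated training set must give every target at least three established
#' (index 1) ligands and every ligand at least three established targets.
#' Removing an entity deletes all of its entries (including index-0 ones),
#' which can invalidate others, so the thresholds are enforced iteratively
#' until stable.  The result is the unique maximal sub-map in which every
#' surviving protein and ligand meets its threshold; it does not depend on
#' the removal order.
#'
#' @param indices data.frame with columns \code{protein_id},
#'   \code{ligand_id}, \code{index} (0/1 only, no \code{NA}).
#' @param min_ligands,min_targets thresholds (default 3 and 3).
#' @return the reduced data.frame (possibly empty).
#' @export
eligibility_fixpoint <- function(indices, min_ligands = 3, min_targets = 3) {
  if (!nrow(indices)) return(indices)
  if (any(is.na(indices$index)) || !all(indices$index %in% c(0L, 1L)))
    stop("indices must contain only 0/1 entries")
  repeat {
    pos <- indices[indices$index == 1L, , drop = FALSE]
    p_ok <- names(which(table(pos$protein_id) >= min_ligands))
    l_ok <- names(which(table(pos$ligand_id) >= min_targets))
    keep <- indices$protein_id %in% p_ok & indices$ligand_id %in% l_ok
    if (all(keep)) break
    indices <- indices[keep, , drop = FALSE]
    if (!nrow(indices)) break
  }
  rownames(indices) <- NULL
  indices
}

#' Assemble a curated interaction dataset
#'
#' Composes the curation pipeline: restrict the affinity table to one
#' parameter, integrate each pair's records into an interaction index
#' ([interaction_indices()]), drop excluded pairs, apply the ligand
#' structure filters ([filter_structures()], remapping merged duplicate ids
#' onto their surviving record), and enforce the eligibility fixpoint
#' ([eligibility_fixpoint()]).
#'
#' @param records affinity-record table (see [affinity_records()]).
#' @param sequences named character vector of protein sequences.
#' @param structures named list of \code{ligand_structure} objects, or a
#'   data.frame with columns \code{ligand_id}, \code{smiles}.
#' @param parameter interaction parameter subset to curate.
#' @param cutoff_umol interaction cutoff in umol/L.
#' @param mna_level MNA level for the duplicate-compound check.
#' @param allow_empty return an empty dataset instead of erroring when
#'   curation removes everything.
#' @return an \code{"InteractionDataset"}: list with \code{proteins} (named
#'   character), \code{ligands} (named list of structures), \code{indices}
#'   (data.frame \code{protein_id, ligand_id, index}), \code{parameter},
#'   \code{cutoff_umol} and a curation \code{report}.
#' @export
build_dataset <- function(records, sequences, structures, parameter,
                          cutoff_umol, mna_level = 2, allow_empty = FALSE) {
  if (is.data.frame(structures))
    structures <- parse_smiles(structures$smiles, structures$ligand_id)
  idx <- interaction_indices(records, parameter, cutoff_umol,
                             keep_excluded = TRUE)
  n_excluded <- sum(is.na(idx$index))
  idx <- idx[!is.na(idx$index), c("protein_id", "ligand_id", "index")]

  filtered <- filter_structures(structures, mna_level = mna_level)
  freport <- attr(filtered, "report")
  # remap merged duplicate ids onto the surviving canonical record
  remap <- list()
  for (s in filtered) for (src in s$source_ids) remap[[src]] <- s$ligand_id
  known <- idx$ligand_id %in% names(remap)
  idx <- idx[known, , drop = FALSE]
  if (nrow(idx))
    idx$ligand_id <- vapply(idx$ligand_id, function(id) remap[[id]], character(1))
  # merging can create duplicate (protein, canonical-ligand) rows; a clash of
  # indices between merged twins would be contradictory data -> drop the pair
  if (nrow(idx)) {
    key <- paste(idx$protein_id, idx$ligand_id, sep = "\r")
    agg <- tapply(idx$index, key, function(v) if (length(unique(v)) == 1L)
      v[1L] else NA_integer_)
    idx <- data.frame(protein_id = sub("\r.*", "", names(agg)),
                      ligand_id = sub(".*\r", "", names(agg)),
                      index = as.integer(agg), stringsAsFactors = FALSE)
    idx <- idx[!is.na(idx$index), , drop = FALSE]
  }

  idx <- eligibility_fixpoint(idx)
  if (!nrow(idx) && !allow_empty)
    stop("curation removed every protein-ligand pair; nothing to train on")

  prot_ids <- sort(unique(idx$protein_id))
  lig_ids <- sort(unique(idx$ligand_id))
  missing_seq <- setdiff(prot_ids, names(sequences))
  if (length(missing_seq))
    stop("no sequence for surviving protein(s): ",
         paste(missing_seq, collapse = ", "))

  ds <- list(proteins = toupper(sequences[prot_ids]),
             ligands = filtered[lig_ids],
             indices = idx,
             parameter = parameter,
             cutoff_umol = cutoff_umol,
             mna_level = mna_level,
             report = list(pairs_excluded = n_excluded,
                           structures = freport,
                           n_proteins = length(prot_ids),
                           n_ligands = length(lig_ids),
                           n_positive = sum(idx$index == 1L),
                           n_negative = sum(idx$index == 0L)))
  class(ds) <- "InteractionDataset"
  ds
}

#' @export
print.InteractionDataset <- function(x, ...) {
  cat(sprintf(paste0("InteractionDataset: %d proteins x %d ligands (%s, ",
                     "cutoff %g umol)\n  %d indexed pairs: %d interacting, ",
                     "%d non-interacting\n"),
              length(x$proteins), length(x$ligands), x$parameter,
              x$cutoff_umol, nrow(x$indices),
              sum(x$indices$index == 1L), sum(x$indices$index == 0L)))
  invisible(x)
}

# index of ligand C on protein P: 1, 0, or NA when unmeasured
.pair_index <- function(dataset, protein_id, ligand_id) {
  hit <- dataset$indices$protein_id == protein_id &
    dataset$indices$ligand_id == ligand_id
  if (!any(hit)) NA_integer_ else dataset$indices$index[which(hit)[1L]]
}
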