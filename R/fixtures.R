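#' Specification of a synthetic proteochemometric benchmark
#'
#' The generator emulates the kind of input the curation pipeline consumes:
#' a sparse protein x ligand affinity table over sequences with planted
#' class motifs and ligands with planted class substructures.  Proteins and
#' ligands fall into \code{n_classes} specificity classes; a protein
#' interacts with exactly the ligands of its own class (the ground truth).
#' Matched pairs receive fixed affinity values well below the cutoffs,
#' mismatched measured pairs values well above; a controllable share of
#' pairs is converted to interval records bracketing the true value so the
#' integration rules have nontrivial work, and a noise share of pairs gets
#' its value regime flipped.
#'
#' @param n_classes number of specificity classes (default 5).
#' @param n_proteins,n_ligands library sizes (default 40 and 120; both must
#'   allow at least 3 members per class).
#' @param seq_len sequence length in residues (default 300).
#' @param motif_len length of the class sequence motif (default 20).
#' @param motif_rate fraction of a class's proteins carrying the motif.
#' @param mutation_rate per-residue background substitution rate applied to
#'   each protein's copy of its class template (default 0.05).
#' @param neg_density probability that a mismatched (truly non-interacting)
#'   pair is measured at all (default 0.5); matched pairs are always
#'   measured so the eligibility thresholds hold by construction.
#' @param interval_fraction share of measured pairs whose fixed records are
#'   replaced by label-preserving interval records (default 0.15).
#' @param noise_rate share of measured pairs whose value regime is flipped
#'   relative to the truth (default 0).
#' @param parameter interaction parameter stamped on the records.
#' @param seed integer seed; the same spec is bit-reproducible.
#' @return a validated \code{"fixture_spec"} list.
#' @export
fixture_spec <- function(n_classes = 5, n_proteins = 40, n_ligands = 120,
                         seq_len = 300, motif_len = 20, motif_rate = 1.0,
                         mutation_rate = 0.05, neg_density = 0.5,
                         interval_fraction = 0.15, noise_rate = 0,
                         parameter = "Ki", seed = 1) {
  spec <- list(n_classes = as.integer(n_classes),
               n_proteins = as.integer(n_proteins),
               n_ligands = as.integer(n_ligands),
               seq_len = as.integer(seq_len),
               motif_len = as.integer(motif_len),
               motif_rate = motif_rate, mutation_rate = mutation_rate,
               neg_density = neg_density,
               interval_fraction = interval_fraction,
               noise_rate = noise_rate, parameter = parameter,
               seed = as.integer(seed))
  rates <- c(spec$motif_rate, spec$mutation_rate, spec$neg_density,
             spec$interval_fraction, spec$noise_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (spec$n_classes < 1) stop("need at least one class")
  if (spec$n_proteins < 3 * spec$n_classes)
    stop("infeasible spec: fewer than 3 proteins per class")
  if (spec$n_ligands < 3 * spec$n_classes)
    stop("infeasible spec: fewer than 3 ligands per class")
  if (spec$motif_len > spec$seq_len) stop("motif longer than the sequence")
  if (!spec$parameter %in% c("IC50", "Ki", "Kd"))
    stop("parameter must be IC50, Ki or Kd")
  class(spec) <- "fixture_spec"
  spec
}

# neutral, concatenation-safe building blocks for ligand SMILES: the class
# group is always terminal, decorations are chainable linear fragments
.CLASS_GROUPS <- c("C(F)(F)F", "N(C)C", "C(=O)OC", "S(=O)(=O)C", "C#N",
                   "C(Cl)(Cl)Cl", "OCC(O)CO", "C(=O)NC")
.DECORATIONS <- c("C", "CC", "CO", "C(C)C", "COC", "CCN")

#' Generate a synthetic benchmark with known ground truth
#'
#' @param spec a [fixture_spec()].
#' @return a \code{"pcm_fixture"}: list with \code{affinities} (record
#'   table), \code{sequences} (named character), \code{smiles} (data.frame
#'   \code{ligand_id}, \code{smiles}), \code{truth} (protein and ligand
#'   class assignments plus the measured-pair truth indices) and
#'   \code{spec}.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) stop("`spec` must be a fixture_spec")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  # --- proteins: mutated copies of class templates with a planted motif
  pclass <- rep_len(seq_len(spec$n_classes), spec$n_proteins)
  templates <- replicate(spec$n_classes,
                         paste(sample(.AA20, spec$seq_len, TRUE), collapse = ""))
  motifs <- replicate(spec$n_classes,
                      paste(sample(.AA20, spec$motif_len, TRUE), collapse = ""))
  motif_pos <- sample.int(spec$seq_len - spec$motif_len + 1L, spec$n_classes,
                          replace = TRUE)
  prot_ids <- sprintf("P%03d", seq_len(spec$n_proteins))
  sequences <- vapply(seq_len(spec$n_proteins), function(i) {
    cl <- pclass[i]
    s <- strsplit(templates[cl], "")[[1]]
    if (stats::runif(1) <= spec$motif_rate)
      s[motif_pos[cl]:(motif_pos[cl] + spec$motif_len - 1L)] <-
        strsplit(motifs[cl], "")[[1]]
    mut <- stats::runif(spec$seq_len) < spec$mutation_rate
    s[mut] <- sample(.AA20, sum(mut), TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(sequences) <- prot_ids

  # --- ligands: decorated alkyl scaffolds with a terminal class group
  lclass <- rep_len(seq_len(spec$n_classes), spec$n_ligands)
  groups <- rep_len(.CLASS_GROUPS, spec$n_classes)
  lig_ids <- sprintf("L%03d", seq_len(spec$n_ligands))
  within <- stats::ave(seq_len(spec$n_ligands), lclass, FUN = seq_along)
  smiles <- vapply(seq_len(spec$n_ligands), function(i) {
    dec <- paste(sample(.DECORATIONS, sample(2:4, 1), TRUE), collapse = "")
    paste0("CC", strrep("C", within[i] - 1L), dec, groups[lclass[i]])
  }, character(1))
  smiles <- .ensure_unique_compounds(smiles, lig_ids)

  # --- affinity records
  cls_match <- outer(pclass, lclass, "==")
  measured <- cls_match |
    matrix(stats::runif(spec$n_proteins * spec$n_ligands) < spec$neg_density,
           spec$n_proteins)
  pairs <- which(measured, arr.ind = TRUE)
  truth_idx <- as.integer(cls_match[pairs])
  flip <- stats::runif(nrow(pairs)) < spec$noise_rate
  obs_idx <- ifelse(flip, 1L - truth_idx, truth_idx)
  as_interval <- stats::runif(nrow(pairs)) < spec$interval_fraction

  recs <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    # interactors: 10-500 nM, well under the 1 umol cutoff;
    # non-interactors: 30-500 uM, well over the 10 umol cutoff
    v <- if (obs_idx[r] == 1L) 10^stats::runif(1, 1, 2.7)
         else 10^stats::runif(1, 4.5, 5.7)
    n_rec <- sample(1:2, 1)
    vals <- v * 10^stats::runif(n_rec, -0.1, 0.1)
    if (as_interval[r]) {
      # label-preserving brackets: "<v, <2v" keeps index 1 (min below cutoff),
      # ">v/2, >v" keeps index 0 (max above cutoff)
      if (obs_idx[r] == 1L) { rel <- "LT"; vals <- c(v, 2 * v) }
      else { rel <- "GT"; vals <- c(v / 2, v) }
    } else rel <- rep("EQ", n_rec)
    recs[[r]] <- data.frame(protein_id = prot_ids[pairs[r, 1L]],
                            ligand_id = lig_ids[pairs[r, 2L]],
                            parameter = spec$parameter,
                            relation = rel, value_nM = vals,
                            stringsAsFactors = FALSE)
  }
  affinities <- do.call(rbind, recs)
  rownames(affinities) <- NULL

  fx <- list(affinities = affinities,
             sequences = sequences,
             smiles = data.frame(ligand_id = lig_ids, smiles = smiles,
                                 stringsAsFactors = FALSE),
             truth = list(protein_classes = stats::setNames(pclass, prot_ids),
                          ligand_classes = stats::setNames(lclass, lig_ids),
                          indices = data.frame(
                            protein_id = prot_ids[pairs[, 1L]],
                            ligand_id = lig_ids[pairs[, 2L]],
                            index = truth_idx, stringsAsFactors = FALSE)),
             spec = spec)
  class(fx) <- "pcm_fixture"
  fx
}

# distinct SMILES strings can still encode the same compound (the duplicate
# key is descriptor-set + weight); extend offenders until the library is
# collision-free so a noise-free fixture survives curation losslessly
.ensure_unique_compounds <- function(smiles, ids) {
  for (it in 1:25) {
    structs <- parse_smiles(smiles, ids)
    if (length(structs) != length(ids))
      stop("internal: generated SMILES failed to parse")
    keys <- vapply(structs, function(s) {
      d <- compute_mna_descriptors(s, 2)$descriptors
      paste(paste(d, collapse = "|"), round(s$mass, 4), sep = "@")
    }, character(1))
    dup <- duplicated(keys)
    if (!any(dup)) return(smiles)
    smiles[dup] <- paste0("C", smiles[dup])
  }
  stop("internal: could not make the compound library collision-free")
}

#' @export
print.pcm_fixture <- function(x, ...) {
  cat(sprintf(paste0("pcm_fixture: %d proteins, %d ligands, %d classes, ",
                     "%d affinity records (seed %d)\n"),
              x$spec$n_proteins, x$spec$n_ligands, x$spec$n_classes,
              nrow(x$affinities), x$spec$seed))
  invisible(x)
}

#' Write a fixture to disk in the standard input formats
#'
#' Produces \code{affinities.csv}, \code{proteins.fasta}, \code{ligands.smi}
#' and \code{truth.tsv} under \code{dir}.
#'
#' @param fixture a [generate_fixture()] result.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!inherits(fixture, "pcm_fixture")) stop("`fixture` must be a pcm_fixture")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- fixture$affinities
  aff$relation <- c(EQ = "=", LT = "<", GT = ">")[aff$relation]
  utils::write.csv(aff, file.path(dir, "affinities.csv"), row.names = FALSE,
                   quote = FALSE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(fixture$sequences),
                              file.path(dir, "proteins.fasta"))
  writeLines(paste(fixture$smiles$smiles, fixture$smiles$ligand_id),
             file.path(dir, "ligands.smi"))
  utils::write.table(fixture$truth$indices, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Curate a fixture into an InteractionDataset
#'
#' Convenience wrapper running [build_dataset()] on a generated fixture.
#'
#' @param fixture a [generate_fixture()] result.
#' @param cutoff_umol cutoff in umol/L (default 1).
#' @param ... passed to [build_dataset()].
#' @export
curate_fixture <- function(fixture, cutoff_umol = 1.0, ...) {
  build_dataset(fixture$affinities, fixture$sequences, fixture$smiles,
                parameter = fixture$spec$parameter,
                cutoff_umol = cutoff_umol, ...)
}
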