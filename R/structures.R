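#' Parse SMILES strings into ligand structures
#'
#' Wraps the OpenBabel-backed SMILES reader from \pkg{ChemmineR} /
#' \pkg{ChemmineOB} and extracts the pieces the curation and descriptor
#' layers need: the heavy-atom graph (elements, bonds with orders),
#' per-atom hydrogen counts (obtained by letting OpenBabel add explicit
#' hydrogens, then collapsing them onto their heavy atom), formal charges
#' and the molecular weight.  Unparseable entries are skipped with a
#' warning, mirroring how curation pipelines treat malformed registry
#' entries.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids ligand identifiers (defaults to names of \code{smiles}).
#' @return a named list of \code{"ligand_structure"} objects, each a list
#'   with \code{ligand_id}, \code{atoms} (data.frame \code{element},
#'   \code{hcount}, \code{charge}), \code{bonds} (data.frame \code{from},
#'   \code{to}, \code{order}, heavy atoms only), \code{mass} (Da),
#'   \code{charged} (logical), \code{smiles} and \code{source_ids}.
#' @export
parse_smiles <- function(smiles, ids = names(smiles)) {
  if (is.null(ids)) stop("ligand ids are required (names of `smiles` or `ids`)")
  if (length(ids) != length(smiles)) stop("ids and smiles differ in length")
  if (anyDuplicated(ids)) stop("duplicate ligand ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  smiles <- stats::setNames(as.character(smiles), ids)

  parsed <- .convert_smiles(smiles)
  # one bad entry truncates a batch conversion: retry the strays one by one
  stray <- setdiff(ids, names(parsed))
  for (id in stray) {
    one <- .convert_smiles(smiles[id])
    if (length(one)) parsed[[id]] <- one[[1]]
    else warning("skipping unparseable SMILES for ligand '", id, "'",
                 call. = FALSE)
  }
  out <- list()
  for (id in ids) if (!is.null(parsed[[id]]))
    out[[id]] <- .structure_from_sdf(parsed[[id]]$comp, id, smiles[[id]],
                                     parsed[[id]]$mass)
  out
}

# SMILES -> SDF components with explicit hydrogens; returns per-id list of
# list(comp, mass); silently drops entries OpenBabel cannot read
.convert_smiles <- function(smiles) {
  src <- paste(paste(smiles, names(smiles)), collapse = "\n")
  txt <- tryCatch(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", source = src,
                              options = data.frame(names = "h", args = ""))),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(list())
  sdf <- tryCatch(suppressWarnings(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines))),
    error = function(e) NULL)
  if (is.null(sdf) || !length(sdf)) return(list())
  ok <- suppressWarnings(ChemmineR::validSDF(sdf))
  sdf <- sdf[ok]
  if (!length(sdf)) return(list())
  got <- ChemmineR::sdfid(sdf)
  mass <- suppressWarnings(ChemmineR::MW(sdf))
  res <- list()
  for (i in seq_along(sdf)) {
    if (!(got[i] %in% names(smiles)) || got[i] %in% names(res)) next
    res[[got[i]]] <- list(comp = sdf[[i]], mass = as.numeric(mass[[i]]))
  }
  res
}

.sdf_charge_codes <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                       `5` = -1L, `6` = -2L, `7` = -3L)

.structure_from_sdf <- function(comp, id, smi, mass) {
  ab <- ChemmineR::atomblock(comp)
  bb <- ChemmineR::bondblock(comp)
  element <- sub("_.*$", "", rownames(ab))
  n <- length(element)
  charge <- integer(n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    known <- code %in% names(.sdf_charge_codes)
    charge[known] <- .sdf_charge_codes[code[known]]
  }
  chg_prop <- tryCatch(ChemmineR::bonds(comp, type = "charge"),
                       error = function(e) NULL)
  charged <- any(charge != 0) || length(chg_prop) > 0

  if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    from <- integer(); to <- integer(); order <- numeric()
  } else {
    from <- as.integer(bb[, 1L]); to <- as.integer(bb[, 2L])
    order <- as.numeric(bb[, 3L])
    order[order == 4] <- 1.5   # aromatic flag in un-kekulized input
  }

  # collapse explicit hydrogens onto their heavy atoms
  is_h <- element == "H"
  hcount <- integer(n)
  h_end <- is_h[from] | is_h[to]
  for (r in which(h_end)) {
    heavy <- if (is_h[from[r]]) to[r] else from[r]
    if (!is_h[heavy]) hcount[heavy] <- hcount[heavy] + 1L
  }
  heavy_idx <- which(!is_h)
  if (!length(heavy_idx)) heavy_idx <- seq_len(n)   # e.g. molecular hydrogen
  remap <- match(seq_len(n), heavy_idx)
  keep <- !h_end & from %in% heavy_idx & to %in% heavy_idx
  bonds <- data.frame(from = remap[from[keep]], to = remap[to[keep]],
                      order = order[keep])
  atoms <- data.frame(element = element[heavy_idx],
                      hcount = hcount[heavy_idx],
                      charge = charge[heavy_idx], stringsAsFactors = FALSE)
  res <- list(ligand_id = id, atoms = atoms, bonds = bonds,
              mass = mass, charged = charged, smiles = unname(smi),
              source_ids = id)
  class(res) <- "ligand_structure"
  res
}

#' @export
print.ligand_structure <- function(x, ...) {
  cat(sprintf("ligand_structure '%s': %d heavy atoms, %d bonds, mass %.2f Da%s\n",
              x$ligand_id, nrow(x$atoms), nrow(x$bonds), x$mass,
              if (isTRUE(x$charged)) " [charged]" else ""))
  invisible(x)
}

#' Apply the compound structure filters
#'
#' Removes ligands that carry any non-zero formal charge, removes ligands
#' heavier than the mass cap (strictly greater than \code{max_mass}), and
#' merges ligands that share an identical MNA descriptor set and identical
#' molecular weight into one record (they describe the same compound; the
#' surviving record lists all merged ids in \code{source_ids}).
#'
#' @param structures list of \code{ligand_structure} objects
#'   (see [parse_smiles()]).
#' @param max_mass mass cap in Da (default 1250).
#' @param mna_level neighborhood level used for the duplicate check.
#' @return the filtered list, with a \code{"report"} attribute holding the
#'   counts removed per filter.
#' @export
filter_structures <- function(structures, max_mass = 1250, mna_level = 2) {
  if (!length(structures)) {
    out <- structures
    attr(out, "report") <- list(input = 0L, removed_charged = 0L,
                                removed_mass = 0L, merged = 0L, retained = 0L)
    return(out)
  }
  charged <- vapply(structures, function(s) isTRUE(s$charged), logical(1))
  heavy   <- vapply(structures, function(s) isTRUE(s$mass > max_mass), logical(1))
  kept <- structures[!charged & !heavy]

  # duplicate key: full descriptor set + molecular weight
  keys <- vapply(kept, function(s) {
    d <- compute_mna_descriptors(s, level = mna_level)
    paste(paste(d$descriptors, collapse = "|"), round(s$mass, 4), sep = "@")
  }, character(1))
  merged <- 0L
  out <- list()
  for (i in seq_along(kept)) {
    k <- keys[[i]]
    hit <- match(k, names(out))
    if (is.na(hit)) {
      out[[k]] <- kept[[i]]
    } else {
      out[[hit]]$source_ids <- c(out[[hit]]$source_ids, kept[[i]]$ligand_id)
      merged <- merged + 1L
    }
  }
  names(out) <- vapply(out, function(s) s$ligand_id, character(1))
  attr(out, "report") <- list(input = length(structures),
                              removed_charged = sum(charged),
                              removed_mass = sum(heavy & !charged),
                              merged = merged,
                              retained = length(out))
  out
}
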