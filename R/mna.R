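#' Multilevel neighborhoods of atoms (MNA) descriptors
#'
#' MNA descriptors encode each atom together with its bonded neighborhood up
#' to a chosen recursion level and fingerprint a molecule as the set of these
#' strings over all atoms and all levels.  The level-0 descriptor of an atom
#' is its element symbol with the implicit hydrogen count (e.g. \code{CH3},
#' \code{OH}, \code{C}); the level-k descriptor appends, in parentheses, the
#' lexicographically sorted multiset of the neighbors' level-(k-1)
#' descriptors.  The encoding depends only on the molecular graph, so any
#' relabeling of atoms yields the identical set.
#'
#' @param structure a \code{ligand_structure} (see [parse_smiles()]).
#' @param level maximum neighborhood level (default 2).
#' @return object of class \code{"mna_descriptor_set"}: a list with
#'   \code{ligand_id}, \code{level} and \code{descriptors} (a sorted
#'   character vector).
#' @examples
#' \dontrun{
#' s <- parse_smiles(c(eth = "CCO"))
#' compute_mna_descriptors(s$eth, level = 1)$descriptors
#' }
#' @export
compute_mna_descriptors <- function(structure, level = 2) {
  if (!inherits(structure, "ligand_structure"))
    stop("`structure` must be a ligand_structure")
  if (!is.numeric(level) || length(level) != 1L || level < 0 ||
      level != floor(level))
    stop("`level` must be a nonnegative integer")
  atoms <- structure$atoms
  n <- nrow(atoms)
  if (n == 0L) stop("structure has no atoms")

  nbr <- vector("list", n)
  if (nrow(structure$bonds)) {
    for (r in seq_len(nrow(structure$bonds))) {
      a <- structure$bonds$from[r]; b <- structure$bonds$to[r]
      nbr[[a]] <- c(nbr[[a]], b)
      nbr[[b]] <- c(nbr[[b]], a)
    }
  }

  lab0 <- paste0(atoms$element,
                 ifelse(atoms$hcount > 0,
                        paste0("H", ifelse(atoms$hcount > 1, atoms$hcount, "")),
                        ""))
  levels <- list(lab0)
  if (level >= 1) {
    for (k in seq_len(level)) {
      prev <- levels[[k]]
      levels[[k + 1L]] <- vapply(seq_len(n), function(a) {
        ns <- nbr[[a]]
        if (!length(ns)) return(lab0[a])
        paste0(lab0[a], "(", paste(sort(prev[ns]), collapse = ","), ")")
      }, character(1))
    }
  }
  res <- list(ligand_id = structure$ligand_id,
              level = as.integer(level),
              descriptors = sort(unique(unlist(levels))))
  class(res) <- "mna_descriptor_set"
  res
}

#' @export
print.mna_descriptor_set <- function(x, ...) {
  cat(sprintf("MNA descriptors '%s' (level %d): %d unique\n",
              x$ligand_id, x$level, length(x$descriptors)))
  utils::head(x$descriptors, 10) |> paste(collapse = "  ") |> cat("\n")
  invisible(x)
}
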