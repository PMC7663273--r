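#' Build a table of affinity records
#'
#' Affinity records are the raw input to curation: one measurement per row,
#' identified by protein, ligand and interaction parameter, with a relation
#' describing whether the value is fixed (\code{"EQ"}) or an interval bound
#' (\code{"LT"} = upper bound "<value", \code{"GT"} = lower bound ">value").
#' All values are concentrations in nmol/L.
#'
#' @param protein_id,ligand_id character identifiers.
#' @param parameter one of \code{"IC50"}, \code{"Ki"}, \code{"Kd"} (recycled).
#' @param relation one of \code{"EQ"}, \code{"LT"}, \code{"GT"}; the symbols
#'   \code{"="}, \code{"<"}, \code{">"} are accepted and mapped.
#' @param value_nM strictly positive finite concentration in nmol/L.
#' @return a validated \code{data.frame} with the five columns above.
#' @export
affinity_records <- function(protein_id, ligand_id, parameter, relation, value_nM) {
  rel_map <- c("=" = "EQ", "<" = "LT", ">" = "GT",
               EQ = "EQ", LT = "LT", GT = "GT")
  relation <- unname(rel_map[as.character(relation)])
  df <- data.frame(protein_id = as.character(protein_id),
                   ligand_id  = as.character(ligand_id),
                   parameter  = as.character(parameter),
                   relation   = relation,
                   value_nM   = as.numeric(value_nM),
                   stringsAsFactors = FALSE)
  validate_affinity_records(df)
  df
}

validate_affinity_records <- function(df) {
  needed <- c("protein_id", "ligand_id", "parameter", "relation", "value_nM")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("affinity records lack column(s): ", paste(missing, collapse = ", "))
  if (any(is.na(df$relation)) || !all(df$relation %in% c("EQ", "LT", "GT")))
    stop("relation must be one of EQ/LT/GT (or =/</>)")
  if (!all(df$parameter %in% c("IC50", "Ki", "Kd")))
    stop("parameter must be one of IC50, Ki, Kd")
  if (any(!is.finite(df$value_nM)) || any(df$value_nM <= 0))
    stop("value_nM must be finite and strictly positive")
  invisible(df)
}

#' Integrate the affinity records of one protein-ligand pair into an
#' interaction index
#'
#' Applies the value-integration rules used to binarise heterogeneous
#' affinity data against a concentration cutoff:
#' \enumerate{
#'   \item If any fixed (\code{EQ}) values exist, interval bounds are ignored
#'     (they may contradict the fixed data); the index is 1 when the median
#'     of the fixed values does not exceed the cutoff, else 0.
#'   \item With interval bounds only, a pair combining upper and lower bounds
#'     is excluded: either the intervals do not intersect (e.g. <100 together
#'     with >5000) or they bracket a two-sided range (e.g. >100 with <5000).
#'   \item Lower bounds only (\code{GT}): index 0 when the maximal bound
#'     exceeds the cutoff, otherwise the pair is excluded.
#'   \item Upper bounds only (\code{LT}): index 1 when the minimal bound is
#'     below the cutoff, otherwise the pair is excluded.
#' }
#'
#' @param records data.frame of affinity records for a single
#'   (protein, ligand, parameter) combination; see [affinity_records()].
#' @param cutoff_umol interaction cutoff in micromol/L (1 umol = 1000 nmol);
#'   the curated datasets use 1.0 or 10.0.
#' @return an object of class \code{"interaction_index"}: a list with
#'   \code{protein_id}, \code{ligand_id}, \code{parameter},
#'   \code{cutoff_umol}, \code{index} (integer 1, 0 or \code{NA} for an
#'   excluded pair), \code{status} (\code{"interacts"},
#'   \code{"non_interacts"} or \code{"excluded"}) and \code{rule}
#'   (which rule fired).
#' @examples
#' r <- affinity_records("P1", "L1", "Ki", c("EQ", "EQ", "EQ"),
#'                       c(500, 800, 2000))
#' compute_interaction_index(r, cutoff_umol = 1.0)$index  # median 800 <= 1000
#' @export
compute_interaction_index <- function(records, cutoff_umol) {
  validate_affinity_records(records)
  if (nrow(records) == 0L) stop("no affinity records supplied")
  if (length(unique(records$parameter)) > 1L)
    stop("mixed parameter types within one pair: ",
         paste(unique(records$parameter), collapse = ", "))
  if (length(unique(records$protein_id)) > 1L ||
      length(unique(records$ligand_id)) > 1L)
    stop("records must all belong to one (protein, ligand) pair")
  if (!is.numeric(cutoff_umol) || length(cutoff_umol) != 1L || cutoff_umol <= 0)
    stop("cutoff_umol must be a single positive number")
  cutoff_nM <- cutoff_umol * 1000

  eq <- records$value_nM[records$relation == "EQ"]
  lt <- records$value_nM[records$relation == "LT"]
  gt <- records$value_nM[records$relation == "GT"]

  if (length(eq)) {
    # fixed values always win over interval bounds
    idx <- if (stats::median(eq) <= cutoff_nM) 1L else 0L
    rule <- "fixed_median"
  } else if (length(lt) && length(gt)) {
    idx <- NA_integer_
    rule <- if (min(lt) <= max(gt)) "nonintersecting_intervals" else "two_sided_interval"
  } else if (length(gt)) {
    if (max(gt) > cutoff_nM) {
      idx <- 0L; rule <- "lower_bounds"
    } else {
      idx <- NA_integer_; rule <- "lower_bounds_uninformative"
    }
  } else {
    if (min(lt) < cutoff_nM) {
      idx <- 1L; rule <- "upper_bounds"
    } else {
      idx <- NA_integer_; rule <- "upper_bounds_uninformative"
    }
  }

  structure(list(protein_id  = records$protein_id[1L],
                 ligand_id   = records$ligand_id[1L],
                 parameter   = records$parameter[1L],
                 cutoff_umol = cutoff_umol,
                 index       = idx,
                 status      = if (is.na(idx)) "excluded"
                               else if (idx == 1L) "interacts" else "non_interacts",
                 rule        = rule),
            class = "interaction_index")
}

#' @export
print.interaction_index <- function(x, ...) {
  cat(sprintf("interaction index (%s, %s) [%s, cutoff %g umol]: %s (%s)\n",
              x$protein_id, x$ligand_id, x$parameter, x$cutoff_umol,
              if (is.na(x$index)) "excluded" else x$index, x$rule))
  invisible(x)
}

#' Compute interaction indices for every pair in an affinity table
#'
#' Splits an affinity-record table by (protein, ligand) pair, restricted to a
#' single interaction parameter, and applies [compute_interaction_index()]
#' to each group.
#'
#' @inheritParams compute_interaction_index
#' @param records full affinity-record table.
#' @param parameter which parameter subset (\code{"IC50"}, \code{"Ki"},
#'   \code{"Kd"}) to curate; records of other parameters are ignored.
#' @param keep_excluded keep excluded pairs (index \code{NA}) in the output?
#' @return data.frame with columns \code{protein_id}, \code{ligand_id},
#'   \code{index}, \code{status}, \code{rule}.
#' @export
interaction_indices <- function(records, parameter, cutoff_umol,
                                keep_excluded = FALSE) {
  validate_affinity_records(records)
  records <- records[records$parameter == parameter, , drop = FALSE]
  if (nrow(records) == 0L)
    return(data.frame(protein_id = character(), ligand_id = character(),
                      index = integer(), status = character(),
                      rule = character(), stringsAsFactors = FALSE))
  key <- paste(records$protein_id, records$ligand_id, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(ii) {
    ix <- compute_interaction_index(records[ii, , drop = FALSE], cutoff_umol)
    data.frame(protein_id = ix$protein_id, ligand_id = ix$ligand_id,
               index = ix$index, status = ix$status, rule = ix$rule,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!keep_excluded) out <- out[!is.na(out$index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
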