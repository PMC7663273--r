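#' Read protein sequences from FASTA
#'
#' Sequences are uppercased; identifiers are the first whitespace-delimited
#' token of each header.  Non-standard residues (B, Z, X, ...) are retained
#' and simply never match under the identity metric.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Read a ligand table (SMILES)
#'
#' Accepts either a \code{.smi} file (one \code{SMILES id} pair per line,
#' whitespace-separated) or a CSV with a header containing
#' \code{ligand_id} and \code{smiles} columns.  Structures are parsed with
#' [parse_smiles()]; unparseable entries are skipped with a warning.
#'
#' @param path input file.
#' @return named list of \code{ligand_structure} objects.
#' @export
read_smiles_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("ligand_id", "smiles") %in% names(df)))
      stop("CSV must have columns ligand_id, smiles")
    smi <- stats::setNames(df$smiles, df$ligand_id)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- lengths(parts) < 2L
    if (any(bad)) {
      warning(sum(bad), " .smi line(s) without an id skipped", call. = FALSE)
      parts <- parts[!bad]
    }
    smi <- stats::setNames(vapply(parts, `[[`, character(1), 1L),
                           vapply(parts, `[[`, character(1), 2L))
  }
  out <- parse_smiles(smi)
  if (!length(out)) stop("no parseable ligand structures in ", path)
  out
}

#' Read an affinity-record table
#'
#' Delimited table (CSV, or TSV for \code{.tsv}/\code{.txt}) with header
#' \code{protein_id, ligand_id, parameter, relation, value_nM}; relations
#' may be written \code{=}/\code{<}/\code{>} or \code{EQ}/\code{LT}/
#' \code{GT}.
#'
#' @param path input file.
#' @return validated affinity-record data.frame.
#' @export
read_affinities <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  affinity_records(df$protein_id, df$ligand_id, df$parameter, df$relation,
                   df$value_nM)
}

#' Write a curated dataset to a directory
#'
#' Produces \code{proteins.fasta}, \code{ligands.smi},
#' \code{interactions.tsv} and a JSON \code{curation_report.json} holding
#' the per-filter removal counts.
#'
#' @param dataset an \code{InteractionDataset}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "InteractionDataset"))
    stop("`dataset` must be an InteractionDataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(dataset$proteins),
                              file.path(dir, "proteins.fasta"))
  writeLines(vapply(dataset$ligands, function(s)
    paste(s$smiles, s$ligand_id), character(1)),
    file.path(dir, "ligands.smi"))
  utils::write.table(dataset$indices, file.path(dir, "interactions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  report <- c(dataset$report,
              list(parameter = dataset$parameter,
                   cutoff_umol = dataset$cutoff_umol))
  jsonlite::write_json(report, file.path(dir, "curation_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a curated dataset directory back
#'
#' @param dir a directory written by [write_dataset()].
#' @return an \code{InteractionDataset}.
#' @export
read_dataset <- function(dir) {
  idx <- utils::read.table(file.path(dir, "interactions.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  idx$index <- as.integer(idx$index)
  report <- jsonlite::read_json(file.path(dir, "curation_report.json"))
  ds <- list(proteins = read_fasta(file.path(dir, "proteins.fasta")),
             ligands = read_smiles_table(file.path(dir, "ligands.smi")),
             indices = idx,
             parameter = as.character(report$parameter %||% NA),
             cutoff_umol = as.numeric(report$cutoff_umol %||% NA),
             mna_level = 2L,
             report = report)
  class(ds) <- "InteractionDataset"
  ds
}

#' Write a prediction table / an evaluation report
#'
#' Predictions go to a TSV with fixed column order and 5-decimal floats;
#' evaluation reports go to JSON with the AUC, class counts and a config
#' echo.
#'
#' @param results data.frame with at least \code{protein_id},
#'   \code{ligand_id}, \code{t}, \code{t0}, \code{B}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(results, path) {
  if (is.null(results) || !nrow(results)) stop("empty prediction results")
  cols <- c("protein_id", "ligand_id", "t", "t0", "B")
  missing <- setdiff(cols, names(results))
  if (length(missing))
    stop("results lack column(s): ", paste(missing, collapse = ", "))
  out <- results[cols]
  for (v in c("t", "t0", "B")) out[[v]] <- sprintf("%.5f", out[[v]])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @param roc a \code{"roc_result"}.
#' @param config optional list echoed into the report.
#' @export
write_report <- function(roc, path, config = list()) {
  if (!inherits(roc, "roc_result")) stop("`roc` must be a roc_result")
  report <- list(auc = roc$auc, n_pos = roc$n_pos, n_neg = roc$n_neg,
                 scenario = roc$scenario %||% NA,
                 frame = roc$frame %||% NA,
                 config = config,
                 tool = list(package = "fuzzyPCM",
                             version = as.character(
                               utils::packageVersion("fuzzyPCM"))))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
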