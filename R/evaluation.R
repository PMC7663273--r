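#' ROC area under the curve by the rank statistic
#'
#' AUC equals the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted one half — the normalized
#' Mann-Whitney statistic computed from midranks.  It coincides with the
#' trapezoidal area under the TPR/FPR curve swept over all score cutoffs.
#'
#' @param scores numeric prediction scores (higher = more likely positive).
#' @param labels 0/1 vector of the same length.
#' @return a \code{"roc_result"}: list with \code{auc}, \code{n_pos},
#'   \code{n_neg} and the score-label \code{pairs} table.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (any(is.na(scores)) || any(is.na(labels))) stop("NA in scores or labels")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L) stop("no positive pairs: ROC analysis needs both classes")
  if (n0 == 0L) stop("no negative pairs: ROC analysis needs both classes")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  res <- list(auc = auc, n_pos = n1, n_neg = n0,
              pairs = data.frame(score = scores, label = labels))
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f  (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Scenario 1 — new ligand for known targets
#'
#' Each ligand is alternately removed from the training set and treated as a
#' test compound: its Pa/Pi against every target carrying an index for it
#' are predicted from naive-Bayes statistics refitted without it, and all
#' scored pairs are pooled into one ROC against the curated indices.
#'
#' @param dataset an \code{InteractionDataset}.
#' @param level,alpha passed to [fit_bayes_models()].
#' @param score ranking score: \code{"pa_minus_pi"} (default) or
#'   \code{"pa"}.
#' @param per_ligand also report a macro-average of per-ligand AUCs (pairs
#'   pooled per dataset remains the headline number).
#' @return a \code{"roc_result"} with the score table in \code{pairs}.
#' @export
scenario1_new_ligand <- function(dataset, level = NULL, alpha = 1,
                                 score = c("pa_minus_pi", "pa"),
                                 per_ligand = FALSE) {
  score <- match.arg(score)
  if (length(dataset$ligands) < 2L)
    stop("leave-one-out over ligands needs at least two ligands")
  tab <- loo_pa_pi(dataset, level = level, alpha = alpha)
  s <- if (score == "pa") tab$pa else tab$pa - tab$pi
  res <- roc_auc(s, tab$label)
  res$pairs <- cbind(tab[c("protein_id", "ligand_id")], res$pairs)
  res$scenario <- 1L
  if (per_ligand) res$macro_auc <- .macro_auc(s, tab$label, tab$ligand_id)
  res
}

.macro_auc <- function(scores, labels, group) {
  per <- vapply(split(seq_along(scores), group), function(ii) {
    if (length(unique(labels[ii])) < 2L) return(NA_real_)
    roc_auc(scores[ii], labels[ii])$auc
  }, numeric(1))
  mean(per, na.rm = TRUE)
}

#' Scenario 2 — new target for known ligands
#'
#' Each protein is alternately held out as an unknown target; the remaining
#' proteins, partitioned by the binary interaction coefficients for each
#' ligand, serve as the training set.  B is computed for every ligand with a
#' curated index on the held-out protein, and all scored pairs are pooled
#' into one ROC.  A ligand whose established interactor set becomes empty
#' when the protein is removed cannot be scored and is skipped with a
#' warning.
#'
#' @inheritParams scenario1_new_ligand
#' @param frame segment length F (7 or 30 in the reference evaluations).
#' @return a \code{"roc_result"}.
#' @export
scenario2_new_target <- function(dataset, frame = 7, per_ligand = FALSE) {
  .scenario_heldout_protein(dataset, frame, mode = "binary",
                            per_ligand = per_ligand)
}

#' Scenario 3 — new protein and new ligand simultaneously
#'
#' The strictest leave-one-out: for each indexed (protein P, ligand C) pair,
#' P is removed from the training sequences and C from the naive-Bayes
#' statistics; C's fuzzy coefficients (Pa, Pi) against every remaining
#' training protein replace the binary ones in the B computation.  The ROC
#' is still evaluated against the curated binary indices.
#'
#' @inheritParams scenario2_new_target
#' @param level,alpha passed to [fit_bayes_models()].
#' @return a \code{"roc_result"}.
#' @export
scenario3_both_new <- function(dataset, frame = 7, level = NULL, alpha = 1,
                               per_ligand = FALSE) {
  .scenario_heldout_protein(dataset, frame, mode = "fuzzy", level = level,
                            alpha = alpha, per_ligand = per_ligand)
}

.scenario_heldout_protein <- function(dataset, frame, mode, level = NULL,
                                      alpha = 1, per_ligand = FALSE) {
  prot_ids <- names(dataset$proteins)
  if (length(prot_ids) < 2L) stop("need at least two proteins to hold one out")
  if (mode == "fuzzy") {
    model <- fit_bayes_models(dataset, level, alpha)
    loo <- loo_pa_pi(dataset, model = model)
    loo_key <- paste(loo$protein_id, loo$ligand_id, sep = "\r")
  }
  out <- list(); skipped <- 0L
  for (p in prot_ids) {
    train_ids <- setdiff(prot_ids, p)
    rows <- dataset$indices[dataset$indices$protein_id == p, , drop = FALSE]
    if (!nrow(rows)) next
    S <- tryCatch(
      positional_score_matrix(dataset$proteins[[p]],
                              dataset$proteins[train_ids], frame),
      error = function(e) stop("scoring held-out protein '", p, "': ",
                               conditionMessage(e), call. = FALSE))
    lig <- rows$ligand_id
    if (mode == "binary") {
      sub <- dataset$indices[dataset$indices$protein_id != p &
                               dataset$indices$ligand_id %in% lig, ,
                             drop = FALSE]
      A <- matrix(0, length(train_ids), length(lig),
                  dimnames = list(train_ids, lig))
      Bm <- A
      if (nrow(sub)) {
        ij <- cbind(match(sub$protein_id, train_ids), match(sub$ligand_id, lig))
        A[ij] <- as.numeric(sub$index == 1L)
        Bm[ij] <- as.numeric(sub$index == 0L)
      }
      scorable <- colSums(A) > 0          # ligand still has interactors
      skipped <- skipped + sum(!scorable)
      if (!any(scorable)) next
      lig <- lig[scorable]; rows <- rows[scorable, , drop = FALSE]
      A <- A[, scorable, drop = FALSE]; Bm <- Bm[, scorable, drop = FALSE]
    } else {
      # fuzzy coefficients: LOO Pa/Pi of each ligand vs the remaining targets
      A <- matrix(0, length(train_ids), length(lig),
                  dimnames = list(train_ids, lig))
      Bm <- A
      for (ci in seq_along(lig)) {
        hit <- match(paste(train_ids, lig[ci], sep = "\r"), loo_key)
        known <- !is.na(hit)
        pp <- vapply(which(!known), function(ki) {
          st <- .target_stats(model, train_ids[ki], lig[ci])
          est <- .pa_pi_from_stats(st, model$descriptors[[lig[ci]]], model)
          c(est$pa, est$pi)
        }, numeric(2))
        A[known, ci] <- loo$pa[hit[known]]
        Bm[known, ci] <- loo$pi[hit[known]]
        if (any(!known)) { A[!known, ci] <- pp[1L, ]; Bm[!known, ci] <- pp[2L, ] }
      }
    }
    res <- .predict_block(S, A, Bm)
    out[[p]] <- data.frame(protein_id = p, ligand_id = lig,
                           t = res$t, t0 = res$t0, B = res$B,
                           label = rows$index, stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(skipped, " pair(s) skipped: held-out protein removal left the ",
            "ligand without established interactors", call. = FALSE)
  tab <- do.call(rbind, out)
  if (is.null(tab) || !nrow(tab)) stop("no scorable pairs remain")
  res <- roc_auc(tab$B, tab$label)
  res$pairs <- tab
  res$scenario <- if (mode == "binary") 2L else 3L
  res$frame <- frame
  res$skipped <- skipped
  if (per_ligand) res$macro_auc <- .macro_auc(tab$B, tab$label, tab$ligand_id)
  res
}
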