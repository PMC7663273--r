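#' Fit per-target naive-Bayes descriptor statistics
#'
#' For every target protein the model counts, over the target's established
#' ligands, how often each MNA descriptor occurs among interacting
#' (index 1) and non-interacting (index 0) compounds.  Prediction turns
#' these counts into two independent probabilities for a query compound:
#' Pa, that it belongs to the target's interacting class, and Pi, that it
#' belongs to the non-interacting class.  Each is a Laplace-smoothed
#' naive-Bayes log-odds of the class against the target's whole ligand pool
#' (the background), squashed through the logistic function — so Pa and Pi
#' are separate estimates and need not sum to one.
#'
#' @param dataset an \code{InteractionDataset}.
#' @param level MNA neighborhood level (defaults to the dataset's).
#' @param alpha Laplace smoothing constant (default 1).
#' @return a \code{"ligand_bayes_model"}: per-target count tables, the
#'   descriptor cache, and the global class priors used for degenerate
#'   targets.
#' @export
fit_bayes_models <- function(dataset, level = NULL, alpha = 1) {
  if (!inherits(dataset, "InteractionDataset"))
    stop("`dataset` must be an InteractionDataset")
  if (is.null(level)) level <- dataset$mna_level %||% 2
  descr <- lapply(dataset$ligands, function(s)
    compute_mna_descriptors(s, level)$descriptors)

  targets <- list()
  for (tid in names(dataset$proteins)) {
    rows <- dataset$indices[dataset$indices$protein_id == tid, , drop = FALSE]
    members <- stats::setNames(as.integer(rows$index), rows$ligand_id)
    act <- .count_descriptors(descr[names(members)[members == 1L]])
    ina <- .count_descriptors(descr[names(members)[members == 0L]])
    targets[[tid]] <- list(target_id = tid, active = act, inactive = ina,
                           n_active = sum(members == 1L),
                           n_inactive = sum(members == 0L),
                           members = members)
  }
  n1 <- sum(dataset$indices$index == 1L)
  n0 <- sum(dataset$indices$index == 0L)
  model <- list(targets = targets, descriptors = descr,
                alpha = alpha, level = as.integer(level),
                prior_active_global = (n1 + 1) / (n1 + n0 + 2),
                prior_inactive_global = (n0 + 1) / (n1 + n0 + 2))
  class(model) <- "ligand_bayes_model"
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.count_descriptors <- function(descr_list) {
  if (!length(descr_list)) return(integer(0))
  tab <- table(unlist(descr_list, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' Fit the descriptor statistics of a single target
#'
#' Standalone (re)fit of one target's count tables, optionally leaving one
#' ligand out entirely — the unit of work of the leave-one-out scenarios.
#' A target left with no interacting or no non-interacting ligand after the
#' exclusion is flagged degenerate; prediction then falls back to the global
#' class prior for the empty class.
#'
#' @inheritParams fit_bayes_models
#' @param target_id protein identifier present in the dataset.
#' @param exclude_ligand optional ligand id to omit from the counts.
#' @return a \code{"target_bayes_stats"} list with \code{active} /
#'   \code{inactive} descriptor counts, \code{n_active}, \code{n_inactive}
#'   and a \code{degenerate} flag.
#' @export
fit_target_model <- function(dataset, target_id, exclude_ligand = NULL,
                             level = NULL, alpha = 1) {
  if (!inherits(dataset, "InteractionDataset"))
    stop("`dataset` must be an InteractionDataset")
  if (!(target_id %in% names(dataset$proteins)))
    stop("unknown target '", target_id, "'")
  if (is.null(level)) level <- dataset$mna_level %||% 2
  rows <- dataset$indices[dataset$indices$protein_id == target_id, ,
                          drop = FALSE]
  if (!is.null(exclude_ligand))
    rows <- rows[rows$ligand_id != exclude_ligand, , drop = FALSE]
  descr <- lapply(dataset$ligands[rows$ligand_id], function(s)
    compute_mna_descriptors(s, level)$descriptors)
  act <- .count_descriptors(descr[rows$index == 1L])
  ina <- .count_descriptors(descr[rows$index == 0L])
  st <- list(target_id = target_id, active = act, inactive = ina,
             n_active = sum(rows$index == 1L),
             n_inactive = sum(rows$index == 0L))
  st$degenerate <- st$n_active == 0L || st$n_inactive == 0L
  class(st) <- "target_bayes_stats"
  st
}

# incremental leave-one-out: subtract the excluded ligand's descriptor
# counts from its class instead of recounting the whole target
.target_stats <- function(model, target_id, exclude_ligand = NULL) {
  st <- model$targets[[target_id]]
  if (is.null(st)) stop("unknown target '", target_id, "'")
  if (!is.null(exclude_ligand) && exclude_ligand %in% names(st$members)) {
    cls <- st$members[[exclude_ligand]]
    d <- model$descriptors[[exclude_ligand]]
    if (cls == 1L) {
      st$active[d] <- st$active[d] - 1L
      st$active <- st$active[st$active > 0L]
      st$n_active <- st$n_active - 1L
    } else {
      st$inactive[d] <- st$inactive[d] - 1L
      st$inactive <- st$inactive[st$inactive > 0L]
      st$n_inactive <- st$n_inactive - 1L
    }
    if (!length(st$active)) st$active <- integer(0)
    if (!length(st$inactive)) st$inactive <- integer(0)
  }
  st$degenerate <- st$n_active == 0L || st$n_inactive == 0L
  class(st) <- "target_bayes_stats"
  st
}

.class_probability <- function(n_cls, n_all, cnt_cls, cnt_all, descr, alpha,
                               fallback_prior) {
  if (n_cls == 0L) return(fallback_prior)
  prior <- (n_cls + 1) / (n_all + 2)
  lo <- stats::qlogis(prior)
  # only descriptors seen in this target's training pool carry evidence
  d <- descr[descr %in% names(cnt_all)]
  if (length(d)) {
    ca <- cnt_all[d]
    cc <- cnt_cls[d]; cc[is.na(cc)] <- 0L
    lo <- lo + sum(log((cc + alpha) / (n_cls + 2 * alpha)) -
                     log((ca + alpha) / (n_all + 2 * alpha)))
  }
  stats::plogis(lo)
}

.pa_pi_from_stats <- function(st, descr, model) {
  n_all <- st$n_active + st$n_inactive
  cnt_all <- .merge_counts(st$active, st$inactive)
  pa <- .class_probability(st$n_active, n_all, st$active, cnt_all, descr,
                           model$alpha, model$prior_active_global)
  pi <- .class_probability(st$n_inactive, n_all, st$inactive, cnt_all, descr,
                           model$alpha, model$prior_inactive_global)
  list(pa = unname(pa), pi = unname(pi),
       degenerate = isTRUE(st$degenerate))
}

.merge_counts <- function(a, b) {
  if (!length(a)) return(b)
  if (!length(b)) return(a)
  keys <- union(names(a), names(b))
  av <- a[keys]; av[is.na(av)] <- 0L
  bv <- b[keys]; bv[is.na(bv)] <- 0L
  stats::setNames(as.integer(av + bv), keys)
}

#' Predict Pa/Pi of a compound against one target
#'
#' @param model a [fit_bayes_models()] result.
#' @param target_id protein identifier.
#' @param descriptors an \code{mna_descriptor_set} or character vector of
#'   descriptor strings; an empty set yields the prior-only estimate.
#' @param exclude_ligand optional ligand id removed from the target's
#'   statistics before predicting (leave-one-out).
#' @return list with \code{pa}, \code{pi} (both in [0,1]) and
#'   \code{degenerate}.
#' @export
predict_pa_pi <- function(model, target_id, descriptors,
                          exclude_ligand = NULL) {
  if (!inherits(model, "ligand_bayes_model"))
    stop("`model` must come from fit_bayes_models()")
  if (inherits(descriptors, "mna_descriptor_set"))
    descriptors <- descriptors$descriptors
  st <- .target_stats(model, target_id, exclude_ligand)
  .pa_pi_from_stats(st, descriptors, model)
}

#' Leave-one-out Pa/Pi table over all indexed pairs
#'
#' For every (target, ligand) pair carrying a curated index, predicts the
#' ligand's Pa/Pi against the target with the ligand excluded from that
#' target's training statistics.  This is the first evaluation scenario's
#' score table and supplies the fuzzy coefficients of the third.
#'
#' @inheritParams fit_bayes_models
#' @param model optional pre-fitted model.
#' @return data.frame with \code{protein_id}, \code{ligand_id}, \code{pa},
#'   \code{pi}, \code{label}.
#' @export
loo_pa_pi <- function(dataset, model = NULL, level = NULL, alpha = 1) {
  if (is.null(model)) model <- fit_bayes_models(dataset, level, alpha)
  idx <- dataset$indices
  pa <- numeric(nrow(idx)); pi <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    st <- .target_stats(model, idx$protein_id[r], idx$ligand_id[r])
    est <- .pa_pi_from_stats(st, model$descriptors[[idx$ligand_id[r]]], model)
    pa[r] <- est$pa; pi[r] <- est$pi
  }
  data.frame(protein_id = idx$protein_id, ligand_id = idx$ligand_id,
             pa = pa, pi = pi, label = idx$index,
             stringsAsFactors = FALSE)
}
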