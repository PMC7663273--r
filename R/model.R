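#' Belonging coefficient vectors
#'
#' Each training protein k carries two coefficients for a given compound C:
#' a_k weights its ability and b_k its inability to interact with C.  In
#' binary mode the coefficients come from curated interaction indices
#' ((1,0) for an established interactor, (0,1) for an established
#' non-interactor, (0,0) for an unmeasured pair, which then drops out of all
#' sums).  In fuzzy mode a_k = Pa and b_k = Pi from the ligand-structure
#' naive-Bayes classifier, so every training protein contributes with a
#' graded weight.
#'
#' @param a,b numeric vectors in [0,1], one entry per training protein.
#' @param mode \code{"binary"} or \code{"fuzzy"}.
#' @return a \code{"coefficient_vector"} list with elements \code{a},
#'   \code{b}, \code{mode}.
#' @export
coefficient_vector <- function(a, b, mode = c("binary", "fuzzy")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("a and b differ in length")
  if (any(!is.finite(a)) || any(!is.finite(b)) ||
      any(a < 0 | a > 1) || any(b < 0 | b > 1))
    stop("coefficients must be finite and within [0, 1]")
  if (mode == "binary" && !all((a == 0 | a == 1) & (b == 0 | b == 1) & a * b == 0))
    stop("binary coefficients must be one of (1,0), (0,1), (0,0)")
  structure(list(a = as.numeric(a), b = as.numeric(b), mode = mode),
            class = "coefficient_vector")
}

#' Integrated per-position score t_p
#'
#' Weights the positional similarity scores of one query position against
#' all N training sequences by the belonging coefficients:
#' \deqn{t_p = \frac{\sum_k S_{pk} (a_k - b_k)}{\sum_k S_{pk} (a_k + b_k)}.}
#' When the denominator is zero there is no information at this position and
#' the neutral value 0 is returned.
#'
#' @param s nonnegative numeric vector of positional scores S_pk, k = 1..N.
#' @param coeffs a [coefficient_vector()].
#' @return t_p in [-1, 1].
#' @export
position_score_tp <- function(s, coeffs) {
  if (length(s) != length(coeffs$a))
    stop("scores and coefficients differ in length")
  if (any(s < 0)) stop("positional scores must be nonnegative")
  den <- sum(s * (coeffs$a + coeffs$b))
  if (den == 0) return(0)
  sum(s * (coeffs$a - coeffs$b)) / den
}

#' Aggregate per-position scores into t
#'
#' The t_p values are averaged on the arcsine scale:
#' \deqn{t = \sin\left[\frac{1}{m}\sum_{p=1}^m \arcsin(t_p)\right].}
#'
#' @param tp numeric vector of per-position scores in [-1, 1] (values beyond
#'   by more than 1e-9 are an error; smaller float excursions are clipped).
#' @return t in [-1, 1].
#' @export
aggregate_t <- function(tp) {
  if (!length(tp)) stop("empty t_p vector")
  if (any(abs(tp) > 1 + 1e-9)) stop("t_p outside [-1, 1]")
  sin(mean(asin(pmin(1, pmax(-1, tp)))))
}

#' A-priori score t0
#'
#' The coefficient-only analogue of t, independent of sequence similarity:
#' \deqn{t_0 = \frac{\sum_k (a_k - b_k)}{\sum_k (a_k + b_k)},}
#' with the neutral value 0 when the denominator vanishes.
#'
#' @inheritParams position_score_tp
#' @return t0 in [-1, 1].
#' @export
prior_t0 <- function(coeffs) {
  den <- sum(coeffs$a + coeffs$b)
  if (den == 0) return(0)
  sum(coeffs$a - coeffs$b) / den
}

#' Final interaction estimate B(C)
#'
#' Contrasts the similarity-weighted score with the a-priori score:
#' \deqn{B(C) = \frac{t - t_0}{1 - t\,t_0}.}
#' B ranges from -1 (no interaction) to +1 (interaction); 0 is the
#' undetermined result, returned whenever t = t0 (including t = t0 = +-1).
#' At the removable singularity |1 - t t0| < 1e-12 with t != t0 the limit
#' sign(t - t0) is returned.
#'
#' @param t,t0 scores in [-1, 1] (tolerance 1e-9).
#' @return B in [-1, 1].
#' @export
estimate_B <- function(t, t0) {
  for (v in c(t, t0)) if (!is.finite(v) || abs(v) > 1 + 1e-9)
    stop("t and t0 must lie in [-1, 1]")
  t <- min(1, max(-1, t)); t0 <- min(1, max(-1, t0))
  if (t == t0) return(0)
  den <- 1 - t * t0
  if (abs(den) < 1e-12) return(sign(t - t0))
  (t - t0) / den
}

# vectorised equation layer shared by predict_pair and the LOO scenarios;
# S: m x N score matrix, A/Bm: N x L coefficient matrices (L compounds)
.predict_block <- function(S, A, Bm) {
  num <- S %*% (A - Bm)
  den <- S %*% (A + Bm)
  tp <- num / den
  tp[den == 0] <- 0
  tp[tp > 1] <- 1
  tp[tp < -1] <- -1
  t <- sin(colMeans(asin(tp)))
  d0 <- colSums(A + Bm)
  t0 <- ifelse(d0 == 0, 0, colSums(A - Bm) / d0)
  bden <- 1 - t * t0
  B <- ifelse(t == t0, 0, ifelse(abs(bden) < 1e-12, sign(t - t0), (t - t0) / bden))
  list(tp = tp, t = as.numeric(t), t0 = as.numeric(t0), B = as.numeric(B))
}

#' Predict the interaction of a test protein with a compound
#'
#' Computes positional scores of the query sequence against every training
#' sequence, builds the belonging coefficients for the compound (binary from
#' the curated indices, or fuzzy Pa/Pi from per-target naive-Bayes models
#' fitted with the compound left out), and evaluates t_p, t, t0 and B.
#'
#' @param query_seq amino-acid sequence of the test protein (which must not
#'   be part of the training set).
#' @param compound a ligand id present in \code{dataset}, or a
#'   \code{ligand_structure} for an external compound (fuzzy mode only).
#' @param dataset an \code{InteractionDataset}.
#' @param mode \code{"binary"} or \code{"fuzzy"}.
#' @param frame segment length F.
#' @param model optional pre-fitted [fit_bayes_models()] result (fuzzy
#'   mode); fitted on the fly when omitted.
#' @param exclude_compound in fuzzy mode, drop the compound from the Bayes
#'   training statistics before predicting (the leave-one-out discipline;
#'   default TRUE when the compound is part of the dataset).
#' @return a \code{"pcm_prediction"}: list with \code{tp}, \code{t},
#'   \code{t0}, \code{B}, \code{m}, \code{N}, \code{mode}, \code{frame}.
#' @export
predict_pair <- function(query_seq, compound, dataset,
                         mode = c("binary", "fuzzy"), frame = 7,
                         model = NULL, exclude_compound = TRUE) {
  mode <- match.arg(mode)
  if (!inherits(dataset, "InteractionDataset"))
    stop("`dataset` must be an InteractionDataset")
  if (!length(dataset$proteins)) stop("training set is empty")
  kids <- names(dataset$proteins)

  if (mode == "binary") {
    if (!is.character(compound) || !(compound %in% names(dataset$ligands)))
      stop("binary mode needs a ligand id present in the dataset")
    idx <- vapply(kids, function(p) .pair_index(dataset, p, compound),
                  integer(1))
    a <- as.numeric(!is.na(idx) & idx == 1L)
    b <- as.numeric(!is.na(idx) & idx == 0L)
    coeffs <- coefficient_vector(a, b, "binary")
  } else {
    if (is.null(model)) model <- fit_bayes_models(dataset)
    if (is.character(compound)) {
      lig_id <- compound
      descr <- model$descriptors[[lig_id]]
      if (is.null(descr)) {
        if (!(compound %in% names(dataset$ligands)))
          stop("unknown ligand id '", compound, "'")
        descr <- compute_mna_descriptors(dataset$ligands[[compound]],
                                         model$level)$descriptors
      }
    } else if (inherits(compound, "ligand_structure")) {
      lig_id <- compound$ligand_id
      descr <- compute_mna_descriptors(compound, model$level)$descriptors
    } else stop("`compound` must be a ligand id or a ligand_structure")
    pp <- vapply(kids, function(k) {
      st <- if (isTRUE(exclude_compound))
        .target_stats(model, k, exclude_ligand = lig_id)
      else .target_stats(model, k)
      est <- .pa_pi_from_stats(st, descr, model)
      c(est$pa, est$pi)
    }, numeric(2))
    coeffs <- coefficient_vector(pp[1L, ], pp[2L, ], "fuzzy")
  }

  S <- positional_score_matrix(query_seq, dataset$proteins, frame)
  res <- .predict_block(S, cbind(coeffs$a), cbind(coeffs$b))
  out <- list(tp = as.numeric(res$tp), t = res$t, t0 = res$t0, B = res$B,
              m = nrow(S), N = length(kids), mode = mode, frame = frame,
              coefficients = coeffs)
  class(out) <- "pcm_prediction"
  out
}

#' @export
print.pcm_prediction <- function(x, ...) {
  cat(sprintf("pcm_prediction (%s, frame %d): t = %.5f, t0 = %.5f, B = %.5f\n",
              x$mode, x$frame, x$t, x$t0, x$B))
  invisible(x)
}
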