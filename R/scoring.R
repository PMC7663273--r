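#' Segment and positional similarity scores between sequences
#'
#' The sequence layer compares a test sequence Q with a training sequence K
#' through ungapped segments of a fixed frame length F.  The segment score
#' for start position i in Q at shift h is the sum of residue similarities
#' over the F aligned pairs,
#' \deqn{R_{ih} = \sum_{j=i}^{i+F-1} sim(q_j, k_{j+h}),}
#' and the positional score of position p against K is the maximum segment
#' score over all segments containing p at all shifts,
#' \deqn{S_{pk} = \max_{h,i} R_{ih}, \quad p-F < i \le p.}
#' The shipped similarity metric is residue identity (1 if equal, else 0);
#' ambiguous residues (B, Z, X and other non-standard letters) never match,
#' not even themselves.  Segments must lie fully inside both sequences, so
#' both must be at least F residues long.
#'
#' @param Q,K protein sequences (single character strings, 1-based
#'   coordinates).
#' @param i segment start position in Q.
#' @param h shift between the sequences: position j of Q is matched with
#'   position j+h of K.  Both signs are allowed as long as the segment stays
#'   inside K.
#' @param frame segment length F in residues (typical choices: 7 and 30).
#' @return `segment_score`: a single number in [0, F].
#'   `positional_scores`: numeric vector of length nchar(Q).
#' @name sequence_scoring
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# integer codes; non-standard residues are coded 0, which never matches
# anything (including itself)
.encode_seq <- function(s, side = 1L) {
  ch <- strsplit(toupper(s), "")[[1]]
  code <- match(ch, .AA20)
  code[is.na(code)] <- 0L
  code
}

#' @rdname sequence_scoring
#' @export
segment_score <- function(Q, K, i, h, frame) {
  q <- .encode_seq(Q, 1L); k <- .encode_seq(K, 2L)
  m <- length(q); n <- length(k)
  if (frame < 1 || frame != floor(frame)) stop("frame must be a positive integer")
  if (i < 1 || i + frame - 1 > m)
    stop("segment start i = ", i, " out of range for |Q| = ", m)
  if (i + h < 1 || i + frame - 1 + h > n)
    stop("shift h = ", h, " puts the segment outside K (|K| = ", n, ")")
  j <- i:(i + frame - 1)
  sum(q[j] > 0 & q[j] == k[j + h])
}

#' @rdname sequence_scoring
#' @export
positional_scores <- function(Q, K, frame) {
  q <- .encode_seq(Q, 1L); k <- .encode_seq(K, 2L)
  .positional_scores_int(q, k, frame)
}

.positional_scores_int <- function(q, k, frame) {
  m <- length(q); n <- length(k)
  if (frame < 1 || frame != floor(frame)) stop("frame must be a positive integer")
  if (m < frame || n < frame)
    stop("sequences must be at least as long as the frame (F = ", frame,
         ", |Q| = ", m, ", |K| = ", n, "); choose a smaller frame")
  .positional_scores_cpp(as.integer(q), as.integer(k), as.integer(frame))
}

#' Positional score matrix of a query against a set of training sequences
#'
#' @param Q query sequence.
#' @param training named character vector of training sequences.
#' @inheritParams sequence_scoring
#' @return numeric matrix, rows = positions of Q, columns = training
#'   sequences (in the order of \code{training}).
#' @export
positional_score_matrix <- function(Q, training, frame) {
  q <- .encode_seq(Q, 1L)
  S <- vapply(training, function(K)
    .positional_scores_int(q, .encode_seq(K, 2L), frame),
    numeric(length(q)))
  if (is.null(dim(S))) S <- matrix(S, nrow = length(q))
  colnames(S) <- names(training)
  S
}
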