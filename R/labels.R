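#' Canonical emotion vocabulary
#'
#' Six modeled Ekman emotions in the fixed canonical order used everywhere a
#' 6-vector is indexed: happy, sad, scared, disgusted, surprised, angry.
#' The annotation vocabulary additionally contains `contempt` (discarded by
#' mapping it to `other` before any aggregation) and `other` (no annotated
#' emotion).  `contempt` and `other` never receive a class index.
#'
#' @return `emotion_levels()` returns the six modeled emotions in canonical
#'   order; `annotation_levels()` returns the full 8-value annotation
#'   vocabulary.
#' @export
emotion_levels <- function() {
  c("happy", "sad", "scared", "disgusted", "surprised", "angry")
}

#' @rdname emotion_levels
#' @export
annotation_levels <- function() {
  c(emotion_levels(), "contempt", "other")
}

assert_labels <- function(x, allow = annotation_levels()) {
  bad <- setdiff(unique(as.character(x)), allow)
  if (length(bad) > 0L) {
    stop("unknown emotion label(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  invisible(as.character(x))
}

#' Normalize annotator votes
#'
#' Maps `contempt` votes to `other`; the six modeled emotions and `other`
#' pass through unchanged.  `contempt` has no counterpart in the facial
#' label stream and is discarded from the label space, so it carries no
#' probability mass in either aggregation scheme.  Normalization is applied
#' per vote, before any aggregation.
#'
#' @param vote Character vector of labels from [annotation_levels()].
#' @return Character vector over the 7-value normalized vocabulary.
#' @export
#' @examples
#' normalize_vote(c("contempt", "happy", "other"))
normalize_vote <- function(vote) {
  vote <- assert_labels(vote)
  vote[vote == "contempt"] <- "other"
  vote
}

#' Majority-vote (Method I) label for one-second intervals
#'
#' Aggregates the three annotators' votes for each second into one
#' categorical label: the label chosen by at least two annotators wins; if
#' all three picked different labels no dominant emotion exists and the
#' interval is `other`.  Votes are normalized with [normalize_vote()]
#' first, so a `contempt` majority also yields `other`.
#'
#' @param votes Either a length-3 character vector (one interval) or an
#'   `n x 3` character matrix (one row per second).
#' @return A single label, or a length-`n` character vector for matrix
#'   input.
#' @export
#' @examples
#' method1_label(c("happy", "happy", "sad"))   # "happy"
#' method1_label(c("sad", "angry", "scared"))  # "other": no majority
method1_label <- function(votes) {
  votes <- vote_matrix(votes)
  v1 <- votes[, 1L]; v2 <- votes[, 2L]; v3 <- votes[, 3L]
  out <- rep("other", nrow(votes))
  out[v1 == v2 | v1 == v3] <- v1[v1 == v2 | v1 == v3]
  out[v2 == v3] <- v2[v2 == v3]
  out
}

#' Proportional-distribution (Method II) labels
#'
#' Converts the three annotators' votes for each second into a 6-vector of
#' vote proportions over the modeled emotions: each emotion receives
#' (votes for it)/3.  `other` votes (including normalized `contempt`)
#' contribute no mass, so entries sum to 0, 1/3, 2/3 or 1; a second on
#' which no annotator picked a modeled emotion is the all-zero vector, the
#' canonical encoding of "no annotated emotion".
#'
#' @inheritParams method1_label
#' @return A named numeric 6-vector in canonical order, or an `n x 6`
#'   matrix for matrix input.
#' @export
#' @examples
#' method2_distribution(c("happy", "sad", "angry"))  # 1/3 each
#' method2_distribution(c("other", "other", "other"))  # zero vector
method2_distribution <- function(votes) {
  votes <- vote_matrix(votes)
  lv <- emotion_levels()
  n <- nrow(votes)
  out <- matrix(0, n, 6L, dimnames = list(NULL, lv))
  for (j in 1:3) {
    idx <- match(votes[, j], lv)
    ok <- !is.na(idx)
    out[cbind(which(ok), idx[ok])] <- out[cbind(which(ok), idx[ok])] + 1 / 3
  }
  if (n == 1L) out[1L, ] else out
}

vote_matrix <- function(votes) {
  if (is.matrix(votes)) {
    if (ncol(votes) != 3L) stop("votes must have exactly 3 columns")
  } else {
    if (length(votes) != 3L) stop("exactly 3 votes are required per second")
    votes <- matrix(as.character(votes), 1L, 3L)
  }
  storage.mode(votes) <- "character"
  m <- matrix(normalize_vote(votes), nrow(votes), 3L)
  m
}

#' One-hot encoding of a categorical label
#'
#' A modeled emotion becomes the unit vector at its canonical class index;
#' `other` becomes the all-zero vector, consistent with the zero-vector
#' convention for unlabeled frames.
#'
#' @param label Character vector of normalized labels.
#' @return An `n x 6` numeric matrix (a plain 6-vector when `n = 1`).
#' @export
encode_onehot <- function(label) {
  label <- normalize_vote(label)
  idx <- match(label, emotion_levels())
  out <- matrix(0, length(label), 6L, dimnames = list(NULL, emotion_levels()))
  ok <- !is.na(idx)
  out[cbind(which(ok), idx[ok])] <- 1
  if (length(label) == 1L) out[1L, ] else out
}

#' Dominant emotion of an intensity distribution
#'
#' Maps a non-negative 6-vector (or rows of an `n x 6` matrix) to its
#' argmax emotion.  The all-zero vector maps to `other` (no annotated
#' emotion); exact ties break to the lowest canonical class index, a
#' deterministic documented rule.
#'
#' @param dist Numeric 6-vector or `n x 6` matrix of non-negative scores.
#' @return Character label(s).
#' @export
#' @examples
#' dominant_from_distribution(c(0.5, 0.5, 0, 0, 0, 0))  # "happy" (tie rule)
dominant_from_distribution <- function(dist) {
  if (!is.matrix(dist)) dist <- matrix(dist, 1L)
  if (ncol(dist) != 6L) stop("distributions must have 6 columns")
  if (any(dist < 0)) stop("distributions must be non-negative")
  idx <- max.col(dist, ties.method = "first")
  out <- emotion_levels()[idx]
  out[rowSums(dist) <= 0] <- "other"
  out
}
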