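# Discrimination metrics -----------------------------------------------------

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability estimate: the proportion of
#' (positive, negative) score pairs in which the positive scores higher,
#' ties counted one half.  Equivalent to the trapezoidal area under the
#' empirical ROC curve and invariant under strictly increasing transforms
#' of the scores.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical), 1 = positive class.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auc(c(3, 1, 2), c(1, 0, 1))  # both positives outrank the negative
compute_auc <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a score threshold
#'
#' A patient is called positive when `score >= threshold`.
#'
#' @inheritParams compute_auc
#' @param threshold Decision threshold on the score scale.
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sens_spec <- function(scores, labels, threshold) {
  labels <- check_binary_labels(scores, labels)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  call_pos <- scores >= threshold
  c(sensitivity = sum(call_pos & labels == 1) / sum(labels == 1),
    specificity = sum(!call_pos & labels == 0) / sum(labels == 0))
}

#' Youden-optimal threshold
#'
#' The candidate threshold (observed score) maximizing
#' sensitivity + specificity - 1; ties broken toward the lower threshold.
#'
#' @inheritParams compute_auc
#' @return A threshold on the score scale.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) sum(sens_spec(scores, labels, t)) - 1,
              numeric(1))
  cand[which.max(j)]
}

check_binary_labels <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels),
            !anyNA(scores), !anyNA(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  labels
}
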