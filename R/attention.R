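#' Instance-dependent annotator reliability scores
#'
#' Cross-attention scores between the model's predicted class distribution
#' (the query) and the annotators' one-hot labels (the keys), instantiated
#' as a plain dot product. Because the query lies on the probability
#' simplex and each key is one-hot, the score is simply the predicted
#' probability of the class the annotator chose, already in `[0, 1]`;
#' no softmax is applied across annotators.
#'
#' @param query Length-`K` probability vector (sums to 1 within 1e-6).
#' @param keys One-hot labels of the observed annotators: a matrix with
#'   one row per annotator (rownames = annotator ids) or a list of
#'   length-`K` one-hot vectors.
#' @return Named numeric vector of scores in `[0, 1]`, one per annotator.
#' @export
reliability_scores <- function(query, keys) {
  query <- check_simplex(query, "query")
  keys <- as_one_hot_matrix(keys, length(query))
  scores <- drop(keys %*% query)
  names(scores) <- rownames(keys)
  scores
}

check_simplex <- function(p, what = "vector", tol = 1e-6) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < -tol) || any(p > 1 + tol) ||
      abs(sum(p) - 1) > tol) {
    abort(paste0(what, " must be a probability vector on the simplex"),
          class = "crowdattn_validation_error")
  }
  p
}

as_one_hot_matrix <- function(keys, class_count) {
  if (is.list(keys)) keys <- do.call(rbind, keys)
  if (is.vector(keys)) keys <- matrix(keys, nrow = 1)
  if (ncol(keys) != class_count) {
    abort("key dimension does not match the query", class = "crowdattn_validation_error")
  }
  ok <- apply(keys, 1, function(k) all(k %in% c(0, 1)) && sum(k) == 1)
  if (nrow(keys) == 0 || !all(ok)) {
    abort("keys must be one-hot vectors (at least one required)",
          class = "crowdattn_validation_error")
  }
  keys
}

#' Reliability-weighted pseudo-label
#'
#' Aggregates the observed one-hot annotations into a consensus
#' distribution: the score-weighted mean of the annotation vectors,
#' normalized by the total score so the result is a valid probability
#' distribution. When the total score is at most `epsilon` (a query
#' orthogonal to every annotation), equal weights over the observed
#' annotators are used instead, which reduces to the soft majority vote.
#'
#' @param scores Numeric reliability weights in `[0, 1]`, one per
#'   observed annotator.
#' @param values The same annotations as one-hot rows (matrix or list),
#'   aligned with `scores`.
#' @param epsilon Fallback threshold on the total score (default 1e-8).
#' @return Length-`K` probability vector on the simplex.
#' @export
pseudo_label <- function(scores, values, epsilon = 1e-8) {
  scores <- as.numeric(scores)
  if (length(scores) == 0) {
    abort("at least one annotator is required", class = "crowdattn_validation_error")
  }
  if (any(!is.finite(scores)) || any(scores < 0)) {
    abort("scores must be finite and non-negative", class = "crowdattn_validation_error")
  }
  values <- if (is.list(values)) do.call(rbind, values) else
    if (is.vector(values)) matrix(values, nrow = 1) else values
  if (nrow(values) != length(scores)) {
    abort("scores and values must be aligned", class = "crowdattn_validation_error")
  }
  total <- sum(scores)
  if (total <= epsilon) scores <- rep(1, length(scores))
  drop(crossprod(values, scores)) / sum(scores)
}

#' Mean cross-entropy of predictions against pseudo-labels
#'
#' The training objective: the average over instances of the cross-entropy
#' between each pseudo-label (target distribution) and the model's
#' predicted distribution. Predictions are clamped at 1e-12 before the
#' logarithm.
#'
#' @param predictions N x K matrix of predicted distributions (rows on the
#'   simplex), or a single vector.
#' @param pseudo_labels N x K matrix of target distributions aligned with
#'   `predictions`.
#' @return Non-negative scalar loss.
#' @export
crowd_cross_entropy <- function(predictions, pseudo_labels) {
  predictions <- if (is.vector(predictions)) matrix(predictions, nrow = 1) else
    as.matrix(predictions)
  pseudo_labels <- if (is.vector(pseudo_labels)) matrix(pseudo_labels, nrow = 1) else
    as.matrix(pseudo_labels)
  if (!all(dim(predictions) == dim(pseudo_labels))) {
    abort("predictions and pseudo_labels must have the same shape",
          class = "crowdattn_validation_error")
  }
  -mean(rowSums(pseudo_labels * log(pmax(predictions, 1e-12))))
}
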