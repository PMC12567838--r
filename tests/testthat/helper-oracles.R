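# Independent oracles used by the tests. These deliberately re-derive the
# quantities with straightforward loop-based code, separate from the
# package's vectorized implementations.

# Attention-score oracle: the score of an annotator is just the query's
# coordinate at the class the annotator picked.
oracle_coordinate_lookup <- function(query, labels) {
  vapply(labels, function(l) query[l + 1L], numeric(1))
}

# Soft majority vote: the empirical distribution of the labels.
oracle_soft_mv <- function(labels, class_count) {
  tabulate(labels + 1L, nbins = class_count) / length(labels)
}

# Plain-loop Dawid-Skene EM: majority-vote proportion initialization,
# additive smoothing, M-step then E-step per iteration, same update order
# as the package but written instance-by-instance.
oracle_dawid_skene <- function(annotations, class_count, n_iter,
                               smoothing = 1e-6) {
  ids <- unique(annotations$instance_id)
  workers <- sort(unique(annotations$annotator_id))
  n <- length(ids)
  K <- class_count
  Tpost <- matrix(0, n, K)
  for (r in seq_len(nrow(annotations))) {
    i <- match(annotations$instance_id[r], ids)
    Tpost[i, annotations$label[r] + 1L] <- Tpost[i, annotations$label[r] + 1L] + 1
  }
  for (i in seq_len(n)) Tpost[i, ] <- Tpost[i, ] / sum(Tpost[i, ])
  loglik <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    priors <- numeric(K)
    for (k in seq_len(K)) priors[k] <- sum(Tpost[, k]) + smoothing
    priors <- priors / sum(priors)
    conf <- list()
    for (w in seq_along(workers)) {
      M <- matrix(smoothing, K, K)
      for (r in seq_len(nrow(annotations))) {
        if (annotations$annotator_id[r] == workers[w]) {
          i <- match(annotations$instance_id[r], ids)
          j <- annotations$label[r] + 1L
          for (k in seq_len(K)) M[k, j] <- M[k, j] + Tpost[i, k]
        }
      }
      for (k in seq_len(K)) M[k, ] <- M[k, ] / sum(M[k, ])
      conf[[w]] <- M
    }
    ll <- 0
    Tnew <- matrix(0, n, K)
    for (i in seq_len(n)) {
      lik <- priors
      for (r in seq_len(nrow(annotations))) {
        if (match(annotations$instance_id[r], ids) == i) {
          w <- match(annotations$annotator_id[r], workers)
          j <- annotations$label[r] + 1L
          for (k in seq_len(K)) lik[k] <- lik[k] * conf[[w]][k, j]
        }
      }
      ll <- ll + log(sum(lik))
      Tnew[i, ] <- lik / sum(lik)
    }
    loglik[it] <- ll
    Tpost <- Tnew
  }
  list(posteriors = Tpost, log_likelihood = loglik, instance_ids = ids)
}

# Friedman statistic from first principles: explicit per-condition ranking
# (rank 1 = best) and the rank-sum formula.
oracle_friedman <- function(scores) {
  k <- nrow(scores)
  n <- ncol(scores)
  R <- numeric(k)
  for (j in seq_len(n)) {
    ord <- order(scores[, j], decreasing = TRUE)
    r <- numeric(k)
    r[ord] <- seq_len(k)
    R <- R + r
  }
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

# A small fully-labelled crowd dataset built in code.
make_toy_dataset <- function(n = 12, n_annotators = 3, class_count = 3,
                             seed = 42) {
  set.seed(seed)
  features <- tibble::tibble(
    instance_id = sprintf("i%02d", seq_len(n)),
    f1 = runif(n), f2 = runif(n)
  )
  annotations <- tidyr::expand_grid(
    instance_id = features$instance_id,
    annotator_id = sprintf("a%d", seq_len(n_annotators))
  )
  annotations$label <- sample(0:(class_count - 1), nrow(annotations),
                              replace = TRUE)
  gold <- tibble::tibble(instance_id = features$instance_id,
                         label = sample(0:(class_count - 1), n, replace = TRUE))
  assemble_dataset(features, annotations, gold = gold,
                   class_count = class_count)
}

tiny_net <- function(class_count = 3) network_config(hidden = c(16, 8),
                                                     class_count = class_count)
tiny_train <- function(seed = 1, epochs = 40, ...) {
  train_config(epochs = epochs, seed = seed, ...)
}

random_simplex <- function(k) {
  g <- -log(runif(k))
  g / sum(g)
}
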