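#' Majority-vote label aggregation
#'
#' The most frequent label per instance, ties broken toward the lowest
#' class index. Assumes homogeneous annotators; serves as the naive
#' aggregation baseline.
#'
#' @param annotations Data frame `instance_id, annotator_id, label`.
#' @param class_count Number of classes `K`.
#' @return A tibble `instance_id, label` with one row per instance, in
#'   order of first appearance.
#' @export
majority_vote <- function(annotations, class_count) {
  class_count <- check_class_count(class_count)
  if (nrow(annotations) == 0) {
    abort("annotations must be non-empty", class = "crowdattn_validation_error")
  }
  annotations |>
    dplyr::group_by(.data$instance_id) |>
    dplyr::summarise(
      label = {
        counts <- tabulate(.data$label + 1L, nbins = class_count)
        which.max(counts) - 1L  # which.max takes the first (lowest) maximum
      },
      .groups = "drop"
    ) |>
    dplyr::slice(match(unique(annotations$instance_id), .data$instance_id))
}

#' Dawid-Skene truth inference by expectation-maximization
#'
#' Jointly estimates latent class posteriors for every instance and a
#' K x K row-stochastic confusion matrix per annotator (row = latent
#' class, column = emitted label). Initialization is the majority-vote
#' posterior; priors and confusion rows are re-estimated with additive
#' smoothing each M-step; the E-step multiplies the prior by each
#' observed annotator's confusion likelihood. Iteration stops when the
#' largest posterior change falls below `tol` or after `max_iter`
#' iterations (the latter sets `converged = FALSE` with a warning, never
#' an error). The observed-data log-likelihood is recorded every
#' iteration and is non-decreasing.
#'
#' @param annotations Data frame `instance_id, annotator_id, label`.
#' @param class_count Number of classes `K` (>= 2).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Convergence threshold on the max posterior change
#'   (default 1e-6).
#' @param smoothing Additive smoothing on priors and confusion rows
#'   (default 1e-6).
#' @return An object of class `dawid_skene`: `posteriors` (tibble
#'   `instance_id`, `p_0` ... `p_{K-1}`, `label`), `confusion` (named list
#'   of K x K matrices), `priors`, `log_likelihood` (per-iteration trace),
#'   `converged`, `iterations`.
#' @export
dawid_skene <- function(annotations, class_count, max_iter = 100, tol = 1e-6,
                        smoothing = 1e-6) {
  class_count <- check_class_count(class_count)
  validate_annotations(annotations, class_count)
  ids <- unique(annotations$instance_id)
  workers <- sort(unique(annotations$annotator_id))
  n <- length(ids)
  K <- class_count
  ni <- match(annotations$instance_id, ids)
  wi <- match(annotations$annotator_id, workers)
  li <- annotations$label + 1L

  # MV-proportion initialization of the posteriors
  Tpost <- matrix(0, n, K)
  for (r in seq_along(ni)) Tpost[ni[r], li[r]] <- Tpost[ni[r], li[r]] + 1
  Tpost <- Tpost / rowSums(Tpost)

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # M-step: priors and per-annotator confusion matrices
    priors <- colSums(Tpost) + smoothing
    priors <- priors / sum(priors)
    conf <- lapply(seq_along(workers), function(w) {
      rows <- which(wi == w)
      M <- matrix(smoothing, K, K)
      for (r in rows) M[, li[r]] <- M[, li[r]] + Tpost[ni[r], ]
      M / rowSums(M)
    })
    # E-step in log space
    logT <- matrix(rep(log(priors), each = n), n, K)
    for (r in seq_along(ni)) {
      logT[ni[r], ] <- logT[ni[r], ] + log(conf[[wi[r]]][, li[r]])
    }
    mx <- apply(logT, 1, max)
    loglik <- c(loglik, sum(mx + log(rowSums(exp(logT - mx)))))
    Tnew <- exp(logT - mx)
    Tnew <- Tnew / rowSums(Tnew)
    delta <- max(abs(Tnew - Tpost))
    Tpost <- Tnew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("Dawid-Skene EM did not converge within %d iterations", max_iter))
  }
  names(conf) <- workers
  post <- tibble::as_tibble(Tpost, .name_repair = ~ paste0("p_", seq_len(K) - 1L))
  post <- dplyr::bind_cols(tibble::tibble(instance_id = ids), post,
                           tibble::tibble(label = max.col(Tpost, ties.method = "first") - 1L))
  structure(
    list(posteriors = post, confusion = conf, priors = priors,
         log_likelihood = loglik, converged = converged, iterations = iter),
    class = "dawid_skene"
  )
}

#' @export
print.dawid_skene <- function(x, ...) {
  cat(sprintf("<dawid_skene> %d instances, %d annotators, %d iterations (%s)\n",
              nrow(x$posteriors), length(x$confusion), x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Per-annotator confusion estimates in long form
#' @param x A `dawid_skene` fit.
#' @param ... Unused.
#' @return A tibble `annotator_id, latent_class, emitted_label, probability`.
#' @exportS3Method generics::tidy
#' @export
tidy.dawid_skene <- function(x, ...) {
  purrr::imap_dfr(x$confusion, function(M, id) {
    K <- nrow(M)
    tibble::tibble(
      annotator_id = id,
      latent_class = rep(seq_len(K) - 1L, times = K),
      emitted_label = rep(seq_len(K) - 1L, each = K),
      probability = as.numeric(M)
    )
  })
}

#' @exportS3Method generics::glance
#' @export
glance.dawid_skene <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    log_likelihood = x$log_likelihood[length(x$log_likelihood)]
  )
}

#' Train the backbone on fixed targets
#'
#' Standard cross-entropy training of the same network and optimizer used
#' by [train_crowdattention()], but against fixed per-instance targets:
#' gold labels (the upper-bound baseline), majority-vote labels, or
#' Dawid-Skene posteriors.
#'
#' @param features Data frame `instance_id` plus feature columns.
#' @param targets Either a data frame `instance_id, label` (hard labels,
#'   one-hot encoded internally) or `instance_id, p_0, ..., p_{K-1}`
#'   (soft targets on the simplex).
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()]; the crowd-specific fields are
#'   ignored.
#' @param method Label recorded on the returned model (default
#'   `"fixed-target"`).
#' @return A `crowdattn_model`.
#' @export
train_on_targets <- function(features, targets, net_cfg = network_config(),
                             train_cfg = train_config(),
                             method = "fixed-target") {
  features <- tibble::as_tibble(features)
  targets <- tibble::as_tibble(targets)
  K <- net_cfg$class_count
  if (!all(features$instance_id %in% targets$instance_id)) {
    abort("every feature instance needs a target", class = "crowdattn_validation_error")
  }
  targets <- targets[match(features$instance_id, targets$instance_id), ]
  if ("label" %in% names(targets) && !("p_0" %in% names(targets))) {
    Tm <- one_hot(targets$label, K)
    if (is.vector(Tm)) Tm <- matrix(Tm, nrow = 1)
  } else {
    cols <- paste0("p_", seq_len(K) - 1L)
    if (!all(cols %in% names(targets))) {
      abort("targets must carry 'label' or 'p_0'..'p_{K-1}' columns",
            class = "crowdattn_validation_error")
    }
    Tm <- as.matrix(targets[cols])
    if (any(Tm < 0) || any(abs(rowSums(Tm) - 1) > 1e-6)) {
      abort("soft targets must lie on the simplex", class = "crowdattn_validation_error")
    }
  }
  X <- as.matrix(features[-1])
  rownames(X) <- features$instance_id
  if (any(!is.finite(X))) {
    abort("features must be finite", class = "crowdattn_validation_error")
  }
  grad_fn <- function(P, idx) {
    Tb <- Tm[idx, , drop = FALSE]
    list(loss = crowd_cross_entropy(P, Tb), d_logits = (P - Tb) / nrow(P))
  }
  fit <- mlp_train(X, grad_fn, ncol(X), net_cfg, train_cfg)
  new_crowdattn_model(fit$params, net_cfg, train_cfg, method,
                      fit$history, ncol(X), colnames(features)[-1])
}

#' Convenience trainers for the three aggregation baselines
#'
#' `train_gold` fits on the dataset's gold labels (upper bound),
#' `train_mv` on majority-vote labels, and `train_ds` on Dawid-Skene
#' posterior distributions.
#'
#' @param dataset A `crowd_dataset` (gold labels required for
#'   `train_gold`).
#' @param net_cfg,train_cfg Passed to [train_on_targets()].
#' @return A `crowdattn_model`.
#' @export
train_gold <- function(dataset, net_cfg = network_config(), train_cfg = train_config()) {
  if (is.null(dataset$gold)) {
    abort("dataset has no gold labels", class = "crowdattn_validation_error")
  }
  train_on_targets(dataset$features, dataset$gold, net_cfg, train_cfg,
                   method = "gold")
}

#' @rdname train_gold
#' @export
train_mv <- function(dataset, net_cfg = network_config(), train_cfg = train_config()) {
  mv <- majority_vote(dataset$annotations, dataset$class_count)
  train_on_targets(dataset$features, mv, net_cfg, train_cfg, method = "mv")
}

#' @rdname train_gold
#' @export
train_ds <- function(dataset, net_cfg = network_config(), train_cfg = train_config()) {
  ds <- dawid_skene(dataset$annotations, dataset$class_count)
  train_on_targets(dataset$features, ds$posteriors, net_cfg, train_cfg,
                   method = "ds")
}
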