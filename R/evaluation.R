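#' Accuracy and per-class / macro F1 of hard predictions
#'
#' Per-class F1 is the harmonic mean of that class's precision and
#' recall; classes with neither true nor predicted support score 0. The
#' macro F1 is the unweighted mean over all `K` classes. All values are
#' reported in percent.
#'
#' @param y_true Integer vector of true labels in `{0..K-1}`.
#' @param y_pred Integer vector of predicted labels, same length.
#' @param class_count Number of classes `K`.
#' @return An object of class `metrics_report`: `accuracy`,
#'   `per_class_f1` (length `K`), `macro_f1`, `n_evaluated`.
#' @export
classification_report <- function(y_true, y_pred, class_count) {
  class_count <- check_class_count(class_count)
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1) {
    abort("y_true and y_pred must be non-empty and of equal length",
          class = "crowdattn_validation_error")
  }
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= class_count)) {
    abort("labels must lie in {0..K-1}", class = "crowdattn_validation_error")
  }
  f1 <- vapply(seq_len(class_count) - 1L, function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  structure(
    list(accuracy = 100 * mean(y_true == y_pred),
         per_class_f1 = 100 * f1,
         macro_f1 = 100 * mean(f1),
         n_evaluated = length(y_true)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  accuracy %.2f%%  macro F1 %.2f%%\n",
              x$n_evaluated, x$accuracy, x$macro_f1))
  cat("per-class F1 (%):", paste(sprintf("%.2f", x$per_class_f1), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(class = seq_along(x$per_class_f1) - 1L, f1 = x$per_class_f1)
}

#' @exportS3Method generics::glance
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1,
                 n_evaluated = x$n_evaluated)
}

#' Reliability-recovery score
#'
#' Compares estimated instance-dependent annotator reliabilities against
#' the true per-annotation correctness indicators: estimates are
#' binarized at `threshold` (>= threshold means "reliable") and, per
#' annotator, the F1 with "reliable" as the positive class is computed;
#' the summary is the unweighted mean over annotators, in percent.
#'
#' @param estimated Data frame `instance_id, annotator_id, score` with
#'   scores in `[0, 1]` (e.g. from [estimate_reliabilities()]).
#' @param truth Data frame `instance_id, annotator_id, reliable` with 0/1
#'   indicators over exactly the same (instance, annotator) pairs.
#' @param threshold Binarization threshold (default 0.5).
#' @return A list: `per_annotator` (tibble `annotator_id, f1` in percent)
#'   and `average_f1`.
#' @export
reliability_recovery_f1 <- function(estimated, truth, threshold = 0.5) {
  estimated <- tibble::as_tibble(estimated)
  truth <- tibble::as_tibble(truth)
  joined <- dplyr::inner_join(estimated, truth,
                              by = c("instance_id", "annotator_id"))
  if (nrow(joined) != nrow(estimated) || nrow(joined) != nrow(truth)) {
    abort("estimated and truth index sets are misaligned",
          class = "crowdattn_validation_error")
  }
  per <- joined |>
    dplyr::mutate(pred = as.integer(.data$score >= threshold)) |>
    dplyr::group_by(.data$annotator_id) |>
    dplyr::summarise(
      f1 = {
        tp <- sum(.data$pred == 1L & .data$reliable == 1L)
        fp <- sum(.data$pred == 1L & .data$reliable == 0L)
        fn <- sum(.data$pred == 0L & .data$reliable == 1L)
        if (2 * tp + fp + fn == 0) 0 else 100 * 2 * tp / (2 * tp + fp + fn)
      },
      .groups = "drop"
    )
  list(per_annotator = per, average_f1 = mean(per$f1))
}

#' Friedman rank test across matched conditions
#'
#' Ranks the methods within each condition (rank 1 = best, average ranks
#' for ties; higher score = better) and computes the classical Friedman
#' chi-square statistic `12 / (N k (k+1)) * sum(R_j^2) - 3 N (k+1)` with
#' `k` methods and `N` conditions, referred to a chi-square distribution
#' with `k - 1` degrees of freedom. No tie-correction factor is applied.
#'
#' @param scores Numeric matrix or data frame, one row per method and one
#'   column per condition; rownames identify the methods.
#' @return A list of class `crowdattn_friedman`: `statistic`, `df`,
#'   `p_value`, `rank_sums`, `n_methods`, `n_conditions`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  k <- nrow(scores)
  n <- ncol(scores)
  if (k < 3) {
    abort("at least 3 methods are required", class = "crowdattn_validation_error")
  }
  if (n < 2) {
    abort("at least 2 conditions are required", class = "crowdattn_validation_error")
  }
  ranks <- apply(scores, 2, function(col) rank(-col, ties.method = "average"))
  rank_sums <- rowSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(rank_sums^2) - 3 * n * (k + 1)
  structure(
    list(statistic = stat, df = k - 1L,
         p_value = pchisq(stat, df = k - 1, lower.tail = FALSE),
         rank_sums = stats::setNames(rank_sums, rownames(scores)),
         n_methods = k, n_conditions = n),
    class = "crowdattn_friedman"
  )
}

#' @export
print.crowdattn_friedman <- function(x, ...) {
  cat(sprintf("Friedman test: chi-square = %.4f, df = %d, p = %.4g (%d methods, %d conditions)\n",
              x$statistic, x$df, x$p_value, x$n_methods, x$n_conditions))
  invisible(x)
}

#' Cumulative annotator-subset sizes
#'
#' The arithmetic progression `1, 1 + step, 1 + 2 step, ...` capped at the
#' annotator count `W`, with `W` always included as the final size.
#'
#' @param annotator_count Total number of annotators `W`.
#' @param step Increment (default 4).
#' @return Strictly increasing integer vector starting at 1 and ending
#'   at `W`.
#' @export
sweep_sizes <- function(annotator_count, step = 4) {
  if (step < 1 || annotator_count < 1) {
    abort("annotator_count and step must be positive",
          class = "crowdattn_validation_error")
  }
  sizes <- seq(1L, as.integer(annotator_count), by = as.integer(step))
  if (sizes[length(sizes)] != annotator_count) {
    sizes <- c(sizes, as.integer(annotator_count))
  }
  sizes
}

#' Cumulative annotator-sweep experiment
#'
#' Sorts annotators by descending number of labelled instances (ties
#' broken by annotator id), then trains and evaluates every method on
#' cumulative annotator subsets of sizes `1, 1 + step, ...` up to all
#' annotators. Training instances left without any annotation under a
#' subset are dropped for that run; evaluation always uses the full test
#' split's gold labels.
#'
#' @param train A `crowd_dataset` used for training.
#' @param test A `crowd_dataset` with gold labels used for evaluation.
#' @param methods Character subset of `c("crowdattention", "mv", "ds",
#'   "gold")`.
#' @param step Subset-size increment (default 4).
#' @param seeds Integer vector of training seeds (one run per seed per
#'   size per method).
#' @param net_cfg,train_cfg Network / training configuration templates;
#'   the seed field of `train_cfg` is overridden per run.
#' @return A tibble of class `sweep_result`: one row per (method,
#'   n_annotators, seed) with the test `macro_f1` (percent).
#' @export
annotator_sweep <- function(train, test, methods = c("crowdattention", "mv", "ds"),
                            step = 4, seeds = 1,
                            net_cfg = network_config(class_count = train$class_count),
                            train_cfg = train_config()) {
  stopifnot(inherits(train, "crowd_dataset"), inherits(test, "crowd_dataset"))
  if (length(methods) == 0) {
    abort("at least one method is required", class = "crowdattn_validation_error")
  }
  methods <- match.arg(methods, c("crowdattention", "mv", "ds", "gold"),
                       several.ok = TRUE)
  if (is.null(test$gold)) {
    abort("test dataset needs gold labels for evaluation",
          class = "crowdattn_validation_error")
  }
  order_tbl <- train$annotations |>
    dplyr::count(.data$annotator_id, name = "n_labels") |>
    dplyr::arrange(dplyr::desc(.data$n_labels), .data$annotator_id)
  sizes <- sweep_sizes(nrow(order_tbl), step)
  y_test <- test$gold$label

  runs <- tidyr::expand_grid(n_annotators = sizes, method = methods, seed = seeds)
  runs$macro_f1 <- purrr::pmap_dbl(runs, function(n_annotators, method, seed) {
    keep <- order_tbl$annotator_id[seq_len(n_annotators)]
    ann <- dplyr::filter(train$annotations, .data$annotator_id %in% keep)
    feats <- dplyr::filter(train$features, .data$instance_id %in% ann$instance_id)
    gold <- if (is.null(train$gold)) NULL else
      dplyr::filter(train$gold, .data$instance_id %in% feats$instance_id)
    sub <- assemble_dataset(feats, ann, gold = gold,
                            class_count = train$class_count)
    cfg <- train_cfg
    cfg$seed <- as.integer(seed)
    model <- switch(method,
      crowdattention = train_crowdattention(sub, net_cfg, cfg),
      mv = train_mv(sub, net_cfg, cfg),
      ds = train_ds(sub, net_cfg, cfg),
      gold = train_gold(sub, net_cfg, cfg)
    )
    preds <- predict(model, test)
    classification_report(y_test, preds$pred_label, train$class_count)$macro_f1
  })
  class(runs) <- c("sweep_result", class(runs))
  attr(runs, "sizes") <- sizes
  runs
}

#' Plot a cumulative annotator sweep
#' @param object A `sweep_result` from [annotator_sweep()].
#' @param ... Unused.
#' @return A ggplot object: mean macro F1 per method against the number
#'   of annotators.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sweep_result <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$method, .data$n_annotators) |>
    dplyr::summarise(macro_f1 = mean(.data$macro_f1), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$n_annotators, y = .data$macro_f1,
                                     color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of annotators", y = "Test macro F1 (%)",
                  color = "Method") +
    ggplot2::theme_minimal()
}
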