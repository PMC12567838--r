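#' Specification of the synthetic three-class task
#'
#' A one-dimensional benchmark: inputs are drawn uniformly on `[0, 1]` and
#' the true class is the argmax of three sinusoids (see [true_label()]).
#'
#' @param n_train Number of training instances (default 300).
#' @param n_test Number of test instances (default 200).
#' @return An object of class `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(n_train = 300, n_test = 200) {
  if (n_train < 1 || n_test < 1) {
    abort("n_train and n_test must be positive", class = "crowdattn_validation_error")
  }
  structure(
    list(n_train = as.integer(n_train), n_test = as.integer(n_test),
         class_count = 3L),
    class = "synthetic_task_spec"
  )
}

#' True label of the synthetic task
#'
#' The class of a point `x` in `[0, 1]` is the index (0-based) of the
#' largest of `sin(2*pi*x)`, `-sin(2*pi*x)` and `0.5 - sin(2*pi*(x + 0.25))`,
#' ties broken toward the lowest index.
#'
#' @param x Numeric vector with values in `[0, 1]`.
#' @return Integer vector of class indices in `{0, 1, 2}`.
#' @export
true_label <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("x must lie in [0, 1]", class = "crowdattn_domain_error")
  }
  f <- cbind(sin(2 * pi * x),
             -sin(2 * pi * x),
             0.5 - sin(2 * pi * (x + 0.25)))
  max.col(f, ties.method = "first") - 1L
}

#' Generate the synthetic task inputs and gold labels
#'
#' @param spec A [synthetic_task_spec()].
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A tibble with columns `instance_id`, `x`, `label` and `split`
#'   (`"train"` or `"test"`).
#' @export
generate_task <- function(spec = synthetic_task_spec(), seed = 1) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  n <- spec$n_train + spec$n_test
  x <- local_seed(seed, runif(n))
  split <- rep(c("train", "test"), c(spec$n_train, spec$n_test))
  id <- sprintf("%s%04d", ifelse(split == "train", "tr", "te"),
                c(seq_len(spec$n_train), seq_len(spec$n_test)))
  tibble::tibble(instance_id = id, x = x, label = true_label(x), split = split)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state after.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Construct an annotator reliability profile
#'
#' A profile is a deterministic reliability function on `[0, 1]`: the
#' annotator labels correctly exactly where `x` falls inside its reliable
#' set, a finite union of disjoint half-open intervals `[lower, upper)`.
#' Outside the reliable set it errs according to `error_rule`.
#'
#' @param intervals Data frame with numeric columns `lower` and `upper`,
#'   disjoint and contained in `[0, 1]`.
#' @param error_rule `"uniform-wrong"` (draw uniformly among the K-1 wrong
#'   classes; allows sub-chance accuracy) or `"uniform-any"` (draw among all
#'   K classes).
#' @param target_accuracy Optional calibration target in percent; the total
#'   interval length must match `target_accuracy / 100` within 0.005.
#' @param id Annotator id string.
#' @return An object of class `annotator_profile`.
#' @export
annotator_profile <- function(intervals, error_rule = c("uniform-wrong", "uniform-any"),
                              target_accuracy = NULL, id = "a1") {
  error_rule <- match.arg(error_rule)
  intervals <- tibble::as_tibble(intervals)
  stopifnot(all(c("lower", "upper") %in% names(intervals)))
  intervals <- dplyr::arrange(intervals, .data$lower)
  if (any(intervals$lower < 0) || any(intervals$upper > 1) ||
      any(intervals$upper <= intervals$lower)) {
    abort("intervals must be non-empty and contained in [0, 1]",
          class = "crowdattn_validation_error")
  }
  if (nrow(intervals) > 1 &&
      any(intervals$lower[-1] < intervals$upper[-nrow(intervals)])) {
    abort("intervals must be disjoint", class = "crowdattn_validation_error")
  }
  measure <- sum(intervals$upper - intervals$lower)
  if (!is.null(target_accuracy) &&
      abs(measure - target_accuracy / 100) > 0.005) {
    abort(sprintf("reliable-set measure %.4f misses target %.4f",
                  measure, target_accuracy / 100),
          class = "crowdattn_validation_error")
  }
  structure(
    list(id = id, intervals = intervals, error_rule = error_rule,
         target_accuracy = target_accuracy %||% (100 * measure),
         measure = measure),
    class = "annotator_profile"
  )
}

#' @export
print.annotator_profile <- function(x, ...) {
  cat(sprintf("<annotator_profile %s> reliable on %s (measure %.4f), errors %s\n",
              x$id,
              paste(sprintf("[%.4f,%.4f)", x$intervals$lower, x$intervals$upper),
                    collapse = " U "),
              x$measure, x$error_rule))
  invisible(x)
}

#' Evaluate a profile's reliability indicator
#'
#' @param profile An [annotator_profile()].
#' @param x Numeric vector in `[0, 1]`.
#' @return Integer 0/1 vector: 1 iff `x` lies in the reliable set
#'   (half-open membership, lower bound inclusive).
#' @export
reliability_value <- function(profile, x) {
  stopifnot(inherits(profile, "annotator_profile"))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("x must lie in [0, 1]", class = "crowdattn_domain_error")
  }
  inside <- vapply(x, function(xi) {
    any(xi >= profile$intervals$lower & xi < profile$intervals$upper)
  }, logical(1))
  as.integer(inside)
}

#' The five default annotator profiles
#'
#' Five simulated labelers of decreasing and qualitatively distinct
#' reliability: two plateau annotators with sharp transitions (a1, a3),
#' two non-monotonic annotators with alternating reliable bumps (a2, a4),
#' and one sparsely reliable annotator (a5). Interval lengths are
#' calibrated so the expected accuracies (in percent, under uniform inputs
#' and uniform-wrong errors) are 84.66, 59.66, 66.33, 55.66 and 27.66 --
#' the last being deliberately adversarial, below the 33.3% chance level
#' of a three-class task.
#'
#' @return A named list of five [annotator_profile()] objects (`a1`..`a5`).
#' @export
default_profiles <- function() {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(lower = m[, 1], upper = m[, 2])
  }
  list(
    a1 = annotator_profile(iv(0, 0.4216, 0.575, 1), "uniform-wrong", 84.66, "a1"),
    a2 = annotator_profile(iv(0.05, 0.25, 0.40, 0.60, 0.75, 0.9466),
                           "uniform-wrong", 59.66, "a2"),
    a3 = annotator_profile(iv(0.10, 0.45, 0.52, 0.8333), "uniform-wrong", 66.33, "a3"),
    a4 = annotator_profile(iv(0, 0.14, 0.28, 0.42, 0.56, 0.70, 0.84, 0.9766),
                           "uniform-wrong", 55.66, "a4"),
    a5 = annotator_profile(iv(0.3617, 0.6383), "uniform-wrong", 27.66, "a5")
  )
}

#' Simulate annotator labels for a set of instances
#'
#' Where a profile's reliability indicator is 1 the annotator emits the
#' gold label; where it is 0 it draws an error according to its rule.
#' The returned truth table records, for every annotation, whether it was
#' correct -- the ground truth for reliability-recovery evaluation.
#'
#' @param profiles List of [annotator_profile()] objects.
#' @param x Numeric inputs in `[0, 1]`.
#' @param gold Integer gold labels for `x`.
#' @param instance_id Character instance ids (same length as `x`).
#' @param class_count Number of classes `K`.
#' @param seed Integer seed.
#' @return A list with `annotations` (tibble `instance_id, annotator_id,
#'   label`) and `reliability` (tibble `instance_id, annotator_id,
#'   reliable`), both with one row per (instance, annotator).
#' @export
simulate_annotations <- function(profiles, x, gold, instance_id,
                                 class_count = 3, seed = 1) {
  if (length(profiles) == 0) {
    abort("at least one annotator profile is required",
          class = "crowdattn_validation_error")
  }
  class_count <- check_class_count(class_count)
  stopifnot(length(x) == length(gold), length(x) == length(instance_id))
  local_seed(seed, {
    per_annot <- purrr::map(profiles, function(pr) {
      rel <- reliability_value(pr, x)
      lab <- gold
      wrong <- which(rel == 0L)
      if (length(wrong) > 0) {
        if (pr$error_rule == "uniform-wrong") {
          # uniform over the K-1 classes != gold
          shift <- sample.int(class_count - 1L, length(wrong), replace = TRUE)
          lab[wrong] <- (gold[wrong] + shift) %% class_count
        } else {
          lab[wrong] <- sample.int(class_count, length(wrong), replace = TRUE) - 1L
        }
      }
      tibble::tibble(
        instance_id = instance_id, annotator_id = pr$id,
        label = as.integer(lab), reliable = as.integer(lab == gold)
      )
    })
    all <- dplyr::bind_rows(per_annot)
    list(
      annotations = dplyr::select(all, "instance_id", "annotator_id", "label"),
      reliability = dplyr::select(all, "instance_id", "annotator_id", "reliable")
    )
  })
}

#' Generate the full synthetic multi-annotator benchmark
#'
#' Draws the task inputs, derives gold labels, and simulates the annotator
#' crowd on the training and test splits. All annotators label every
#' instance.
#'
#' @param spec A [synthetic_task_spec()].
#' @param profiles List of [annotator_profile()] objects; defaults to
#'   [default_profiles()].
#' @param seed Integer seed driving both the input draw and the annotator
#'   errors.
#' @return A list of class `synthetic_crowd_data` with elements `train`
#'   and `test` (each a `crowd_dataset` with gold labels), `reliability`
#'   (named list of the two truth tables) and `profiles`.
#' @export
simulate_crowd_benchmark <- function(spec = synthetic_task_spec(),
                                     profiles = default_profiles(), seed = 1) {
  task <- generate_task(spec, seed)
  sims <- purrr::map(c(train = "train", test = "test"), function(sp) {
    part <- task[task$split == sp, ]
    sim <- simulate_annotations(
      profiles, part$x, part$label, part$instance_id,
      class_count = spec$class_count,
      seed = seed + ifelse(sp == "train", 1L, 2L)
    )
    features <- tibble::tibble(instance_id = part$instance_id, f1 = part$x)
    gold <- tibble::tibble(instance_id = part$instance_id, label = part$label)
    list(
      dataset = assemble_dataset(features, sim$annotations, gold = gold,
                                 class_count = spec$class_count),
      reliability = sim$reliability
    )
  })
  structure(
    list(train = sims$train$dataset, test = sims$test$dataset,
         reliability = list(train = sims$train$reliability,
                            test = sims$test$reliability),
         profiles = profiles, spec = spec, seed = seed),
    class = "synthetic_crowd_data"
  )
}

#' Realized accuracy of each simulated annotator
#'
#' @param dataset A `crowd_dataset` with gold labels.
#' @return A tibble `annotator_id, n, accuracy` (accuracy in percent).
#' @export
annotator_accuracy <- function(dataset) {
  stopifnot(inherits(dataset, "crowd_dataset"), !is.null(dataset$gold))
  dataset$annotations |>
    dplyr::left_join(dataset$gold, by = "instance_id",
                     suffix = c("", "_gold")) |>
    dplyr::group_by(.data$annotator_id) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = 100 * mean(.data$label == .data$label_gold),
                     .groups = "drop")
}
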