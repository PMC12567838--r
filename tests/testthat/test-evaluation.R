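test_that("classification report matches hand-computed precision/recall", {
  r <- classification_report(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(r$accuracy, 100)
  expect_equal(r$macro_f1, 100)

  flipped <- classification_report(c(0, 0, 1, 1), c(1, 1, 0, 0), 2)
  expect_equal(flipped$macro_f1, 0)

  # hand-worked: per-class F1 (50, 80, 66.67), macro 65.56
  r <- classification_report(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 2, 0), 3)
  expect_equal(r$per_class_f1, c(50, 80, 200 / 3), tolerance = 1e-10)
  expect_equal(r$macro_f1, mean(c(50, 80, 200 / 3)), tolerance = 1e-10)
  expect_equal(r$accuracy, 100 * 4 / 6)

  expect_error(classification_report(c(0, 3), c(0, 1), 3),
               class = "crowdattn_validation_error")
})

test_that("macro F1 is the mean of per-class F1 and accuracy the trace fraction", {
  set.seed(23)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(10:40, 1)
    yt <- sample(0:(k - 1), n, replace = TRUE)
    yp <- sample(0:(k - 1), n, replace = TRUE)
    r <- classification_report(yt, yp, k)
    expect_equal(r$macro_f1, mean(r$per_class_f1))
    cm <- table(factor(yt, levels = 0:(k - 1)), factor(yp, levels = 0:(k - 1)))
    expect_equal(r$accuracy, 100 * sum(diag(cm)) / n)
  }
})

test_that("reliability recovery thresholds estimates and averages annotator F1", {
  truth <- tibble::tibble(instance_id = sprintf("i%d", 1:4),
                          annotator_id = "a1",
                          reliable = c(1L, 0L, 1L, 0L))
  est_perfect <- dplyr::mutate(truth, score = as.numeric(reliable),
                               reliable = NULL)
  expect_equal(reliability_recovery_f1(est_perfect, truth)$average_f1, 100)

  est <- dplyr::mutate(truth, score = c(0.9, 0.4, 0.6, 0.1), reliable = NULL)
  expect_equal(reliability_recovery_f1(est, truth)$average_f1, 100)

  all_one <- dplyr::mutate(truth, reliable = 1L)
  none <- dplyr::mutate(est, score = 0)
  expect_equal(reliability_recovery_f1(none, all_one)$average_f1, 0)

  # invariance under a strictly monotone transform preserving the 0.5 crossing
  trans <- dplyr::mutate(est, score = plogis(10 * (score - 0.5)))
  expect_equal(reliability_recovery_f1(trans, truth)$average_f1,
               reliability_recovery_f1(est, truth)$average_f1)

  misaligned <- dplyr::mutate(truth, instance_id = paste0("x", instance_id))
  expect_error(reliability_recovery_f1(est, misaligned),
               class = "crowdattn_validation_error")
})

test_that("Friedman statistic matches the rank-sum formula and oracles", {
  same <- matrix(1, nrow = 3, ncol = 4)
  expect_equal(friedman_test(same)$statistic, 0)

  strict <- rbind(c(3, 3, 3), c(2, 2, 2), c(1, 1, 1))
  ft <- friedman_test(strict)
  expect_equal(ft$statistic, 6.0)
  expect_equal(unname(ft$rank_sums), c(3, 6, 9))
  # permuting method rows leaves the statistic unchanged
  expect_equal(friedman_test(strict[c(2, 3, 1), ])$statistic, 6.0)

  expect_error(friedman_test(strict[1:2, ]), class = "crowdattn_validation_error")

  set.seed(41)
  for (rep in 1:15) {
    s <- matrix(sample(1:1000, 24), nrow = 4, ncol = 6)  # no ties
    ours <- friedman_test(s)$statistic
    expect_equal(ours, oracle_friedman(s), tolerance = 1e-9)
    # cross-check against the base-R implementation (tie-free case)
    base_stat <- unname(stats::friedman.test(t(s))$statistic)
    expect_equal(ours, base_stat, tolerance = 1e-9)
  }
})

test_that("sweep sizes follow the capped arithmetic progression", {
  expect_equal(sweep_sizes(57, 4), c(seq(1, 57, by = 4)))
  expect_length(sweep_sizes(57, 4), 15)
  expect_equal(sweep_sizes(5, 4), c(1L, 5L))
  expect_equal(sweep_sizes(6, 4), c(1L, 5L, 6L))
  expect_equal(sweep_sizes(1, 4), 1L)
  expect_error(sweep_sizes(0, 4), class = "crowdattn_validation_error")
})

test_that("the annotator sweep orders by label count, drops uncovered instances", {
  ds <- make_toy_dataset(n = 16, n_annotators = 4, seed = 19)
  # make a3 the most prolific and a1 sparse to force a reordering
  ann <- dplyr::filter(
    ds$annotations,
    !(annotator_id == "a1" & instance_id %in% sprintf("i%02d", 1:12)),
    !(annotator_id == "a2" & instance_id %in% sprintf("i%02d", 1:6))
  )
  train <- assemble_dataset(ds$features, ann, gold = ds$gold, class_count = 3)
  test <- make_toy_dataset(n = 8, n_annotators = 3, seed = 20)
  res <- annotator_sweep(train, test, methods = "mv", step = 4, seeds = 1,
                         net_cfg = tiny_net(),
                         train_cfg = tiny_train(epochs = 5))
  expect_equal(attr(res, "sizes"), c(1L, 4L))
  expect_equal(sort(unique(res$n_annotators)), c(1L, 4L))
  expect_true(all(res$macro_f1 >= 0 & res$macro_f1 <= 100))
  # subset sizes do not depend on the seed or method
  res2 <- annotator_sweep(train, test, methods = "gold", step = 4, seeds = 2,
                          net_cfg = tiny_net(),
                          train_cfg = tiny_train(epochs = 5))
  expect_equal(attr(res2, "sizes"), attr(res, "sizes"))
  expect_s3_class(autoplot(res), "ggplot")
})
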