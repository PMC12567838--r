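test_that("true_label is the argmax of the three sinusoids", {
  # hand-evaluated: f(0.1) ~ (0.588, -0.588, -0.309); f(0.5) = (0, 0, 1.5);
  # f(0.75) = (-1, 1, 0.5)
  expect_equal(true_label(0.1), 0L)
  expect_equal(true_label(0.5), 2L)
  expect_equal(true_label(0.75), 1L)
  expect_error(true_label(1.2), class = "crowdattn_domain_error")
  x <- seq(0, 1, by = 0.001)
  f <- cbind(sin(2 * pi * x), -sin(2 * pi * x), 0.5 - sin(2 * pi * (x + 0.25)))
  expect_equal(true_label(x),
               apply(f, 1, function(r) which(r == max(r))[1]) - 1L)
})

test_that("generate_task draws the right counts, support and is seeded", {
  task <- generate_task(synthetic_task_spec(), seed = 7)
  expect_equal(sum(task$split == "train"), 300)
  expect_equal(sum(task$split == "test"), 200)
  expect_true(all(task$x >= 0 & task$x <= 1))
  expect_identical(task, generate_task(synthetic_task_spec(), seed = 7))
  expect_false(identical(task, generate_task(synthetic_task_spec(), seed = 8)))
  # all three classes occur at n >= 300: every class preimage has
  # positive measure on [0,1]
  expect_true(all(tabulate(task$label + 1L, 3) > 0))
  expect_error(synthetic_task_spec(n_train = 0),
               class = "crowdattn_validation_error")
})

test_that("default profiles are calibrated to the target accuracy vector", {
  profs <- default_profiles()
  expect_length(profs, 5)
  targets <- c(84.66, 59.66, 66.33, 55.66, 27.66)
  measures <- vapply(profs, function(p) p$measure, numeric(1))
  expect_equal(unname(measures), targets / 100, tolerance = 0.005)
  # the adversarial annotator sits below the 1/3 chance level
  expect_lt(profs$a5$measure, 1 / 3)
  n_iv <- vapply(profs, function(p) nrow(p$intervals), integer(1))
  expect_equal(unname(n_iv), c(2L, 3L, 2L, 4L, 1L))
})

test_that("reliability_value uses half-open interval membership", {
  pr <- annotator_profile(tibble::tibble(lower = c(0.1, 0.6),
                                         upper = c(0.3, 0.8)), id = "p")
  expect_equal(reliability_value(pr, c(0.15, 0.1, 0.3, 0.5, 0.8, 0.79)),
               c(1L, 1L, 0L, 0L, 0L, 1L))
  expect_error(reliability_value(pr, -0.1), class = "crowdattn_domain_error")
  expect_error(
    annotator_profile(tibble::tibble(lower = c(0, 0.2), upper = c(0.3, 0.5))),
    class = "crowdattn_validation_error"
  )
})

test_that("simulated labels are gold inside the reliable set and the truth indicator is exact", {
  profs <- default_profiles()
  task <- generate_task(synthetic_task_spec(), seed = 3)
  sim <- simulate_annotations(profs, task$x, task$label, task$instance_id,
                              class_count = 3, seed = 5)
  joined <- dplyr::inner_join(sim$annotations, sim$reliability,
                              by = c("instance_id", "annotator_id"))
  gold <- task$label[match(joined$instance_id, task$instance_id)]
  # indicator <=> correctness, exact for every annotation
  expect_identical(joined$reliable, as.integer(joined$label == gold))
  # inside the reliable set the label is always the gold label
  a1 <- dplyr::filter(joined, annotator_id == "a1")
  x1 <- task$x[match(a1$instance_id, task$instance_id)]
  g1 <- true_label(x1)
  inside <- reliability_value(profs$a1, x1) == 1L
  expect_true(all(a1$label[inside] == g1[inside]))
  # uniform-wrong: outside the reliable set the label is never the gold one
  expect_true(all(a1$label[!inside] != g1[!inside]))
  expect_error(simulate_annotations(list(), task$x, task$label,
                                    task$instance_id),
               class = "crowdattn_validation_error")
})

test_that("Monte-Carlo accuracies at n = 10000 hit the calibration targets", {
  profs <- default_profiles()
  set.seed(99)
  x <- runif(10000)
  y <- true_label(x)
  sim <- simulate_annotations(profs, x, y, sprintf("i%05d", seq_along(x)),
                              class_count = 3, seed = 17)
  acc <- sim$reliability |>
    dplyr::group_by(annotator_id) |>
    dplyr::summarise(acc = 100 * mean(reliable), .groups = "drop")
  targets <- c(a1 = 84.66, a2 = 59.66, a3 = 66.33, a4 = 55.66, a5 = 27.66)
  expect_equal(acc$acc, unname(targets[acc$annotator_id]), tolerance = 1.5 / 50)
  expect_true(all(abs(acc$acc - targets[acc$annotator_id]) <= 1.5))
})

test_that("the full benchmark is deterministic in (spec, profiles, seed)", {
  b1 <- simulate_crowd_benchmark(seed = 21)
  b2 <- simulate_crowd_benchmark(seed = 21)
  expect_equal(b1$train$annotations, b2$train$annotations)
  expect_equal(b1$test$features, b2$test$features)
  expect_equal(b1$reliability, b2$reliability)
  expect_equal(nrow(b1$train$features), 300)
  expect_equal(nrow(b1$test$features), 200)
  expect_equal(nrow(b1$train$annotations), 1500)
})
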