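test_that("majority vote takes the plurality with ties to the lowest class", {
  ann <- tibble::tibble(
    instance_id = c("i1", "i1", "i1", "i2", "i2", "i3"),
    annotator_id = c("a1", "a2", "a3", "a1", "a2", "a1"),
    label = c(1L, 1L, 2L, 0L, 2L, 2L)
  )
  mv <- majority_vote(ann, class_count = 3)
  expect_equal(mv$label[mv$instance_id == "i1"], 1L)
  expect_equal(mv$label[mv$instance_id == "i2"], 0L)  # tie {0,2} -> 0
  expect_equal(mv$label[mv$instance_id == "i3"], 2L)  # single annotator
  expect_error(majority_vote(ann[0, ], 3), class = "crowdattn_validation_error")
})

test_that("majority vote agrees with the argmax of the uniform-score pseudo-label", {
  set.seed(77)
  for (rep in 1:30) {
    k <- sample(2:4, 1)
    labels <- sample(0:(k - 1), sample(c(3, 5, 7), 1), replace = TRUE)
    ann <- tibble::tibble(instance_id = "i1",
                          annotator_id = sprintf("a%d", seq_along(labels)),
                          label = labels)
    mv <- majority_vote(ann, k)$label
    pl <- pseudo_label(rep(1, length(labels)), one_hot(labels, k))
    expect_equal(mv, which(pl == max(pl))[1] - 1L)
  }
})

test_that("Dawid-Skene fixes unanimous labels and follows a single annotator", {
  ann <- tidyr::expand_grid(instance_id = sprintf("i%d", 1:6),
                            annotator_id = sprintf("a%d", 1:3))
  ann$label <- rep(c(0L, 1L, 2L, 0L, 2L, 1L), each = 3)
  fit <- dawid_skene(ann, class_count = 3)
  P <- as.matrix(fit$posteriors[paste0("p_", 0:2)])
  expect_true(all(P[cbind(1:6, c(0, 1, 2, 0, 2, 1) + 1L)] > 0.99))
  expect_equal(fit$posteriors$label, c(0L, 1L, 2L, 0L, 2L, 1L))

  solo <- tibble::tibble(instance_id = sprintf("i%d", 1:5),
                         annotator_id = "a1",
                         label = c(0L, 1L, 1L, 0L, 1L))
  fit1 <- dawid_skene(solo, class_count = 2)
  expect_equal(fit1$posteriors$label, solo$label)
})

test_that("Dawid-Skene matches the brute-force EM oracle on a 4x2x2 toy", {
  ann <- tibble::tibble(
    instance_id = rep(sprintf("i%d", 1:4), each = 2),
    annotator_id = rep(c("a1", "a2"), times = 4),
    label = c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L)
  )
  n_iter <- 25
  fit <- suppressWarnings(
    dawid_skene(ann, class_count = 2, max_iter = n_iter, tol = 0))
  oracle <- oracle_dawid_skene(ann, class_count = 2, n_iter = n_iter)
  P <- as.matrix(fit$posteriors[paste0("p_", 0:1)])
  expect_equal(max(abs(P - oracle$posteriors)), 0, tolerance = 1e-9)
  expect_equal(fit$log_likelihood, oracle$log_likelihood, tolerance = 1e-9)
})

test_that("Dawid-Skene log-likelihood is non-decreasing on random instances", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(5:10, 1)
    w <- sample(2:4, 1)
    k <- sample(2:3, 1)
    ann <- tidyr::expand_grid(instance_id = sprintf("i%d", 1:n),
                              annotator_id = sprintf("a%d", 1:w))
    ann$label <- sample(0:(k - 1), nrow(ann), replace = TRUE)
    fit <- suppressWarnings(dawid_skene(ann, class_count = k, max_iter = 40))
    ll <- fit$log_likelihood
    expect_true(all(diff(ll) >= -1e-9))
  }
})

test_that("fixed-target training is deterministic and MV on a unanimous crowd equals gold", {
  ds <- make_toy_dataset(n = 14, n_annotators = 3, seed = 10)
  m1 <- train_on_targets(ds$features, ds$gold, tiny_net(), tiny_train(seed = 6))
  m2 <- train_on_targets(ds$features, ds$gold, tiny_net(), tiny_train(seed = 6))
  expect_identical(m1$params, m2$params)

  # unanimous crowd at the gold labels: MV targets coincide with gold
  unanimous <- tidyr::expand_grid(instance_id = ds$features$instance_id,
                                  annotator_id = c("a1", "a2", "a3"))
  unanimous$label <- ds$gold$label[match(unanimous$instance_id,
                                         ds$gold$instance_id)]
  ds_u <- assemble_dataset(ds$features, unanimous, gold = ds$gold,
                           class_count = 3)
  mg <- train_gold(ds_u, tiny_net(), tiny_train(seed = 6))
  mm <- train_mv(ds_u, tiny_net(), tiny_train(seed = 6))
  expect_identical(mg$params, mm$params)
})

test_that("soft targets are validated and DS posteriors can train the backbone", {
  ds <- make_toy_dataset(n = 10, n_annotators = 3, seed = 15)
  fit <- suppressWarnings(dawid_skene(ds$annotations, 3))
  m <- train_on_targets(ds$features, fit$posteriors, tiny_net(),
                        tiny_train(seed = 2, epochs = 10), method = "ds")
  expect_s3_class(m, "crowdattn_model")
  bad <- ds$gold
  bad$label <- NULL
  bad$p_0 <- 2
  bad$p_1 <- 0.5
  bad$p_2 <- 0.5
  expect_error(train_on_targets(ds$features, bad, tiny_net(), tiny_train()),
               class = "crowdattn_validation_error")
})
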