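#' Classification network configuration
#'
#' The backbone is a fully connected network: ReLU hidden layers followed
#' by a linear head and a softmax, so every forward pass returns a
#' probability distribution over the `K` classes.
#'
#' @param hidden Integer vector of hidden-layer widths (default `c(512, 256)`).
#' @param class_count Number of classes `K` (>= 2).
#' @return An object of class `network_config`.
#' @export
network_config <- function(hidden = c(512, 256), class_count = 3) {
  class_count <- check_class_count(class_count)
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || any(hidden < 1)) {
    abort("at least one hidden layer with positive width is required",
          class = "crowdattn_validation_error")
  }
  structure(list(hidden = hidden, class_count = class_count),
            class = "network_config")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.005).
#' @param epochs Number of passes over the data (default 500).
#' @param batch_size Mini-batch size; `NULL` (default) trains full-batch,
#'   i.e. every instance in every gradient step.
#' @param seed Integer seed controlling initialization and batch order.
#' @param detach_pseudo_label If `TRUE` (default) the pseudo-label is
#'   treated as a constant target in each step, the standard
#'   pseudo-labelling convention; if `FALSE` the gradient also flows
#'   through the attention scores that build the pseudo-label.
#' @param epsilon Total-score threshold below which pseudo-labelling falls
#'   back to equal annotator weights (default 1e-8).
#' @param verbose Log epoch losses to the message stream.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.005, epochs = 500, batch_size = NULL,
                         seed = 1, detach_pseudo_label = TRUE, epsilon = 1e-8,
                         verbose = FALSE) {
  if (learning_rate <= 0) {
    abort("learning_rate must be positive", class = "crowdattn_validation_error")
  }
  if (epochs < 1) {
    abort("epochs must be >= 1", class = "crowdattn_validation_error")
  }
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
         seed = as.integer(seed),
         detach_pseudo_label = isTRUE(detach_pseudo_label),
         epsilon = epsilon, verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

# N x K matrix of per-class annotation counts, rows aligned with features.
annotation_count_matrix <- function(dataset) {
  ids <- dataset$features$instance_id
  K <- dataset$class_count
  m <- matrix(0, nrow = length(ids), ncol = K, dimnames = list(ids, NULL))
  idx <- cbind(match(dataset$annotations$instance_id, ids),
               dataset$annotations$label + 1L)
  for (r in seq_len(nrow(idx))) m[idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] + 1
  m
}

new_crowdattn_model <- function(params, net_cfg, train_cfg, method,
                                history, input_dim, feature_names) {
  structure(
    list(params = params, net_cfg = net_cfg, train_cfg = train_cfg,
         method = method,
         history = tibble::tibble(epoch = seq_along(history), loss = history),
         input_dim = input_dim, feature_names = feature_names),
    class = "crowdattn_model"
  )
}

#' Train a classifier jointly with annotator reliabilities
#'
#' Trains the backbone directly on the noisy multi-annotator labels: in
#' every epoch the current predictions act as attention queries over the
#' one-hot annotations, giving each annotator an instance-dependent
#' reliability score equal to the predicted probability of the class it
#' chose; the score-weighted, normalized consensus of the annotations is
#' the pseudo-label, and the model descends the mean cross-entropy between
#' its predictions and these pseudo-labels. No gold labels are consumed.
#'
#' @param dataset A `crowd_dataset` (gold labels, if present, are ignored).
#' @param net_cfg A [network_config()]; its `class_count` must match the
#'   dataset.
#' @param train_cfg A [train_config()].
#' @return A `crowdattn_model` with trained parameters and the per-epoch
#'   loss history.
#' @export
train_crowdattention <- function(dataset, net_cfg = network_config(),
                                 train_cfg = train_config()) {
  stopifnot(inherits(dataset, "crowd_dataset"),
            inherits(net_cfg, "network_config"),
            inherits(train_cfg, "train_config"))
  if (net_cfg$class_count != dataset$class_count) {
    abort("network class_count does not match the dataset",
          class = "crowdattn_validation_error")
  }
  X <- feature_matrix(dataset)
  count_mat <- annotation_count_matrix(dataset)
  grad_fn <- function(P, idx) {
    crowd_loss_grad(P, count_mat[idx, , drop = FALSE],
                    detach = train_cfg$detach_pseudo_label,
                    epsilon = train_cfg$epsilon)
  }
  fit <- mlp_train(X, grad_fn, ncol(X), net_cfg, train_cfg)
  new_crowdattn_model(fit$params, net_cfg, train_cfg, "crowdattention",
                      fit$history, ncol(X), colnames(dataset$features)[-1])
}

#' @export
print.crowdattn_model <- function(x, ...) {
  cat(sprintf(
    "<crowdattn_model method=%s> %d -> %s -> %d, %d epochs, final loss %.4f\n",
    x$method, x$input_dim, paste(x$net_cfg$hidden, collapse = "/"),
    x$net_cfg$class_count, nrow(x$history), x$history$loss[nrow(x$history)]
  ))
  invisible(x)
}

#' Predict class distributions for new instances
#'
#' Prediction uses the classification network alone: it depends only on
#' the input features, never on annotations.
#'
#' @param object A `crowdattn_model`.
#' @param newdata A `crowd_dataset`, a data frame with `instance_id` plus
#'   feature columns, or a bare numeric matrix.
#' @param ... Unused.
#' @return A tibble with `instance_id`, probability columns `p_0` ...
#'   `p_{K-1}` and `pred_label` (argmax, ties to the lowest index).
#' @export
predict.crowdattn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "crowd_dataset")) {
    X <- feature_matrix(newdata)
  } else if (is.data.frame(newdata)) {
    stopifnot(names(newdata)[1] == "instance_id")
    X <- as.matrix(newdata[-1])
    rownames(X) <- as.character(newdata$instance_id)
  } else {
    X <- as.matrix(newdata)
    if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  }
  if (ncol(X) != object$input_dim) {
    abort("feature dimension does not match the trained model",
          class = "crowdattn_validation_error")
  }
  if (any(!is.finite(X))) {
    abort("features must be finite", class = "crowdattn_validation_error")
  }
  P <- mlp_forward(object$params, X)$probs
  out <- tibble::as_tibble(P, .name_repair = ~ paste0("p_", seq_along(.x) - 1L))
  dplyr::bind_cols(
    tibble::tibble(instance_id = rownames(X)),
    out,
    tibble::tibble(pred_label = max.col(P, ties.method = "first") - 1L)
  )
}

#' Instance-dependent reliability scores for every annotation
#'
#' For each observed (instance, annotator) pair, the attention score of
#' the trained model: the predicted probability of the class that
#' annotator chose on that instance.
#'
#' @param model A `crowdattn_model`.
#' @param dataset A `crowd_dataset` whose annotations to score.
#' @return A tibble `instance_id, annotator_id, label, score` with scores
#'   in `[0, 1]`.
#' @export
estimate_reliabilities <- function(model, dataset) {
  stopifnot(inherits(model, "crowdattn_model"), inherits(dataset, "crowd_dataset"))
  preds <- predict(model, dataset)
  P <- as.matrix(preds[paste0("p_", seq_len(dataset$class_count) - 1L)])
  rownames(P) <- preds$instance_id
  ann <- dataset$annotations
  score <- P[cbind(match(ann$instance_id, rownames(P)), ann$label + 1L)]
  tibble::tibble(instance_id = ann$instance_id,
                 annotator_id = ann$annotator_id,
                 label = ann$label, score = score)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted model
#' @param x A `crowdattn_model`.
#' @param ... Unused.
#' @return A tibble `epoch, loss`.
#' @exportS3Method generics::tidy
#' @export
tidy.crowdattn_model <- function(x, ...) x$history

#' One-row summary of a fitted model
#' @param x A `crowdattn_model`.
#' @param ... Unused.
#' @return A one-row tibble: method, epochs, final/initial loss, parameter
#'   count.
#' @exportS3Method generics::glance
#' @export
glance.crowdattn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params$W, length, 1L)) + sum(vapply(x$params$b, length, 1L))
  tibble::tibble(
    method = x$method,
    epochs = nrow(x$history),
    initial_loss = x$history$loss[1],
    final_loss = x$history$loss[nrow(x$history)],
    n_parameters = n_par
  )
}

#' Loss-curve plot of a fitted model
#' @param object A `crowdattn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.crowdattn_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "Epoch", y = "Training loss",
                  title = paste0("Training loss (", object$method, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing JSON document holding the network
#' configuration, training configuration, parameters and loss history.
#'
#' @param model A `crowdattn_model`.
#' @param path Output file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns
#'   the restored `crowdattn_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "crowdattn_model"))
  payload <- list(
    method = model$method,
    input_dim = model$input_dim,
    feature_names = model$feature_names,
    net_cfg = unclass(model$net_cfg),
    train_cfg = unclass(model$train_cfg),
    history = model$history,
    W = lapply(model$params$W, function(m) list(dim = dim(m), data = as.numeric(m))),
    b = model$params$b
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- list(
    W = lapply(seq_len(nrow_safe(p$W)), function(i) {
      matrix(p$W$data[[i]], p$W$dim[[i]][1], p$W$dim[[i]][2])
    }),
    b = lapply(p$b, as.numeric)
  )
  tc <- p$train_cfg
  train_cfg <- train_config(tc$learning_rate, tc$epochs, tc$batch_size,
                            tc$seed, tc$detach_pseudo_label, tc$epsilon)
  net_cfg <- network_config(p$net_cfg$hidden, p$net_cfg$class_count)
  new_crowdattn_model(params, net_cfg, train_cfg, p$method,
                      p$history$loss, p$input_dim, p$feature_names)
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
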