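# Internal feed-forward engine: a ReLU MLP with a softmax head, trained by
# Adam. Written on plain matrices; the package's training loops (crowd
# pseudo-labelling and fixed-target baselines) both sit on top of this.

mlp_init <- function(input_dim, hidden, class_count, seed) {
  sizes <- c(input_dim, hidden, class_count)
  local_seed(seed, {
    n_layer <- length(sizes) - 1L
    W <- vector("list", n_layer)
    b <- vector("list", n_layer)
    for (l in seq_len(n_layer)) {
      fan_in <- sizes[l]
      if (l == n_layer) {
        # zero head: initial predictions are exactly uniform, so the first
        # crowd pseudo-label is exactly the soft majority vote (warm start)
        W[[l]] <- matrix(0, fan_in, sizes[l + 1])
        b[[l]] <- rep(0, sizes[l + 1])
      } else {
        lim <- 1 / sqrt(fan_in)
        W[[l]] <- matrix(runif(fan_in * sizes[l + 1], -lim, lim), fan_in, sizes[l + 1])
        b[[l]] <- runif(sizes[l + 1], -lim, lim)
      }
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(params, X, keep_cache = FALSE) {
  n_layer <- length(params$W)
  A <- X
  Zs <- vector("list", n_layer)
  As <- vector("list", n_layer)  # activations entering layer l
  for (l in seq_len(n_layer)) {
    As[[l]] <- A
    Z <- sweep(A %*% params$W[[l]], 2, params$b[[l]], "+")
    Zs[[l]] <- Z
    A <- if (l < n_layer) pmax(Z, 0) else Z
  }
  logits <- A
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  if (keep_cache) list(probs = P, Z = Zs, A = As) else list(probs = P)
}

# Backpropagate a gradient w.r.t. the logits through the cached forward pass.
mlp_backward <- function(params, cache, d_logits) {
  n_layer <- length(params$W)
  dW <- vector("list", n_layer)
  db <- vector("list", n_layer)
  delta <- d_logits
  for (l in rev(seq_len(n_layer))) {
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params$W[[l]])) * (cache$Z[[l - 1]] > 0)
    }
  }
  list(W = dW, b = db)
}

adam_init <- function(params) {
  zeros <- function(p) lapply(p, function(x) x * 0)
  list(mW = zeros(params$W), vW = zeros(params$W),
       mb = zeros(params$b), vb = zeros(params$b), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Batched pseudo-label computation. `count_mat` is the N x K matrix of
# per-class annotation counts; with probs P the attention scores of the
# annotators labelling class k on instance n are all equal to P[n, k], so
# the unnormalized pseudo-label is count_mat * P row-normalized by
# sigma = rowSums(count_mat * P). Rows with sigma <= epsilon fall back to
# equal weights, i.e. the empirical label distribution.
crowd_pseudo_labels <- function(P, count_mat, epsilon = 1e-8) {
  S <- count_mat * P
  sigma <- rowSums(S)
  fallback <- sigma <= epsilon
  Y <- S / pmax(sigma, .Machine$double.xmin)
  if (any(fallback)) {
    emp <- count_mat[fallback, , drop = FALSE]
    Y[fallback, ] <- emp / rowSums(emp)
  }
  list(targets = Y, sigma = sigma, fallback = fallback)
}

# Gradient of the crowd pseudo-label loss w.r.t. the logits for one batch.
# Detached mode treats the pseudo-label as a constant target; attached mode
# additionally differentiates through the attention scores.
crowd_loss_grad <- function(P, count_mat, detach, epsilon) {
  pl <- crowd_pseudo_labels(P, count_mat, epsilon)
  Y <- pl$targets
  n <- nrow(P)
  logP <- log(pmax(P, 1e-12))
  loss <- -mean(rowSums(Y * logP))
  if (detach) {
    d_logits <- (P - Y) / n
  } else {
    # dL/dP has a direct cross-entropy term and an attention term through
    # y~: for annotators of class j, d y~_k / d p_j = m_j(1[k=j] - y~_k)/sigma
    g_direct <- -Y / pmax(P, 1e-12)
    inner <- rowSums(Y * logP)
    g_att <- count_mat * (-logP + inner) / pmax(pl$sigma, .Machine$double.xmin)
    g_att[pl$fallback, ] <- 0
    g <- (g_direct + g_att) / n
    # softmax Jacobian: dZ_i = P_i (g_i - sum_j P_j g_j)
    d_logits <- P * (g - rowSums(P * g))
  }
  list(loss = loss, d_logits = d_logits, targets = Y)
}

# Core optimizer loop shared by every trainer. `grad_fn(P, idx)` returns
# list(loss, d_logits) for the rows `idx` of X.
mlp_train <- function(X, grad_fn, input_dim, net_cfg, train_cfg) {
  params <- mlp_init(input_dim, net_cfg$hidden, net_cfg$class_count,
                     seed = train_cfg$seed)
  state <- adam_init(params)
  n <- nrow(X)
  batch <- train_cfg$batch_size %||% n
  history <- numeric(train_cfg$epochs)
  for (ep in seq_len(train_cfg$epochs)) {
    order_idx <- if (batch >= n) seq_len(n) else
      local_seed(train_cfg$seed + ep, sample.int(n))
    ep_loss <- 0
    for (start in seq(1, n, by = batch)) {
      idx <- order_idx[start:min(start + batch - 1, n)]
      fwd <- mlp_forward(params, X[idx, , drop = FALSE], keep_cache = TRUE)
      g <- grad_fn(fwd$probs, idx)
      grads <- mlp_backward(params, fwd, g$d_logits)
      upd <- adam_step(params, grads, state, lr = train_cfg$learning_rate)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + g$loss * length(idx)
    }
    history[ep] <- ep_loss / n
    if (isTRUE(train_cfg$verbose) && (ep %% 50 == 0 || ep == 1)) {
      message(sprintf("epoch %4d  loss %.6f", ep, history[ep]))
    }
  }
  list(params = params, history = history)
}
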