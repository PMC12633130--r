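# Minimal dense neural-network core: rectified-linear hidden layers, manual
# backpropagation, Adam and SGD optimizers. Powers both the heterogeneous
# variational autoencoder and the multilayer-perceptron baseline; written
# against base R matrix operations, so training is fully reproducible from
# the R RNG seed.

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# He-normal initialization for a stack of dense layers.
# sizes = c(d_in, h1, ..., d_out); returns list(W1, b1, W2, b2, ...).
nn_init <- function(sizes) {
  params <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", i)]] <- matrix(
      stats::rnorm(sizes[i] * sizes[i + 1L], sd = sqrt(2 / sizes[i])),
      sizes[i], sizes[i + 1L])
    params[[paste0("b", i)]] <- numeric(sizes[i + 1L])
  }
  params
}

# Forward pass through L dense layers; relu on all but the last.
# Returns list(out, acts) with acts[[i]] the post-activation of layer i-1
# (acts[[1]] = input).
nn_forward <- function(params, X, n_layers) {
  acts <- vector("list", n_layers + 1L)
  acts[[1]] <- X
  for (i in seq_len(n_layers)) {
    Z <- acts[[i]] %*% params[[paste0("W", i)]] +
      matrix(params[[paste0("b", i)]], nrow(X), ncol = length(params[[paste0("b", i)]]),
             byrow = TRUE)
    acts[[i + 1L]] <- if (i < n_layers) relu(Z) else Z
  }
  list(out = acts[[n_layers + 1L]], acts = acts)
}

# Backward pass given d(out); returns gradients for every W/b and d(input).
nn_backward <- function(params, acts, d_out, n_layers) {
  grads <- list()
  d <- d_out
  for (i in rev(seq_len(n_layers))) {
    grads[[paste0("W", i)]] <- crossprod(acts[[i]], d)
    grads[[paste0("b", i)]] <- colSums(d)
    if (i > 1L) {
      d <- (d %*% t(params[[paste0("W", i)]])) * (acts[[i]] > 0)
    }
  }
  grads
}

# ---- optimizers ------------------------------------------------------------

opt_init <- function(params, solver = c("adam", "sgd")) {
  solver <- match.arg(solver)
  state <- list(solver = solver, t = 0L)
  if (solver == "adam") {
    state$m <- purrr::map(params, ~ .x * 0)
    state$v <- purrr::map(params, ~ .x * 0)
  }
  state
}

opt_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  if (state$solver == "adam") {
    for (nm in names(params)) {
      g <- grads[[nm]]
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]] / (1 - beta1^state$t)
      vhat <- state$v[[nm]] / (1 - beta2^state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  } else {
    for (nm in names(params)) {
      params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    }
  }
  list(params = params, state = state)
}

# ---- multilayer perceptron -------------------------------------------------

# Fit an MLP classifier (softmax + weighted cross-entropy over `classes`)
# or regressor (weighted MSE). X must be a complete numeric matrix
# (impute first); y is a label vector or numeric vector. Deterministic
# given the seed.
mlp_fit <- function(X, y, task = c("classification", "regression"),
                    classes = NULL, hidden = c(50, 50), solver = "adam",
                    lr = 0.001, epochs = 200, batch_size = 200,
                    weights = NULL, l2 = 1e-4, seed = 1) {
  task <- match.arg(task)
  stopifnot(!anyNA(X))
  n <- nrow(X)
  weights <- weights %||% rep(1, n)
  with_seed(seed, {
    if (task == "classification") {
      classes <- classes %||% sort(unique(y))
      Y <- outer(y, classes, `==`) * 1
      out_dim <- length(classes)
    } else {
      Y <- matrix(y, ncol = 1)
      out_dim <- 1L
    }
    sizes <- c(ncol(X), hidden, out_dim)
    n_layers <- length(sizes) - 1L
    params <- nn_init(sizes)
    state <- opt_init(params, solver)
    bs <- min(batch_size, n)

    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        wb <- weights[idx]
        fw <- nn_forward(params, Xb, n_layers)
        if (task == "classification") {
          P <- softmax_rows(fw$out)
          d_out <- (P - Yb) * wb / sum(wb)
        } else {
          d_out <- 2 * (fw$out - Yb) * wb / sum(wb)
        }
        grads <- nn_backward(params, fw$acts, d_out, n_layers)
        if (l2 > 0) {
          for (i in seq_len(n_layers)) {
            nm <- paste0("W", i)
            grads[[nm]] <- grads[[nm]] + l2 * params[[nm]]
          }
        }
        upd <- opt_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
    }
    structure(list(params = params, n_layers = n_layers, task = task,
                   classes = classes),
              class = "twin_mlp")
  })
}

mlp_predict <- function(model, X, type = c("response", "prob", "class")) {
  type <- match.arg(type)
  out <- nn_forward(model$params, X, model$n_layers)$out
  if (model$task == "regression") return(as.numeric(out))
  P <- softmax_rows(out)
  colnames(P) <- model$classes
  switch(type,
         prob = P,
         class = model$classes[max.col(P, ties.method = "first")],
         response = P)
}
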