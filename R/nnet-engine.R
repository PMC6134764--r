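# Minimal seeded feed-forward network engine shared by the autoencoder and
# the three-hidden-layer classifier. Dense layers, tanh / rectifier /
# linear activations, softmax + cross-entropy or linear + MSE heads,
# inverted dropout, L1/L2 penalties, Adam updates. Everything runs through
# base matrix products so training is deterministic for a fixed seed on a
# single thread.

mlp_activate <- function(z, activation) {
  switch(activation,
         tanh = tanh(z),
         rectifier = pmax(z, 0),
         linear = z,
         abort(sprintf("Unknown activation '%s'.", activation)))
}

mlp_activate_grad <- function(a, activation) {
  switch(activation,
         tanh = 1 - a^2,
         rectifier = (a > 0) * 1,
         linear = array(1, dim(a)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(layer_sizes, seed) {
  with_seed(seed, {
    n_layers <- length(layer_sizes) - 1
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      n_in <- layer_sizes[l]
      n_out <- layer_sizes[l + 1]
      lim <- sqrt(6 / (n_in + n_out))
      W[[l]] <- matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
      b[[l]] <- rep(0, n_out)
    }
    list(W = W, b = b, layer_sizes = layer_sizes)
  })
}

# forward pass; returns activations of every layer (a[[1]] is the input,
# possibly dropout-masked). dropout = list(input = rate, hidden = rates)
mlp_forward <- function(net, X, activation, output = c("linear", "softmax"),
                        dropout = NULL, training = FALSE) {
  output <- match.arg(output)
  n_layers <- length(net$W)
  a <- vector("list", n_layers + 1)
  if (training && !is.null(dropout) && dropout$input > 0) {
    keep <- 1 - dropout$input
    mask <- matrix(runif(length(X)) < keep, nrow(X), ncol(X)) / keep
    a[[1]] <- X * mask
  } else {
    a[[1]] <- X
  }
  for (l in seq_len(n_layers)) {
    z <- sweep(a[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < n_layers) {
      h <- mlp_activate(z, activation)
      rate <- if (!is.null(dropout)) dropout$hidden[l] else 0
      if (training && !is.na(rate) && rate > 0) {
        keep <- 1 - rate
        mask <- matrix(runif(length(h)) < keep, nrow(h), ncol(h)) / keep
        h <- h * mask
      }
      a[[l + 1]] <- h
    } else {
      a[[l + 1]] <- if (output == "softmax") softmax_rows(z) else z
    }
  }
  a
}

mlp_loss <- function(net, X, Y, activation, output, loss) {
  a <- mlp_forward(net, X, activation, output, training = FALSE)
  yhat <- a[[length(a)]]
  if (loss == "mse") {
    mean((yhat - Y)^2)
  } else {
    -mean(log(pmax(rowSums(yhat * Y), 1e-12)))
  }
}

# one Adam step on a minibatch; returns updated net + optimizer state
mlp_step <- function(net, state, X, Y, activation, output, loss,
                     lr, l1, l2, dropout, t_step) {
  n_layers <- length(net$W)
  a <- mlp_forward(net, X, activation, output, dropout = dropout,
                   training = TRUE)
  yhat <- a[[n_layers + 1]]
  n <- nrow(X)
  delta <- if (loss == "mse") {
    2 * (yhat - Y) / (n * ncol(Y))
  } else {
    (yhat - Y) / n  # softmax + cross-entropy
  }
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (l in rev(seq_len(n_layers))) {
    W_old <- net$W[[l]]
    gW <- crossprod(a[[l]], delta) + 2 * l2 * net$W[[l]] +
      l1 * sign(net$W[[l]])
    gb <- colSums(delta)
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * gW
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * gW^2
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * gb
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * gb^2
    corr1 <- 1 - beta1^t_step
    corr2 <- 1 - beta2^t_step
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / corr1) /
      (sqrt(state$vW[[l]] / corr2) + eps)
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / corr1) /
      (sqrt(state$vb[[l]] / corr2) + eps)
    if (l > 1) {
      delta <- (delta %*% t(W_old)) * mlp_activate_grad(a[[l]], activation)
    }
  }
  list(net = net, state = state)
}

mlp_train <- function(layer_sizes, X, Y, activation = "tanh",
                      output = c("linear", "softmax"),
                      loss = c("mse", "xent"), epochs = 10,
                      batch_size = 32, lr = 1e-3, l1 = 0, l2 = 0,
                      input_dropout = 0, hidden_dropout = NULL, seed = 1) {
  output <- match.arg(output)
  loss <- match.arg(loss)
  n_hidden <- length(layer_sizes) - 2
  hidden_dropout <- hidden_dropout %||% rep(0, n_hidden)
  dropout <- list(input = input_dropout, hidden = hidden_dropout)
  net <- mlp_init(layer_sizes, seed = derive_seed(seed, "init"))
  zeros <- function(x) lapply(x, function(w) w * 0)
  state <- list(mW = zeros(net$W), vW = zeros(net$W),
                mb = zeros(net$b), vb = zeros(net$b))
  n <- nrow(X)
  loss_history <- numeric(epochs + 1)
  loss_history[1] <- mlp_loss(net, X, Y, activation, output, loss)
  t_step <- 0
  with_seed(derive_seed(seed, "train"), {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        t_step <- t_step + 1
        upd <- mlp_step(net, state, X[idx, , drop = FALSE],
                        Y[idx, , drop = FALSE], activation, output, loss,
                        lr, l1, l2, dropout, t_step)
        net <- upd$net
        state <- upd$state
      }
      loss_history[epoch + 1] <- mlp_loss(net, X, Y, activation, output,
                                          loss)
    }
  })
  net$activation <- activation
  net$output <- output
  net$loss_history <- loss_history
  net
}

mlp_predict <- function(net, X, output = net$output) {
  a <- mlp_forward(net, X, net$activation, output, training = FALSE)
  a[[length(a)]]
}
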