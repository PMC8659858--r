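# Small fully-connected regression network, trained with Adam.
#
# Architecture and training follow the package's ANN learner configuration:
# two hidden layers (default 50 units each) with relu activation, a single
# relu output unit, mean-squared-error loss, full-batch Adam, and early
# stopping on a held-out validation split (patience in epochs without
# improvement; best weights restored). The output bias is initialized at
# mean(y) so the relu output unit starts active on positive responses.

mlp_init <- function(p, hidden, y_mean, seed) {
  sizes <- c(p, hidden, 1L)
  with_seed(seed, {
    W <- lapply(seq_len(length(sizes) - 1L), function(l) {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
             nrow = sizes[l])
    })
    b <- lapply(seq_len(length(sizes) - 1L), function(l) rep(0, sizes[l + 1L]))
    b[[length(b)]] <- y_mean
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% par$W[[l]]
    z <- sweep(z, 2, par$b[[l]], "+")
    acts[[l + 1L]] <- pmax(z, 0)      # relu on hidden and output layers
  }
  acts
}

mlp_fit <- function(X, y, hidden = c(50L, 50L), learning_rate = 0.01,
                    max_epochs = 1000L, patience = 20L, val_frac = 0.1,
                    seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2)
  n_val <- max(1L, round(val_frac * n))
  idx <- with_seed(child_seed(seed, 1L), sample.int(n))
  vi <- idx[seq_len(n_val)]; ti <- idx[-seq_len(n_val)]
  if (length(ti) == 0L) { ti <- vi }
  Xt <- X[ti, , drop = FALSE]; yt <- y[ti]
  Xv <- X[vi, , drop = FALSE]; yv <- y[vi]

  par <- mlp_init(p, hidden, mean(y), child_seed(seed, 2L))
  L <- length(par$W)
  m <- lapply(par$W, function(w) w * 0); v <- m
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- par; best_val <- Inf; stall <- 0L; t <- 0L

  for (epoch in seq_len(max_epochs)) {
    acts <- mlp_forward(par, Xt)
    pred <- acts[[L + 1L]][, 1L]
    # backprop of MSE through the relu stack
    delta <- matrix(2 * (pred - yt) / length(yt), ncol = 1L) *
      (acts[[L + 1L]] > 0)
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      gW[[l]] <- crossprod(acts[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(par$W[[l]])) * (acts[[l]] > 0)
    }
    t <- t + 1L
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    for (l in seq_len(L)) {
      m[[l]] <- beta1 * m[[l]] + (1 - beta1) * gW[[l]]
      v[[l]] <- beta2 * v[[l]] + (1 - beta2) * gW[[l]]^2
      par$W[[l]] <- par$W[[l]] - learning_rate * (m[[l]] / c1) /
        (sqrt(v[[l]] / c2) + eps)
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      par$b[[l]] <- par$b[[l]] - learning_rate * (mb[[l]] / c1) /
        (sqrt(vb[[l]] / c2) + eps)
    }
    val_pred <- mlp_forward(par, Xv)[[L + 1L]][, 1L]
    val_loss <- mean((val_pred - yv)^2)
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best <- par; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  list(par = best, hidden = hidden, epochs = epoch, val_loss = best_val)
}

mlp_predict <- function(fit, X) {
  acts <- mlp_forward(fit$par, as.matrix(X))
  acts[[length(acts)]][, 1L]
}
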