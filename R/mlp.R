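# Minimal feed-forward regression network (ReLU hidden layers, linear
# output) trained with Adam and inverted dropout. Written in plain matrix
# algebra: the defensive-influence approximator needs exactly one small MLP
# and nothing on CRAN in this stack provides a multi-hidden-layer regressor
# with dropout, so the ~100 lines live here. All randomness goes through R's
# RNG, so training is reproducible under a seed.

mlp_new <- function(sizes, seed = 1) {
  with_seed(seed, {
    L <- length(sizes) - 1
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      # He initialization for ReLU layers
      sdl <- sqrt(2 / sizes[l])
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sdl),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    list(sizes = sizes, W = W, b = b)
  })
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- X
  for (l in seq_len(L - 1)) {
    A <- pmax(sweep(A %*% net$W[[l]], 2, net$b[[l]], `+`), 0)
  }
  drop(sweep(A %*% net$W[[L]], 2, net$b[[L]], `+`))
}

mlp_train <- function(net, X, y, epochs = 50, batch = 256, lr = 1e-3,
                      dropout = 0.1, seed = 1, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, verbose = FALSE) {
  n <- nrow(X)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  step <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = batch)) {
        ix <- ord[s:min(s + batch - 1, n)]
        Xb <- X[ix, , drop = FALSE]
        yb <- y[ix]
        m <- length(ix)
        step <- step + 1L
        # forward with inverted dropout on hidden activations
        A <- vector("list", L + 1)
        M <- vector("list", L)
        A[[1]] <- Xb
        for (l in seq_len(L - 1)) {
          h <- pmax(sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`), 0)
          if (dropout > 0) {
            M[[l]] <- matrix(stats::rbinom(length(h), 1, 1 - dropout),
                             nrow(h), ncol(h)) / (1 - dropout)
            h <- h * M[[l]]
          }
          A[[l + 1]] <- h
        }
        pred <- drop(sweep(A[[L]] %*% net$W[[L]], 2, net$b[[L]], `+`))
        # backward (MSE loss)
        delta <- matrix(2 * (pred - yb) / m, ncol = 1)
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(net$W[[l]])
            delta <- delta * (A[[l]] > 0)
            if (dropout > 0 && !is.null(M[[l - 1]])) delta <- delta * M[[l - 1]]
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^step)
          vhW <- vW[[l]] / (1 - beta2^step)
          mhb <- mb[[l]] / (1 - beta1^step)
          vhb <- vb[[l]] / (1 - beta2^step)
          net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
        if (!all(is.finite(net$W[[L]]))) {
          stop("training error: non-finite loss/weights at epoch ", ep)
        }
      }
      if (verbose && ep %% 10 == 0) {
        cat(sprintf("epoch %d: mse %.5f\n", ep,
                    mean((mlp_forward(net, X) - y)^2)))
      }
    }
  })
  net
}
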