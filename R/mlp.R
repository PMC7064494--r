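# Compact multilayer perceptron for binary classification: ReLU hidden
# layers, logistic output, cross-entropy loss with L2 weight decay, trained
# full-batch with Adam from a seeded He initialization. Problem sizes here
# are tiny (~10^2 samples, ~15 inputs), so plain matrix ops suffice.

mlp_fit <- function(X, y, hidden = c(30L, 30L, 30L, 10L), l2 = 1e-4,
                    epochs = 500L, lr = 1e-3, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1L]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))

    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    n <- nrow(X)

    for (t in seq_len(epochs)) {
      # forward
      a <- vector("list", L + 1L)
      a[[1L]] <- X
      for (l in seq_len(L)) {
        z <- sweep(a[[l]] %*% W[[l]], 2L, b[[l]], "+")
        a[[l + 1L]] <- if (l < L) pmax(z, 0) else plogis(z)
      }
      p <- a[[L + 1L]][, 1L]
      # backward (cross-entropy + logistic output cancels to p - y)
      delta <- matrix((p - y) / n, n, 1L)
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(a[[l]], delta) + 2 * l2 * W[[l]]
        gb[[l]] <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      }
      # Adam update
      c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
      }
    }
    structure(list(W = W, b = b, sizes = sizes), class = "blastometry_mlp")
  })
}

mlp_predict <- function(model, X) {
  X <- as.matrix(X)
  L <- length(model$W)
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$W[[l]], 2L, model$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else plogis(z)
  }
  a[, 1L]
}
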