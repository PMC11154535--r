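# Small fully-connected classifier with two hidden layers (tanh) and a
# softmax output, trained full-batch with Adam. Used only as a baseline in
# baseline_compare(); inputs are expected already standardized.

mlp_fit <- function(x, y, hidden = c(20L, 20L), epochs = 300L, lr = 0.01,
                    seed = 1L) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2L)
  yy <- match(y, classes) - 1L               # 0/1
  n <- nrow(x); p <- ncol(x)
  sizes <- c(p, hidden, 2L)
  with_local_seed(seed, {
    W <- lapply(seq_len(length(sizes) - 1L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1L]))
    b <- lapply(sizes[-1L], function(k) rep(0, k))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(bb) bb * 0); vb <- mb
    onehot <- cbind(1 - yy, yy)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    for (ep in seq_len(epochs)) {
      # forward
      a <- list(x)
      for (l in seq_along(W)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], `+`)
        a[[l + 1L]] <- if (l < length(W)) tanh(z) else z
      }
      zo <- a[[length(a)]]
      zo <- zo - apply(zo, 1, max)
      pr <- exp(zo); pr <- pr / rowSums(pr)
      # backward
      delta <- (pr - onehot) / n
      for (l in rev(seq_along(W))) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) delta <- (delta %*% t(W[[l]])) * (1 - a[[l]]^2)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cw <- 1 - beta1^ep; cv <- 1 - beta2^ep
        W[[l]] <- W[[l]] - lr * (mW[[l]] / cw) / (sqrt(vW[[l]] / cv) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / cw) / (sqrt(vb[[l]] / cv) + eps)
      }
    }
    structure(list(W = W, b = b, classes = classes), class = "cagemon_mlp")
  })
}

mlp_predict <- function(model, x) {
  a <- as.matrix(x)
  nl <- length(model$W)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], `+`)
    a <- if (l < nl) tanh(z) else z
  }
  model$classes[max.col(a, ties.method = "first")]
}
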