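# Minimal multilayer perceptron (dense, ELU hidden units, inverted dropout,
# Adam, MSE loss). Deliberately self-contained: the regressor is small
# enough that base-R matrix algebra trains it in seconds, and keeping it in
# the package makes the simulation-based inference fully reproducible from
# a single RNG seed.

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(a) ifelse(a > 0, 1, a + 1)  # a = elu(x)

mlp_init <- function(dims) {
  # He initialization scaled for ELU
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                  sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b, dims = dims)
}

mlp_forward <- function(net, X, dropout = 0, train = FALSE) {
  L <- length(net$W)
  A <- list(X)                        # layer inputs (post-dropout)
  H_raw <- vector("list", L)          # post-ELU, pre-dropout activations
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`)
    if (l < L) {
      H <- elu(Z)
      H_raw[[l]] <- H
      if (train && dropout > 0) {
        keep <- 1 - dropout
        mask <- matrix(stats::runif(length(H)) < keep, nrow(H), ncol(H)) / keep
        H <- H * mask
        masks[[l]] <- mask
      }
      A[[l + 1]] <- H
    } else A[[l + 1]] <- Z             # linear output
  }
  list(A = A, H_raw = H_raw, masks = masks)
}

mlp_backward <- function(net, fwd, Y) {
  L <- length(net$W)
  n <- nrow(Y)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- 2 * (fwd$A[[L + 1]] - Y) / (n * ncol(Y))   # MSE gradient
  for (l in L:1) {
    gW[[l]] <- crossprod(fwd$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(net$W[[l]])
      if (!is.null(fwd$masks[[l - 1]])) delta <- delta * fwd$masks[[l - 1]]
      delta <- delta * elu_grad(fwd$H_raw[[l - 1]])
    }
  }
  list(W = gW, b = gb)
}

mlp_train <- function(X, Y, hidden = c(132, 64, 32), dropout = 0.5,
                      val = NULL, epochs = 400, batch = 128, lr = 1e-3,
                      patience = 20, seed = 1L, verbose = FALSE) {
  set.seed(seed)
  dims <- c(ncol(X), hidden, ncol(Y))
  net <- mlp_init(dims)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(bb) bb * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_adam <- 0
  n <- nrow(X)
  history <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  best <- list(loss = Inf, net = net, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      rows <- idx[start:min(start + batch - 1, n)]
      fwd <- mlp_forward(net, X[rows, , drop = FALSE], dropout, train = TRUE)
      grad <- mlp_backward(net, fwd, Y[rows, , drop = FALSE])
      t_adam <- t_adam + 1
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * grad$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * grad$W[[l]]^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * grad$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * grad$b[[l]]^2
        mhW <- mW[[l]] / (1 - b1^t_adam); vhW <- vW[[l]] / (1 - b2^t_adam)
        mhb <- mb[[l]] / (1 - b1^t_adam); vhb <- vb[[l]] / (1 - b2^t_adam)
        net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    tr_loss <- mean((mlp_forward(net, X)$A[[L + 1]] - Y)^2)
    vl_loss <- if (!is.null(val))
      mean((mlp_forward(net, val$X)$A[[L + 1]] - val$Y)^2) else tr_loss
    history <- rbind(history, data.frame(epoch = ep, train = tr_loss, val = vl_loss))
    if (!is.finite(tr_loss)) stop2("non-finite training loss at epoch ", ep)
    if (vl_loss < best$loss - 1e-7) {
      best <- list(loss = vl_loss, net = net, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
    if (verbose && ep %% 20 == 0)
      ed_log(sprintf("mlp epoch %d: train %.5f val %.5f", ep, tr_loss, vl_loss))
  }
  list(net = best$net, history = history, best_epoch = best$epoch,
       dropout = dropout)
}

mlp_predict <- function(model, X) {
  net <- model$net %||% model
  mlp_forward(net, X)$A[[length(net$W) + 1]]
}
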