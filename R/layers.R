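## Internal layer primitives operating on (B*W*H) x C activation
## matrices (pixel index p = b*W*H + x*H + y).  Conv units follow the
## atomic block used throughout the architecture: 3x3 convolution
## (stride 1, same padding) -> batch normalization -> ReLU.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

unit_init <- function(Cin, Cout) {
  ## He initialization for ReLU conv units, fan-in = 9 * Cin.
  list(
    W = matrix(rnorm(9 * Cin * Cout, sd = sqrt(2 / (9 * Cin))), 9 * Cin, Cout),
    b = numeric(Cout),
    gamma = rep(1, Cout),
    beta = numeric(Cout),
    rmean = numeric(Cout),
    rvar = rep(1, Cout)
  )
}

col_broadcast <- function(v, n) rep(v, each = n)

unit_forward <- function(p, X, H, W, B, training = FALSE, pad = 0L,
                         keep_cache = FALSE) {
  Z <- .cpp_conv3x3_forward(X, p$W, p$b, H, W, B, pad)
  if (training) {
    mu <- colMeans(Z)
    va <- colMeans(Z * Z) - mu^2
    va[va < 0] <- 0
  } else {
    mu <- p$rmean
    va <- p$rvar
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  bn <- .cpp_bn_act_forward(Z, mu, invstd, p$gamma, p$beta)
  cache <- if (keep_cache) list(X = X, xhat = bn$xhat, invstd = invstd,
                                Y = bn$Y, H = H, W = W, B = B, pad = pad)
  stats <- if (training) list(mu = mu, va = va)
  list(Y = bn$Y, cache = cache, stats = stats)
}

unit_backward <- function(p, cache, dY) {
  bn <- .cpp_bn_act_backward(dY, cache$Y, cache$xhat, p$gamma, cache$invstd)
  cb <- .cpp_conv3x3_backward(cache$X, p$W, bn$dZ, cache$H, cache$W, cache$B,
                              cache$pad)
  list(dX = cb$dX,
       grads = list(W = cb$dW, b = as.numeric(cb$db),
                    gamma = as.numeric(bn$dgamma),
                    beta = as.numeric(bn$dbeta)))
}

## Merge freshly computed batch statistics into the running BN buffers.
update_bn_stats <- function(net, stats, momentum = BN_MOMENTUM) {
  for (nm in names(stats)) {
    net$params[[nm]]$rmean <- momentum * net$params[[nm]]$rmean +
      (1 - momentum) * stats[[nm]]$mu
    net$params[[nm]]$rvar <- momentum * net$params[[nm]]$rvar +
      (1 - momentum) * stats[[nm]]$va
  }
  net
}

dropout_forward <- function(X, rate) {
  mask <- (matrix(runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

softmax_rows <- function(Z) {
  mx <- Z[, 1L]
  for (j in 2:ncol(Z)) mx <- pmax(mx, Z[, j])
  E <- exp(Z - mx)
  E / rowSums(E)
}

## dL/dlogits from dL/dP through the softmax Jacobian.
softmax_backward <- function(P, dP) {
  P * (dP - rowSums(P * dP))
}

## ---- Adam ---------------------------------------------------------------

TRAINABLE_KEYS <- c("W", "b", "gamma", "beta")

adam_init <- function(params) {
  st <- list(t = 0L)
  for (nm in names(params)) {
    for (k in intersect(TRAINABLE_KEYS, names(params[[nm]]))) {
      key <- paste0(nm, ".", k)
      st[[key]] <- list(m = params[[nm]][[k]] * 0, v = params[[nm]][[k]] * 0)
    }
  }
  st
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (k in names(grads[[nm]])) {
      key <- paste0(nm, ".", k)
      g <- grads[[nm]][[k]]
      s <- state[[key]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      state[[key]] <- s
      params[[nm]][[k]] <- params[[nm]][[k]] -
        lr * (s$m / c1) / (sqrt(s$v / c2) + eps)
    }
  }
  list(params = params, state = state)
}

accumulate_grads <- function(acc, nm, g) {
  if (is.null(acc[[nm]])) {
    acc[[nm]] <- g
  } else {
    for (k in names(g)) acc[[nm]][[k]] <- acc[[nm]][[k]] + g[[k]]
  }
  acc
}
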