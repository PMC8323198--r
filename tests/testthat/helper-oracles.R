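# Independent naive implementations used as oracles.  All are written
# as literal per-pixel double loops over the defining formulas, kept
# deliberately separate from the vectorized package code paths.

REGION_LABELS <- list(
  background = 0L, complete = c(1L, 2L, 3L, 4L), core = c(1L, 3L, 4L),
  enhancing = 4L
)

naive_ce <- function(P, G, clip = 1e-7) {
  acc <- 0
  for (i in seq_len(nrow(P))) {
    for (k in seq_len(ncol(P))) {
      p <- min(max(P[i, k], clip), 1 - clip)
      acc <- acc + G[i, k] * log(p)
    }
  }
  -acc / nrow(P)
}

naive_dice_channel <- function(p, g, eps = 1e-5) {
  num <- 0; sp <- 0; sg <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * g[i]
    sp <- sp + p[i]
    sg <- sg + g[i]
  }
  1 - (2 * num + eps) / (sp + sg + eps)
}

naive_region_channel <- function(M, labels) {
  out <- numeric(nrow(M))
  for (i in seq_len(nrow(M))) {
    for (k in labels) out[i] <- out[i] + M[i, k + 1L]
  }
  out
}

naive_dice_class <- function(P, G, k, eps = 1e-5) {
  naive_dice_channel(P[, k + 1L], G[, k + 1L], eps)
}

naive_dice_region <- function(P, G, region, eps = 1e-5) {
  lab <- REGION_LABELS[[region]]
  naive_dice_channel(naive_region_channel(P, lab),
                     naive_region_channel(G, lab), eps)
}

naive_combined_dice <- function(P, G, eps = 1e-5) {
  naive_dice_region(P, G, "background", eps) +
    naive_dice_region(P, G, "complete", eps) +
    naive_dice_region(P, G, "core", eps) +
    naive_dice_region(P, G, "enhancing", eps)
}

naive_sliced_dice <- function(P, G, eps = 1e-5) {
  acc <- 0
  for (k in 0:4) acc <- acc + naive_dice_class(P, G, k, eps)
  acc
}

naive_recall_channel <- function(p, g, eps = 1e-5) {
  num <- 0; sg <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * g[i]
    sg <- sg + g[i]
  }
  1 - (num + eps) / (sg + eps)
}

naive_recall <- function(P, G, target, eps = 1e-5) {
  if (is.numeric(target)) {
    naive_recall_channel(P[, target + 1L], G[, target + 1L], eps)
  } else {
    lab <- REGION_LABELS[[target]]
    naive_recall_channel(naive_region_channel(P, lab),
                         naive_region_channel(G, lab), eps)
  }
}

naive_hl1 <- function(P, G, w = c(20, 0.5, 1, 0.5)) {
  w[1] * naive_ce(P, G) + w[2] * naive_recall(P, G, "complete") +
    w[3] * naive_recall(P, G, "core") + w[4] * naive_recall(P, G, "enhancing")
}

naive_hl2 <- function(P, G, w = c(1, 0.1, 1.3, 0.5)) {
  w[1] * naive_combined_dice(P, G) + w[2] * naive_recall(P, G, "complete") +
    w[3] * naive_recall(P, G, "core") + w[4] * naive_recall(P, G, "enhancing")
}

# Random softmax-like probability matrix and matching one-hot truth.
random_prob_pair <- function(n, K = 5L, kind = c("random", "onehot",
                                                 "uniform", "empty_region")) {
  kind <- match.arg(kind)
  G <- matrix(0, n, K)
  lab <- switch(kind,
    empty_region = sample(c(0L, 2L), n, replace = TRUE),  # no core/enh at all
    sample(0:(K - 1L), n, replace = TRUE)
  )
  G[cbind(seq_len(n), lab + 1L)] <- 1
  P <- switch(kind,
    onehot = G,
    uniform = matrix(1 / K, n, K),
    {
      Z <- matrix(rexp(n * K), n, K)
      Z / rowSums(Z)
    }
  )
  list(P = P, G = G, labels = lab)
}

# Small phantom settings for fast training tests.
tiny_phantom_params <- function(shape = c(32L, 32L, 12L)) {
  phantom_params(volume_shape = shape, tumor_probability = 1,
                 edema_radius_frac = c(0.2, 0.3))
}

tiny_net_config <- function(input_size = 16L) {
  net_config(input_size = input_size,
             stage_channels = c(2L, 3L, 4L, 5L, 6L), fusing_channels = 4L,
             dropout = 0)
}
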