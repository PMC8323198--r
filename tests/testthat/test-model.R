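test_that("conv-unit parameter accounting matches layer arithmetic", {
  set.seed(1)
  u <- msffn:::unit_init(4L, 16L)
  # a 3 x 3 convolution 4 -> 16 with bias
  expect_equal(length(u$W) + length(u$b), 4 * 16 * 9 + 16)
  # batch norm: scale, shift and both moving statistics, 4 per channel
  expect_equal(length(u$gamma) + length(u$beta) + length(u$rmean) +
                 length(u$rvar), 4 * 16)
})

test_that("the default architecture reproduces the published model size", {
  # independent layer-by-layer arithmetic oracle, written out explicitly
  conv_params <- function(cin, cout) cin * cout * 9 + cout + 4 * cout
  sc <- c(16, 32, 64, 128, 256)
  su <- c(4, 2, 2, 2, 2)
  expected <- 0
  cin <- 4
  for (s in 1:5) for (u in seq_len(su[s])) {
    expected <- expected + conv_params(cin, sc[s])
    cin <- sc[s]
  }
  cat_ch <- 4 * sc[1] + sum(sc[2:5])
  expect_equal(cat_ch, 544)
  expected <- expected + conv_params(cat_ch, 64) + conv_params(64, 64) +
    conv_params(64, 64) + (64 * 5 + 5)

  net <- msffn_net(net_config())
  pc <- count_parameters(net)
  expect_equal(pc$count, expected)
  expect_equal(pc$bytes, 4L * expected)
  expect_equal(param_size_mb(net), 6.3)

  # twelve convolution layers in the extraction network
  n_fen <- sum(grepl("^fen_", names(net$params)))
  expect_equal(n_fen, 12)
  # three conv units in the fusing block
  expect_equal(sum(grepl("^fuse_", names(net$params))), 3)
})

test_that("tap resolutions follow the four-pooling pyramid", {
  net176 <- msffn_net(net_config(), seed = 2)
  img <- array(rnorm(176 * 176 * 4), dim = c(176, 176, 4))
  taps <- fen_taps(net176, img)
  expect_length(taps, 8)
  sizes <- vapply(taps, function(t) dim(t)[1], numeric(1))
  expect_equal(sizes, c(176, 176, 176, 176, 88, 44, 22, 11))
  chans <- vapply(taps, function(t) dim(t)[3], numeric(1))
  expect_equal(chans, c(16, 16, 16, 16, 32, 64, 128, 256))

  net64 <- msffn_net(net_config(input_size = 64L), seed = 2)
  img64 <- array(rnorm(64 * 64 * 4), dim = c(64, 64, 4))
  t64 <- fen_taps(net64, img64)
  expect_equal(vapply(t64, function(t) dim(t)[1], numeric(1)),
               c(64, 64, 64, 64, 32, 16, 8, 4))
})

test_that("the fused head emits normalized probabilities deterministically", {
  cfg <- net_config(input_size = 32L)
  net <- msffn_net(cfg, seed = 3)
  S <- 32L; B <- 2L
  X <- matrix(rnorm(B * S * S * 4), B * S * S, 4)
  f1 <- msffn:::net_forward(net, X, S, S, B)
  expect_identical(dim(f1$P), c(B * S * S, 5L))
  expect_lt(max(abs(rowSums(f1$P) - 1)), 1e-5)
  # evaluation mode is deterministic: identical input, identical output
  f2 <- msffn:::net_forward(net, X, S, S, B)
  expect_identical(f1$P, f2$P)

  probs <- predict_probs(net, array(X[1:(S * S), ], dim = c(S, S, 4)))
  expect_identical(dim(probs), c(S, S, 5L))
  expect_error(predict_probs(net, array(0, dim = c(30, 30, 4))), "divisible")
  expect_error(net_config(input_size = 100L), "divisible")
})

test_that("every tap contributes to the output", {
  cfg <- net_config(input_size = 32L)
  net <- msffn_net(cfg, seed = 4)
  S <- 32L
  X <- matrix(rnorm(S * S * 4), S * S, 4)
  base <- msffn:::net_forward(net, X, S, S, 1L)$logits
  for (j in 1:8) {
    mask <- rep(TRUE, 8); mask[j] <- FALSE
    alt <- msffn:::net_forward(net, X, S, S, 1L, tap_mask = mask)$logits
    expect_gt(max(abs(alt - base)), 1e-8)
  }
})

test_that("the network is translation-equivariant on a torus", {
  cfg <- net_config(input_size = 64L)
  net <- msffn_net(cfg, seed = 5)
  S <- 64L
  img <- array(rnorm(S * S * 4), dim = c(S, S, 4))
  sh <- 16L  # multiple of the total pooling factor
  img_sh <- img[c((S - sh + 1):S, 1:(S - sh)), c((S - sh + 1):S, 1:(S - sh)), ,
                drop = FALSE]
  X <- msffn:::images_to_batch(list(img))
  Xs <- msffn:::images_to_batch(list(img_sh))
  L1 <- msffn:::net_forward(net, X, S, S, 1L, pad = 1L)$logits
  L2 <- msffn:::net_forward(net, Xs, S, S, 1L, pad = 1L)$logits
  A1 <- array(L1, dim = c(S, S, 5))
  A2 <- array(L2, dim = c(S, S, 5))
  A1s <- A1[c((S - sh + 1):S, 1:(S - sh)), c((S - sh + 1):S, 1:(S - sh)), ,
            drop = FALSE]
  expect_equal(A2, A1s, tolerance = 1e-10)
})

test_that("the model builds and runs at any input size divisible by 16", {
  for (S in c(32L, 48L)) {
    net <- msffn_net(net_config(input_size = S), seed = 6)
    probs <- predict_probs(net, array(rnorm(S * S * 4), dim = c(S, S, 4)))
    expect_identical(dim(probs), c(S, S, 5L))
  }
})

test_that("backpropagated gradients match finite differences end to end", {
  cfg <- tiny_net_config()
  net <- msffn_net(cfg, seed = 7)
  S <- 16L; B <- 2L
  set.seed(8)
  X <- matrix(rnorm(B * S * S * 4), B * S * S, 4)
  lab <- sample(0:4, B * S * S, replace = TRUE)
  G <- matrix(0, B * S * S, 5); G[cbind(seq_along(lab), lab + 1)] <- 1
  loss_of <- function(nt) {
    f <- msffn:::net_forward(nt, X, S, S, B, training = TRUE, keep_cache = TRUE)
    list(v = seg_loss(f$P, G, "hl2"), f = f)
  }
  r <- loss_of(net)
  dP <- seg_loss_grad(r$f$P, G, "hl2")
  dL <- msffn:::softmax_backward(r$f$P, dP)
  gr <- msffn:::net_backward(net, r$f, dL, S, S, B)
  h <- 1e-6
  set.seed(9)
  for (nm in c("fen_s1_u2", "fen_s3_u1", "fen_s5_u2", "fuse_u1", "cls")) {
    for (key in intersect(c("W", "gamma", "beta"), names(gr[[nm]]))) {
      idx <- sample(length(gr[[nm]][[key]]), 2)
      for (i in idx) {
        n2 <- net
        n2$params[[nm]][[key]][i] <- n2$params[[nm]][[key]][i] + h
        lp <- loss_of(n2)$v
        n2$params[[nm]][[key]][i] <- n2$params[[nm]][[key]][i] - 2 * h
        lm <- loss_of(n2)$v
        num <- (lp - lm) / (2 * h)
        ana <- gr[[nm]][[key]][i]
        expect_equal(ana, num, tolerance = 1e-4)
      }
    }
  }
  # every trainable gradient is finite after one HL2 backward pass
  expect_true(all(vapply(gr, function(g)
    all(vapply(g, function(v) all(is.finite(v)), logical(1))), logical(1))))
})

test_that("the U-net baseline honors its channel plan and output contract", {
  un <- unet_net(seed = 10)
  expect_equal(un$cfg$stage_channels, c(32L, 64L, 128L, 256L, 512L))
  # encoder unit shapes encode the stated widths
  expect_equal(ncol(un$params$enc_s1_u1$W), 32)
  expect_equal(ncol(un$params$enc_s5_u2$W), 512)
  expect_equal(nrow(un$params$enc_s5_u1$W), 9 * 256)

  # smaller instantiation for a forward pass
  cfg <- net_config(input_size = 32L,
                    stage_channels = c(8L, 12L, 16L, 20L, 24L))
  uns <- unet_net(cfg, seed = 11)
  probs <- predict_probs(uns, array(rnorm(32 * 32 * 4), dim = c(32, 32, 4)))
  expect_identical(dim(probs), c(32L, 32L, 5L))
  expect_lt(max(abs(apply(probs, c(1, 2), sum) - 1)), 1e-5)

  # the baseline is the larger model
  expect_gt(count_parameters(un)$count,
            count_parameters(msffn_net(net_config()))$count)
})
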