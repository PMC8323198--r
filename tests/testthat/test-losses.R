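test_that("cross-entropy matches its closed forms", {
  pp <- random_prob_pair(30, kind = "onehot")
  expect_lt(cross_entropy(pp$P, pp$G), 1e-6)

  un <- random_prob_pair(40, kind = "uniform")
  expect_equal(cross_entropy(un$P, un$G), log(5), tolerance = 1e-9)

  P <- matrix(c(0.5, 0.2, 0.1, 0.1, 0.1), 1)
  G <- matrix(c(1, 0, 0, 0, 0), 1)
  expect_equal(cross_entropy(P, G), -log(0.5), tolerance = 1e-9)
  expect_error(cross_entropy(P, matrix(1, 2, 5)), "differ")
})

test_that("per-class Dice loss matches hand evaluation", {
  # 4 pixels, class k channel: p = (1, .5, 0, 0), g = (1, 1, 0, 0)
  P <- matrix(0, 4, 5); G <- matrix(0, 4, 5)
  P[, 2] <- c(1, 0.5, 0, 0); P[, 1] <- 1 - P[, 2]
  G[, 2] <- c(1, 1, 0, 0); G[, 1] <- 1 - G[, 2]
  expect_equal(dice_loss_class(P, G, 1L), 1 - 3 / 3.5, tolerance = 1e-4)

  oh <- random_prob_pair(25, kind = "onehot")
  k_present <- oh$labels[1]
  expect_lt(dice_loss_class(oh$P, oh$G, k_present), 1e-6)
  # class absent from both prediction and truth scores 0 under smoothing
  pp <- random_prob_pair(25, kind = "empty_region")
  P0 <- pp$G   # predict exactly the truth; classes 1, 3, 4 all absent
  expect_equal(dice_loss_class(P0, pp$G, 4L), 0)
})

test_that("region Dice losses follow the member-channel sums", {
  # 2 pixels: G labels (2, 0); P rows (0,.5,.5,0,0) and (1,0,0,0,0)
  P <- rbind(c(0, 0.5, 0.5, 0, 0), c(1, 0, 0, 0, 0))
  G <- rbind(c(0, 0, 1, 0, 0), c(1, 0, 0, 0, 0))
  expect_lt(dice_loss_region(P, G, "complete"), 1e-5)
  expect_gt(dice_loss_region(P, G, "core"), 0.999)

  oh <- random_prob_pair(30, kind = "onehot")
  for (r in c("background", "complete", "core", "enhancing"))
    expect_lt(dice_loss_region(oh$P, oh$G, r), 1e-6)
})

test_that("combined and sliced Dice losses obey their bounds and sums", {
  oh <- random_prob_pair(30, kind = "onehot")
  expect_lt(combined_dice_loss(oh$P, oh$G), 1e-6)
  expect_lt(sliced_dice_loss(oh$P, oh$G), 1e-6)

  # uniform prediction over a single-class image: DL_c = 2/3, others 1
  n <- 20
  G <- matrix(0, n, 5); G[, 3] <- 1
  P <- matrix(1 / 5, n, 5)
  expect_equal(sliced_dice_loss(P, G), 2 / 3 + 4, tolerance = 1e-3)

  set.seed(21)
  for (i in 1:10) {
    pp <- random_prob_pair(16)
    expect_lte(combined_dice_loss(pp$P, pp$G), 4)
    expect_lte(sliced_dice_loss(pp$P, pp$G), 5)
    # permutation invariance
    idx <- sample(16)
    expect_equal(sliced_dice_loss(pp$P[idx, ], pp$G[idx, ]),
                 sliced_dice_loss(pp$P, pp$G))
  }
})

test_that("recall loss penalizes missed target pixels only", {
  P <- matrix(0, 4, 5); G <- matrix(0, 4, 5)
  P[, 2] <- c(1, 0.5, 0, 0)
  G[, 2] <- c(1, 1, 0, 0)
  expect_equal(recall_loss(P, G, 1L), 0.25, tolerance = 1e-4)

  oh <- random_prob_pair(30, kind = "onehot")
  expect_lt(recall_loss(oh$P, oh$G, "complete"), 1e-6)

  # a total miss scores 1
  Pmiss <- matrix(0, 4, 5); Pmiss[, 1] <- 1
  expect_equal(recall_loss(Pmiss, G, 1L), 1, tolerance = 1e-4)
})

test_that("core recall has no factor 2 so no loss can go negative", {
  # a perfect prediction: recall ratio is 1, loss 0 (a spurious doubled
  # numerator would drive this to -1)
  n <- 30
  G <- matrix(0, n, 5); G[, 4] <- 1
  expect_equal(recall_loss(G, G, "core"), 0, tolerance = 1e-5)
  set.seed(31)
  for (i in 1:20) {
    pp <- random_prob_pair(12)
    for (target in list("complete", "core", "enhancing", 0L, 2L, 4L)) {
      v <- recall_loss(pp$P, pp$G, target)
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("hybrid losses are the stated weighted sums", {
  set.seed(41)
  pp <- random_prob_pair(24)
  P <- pp$P; G <- pp$G
  w1 <- loss_weights("hl1")
  expect_equal(c(w1$alpha, w1$beta, w1$gamma, w1$delta), c(20, 0.5, 1, 0.5))
  manual1 <- 20 * cross_entropy(P, G) + 0.5 * recall_loss(P, G, "complete") +
    1 * recall_loss(P, G, "core") + 0.5 * recall_loss(P, G, "enhancing")
  expect_equal(hybrid_hl1(P, G), manual1, tolerance = 1e-12)

  w2 <- loss_weights("hl2")
  expect_equal(c(w2$alpha, w2$beta, w2$gamma, w2$delta), c(1, 0.1, 1.3, 0.5))
  manual2 <- combined_dice_loss(P, G) + 0.1 * recall_loss(P, G, "complete") +
    1.3 * recall_loss(P, G, "core") + 0.5 * recall_loss(P, G, "enhancing")
  expect_equal(hybrid_hl2(P, G), manual2, tolerance = 1e-12)

  # the weighted-sum arithmetic itself, on fixed component values
  expect_equal(sum(c(20, 0.5, 1, 0.5) * c(0.1, 0.2, 0.3, 0.4)), 2.6)
  expect_equal(sum(c(1, 0.1, 1.3, 0.5) * c(1.0, 0.2, 0.3, 0.4)), 1.61)

  # linearity in the weights
  dbl <- loss_weights("hl1", alpha = 40, beta = 1, gamma = 2, delta = 1)
  expect_equal(hybrid_hl1(P, G, dbl), 2 * hybrid_hl1(P, G), tolerance = 1e-12)

  # HL2 with beta = gamma = delta = 0, alpha = 1 reduces to combined Dice
  red <- loss_weights("hl2", alpha = 1, beta = 0, gamma = 0, delta = 0)
  expect_equal(hybrid_hl2(P, G, red), combined_dice_loss(P, G))

  oh <- random_prob_pair(24, kind = "onehot")
  expect_lt(hybrid_hl1(oh$P, oh$G), 20 * 1e-6)
  expect_lt(hybrid_hl2(oh$P, oh$G), 1e-5)
})

test_that("vectorized losses agree with naive double-loop oracles", {
  set.seed(51)
  kinds <- c(rep("random", 35), rep("onehot", 5), rep("uniform", 5),
             rep("empty_region", 5))
  for (kind in kinds) {
    pp <- random_prob_pair(64, kind = kind)
    P <- pp$P; G <- pp$G
    expect_equal(cross_entropy(P, G), naive_ce(P, G), tolerance = 1e-6)
    for (k in 0:4)
      expect_equal(dice_loss_class(P, G, k), naive_dice_class(P, G, k),
                   tolerance = 1e-6)
    for (r in c("background", "complete", "core", "enhancing")) {
      expect_equal(dice_loss_region(P, G, r), naive_dice_region(P, G, r),
                   tolerance = 1e-6)
      expect_equal(recall_loss(P, G, r), naive_recall(P, G, r),
                   tolerance = 1e-6)
    }
    expect_equal(combined_dice_loss(P, G), naive_combined_dice(P, G),
                 tolerance = 1e-6)
    expect_equal(sliced_dice_loss(P, G), naive_sliced_dice(P, G),
                 tolerance = 1e-6)
    expect_equal(hybrid_hl1(P, G), naive_hl1(P, G), tolerance = 1e-6)
    expect_equal(hybrid_hl2(P, G), naive_hl2(P, G), tolerance = 1e-6)
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(61)
  n <- 16   # a 4 x 4 slice
  Z <- matrix(rnorm(n * 5), n, 5)
  P <- exp(Z) / rowSums(exp(Z))   # interior of (0, 1)
  lab <- sample(0:4, n, replace = TRUE)
  G <- matrix(0, n, 5); G[cbind(1:n, lab + 1)] <- 1
  h <- 1e-6
  for (loss in c("ce", "sliced_dice", "combined_dice", "hl1", "hl2")) {
    ana <- seg_loss_grad(P, G, loss)
    num <- matrix(0, n, 5)
    for (i in 1:n) for (k in 1:5) {
      Pp <- P; Pp[i, k] <- Pp[i, k] + h
      Pm <- P; Pm[i, k] <- Pm[i, k] - h
      num[i, k] <- (seg_loss(Pp, G, loss) - seg_loss(Pm, G, loss)) / (2 * h)
    }
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("losses pool over a batch as a single pixel set", {
  set.seed(71)
  a <- random_prob_pair(20)
  b <- random_prob_pair(12)
  P <- rbind(a$P, b$P); G <- rbind(a$G, b$G)
  # CE: mean over N = all pixels
  expect_equal(cross_entropy(P, G),
               (20 * cross_entropy(a$P, a$G) + 12 * cross_entropy(b$P, b$G)) / 32,
               tolerance = 1e-12)
  # ratio losses: sums pooled over the whole batch, not averaged per image
  pc <- region_soft(P, "complete"); gc <- region_soft(G, "complete")
  expect_equal(dice_loss_region(P, G, "complete"),
               1 - (2 * sum(pc * gc) + 1e-5) / (sum(pc) + sum(gc) + 1e-5),
               tolerance = 1e-12)
  # array and matrix views give identical values
  Parr <- array(a$P[1:16, ], dim = c(4, 4, 5))
  Garr <- array(a$G[1:16, ], dim = c(4, 4, 5))
  expect_equal(hybrid_hl2(Parr, Garr), hybrid_hl2(a$P[1:16, ], a$G[1:16, ]))
})
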