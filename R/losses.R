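## Class-imbalance-aware segmentation losses.
##
## Every loss consumes a softmax probability map P and a one-hot ground
## truth G.  Both may be given as H x W x K arrays (one slice) or N x K
## matrices (N pixels pooled over a whole batch); ratio losses pool their
## sums over all supplied pixels, matching the single-N form of the
## defining formulas.  K = 5 channels indexed by raw label value.

as_pg_matrix <- function(x, name = "input") {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop(name, " must be an H x W x K array or N x K matrix")
  matrix(x, nrow = d[1L] * d[2L], ncol = d[3L])
}

check_pg <- function(P, G) {
  P <- as_pg_matrix(P, "P"); G <- as_pg_matrix(G, "G")
  if (!identical(dim(P), dim(G)))
    stop("prediction and ground truth shapes differ: ",
         paste(dim(P), collapse = "x"), " vs ", paste(dim(G), collapse = "x"))
  list(P = P, G = G)
}

#' Loss weights for the hybrid losses
#'
#' Defaults are the settings reported to work best for each hybrid:
#' HL1 uses (alpha, beta, gamma, delta) = (20, 0.5, 1, 0.5) and HL2
#' uses (1, 0.1, 1.3, 0.5), weighting the base term (cross-entropy for
#' HL1, combined Dice for HL2) and the complete/core/enhancing recall
#' losses respectively.
#'
#' @param loss `"hl1"` or `"hl2"` selects the published defaults.
#' @param alpha,beta,gamma,delta Nonnegative overrides.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(loss = c("hl1", "hl2"), alpha = NULL, beta = NULL,
                         gamma = NULL, delta = NULL) {
  loss <- match.arg(loss)
  def <- if (loss == "hl1") c(20, 0.5, 1, 0.5) else c(1, 0.1, 1.3, 0.5)
  w <- c(alpha %||% def[1L], beta %||% def[2L], gamma %||% def[3L],
         delta %||% def[4L])
  if (any(w < 0)) stop("loss weights must be nonnegative")
  structure(list(alpha = w[1L], beta = w[2L], gamma = w[3L], delta = w[4L]),
            class = "loss_weights")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-class cross-entropy loss
#'
#' Mean over pixels of `-sum_k g_k log p_k`, with probabilities clipped
#' to `[clip, 1 - clip]` before the logarithm.
#'
#' @param P Probability map (`H x W x K` array or `N x K` matrix).
#' @param G One-hot ground truth, same shape.
#' @param clip Clipping bound keeping the log finite (default 1e-7).
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(P, G, clip = 1e-7) {
  m <- check_pg(P, G)
  Pc <- pmin(pmax(m$P, clip), 1 - clip)
  -sum(m$G * log(Pc)) / nrow(m$P)
}

cross_entropy_grad <- function(P, G, clip = 1e-7) {
  m <- check_pg(P, G)
  Pc <- pmin(pmax(m$P, clip), 1 - clip)
  inside <- (m$P > clip) & (m$P < 1 - clip)
  -(m$G / Pc) * inside / nrow(m$P)
}

## Soft Dice on a single (possibly composite) channel pair of column sums.
dice_ratio <- function(p, g, eps) {
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

#' Per-class soft Dice loss
#'
#' `1 - (2 sum p_k g_k + eps) / (sum p_k + sum g_k + eps)` for one class
#' channel; the smoothing term makes an absent class (empty in both P
#' and G) a perfect score rather than a division failure.
#'
#' @inheritParams cross_entropy
#' @param k Class index in `0:4` (raw label value).
#' @param eps Smoothing constant (default 1e-5).
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss_class <- function(P, G, k, eps = 1e-5) {
  m <- check_pg(P, G)
  if (k < 0 || k >= ncol(m$P)) stop("class index k = ", k, " out of range")
  dice_ratio(m$P[, k + 1L], m$G[, k + 1L], eps)
}

#' Per-region soft Dice loss
#'
#' The per-class Dice form applied to soft region memberships (sums of
#' the member-label channels): background, complete, core or enhancing.
#'
#' @inheritParams dice_loss_class
#' @param region Region name or [region_spec].
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss_region <- function(P, G, region, eps = 1e-5) {
  m <- check_pg(P, G)
  region <- region_spec(region)
  dice_ratio(region_soft(m$P, region), region_soft(m$G, region), eps)
}

#' Combined Dice loss
#'
#' Sum of the region Dice losses for background, complete, core and
#' enhancing; the four-region form used as a training objective and as
#' the base term of HL2.
#'
#' @inheritParams dice_loss_class
#' @return Scalar in `[0, 4]`.
#' @export
combined_dice_loss <- function(P, G, eps = 1e-5) {
  sum(vapply(c("background", EVAL_REGIONS), function(r)
    dice_loss_region(P, G, r, eps), numeric(1)))
}

#' Sliced Dice loss
#'
#' Sum of the per-class Dice losses over all five labels.
#'
#' @inheritParams dice_loss_class
#' @return Scalar in `[0, 5]`.
#' @export
sliced_dice_loss <- function(P, G, eps = 1e-5) {
  sum(vapply(0:4, function(k) dice_loss_class(P, G, k, eps), numeric(1)))
}

#' Recall (soft sensitivity) loss
#'
#' `1 - (sum p g + eps) / (sum g + eps)` over a class channel or a soft
#' region; penalizes missed target pixels only, shifting emphasis to
#' the minority classes.
#'
#' @inheritParams dice_loss_class
#' @param target A class index in `0:4`, or a region name /
#'   [region_spec].
#' @return Scalar in `[0, 1]`.
#' @export
recall_loss <- function(P, G, target, eps = 1e-5) {
  m <- check_pg(P, G)
  if (is.numeric(target)) {
    if (target < 0 || target >= ncol(m$P)) stop("class index out of range: ", target)
    p <- m$P[, target + 1L]; g <- m$G[, target + 1L]
  } else {
    region <- region_spec(target)
    p <- region_soft(m$P, region); g <- region_soft(m$G, region)
  }
  1 - (sum(p * g) + eps) / (sum(g) + eps)
}

#' Hybrid loss 1: cross-entropy plus region recall losses
#'
#' `alpha * CE + beta * RL_complete + gamma * RL_core + delta * RL_enhancing`.
#'
#' @inheritParams cross_entropy
#' @param weights A [loss_weights] (defaults to the HL1 settings
#'   (20, 0.5, 1, 0.5)).
#' @param eps Smoothing constant for the recall ratios.
#' @return Nonnegative scalar.
#' @export
hybrid_hl1 <- function(P, G, weights = loss_weights("hl1"), eps = 1e-5,
                       clip = 1e-7) {
  weights$alpha * cross_entropy(P, G, clip) +
    weights$beta * recall_loss(P, G, "complete", eps) +
    weights$gamma * recall_loss(P, G, "core", eps) +
    weights$delta * recall_loss(P, G, "enhancing", eps)
}

#' Hybrid loss 2: combined Dice plus region recall losses
#'
#' `alpha * combined Dice + beta * RL_complete + gamma * RL_core +
#' delta * RL_enhancing`.
#'
#' @inheritParams hybrid_hl1
#' @param weights A [loss_weights] (defaults to the HL2 settings
#'   (1, 0.1, 1.3, 0.5)).
#' @return Nonnegative scalar.
#' @export
hybrid_hl2 <- function(P, G, weights = loss_weights("hl2"), eps = 1e-5) {
  weights$alpha * combined_dice_loss(P, G, eps) +
    weights$beta * recall_loss(P, G, "complete", eps) +
    weights$gamma * recall_loss(P, G, "core", eps) +
    weights$delta * recall_loss(P, G, "enhancing", eps)
}

SEG_LOSSES <- c("ce", "sliced_dice", "combined_dice", "hl1", "hl2")

#' Evaluate a selectable segmentation loss
#'
#' @inheritParams cross_entropy
#' @param loss One of `"ce"`, `"sliced_dice"`, `"combined_dice"`,
#'   `"hl1"`, `"hl2"`.
#' @param weights [loss_weights] for the hybrid losses.
#' @param eps Smoothing constant for ratio losses.
#' @return Scalar loss value.
#' @export
seg_loss <- function(P, G, loss = SEG_LOSSES, weights = NULL, eps = 1e-5,
                     clip = 1e-7) {
  loss <- match.arg(loss)
  switch(loss,
    ce = cross_entropy(P, G, clip),
    sliced_dice = sliced_dice_loss(P, G, eps),
    combined_dice = combined_dice_loss(P, G, eps),
    hl1 = hybrid_hl1(P, G, weights %||% loss_weights("hl1"), eps, clip),
    hl2 = hybrid_hl2(P, G, weights %||% loss_weights("hl2"), eps)
  )
}

## ---- analytic gradients with respect to P -------------------------------

dice_ratio_grad <- function(p, g, eps) {
  den <- sum(p) + sum(g) + eps
  num <- 2 * sum(p * g) + eps
  -(2 * g * den - num) / den^2
}

dice_class_grad <- function(P, G, k, eps) {
  dP <- matrix(0, nrow(P), ncol(P))
  dP[, k + 1L] <- dice_ratio_grad(P[, k + 1L], G[, k + 1L], eps)
  dP
}

dice_region_grad <- function(P, G, region, eps) {
  region <- region_spec(region)
  ch <- region$member_labels + 1L
  gr <- dice_ratio_grad(region_soft(P, region), region_soft(G, region), eps)
  dP <- matrix(0, nrow(P), ncol(P))
  for (c2 in ch) dP[, c2] <- gr
  dP
}

recall_grad <- function(P, G, target, eps) {
  dP <- matrix(0, nrow(P), ncol(P))
  if (is.numeric(target)) {
    g <- G[, target + 1L]
    dP[, target + 1L] <- -g / (sum(g) + eps)
  } else {
    region <- region_spec(target)
    ch <- region$member_labels + 1L
    g <- region_soft(G, region)
    gr <- -g / (sum(g) + eps)
    for (c2 in ch) dP[, c2] <- gr
  }
  dP
}

#' Gradient of a segmentation loss with respect to the probabilities
#'
#' Analytic `dL/dP`, pooled over all supplied pixels; used by the
#' training loop (chained through the softmax Jacobian) and verified by
#' finite differences in the test suite.
#'
#' @inheritParams seg_loss
#' @return Matrix (or array matching `P`) of partial derivatives.
#' @export
seg_loss_grad <- function(P, G, loss = SEG_LOSSES, weights = NULL, eps = 1e-5,
                          clip = 1e-7) {
  loss <- match.arg(loss)
  shape <- dim(P)
  m <- check_pg(P, G)
  P <- m$P; G <- m$G
  dP <- switch(loss,
    ce = cross_entropy_grad(P, G, clip),
    sliced_dice = Reduce(`+`, lapply(0:4, function(k)
      dice_class_grad(P, G, k, eps))),
    combined_dice = Reduce(`+`, lapply(c("background", EVAL_REGIONS),
      function(r) dice_region_grad(P, G, r, eps))),
    hl1 = {
      w <- weights %||% loss_weights("hl1")
      w$alpha * cross_entropy_grad(P, G, clip) +
        w$beta * recall_grad(P, G, "complete", eps) +
        w$gamma * recall_grad(P, G, "core", eps) +
        w$delta * recall_grad(P, G, "enhancing", eps)
    },
    hl2 = {
      w <- weights %||% loss_weights("hl2")
      w$alpha * Reduce(`+`, lapply(c("background", EVAL_REGIONS),
        function(r) dice_region_grad(P, G, r, eps))) +
        w$beta * recall_grad(P, G, "complete", eps) +
        w$gamma * recall_grad(P, G, "core", eps) +
        w$delta * recall_grad(P, G, "enhancing", eps)
    }
  )
  if (!is.null(shape) && length(shape) == 3L) dim(dP) <- shape
  dP
}
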