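#' Network configuration
#'
#' Defaults reproduce the published architecture: 176 x 176 four-channel
#' input, five extraction stages of (4, 2, 2, 2, 2) conv units at
#' channel widths (16, 32, 64, 128, 256) with 2 x 2 max-pooling between
#' stages, a three-unit fusing block of width 64 over the 544-channel
#' concatenation of all eight taps, and a 1 x 1 classifier to 5 classes.
#' This configuration totals 6.3 MB of parameters at 4 bytes each.
#'
#' @param input_size In-plane input size in pixels; must be divisible
#'   by 16 (four 2x poolings).
#' @param in_channels Input channels (the 4 MRI sequences).
#' @param num_classes Output classes (5 BRATS labels).
#' @param stage_channels Channel width of each of the five stages.
#' @param stage_units Conv units per stage; fixed at (4, 2, 2, 2, 2).
#' @param fusing_channels Width of the fusing block.
#' @param dropout Dropout rate after each pooling and after the fusing
#'   block (training only).
#' @param channel_order Modality order of the input channels.
#' @return A `net_config` list.
#' @export
net_config <- function(input_size = 176L, in_channels = 4L, num_classes = 5L,
                       stage_channels = c(16L, 32L, 64L, 128L, 256L),
                       stage_units = c(4L, 2L, 2L, 2L, 2L),
                       fusing_channels = 64L, dropout = 0.2,
                       channel_order = c("T1", "T1c", "T2", "FLAIR")) {
  if (input_size %% 16L != 0L)
    stop("input_size must be divisible by 16 (four 2x poolings); got ",
         input_size)
  if (length(stage_channels) != 5L || any(stage_channels < 1L))
    stop("stage_channels must be 5 positive integers")
  if (!identical(as.integer(stage_units), c(4L, 2L, 2L, 2L, 2L)))
    stop("stage_units is fixed at (4, 2, 2, 2, 2): four conv units in the ",
         "first stage, two in each later stage")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(
    input_size = as.integer(input_size), in_channels = as.integer(in_channels),
    num_classes = as.integer(num_classes),
    stage_channels = as.integer(stage_channels),
    stage_units = as.integer(stage_units),
    fusing_channels = as.integer(fusing_channels), dropout = dropout,
    channel_order = channel_order
  ), class = "net_config")
}

#' Build the full segmentation network
#'
#' Instantiates the two-part architecture: the feature extraction
#' network (five stages of conv units, eight exported taps) and the
#' multi-scale feature fusing head (bilinear upsampling of every tap to
#' input resolution, channel concatenation, three fusing conv units,
#' dropout, 1 x 1 classifier, softmax).
#'
#' @param cfg A [net_config].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `msffn_net`.
#' @export
msffn_net <- function(cfg = net_config(), seed = NULL) {
  stopifnot(inherits(cfg, "net_config"))
  if (!is.null(seed)) set.seed(seed)
  params <- list()
  cin <- cfg$in_channels
  for (s in 1:5) {
    for (u in seq_len(cfg$stage_units[s])) {
      params[[sprintf("fen_s%d_u%d", s, u)]] <- unit_init(cin, cfg$stage_channels[s])
      cin <- cfg$stage_channels[s]
    }
  }
  cat_channels <- 4L * cfg$stage_channels[1L] + sum(cfg$stage_channels[2:5])
  cin <- cat_channels
  for (u in 1:3) {
    params[[sprintf("fuse_u%d", u)]] <- unit_init(cin, cfg$fusing_channels)
    cin <- cfg$fusing_channels
  }
  params[["cls"]] <- list(
    W = matrix(rnorm(cfg$fusing_channels * cfg$num_classes,
                     sd = sqrt(2 / cfg$fusing_channels)),
               cfg$fusing_channels, cfg$num_classes),
    b = numeric(cfg$num_classes)
  )
  structure(list(arch = "msffn", cfg = cfg, params = params,
                 cat_channels = cat_channels),
            class = c("msffn_net", "seg_net"))
}

#' @export
print.msffn_net <- function(x, ...) {
  pc <- count_parameters(x)
  cat("<msffn_net> FEN (", paste(x$cfg$stage_channels, collapse = "/"),
      " channels, ", sum(x$cfg$stage_units), " conv layers) + MSFFN (",
      x$cat_channels, " fused channels -> ", x$cfg$fusing_channels, ")\n",
      "  input ", x$cfg$input_size, " x ", x$cfg$input_size, " x ",
      x$cfg$in_channels, ", ", x$cfg$num_classes, " classes\n",
      "  parameters: ", format(pc$count, big.mark = ","), " (",
      sprintf("%.1f MB", pc$bytes / 1e6), ")\n", sep = "")
  invisible(x)
}

#' Build the U-net baseline
#'
#' Standard encoder-decoder U-net used as the comparison baseline, with
#' encoder channels (32, 64, 128, 256, 512), two conv units per stage,
#' BN in every unit, bilinear upsampling + conv decoding with skip
#' concatenations, and the same input/output contract as [msffn_net()].
#'
#' @param cfg A [net_config]; `stage_channels` defaults to the baseline
#'   widths (32, 64, 128, 256, 512).
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `unet_net`.
#' @export
unet_net <- function(cfg = net_config(stage_channels = c(32L, 64L, 128L, 256L, 512L)),
                     seed = NULL) {
  stopifnot(inherits(cfg, "net_config"))
  if (!is.null(seed)) set.seed(seed)
  ec <- cfg$stage_channels
  params <- list()
  cin <- cfg$in_channels
  for (s in 1:5) {
    for (u in 1:2) {
      params[[sprintf("enc_s%d_u%d", s, u)]] <- unit_init(cin, ec[s])
      cin <- ec[s]
    }
  }
  for (d in 4:1) {
    params[[sprintf("dec_s%d_u1", d)]] <- unit_init(ec[d] + ec[d + 1L], ec[d])
    params[[sprintf("dec_s%d_u2", d)]] <- unit_init(ec[d], ec[d])
  }
  params[["cls"]] <- list(
    W = matrix(rnorm(ec[1L] * cfg$num_classes, sd = sqrt(2 / ec[1L])),
               ec[1L], cfg$num_classes),
    b = numeric(cfg$num_classes)
  )
  structure(list(arch = "unet", cfg = cfg, params = params),
            class = c("unet_net", "seg_net"))
}

#' @export
print.unet_net <- function(x, ...) {
  pc <- count_parameters(x)
  cat("<unet_net> encoder channels ", paste(x$cfg$stage_channels, collapse = "/"),
      ", parameters: ", format(pc$count, big.mark = ","), " (",
      sprintf("%.1f MB", pc$bytes / 1e6), ")\n", sep = "")
  invisible(x)
}

#' Count network parameters
#'
#' Counts every stored parameter: convolution kernels and biases, BN
#' scale and shift, and the BN moving statistics (the "total
#' parameters" convention of common frameworks).  Bytes assume 32-bit
#' storage (4 bytes per parameter).
#'
#' @param net A network built by [msffn_net()] or [unet_net()].
#' @return List with `count` and `bytes` (`count * 4`).
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "seg_net"))
  count <- sum(vapply(net$params, function(p)
    sum(vapply(p, length, integer(1))), numeric(1)))
  list(count = as.integer(count), bytes = as.integer(4L * count))
}

#' Parameter size in decimal megabytes
#'
#' @inheritParams count_parameters
#' @param digits Decimals to round to (default 1, as sizes are usually
#'   quoted).
#' @return Numeric scalar, e.g. `6.3` for the default architecture.
#' @export
param_size_mb <- function(net, digits = 1L) {
  round(count_parameters(net)$bytes / 1e6, digits)
}

## ---- forward / backward graphs ------------------------------------------

fen_forward <- function(net, X, H, W, B, training = FALSE, pad = 0L,
                        keep_cache = FALSE) {
  cfg <- net$cfg
  taps <- list()
  tapdims <- list()
  caches <- list()
  stats <- list()
  cur <- X; h <- H; w <- W
  for (s in 1:5) {
    for (u in seq_len(cfg$stage_units[s])) {
      nm <- sprintf("fen_s%d_u%d", s, u)
      r <- unit_forward(net$params[[nm]], cur, h, w, B, training, pad, keep_cache)
      if (keep_cache) caches[[nm]] <- r$cache
      if (training) stats[[nm]] <- r$stats
      cur <- r$Y
      if (s == 1L) {
        taps[[length(taps) + 1L]] <- cur
        tapdims[[length(tapdims) + 1L]] <- c(h, w)
      }
    }
    if (s > 1L) {
      taps[[length(taps) + 1L]] <- cur
      tapdims[[length(tapdims) + 1L]] <- c(h, w)
    }
    if (s < 5L) {
      mp <- .cpp_maxpool_forward(cur, h, w, B)
      if (keep_cache)
        caches[[sprintf("pool%d", s)]] <- list(idx = mp$idx, n_in = nrow(cur))
      cur <- mp$Y
      h <- h %/% 2L; w <- w %/% 2L
      if (training && cfg$dropout > 0) {
        dr <- dropout_forward(cur, cfg$dropout)
        if (keep_cache) caches[[sprintf("drop%d", s)]] <- dr$mask
        cur <- dr$Y
      }
    }
  }
  list(taps = taps, tapdims = tapdims, caches = caches, stats = stats)
}

msffn_forward <- function(net, X, H, W, B, training = FALSE, pad = 0L,
                          keep_cache = FALSE, tap_mask = NULL) {
  cfg <- net$cfg
  fen <- fen_forward(net, X, H, W, B, training, pad, keep_cache)
  taps <- fen$taps
  if (!is.null(tap_mask)) {
    for (j in which(!tap_mask)) taps[[j]] <- taps[[j]] * 0
  }
  up <- taps
  factors <- c(1L, 1L, 1L, 1L, 2L, 4L, 8L, 16L)
  for (j in 5:8) {
    d <- fen$tapdims[[j]]
    up[[j]] <- .cpp_upsample_forward(taps[[j]], d[1L], d[2L], B, factors[j], pad)
    if (nrow(up[[j]]) != H * W * B)
      stop("internal: tap ", j, " upsampled to ", nrow(up[[j]]),
           " pixels, expected ", H * W * B)
  }
  widths <- vapply(up, ncol, integer(1))
  Xcat <- do.call(cbind, up)
  caches <- fen$caches
  stats <- fen$stats
  cur <- Xcat
  for (u in 1:3) {
    nm <- sprintf("fuse_u%d", u)
    r <- unit_forward(net$params[[nm]], cur, H, W, B, training, pad, keep_cache)
    if (keep_cache) caches[[nm]] <- r$cache
    if (training) stats[[nm]] <- r$stats
    cur <- r$Y
  }
  if (training && cfg$dropout > 0) {
    dr <- dropout_forward(cur, cfg$dropout)
    if (keep_cache) caches[["drop_fuse"]] <- dr$mask
    cur <- dr$Y
  }
  logits <- cur %*% net$params$cls$W +
    col_broadcast(net$params$cls$b, nrow(cur))
  P <- softmax_rows(logits)
  if (keep_cache) caches[["cls_in"]] <- cur
  list(P = P, logits = logits, taps = fen$taps, tapdims = fen$tapdims,
       tap_widths = widths, caches = caches, stats = stats)
}

msffn_backward <- function(net, fwd, dLogits, H, W, B, pad = 0L) {
  cfg <- net$cfg
  caches <- fwd$caches
  grads <- list()
  grads[["cls"]] <- list(W = t(caches$cls_in) %*% dLogits,
                         b = colSums(dLogits))
  dcur <- dLogits %*% t(net$params$cls$W)
  if (!is.null(caches$drop_fuse)) dcur <- dcur * caches$drop_fuse
  for (u in 3:1) {
    nm <- sprintf("fuse_u%d", u)
    r <- unit_backward(net$params[[nm]], caches[[nm]], dcur)
    grads[[nm]] <- r$grads
    dcur <- r$dX
  }
  ## split the concatenation back into per-tap gradients
  widths <- fwd$tap_widths
  offs <- cumsum(c(0L, widths))
  factors <- c(1L, 1L, 1L, 1L, 2L, 4L, 8L, 16L)
  dtap <- vector("list", 8L)
  for (j in 1:8) {
    dj <- dcur[, (offs[j] + 1L):offs[j + 1L], drop = FALSE]
    if (j >= 5L) {
      d <- fwd$tapdims[[j]]
      dj <- .cpp_upsample_backward(dj, d[1L], d[2L], B, factors[j], pad)
    }
    dtap[[j]] <- dj
  }
  ## back through the extraction network
  dcur <- dtap[[8L]]
  for (u in cfg$stage_units[5L]:1L) {
    nm <- sprintf("fen_s5_u%d", u)
    r <- unit_backward(net$params[[nm]], caches[[nm]], dcur)
    grads[[nm]] <- r$grads
    dcur <- r$dX
  }
  for (s in 4:1) {
    mask <- caches[[sprintf("drop%d", s)]]
    if (!is.null(mask)) dcur <- dcur * mask
    pl <- caches[[sprintf("pool%d", s)]]
    dcur <- .cpp_maxpool_backward(dcur, pl$idx, pl$n_in)
    dcur <- dcur + dtap[[if (s == 1L) 4L else s + 3L]]
    for (u in cfg$stage_units[s]:1L) {
      nm <- sprintf("fen_s%d_u%d", s, u)
      r <- unit_backward(net$params[[nm]], caches[[nm]], dcur)
      grads[[nm]] <- r$grads
      dcur <- r$dX
      if (s == 1L && u > 1L) dcur <- dcur + dtap[[u - 1L]]
    }
  }
  grads
}

unet_forward <- function(net, X, H, W, B, training = FALSE, pad = 0L,
                         keep_cache = FALSE) {
  cfg <- net$cfg
  caches <- list()
  stats <- list()
  skips <- list()
  skipdims <- list()
  cur <- X; h <- H; w <- W
  for (s in 1:5) {
    for (u in 1:2) {
      nm <- sprintf("enc_s%d_u%d", s, u)
      r <- unit_forward(net$params[[nm]], cur, h, w, B, training, pad, keep_cache)
      if (keep_cache) caches[[nm]] <- r$cache
      if (training) stats[[nm]] <- r$stats
      cur <- r$Y
    }
    if (s < 5L) {
      skips[[s]] <- cur
      skipdims[[s]] <- c(h, w)
      mp <- .cpp_maxpool_forward(cur, h, w, B)
      if (keep_cache)
        caches[[sprintf("pool%d", s)]] <- list(idx = mp$idx, n_in = nrow(cur))
      cur <- mp$Y
      h <- h %/% 2L; w <- w %/% 2L
      if (training && cfg$dropout > 0) {
        dr <- dropout_forward(cur, cfg$dropout)
        if (keep_cache) caches[[sprintf("drop%d", s)]] <- dr$mask
        cur <- dr$Y
      }
    }
  }
  skip_ch <- integer(4L)
  for (d in 4:1) {
    up <- .cpp_upsample_forward(cur, h, w, B, 2L, pad)
    h <- h * 2L; w <- w * 2L
    skip_ch[d] <- ncol(skips[[d]])
    if (keep_cache) caches[[sprintf("updim%d", d)]] <- c(h %/% 2L, w %/% 2L)
    cur <- cbind(skips[[d]], up)
    for (u in 1:2) {
      nm <- sprintf("dec_s%d_u%d", d, u)
      r <- unit_forward(net$params[[nm]], cur, h, w, B, training, pad, keep_cache)
      if (keep_cache) caches[[nm]] <- r$cache
      if (training) stats[[nm]] <- r$stats
      cur <- r$Y
    }
  }
  logits <- cur %*% net$params$cls$W +
    col_broadcast(net$params$cls$b, nrow(cur))
  P <- softmax_rows(logits)
  if (keep_cache) {
    caches[["cls_in"]] <- cur
    caches[["skip_ch"]] <- skip_ch
  }
  list(P = P, logits = logits, caches = caches, stats = stats)
}

unet_backward <- function(net, fwd, dLogits, H, W, B, pad = 0L) {
  caches <- fwd$caches
  grads <- list()
  grads[["cls"]] <- list(W = t(caches$cls_in) %*% dLogits,
                         b = colSums(dLogits))
  dcur <- dLogits %*% t(net$params$cls$W)
  dskip <- vector("list", 4L)
  for (d in 1:4) {
    for (u in 2:1) {
      nm <- sprintf("dec_s%d_u%d", d, u)
      r <- unit_backward(net$params[[nm]], caches[[nm]], dcur)
      grads[[nm]] <- r$grads
      dcur <- r$dX
    }
    nsk <- caches$skip_ch[d]
    dskip[[d]] <- dcur[, seq_len(nsk), drop = FALSE]
    dup <- dcur[, (nsk + 1L):ncol(dcur), drop = FALSE]
    dd <- caches[[sprintf("updim%d", d)]]
    dcur <- .cpp_upsample_backward(dup, dd[1L], dd[2L], B, 2L, pad)
  }
  for (s in 5:1) {
    if (s < 5L) {
      mask <- caches[[sprintf("drop%d", s)]]
      if (!is.null(mask)) dcur <- dcur * mask
      pl <- caches[[sprintf("pool%d", s)]]
      dcur <- .cpp_maxpool_backward(dcur, pl$idx, pl$n_in)
      dcur <- dcur + dskip[[s]]
    }
    for (u in 2:1) {
      nm <- sprintf("enc_s%d_u%d", s, u)
      r <- unit_backward(net$params[[nm]], caches[[nm]], dcur)
      grads[[nm]] <- r$grads
      dcur <- r$dX
    }
  }
  grads
}

net_forward <- function(net, X, H, W, B, training = FALSE, pad = 0L,
                        keep_cache = FALSE, tap_mask = NULL) {
  if (net$arch == "msffn") {
    msffn_forward(net, X, H, W, B, training, pad, keep_cache, tap_mask)
  } else {
    unet_forward(net, X, H, W, B, training, pad, keep_cache)
  }
}

net_backward <- function(net, fwd, dLogits, H, W, B, pad = 0L) {
  if (net$arch == "msffn") {
    msffn_backward(net, fwd, dLogits, H, W, B, pad)
  } else {
    unet_backward(net, fwd, dLogits, H, W, B, pad)
  }
}

## Stack a list of H x W x C image arrays into one (B*W*H) x C matrix.
images_to_batch <- function(images) {
  B <- length(images)
  d <- dim(images[[1L]])
  X <- matrix(0, B * d[1L] * d[2L], d[3L])
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * d[1L] * d[2L] + 1L):(b * d[1L] * d[2L])
    X[rows, ] <- matrix(images[[b]], d[1L] * d[2L], d[3L])
  }
  X
}

batch_to_images <- function(X, H, W, B) {
  lapply(seq_len(B), function(b) {
    rows <- ((b - 1L) * H * W + 1L):(b * H * W)
    array(X[rows, ], dim = c(H, W, ncol(X)))
  })
}

#' Per-pixel class probabilities for one slice image
#'
#' Runs the network forward in evaluation mode (dropout off, BN moving
#' statistics) and returns the softmax probability map.
#'
#' @param net A network built by [msffn_net()] or [unet_net()].
#' @param image `H x W x in_channels` array (channel order T1, T1c,
#'   T2, FLAIR), H = W divisible by 16.
#' @return `H x W x num_classes` probability array (per-pixel sum 1).
#' @export
predict_probs <- function(net, image) {
  stopifnot(inherits(net, "seg_net"))
  d <- dim(image)
  if (length(d) != 3L || d[3L] != net$cfg$in_channels)
    stop("image must be H x W x ", net$cfg$in_channels)
  if (d[1L] %% 16L != 0L || d[2L] %% 16L != 0L)
    stop("in-plane size must be divisible by 16; got ", d[1L], " x ", d[2L])
  fwd <- net_forward(net, images_to_batch(list(image)), d[1L], d[2L], 1L)
  array(fwd$P, dim = c(d[1L], d[2L], net$cfg$num_classes))
}

#' Multi-scale feature taps for one slice image
#'
#' Exposes the eight feature maps the fusing head consumes: the four
#' stage-1 unit outputs at full resolution plus the last-unit output of
#' stages 2-5 at their native resolutions (S/2, S/4, S/8, S/16).
#'
#' @inheritParams predict_probs
#' @return List of eight `h x w x c` arrays.
#' @export
fen_taps <- function(net, image) {
  stopifnot(inherits(net, "msffn_net"))
  d <- dim(image)
  fen <- fen_forward(net, images_to_batch(list(image)), d[1L], d[2L], 1L)
  lapply(seq_along(fen$taps), function(j) {
    dd <- fen$tapdims[[j]]
    array(fen$taps[[j]], dim = c(dd[1L], dd[2L], ncol(fen$taps[[j]])))
  })
}
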