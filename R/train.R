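#' Cyclical learning rate (triangular policy)
#'
#' Linear rise from `lr_min` to `lr_max` over `cycle_length` iterations
#' followed by a linear fall back; periodic with period
#' `2 * cycle_length` and bounded in `[lr_min, lr_max]`.
#'
#' @param iteration Zero-based iteration counter.
#' @param lr_min,lr_max Learning-rate bounds (defaults 1e-6 and 1e-3).
#' @param cycle_length Iterations per half-cycle.
#' @return Learning rate(s), vectorized over `iteration`.
#' @export
cyclical_lr <- function(iteration, lr_min = 1e-6, lr_max = 1e-3,
                        cycle_length = 2000L) {
  stopifnot(all(iteration >= 0), lr_min > 0, lr_min < lr_max,
            cycle_length >= 1)
  pos <- iteration %% (2 * cycle_length)
  lr_min + (lr_max - lr_min) * (1 - abs(pos / cycle_length - 1))
}

#' Case-level train/validation split
#'
#' Splits a list of cases into disjoint, exhaustive train and
#' validation partitions.  The split is always by case, never by
#' slice, and is reproducible given the seed.
#'
#' @param cases List of cases (or case identifiers).
#' @param validation_fraction Fraction held out (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `validation` sublists.
#' @export
split_dataset <- function(cases, validation_fraction = 0.2, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)")
  n <- length(cases)
  n_val <- max(1L, round(validation_fraction * n))
  if (n_val >= n) stop("not enough cases to split: n = ", n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx_val <- sort(sample.int(n, n_val))
  list(train = cases[setdiff(seq_len(n), idx_val)],
       validation = cases[idx_val])
}

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam, batch size 40,
#' cyclical learning rates between 1e-6 and 1e-3, flip/rotation
#' augmentation.  `cycle_length` defaults to four epochs' worth of
#' iterations.  `slices_per_case` caps how many axial slices per case
#' enter each epoch (sampled afresh every epoch) - the standard device
#' for training 2-D networks from volumes on a compute budget; `NULL`
#' uses every brain-content slice.
#'
#' @param batch_size Slices per optimizer step (default 40).
#' @param lr_min,lr_max Cyclical learning-rate bounds.
#' @param cycle_length Iterations per half-cycle (`NULL` = 4 epochs).
#' @param epochs Training epochs.
#' @param loss One of `"ce"`, `"sliced_dice"`, `"combined_dice"`,
#'   `"hl1"`, `"hl2"`.
#' @param weights Optional [loss_weights] override for the hybrids.
#' @param augment Apply random flips and 90-degree rotations.
#' @param keep_empty_slices Keep slices without brain content in the
#'   training pool.
#' @param slices_per_case Per-epoch slice subsample size per case.
#' @param tumor_slice_bias Fraction of each per-case subsample drawn
#'   preferentially from tumor-bearing slices (class-imbalance
#'   mitigation at the sampling level); 0 disables, default 0.5.
#'   Only active when `slices_per_case` is set.
#' @param val_slices_max Cap on the number of validation slices used
#'   for the per-epoch validation loss (drawn once, evenly across
#'   validation cases); `NULL` uses all brain-content slices.
#' @param seed Integer seed governing shuffling, augmentation and
#'   dropout.
#' @param verbose Print per-epoch progress.
#' @return A `train_control` list.
#' @export
train_control <- function(batch_size = 40L, lr_min = 1e-6, lr_max = 1e-3,
                          cycle_length = NULL, epochs = 10L,
                          loss = c("hl2", "hl1", "ce", "sliced_dice",
                                   "combined_dice"),
                          weights = NULL, augment = TRUE,
                          keep_empty_slices = FALSE, slices_per_case = NULL,
                          tumor_slice_bias = 0.5, val_slices_max = NULL,
                          seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (!(lr_min > 0 && lr_min < lr_max)) stop("need 0 < lr_min < lr_max")
  if (tumor_slice_bias < 0 || tumor_slice_bias > 1)
    stop("tumor_slice_bias must lie in [0, 1]")
  structure(list(batch_size = as.integer(batch_size), lr_min = lr_min,
                 lr_max = lr_max, cycle_length = cycle_length,
                 epochs = as.integer(epochs), loss = loss, weights = weights,
                 augment = augment, keep_empty_slices = keep_empty_slices,
                 slices_per_case = slices_per_case,
                 tumor_slice_bias = tumor_slice_bias,
                 val_slices_max = val_slices_max, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

## Crop (if needed) + normalize + slice one case for the given network
## input size.  Returns the slice list.
prepare_case_slices <- function(case, input_size, keep_empty = FALSE) {
  shp <- dim(case$volumes[[1L]])
  if (shp[1L] > input_size || shp[2L] > input_size)
    case <- crop_case(case, input_size)
  shp <- dim(case$volumes[[1L]])
  if (shp[1L] != input_size || shp[2L] != input_size)
    stop("case ", case$case_id, " is ", shp[1L], " x ", shp[2L],
         " in plane; the network expects ", input_size)
  case <- normalize_case(case)
  extract_slices(case, keep_empty = keep_empty)
}

slices_to_batch <- function(slices) {
  images_to_batch(lapply(slices, `[[`, "image"))
}

slices_to_onehot <- function(slices, K = 5L) {
  lab <- unlist(lapply(slices, function(s) as.vector(s$labels)))
  G <- matrix(0, length(lab), K)
  G[cbind(seq_along(lab), lab + 1L)] <- 1
  G
}

random_augment <- function(slice) {
  augment(slice, seed = NULL,
          flip_h = runif(1) < 0.5, flip_v = runif(1) < 0.5,
          k_rot = sample(0:3, 1L))
}

## Pooled region Dice of hard label vectors (prediction vs truth).
pooled_region_dsc <- function(pred_lab, true_lab) {
  vapply(EVAL_REGIONS, function(r) {
    mem <- region_spec(r)$member_labels
    dsc(pred_lab %in% mem, true_lab %in% mem)
  }, numeric(1))
}

eval_slices <- function(net, slices, batch_size, loss, weights) {
  S <- net$cfg$input_size
  n <- length(slices)
  Ps <- vector("list", ceiling(n / batch_size))
  i <- 1L; j <- 0L
  while (i <= n) {
    take <- slices[i:min(n, i + batch_size - 1L)]
    X <- slices_to_batch(take)
    fwd <- net_forward(net, X, S, S, length(take))
    j <- j + 1L
    Ps[[j]] <- fwd$P
    i <- i + batch_size
  }
  P <- do.call(rbind, Ps)
  G <- slices_to_onehot(slices, net$cfg$num_classes)
  pred_lab <- max.col(P) - 1L
  true_lab <- max.col(G) - 1L
  list(loss = seg_loss(P, G, loss, weights),
       dsc = pooled_region_dsc(pred_lab, true_lab))
}

#' Train a segmentation network
#'
#' Fits a network built by [msffn_net()] (or [unet_net()]) on a list of
#' labeled cases with Adam and a triangular cyclical learning rate,
#' selecting the best weights on the validation loss.  Cases are
#' cropped to the network input size, z-score normalized per modality,
#' decomposed into axial slices and optionally augmented with flips
#' and right-angle rotations.
#'
#' @param net A `seg_net` (untrained or to be fine-tuned).
#' @param train_cases Nonempty list of labeled [case_sample]s.
#' @param val_cases Optional list of labeled validation cases; without
#'   it the final weights are kept and no selection happens.
#' @param control A [train_control].
#' @return An object of class `msffn_fit` with elements `net` (the
#'   selected weights), `history` (per-epoch train/validation loss and
#'   validation region DSC), `best_epoch` and `control`.
#' @export
msffn_train <- function(net, train_cases, val_cases = NULL,
                        control = train_control()) {
  stopifnot(inherits(net, "seg_net"), inherits(control, "train_control"))
  if (!length(train_cases)) stop("empty training set")
  if (any(vapply(train_cases, function(cs) is.null(cs$labels), logical(1))))
    stop("all training cases must carry labels")
  set.seed(control$seed)
  S <- net$cfg$input_size
  train_pool <- lapply(train_cases, prepare_case_slices, input_size = S,
                       keep_empty = control$keep_empty_slices)
  val_slices <- NULL
  if (length(val_cases)) {
    val_slices <- unlist(lapply(val_cases, prepare_case_slices, input_size = S,
                                keep_empty = FALSE), recursive = FALSE)
    vmax <- control$val_slices_max
    if (!is.null(vmax) && length(val_slices) > vmax) {
      keep <- round(seq(1L, length(val_slices), length.out = vmax))
      val_slices <- val_slices[keep]
    }
  }
  spc <- control$slices_per_case
  n_epoch_slices <- sum(vapply(train_pool, function(p)
    if (is.null(spc)) length(p) else min(spc, length(p)), numeric(1)))
  steps_per_epoch <- max(1L, ceiling(n_epoch_slices / control$batch_size))
  cycle_length <- control$cycle_length %||% (4L * steps_per_epoch)
  opt <- adam_init(net$params)
  history <- NULL
  best_loss <- Inf
  best_params <- net$params
  best_epoch <- NA_integer_
  iter <- 0L
  for (epoch in seq_len(control$epochs)) {
    pool <- unlist(lapply(train_pool, function(p) {
      if (is.null(spc) || length(p) <= spc) return(p)
      bias <- control$tumor_slice_bias %||% 0
      has_tumor <- vapply(p, function(s)
        !is.null(s$labels) && any(s$labels > 0L), logical(1))
      n_t <- min(round(bias * spc), sum(has_tumor))
      it <- if (n_t > 0) sample(which(has_tumor), n_t) else integer(0)
      rest <- setdiff(seq_along(p), it)
      p[c(it, rest[sample.int(length(rest), spc - n_t)])]
    }), recursive = FALSE)
    pool <- pool[sample.int(length(pool))]
    epoch_loss <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(pool)) {
      batch <- pool[i:min(length(pool), i + control$batch_size - 1L)]
      if (control$augment) batch <- lapply(batch, random_augment)
      X <- slices_to_batch(batch)
      G <- slices_to_onehot(batch, net$cfg$num_classes)
      B <- length(batch)
      fwd <- net_forward(net, X, S, S, B, training = TRUE, keep_cache = TRUE)
      loss_val <- seg_loss(fwd$P, G, control$loss, control$weights)
      if (!is.finite(loss_val))
        stop("training diverged: non-finite ", control$loss, " at epoch ",
             epoch, ", iteration ", iter)
      dP <- seg_loss_grad(fwd$P, G, control$loss, control$weights)
      dLogits <- softmax_backward(fwd$P, dP)
      grads <- net_backward(net, fwd, dLogits, S, S, B)
      lr <- cyclical_lr(iter, control$lr_min, control$lr_max, cycle_length)
      upd <- adam_step(net$params, grads, opt, lr)
      net$params <- upd$params
      opt <- upd$state
      net <- update_bn_stats(net, fwd$stats)
      epoch_loss <- epoch_loss + loss_val
      nb <- nb + 1L
      iter <- iter + 1L
      i <- i + control$batch_size
    }
    row <- data.frame(epoch = epoch, train_loss = epoch_loss / nb,
                      val_loss = NA_real_, val_dsc_complete = NA_real_,
                      val_dsc_core = NA_real_, val_dsc_enhancing = NA_real_)
    if (!is.null(val_slices)) {
      ev <- eval_slices(net, val_slices, control$batch_size, control$loss,
                        control$weights)
      row$val_loss <- ev$loss
      row$val_dsc_complete <- ev$dsc[["complete"]]
      row$val_dsc_core <- ev$dsc[["core"]]
      row$val_dsc_enhancing <- ev$dsc[["enhancing"]]
      if (ev$loss < best_loss) {
        best_loss <- ev$loss
        best_params <- net$params
        best_epoch <- epoch
      }
    }
    history <- rbind(history, row)
    if (control$verbose)
      message(sprintf("epoch %d/%d: train %.4f val %.4f", epoch,
                      control$epochs, row$train_loss, row$val_loss))
  }
  if (is.null(val_slices)) {
    best_params <- net$params
    best_epoch <- control$epochs
  }
  net$params <- best_params
  structure(list(net = net, history = history, best_epoch = best_epoch,
                 control = control,
                 train_ids = vapply(train_cases, `[[`, "", "case_id"),
                 val_ids = if (length(val_cases))
                   vapply(val_cases, `[[`, "", "case_id") else character(0)),
            class = "msffn_fit")
}

#' @export
print.msffn_fit <- function(x, ...) {
  cat("<msffn_fit> ", x$net$arch, " trained ", nrow(x$history), " epochs on ",
      length(x$train_ids), " case(s), loss = ", x$control$loss, "\n", sep = "")
  if (!is.na(x$best_epoch)) {
    h <- x$history[x$best_epoch, ]
    cat(sprintf("  best epoch %d: val loss %.4f, val DSC %.3f/%.3f/%.3f (complete/core/enh)\n",
                x$best_epoch, h$val_loss, h$val_dsc_complete, h$val_dsc_core,
                h$val_dsc_enhancing))
  }
  invisible(x)
}

#' @export
summary.msffn_fit <- function(object, ...) {
  pc <- count_parameters(object$net)
  cat("Segmentation fit (", object$net$arch, ")\n", sep = "")
  cat("  parameters:", format(pc$count, big.mark = ","),
      sprintf("(%.1f MB)\n", pc$bytes / 1e6))
  cat("  loss:", object$control$loss, " epochs:", nrow(object$history),
      " batch:", object$control$batch_size, "\n")
  cat("  training cases:", length(object$train_ids),
      " validation cases:", length(object$val_ids), "\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.msffn_fit <- function(object, ...) object$net$params

#' @export
plot.msffn_fit <- function(x, ...) {
  h <- x$history
  rng <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16, ylim = rng,
                 xlab = "epoch", ylab = paste(x$control$loss, "loss"), ...)
  if (any(is.finite(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, type = "b", pch = 1, lty = 2)
    graphics::legend("topright", c("train", "validation"), pch = c(16, 1),
                     lty = c(1, 2), bty = "n")
  }
  invisible(h)
}

#' Save / load a fit or network checkpoint
#'
#' Checkpoints carry the full parameter set plus the configuration
#' metadata (channel order, input size), so a reloaded model predicts
#' identically.
#'
#' @param object An `msffn_fit` or `seg_net`.
#' @param path Checkpoint file path (`.rds`).
#' @return `save_checkpoint`: `path`, invisibly; `load_checkpoint`:
#'   the restored object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "msffn_fit") || inherits(object, "seg_net"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}

as_seg_net <- function(x) {
  if (inherits(x, "msffn_fit")) return(x$net)
  if (inherits(x, "seg_net")) return(x)
  stop("expected an msffn_fit or seg_net, got ", paste(class(x), collapse = "/"))
}

#' Segment one case
#'
#' Applies the training preprocessing (centered crop to the network
#' input size, per-modality z-scoring), runs every axial slice through
#' the network in evaluation mode, takes the per-pixel argmax over the
#' five classes and restacks the slices to the case's full Z extent.
#' For an ensemble, softmax maps are averaged across members before
#' the argmax (majority voting over member argmaxes is available via
#' `fuse = "vote"`).
#'
#' @param model An `msffn_fit`, `seg_net` or `msffn_ensemble`.
#' @param case A [case_sample].
#' @param batch_size Slices per forward pass.
#' @param fuse Ensemble fusion rule: `"average"` (default) or
#'   `"vote"`.
#' @return Predicted 3-D label volume (integer array, values 0..4).
#' @export
predict_case <- function(model, case, batch_size = 8L,
                         fuse = c("average", "vote")) {
  fuse <- match.arg(fuse)
  nets <- if (inherits(model, "msffn_ensemble")) model$nets
          else list(as_seg_net(model))
  S <- nets[[1L]]$cfg$input_size
  slices <- prepare_case_slices(case, S, keep_empty = TRUE)
  n <- length(slices)
  K <- nets[[1L]]$cfg$num_classes
  pred <- array(0L, dim = c(S, S, n))
  i <- 1L
  while (i <= n) {
    take <- slices[i:min(n, i + batch_size - 1L)]
    X <- slices_to_batch(take)
    B <- length(take)
    if (fuse == "average" || length(nets) == 1L) {
      P <- 0
      for (nt in nets) P <- P + net_forward(nt, X, S, S, B)$P
      lab <- max.col(P / length(nets), ties.method = "first") - 1L
    } else {
      votes <- matrix(0L, nrow(X), K)
      for (nt in nets) {
        l1 <- max.col(net_forward(nt, X, S, S, B)$P, ties.method = "first")
        votes[cbind(seq_along(l1), l1)] <- votes[cbind(seq_along(l1), l1)] + 1L
      }
      lab <- max.col(votes, ties.method = "first") - 1L
    }
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * S * S + 1L):(b * S * S)
      pred[, , i + b - 1L] <- matrix(lab[rows], S, S)
    }
    i <- i + B
  }
  pred
}

#' @export
predict.msffn_fit <- function(object, case, ...) {
  predict_case(object, case, ...)
}

#' Build a prediction ensemble
#'
#' @param members List of `msffn_fit`/`seg_net` objects or checkpoint
#'   file paths (typically the five models trained on re-seeded 80/20
#'   splits).
#' @return An object of class `msffn_ensemble`.
#' @export
build_ensemble <- function(members) {
  if (!length(members)) stop("empty ensemble")
  nets <- lapply(members, function(m) {
    if (is.character(m)) m <- load_checkpoint(m)
    as_seg_net(m)
  })
  sizes <- vapply(nets, function(nt) nt$cfg$input_size, integer(1))
  if (length(unique(sizes)) != 1L)
    stop("ensemble members disagree on input size")
  structure(list(nets = nets), class = "msffn_ensemble")
}

#' @export
print.msffn_ensemble <- function(x, ...) {
  cat("<msffn_ensemble> ", length(x$nets), " member(s), input ",
      x$nets[[1L]]$cfg$input_size, "\n", sep = "")
  invisible(x)
}

#' @export
predict.msffn_ensemble <- function(object, case, ...) {
  predict_case(object, case, ...)
}
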