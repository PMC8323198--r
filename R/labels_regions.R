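#' Evaluation region definitions
#'
#' The three overlapping tumor regions scored by the BRATS protocol,
#' plus background: complete tumor = labels \{1,2,3,4\}, tumor core =
#' \{1,3,4\}, enhancing tumor = \{4\}, background = \{0\}.
#'
#' @param name One of `"complete"`, `"core"`, `"enhancing"`,
#'   `"background"`, or an existing `region_spec`.
#' @return A `region_spec`: list with `name` and `member_labels`.
#' @export
region_spec <- function(name) {
  if (inherits(name, "region_spec")) return(name)
  name <- match.arg(name, c("complete", "core", "enhancing", "background"))
  members <- switch(name,
    complete = c(1L, 2L, 3L, 4L),
    core = c(1L, 3L, 4L),
    enhancing = 4L,
    background = 0L
  )
  structure(list(name = name, member_labels = members), class = "region_spec")
}

EVAL_REGIONS <- c("complete", "core", "enhancing")

#' One-hot encode a label image
#'
#' Channel index k corresponds to raw label value k (channel 1 of the
#' returned array is label 0), so region and loss formulas read off the
#' channels directly.
#'
#' @param labels 2-D integer matrix with values in `0:(K-1)`.
#' @param K Number of classes (default 5).
#' @return `H x W x K` array of 0/1 with per-pixel channel sum 1.
#' @export
one_hot <- function(labels, K = 5L) {
  bad <- setdiff(unique(as.vector(labels)), 0:(K - 1L))
  if (length(bad))
    stop("labels outside 0..", K - 1L, ": ", paste(bad, collapse = ", "))
  out <- array(0, dim = c(dim(labels), K))
  for (k in 0:(K - 1L)) out[, , k + 1L] <- (labels == k) * 1
  out
}

#' Soft region membership from a probability map
#'
#' Per-pixel sum of the softmax channels belonging to the region's
#' member labels (e.g. complete tumor = p1 + p2 + p3 + p4).
#'
#' @param probs `H x W x K` probability array (or `N x K` matrix).
#' @param region Region name or `region_spec`.
#' @return 2-D array (or vector for matrix input) of soft memberships
#'   in `[0, 1]`.
#' @export
region_soft <- function(probs, region) {
  region <- region_spec(region)
  ch <- region$member_labels + 1L
  if (is.matrix(probs)) {
    if (length(ch) == 1L) return(probs[, ch]) else return(rowSums(probs[, ch, drop = FALSE]))
  }
  nd <- length(dim(probs))
  if (nd != 3L) stop("`probs` must be an H x W x K array or N x K matrix")
  out <- probs[, , ch[1L]]
  for (c2 in ch[-1L]) out <- out + probs[, , c2]
  out
}

#' Hard region mask from a label image
#'
#' @param labels Integer array (2-D or 3-D) of labels in `0:4`.
#' @param region Region name or `region_spec`.
#' @return Binary mask (same shape) with 1 where the label belongs to
#'   the region.
#' @export
region_hard <- function(labels, region) {
  region <- region_spec(region)
  mask <- array(as.integer(labels %in% region$member_labels), dim = dim(labels))
  mask
}
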