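#' Center-crop a case in plane
#'
#' Crops every modality (and the label volume, if present) to
#' `size x size` in plane with an identical, centered crop window,
#' leaving the slice (Z) axis untouched.  For the standard 240 x 240
#' BRATS grid and the default size this removes a 32-voxel border on
#' each side, discarding only air around the skull-stripped brain.
#'
#' @param case A [case_sample].
#' @param size Target in-plane size in pixels (default 176).
#' @return The cropped [case_sample].
#' @export
crop_case <- function(case, size = 176L) {
  stopifnot(inherits(case, "case_sample"))
  shp <- dim(case$volumes[[1L]])
  if (shp[1L] < size || shp[2L] < size)
    stop("in-plane dimensions ", shp[1L], " x ", shp[2L],
         " are smaller than the crop size ", size)
  off <- floor((shp[1:2] - size) / 2)
  ix <- (off[1L] + 1L):(off[1L] + size)
  iy <- (off[2L] + 1L):(off[2L] + size)
  vols <- lapply(case$volumes, function(v) v[ix, iy, , drop = FALSE])
  labels <- if (!is.null(case$labels)) case$labels[ix, iy, , drop = FALSE] else NULL
  out <- case_sample(case$case_id, vols, labels = labels, spacing = case$spacing)
  attr(out, "crop_offset") <- off
  out
}

#' Z-score normalize a volume
#'
#' Rescales to zero mean and unit standard deviation over all voxels.
#' A constant volume (zero variance) is mapped to all zeros with a
#' warning.  Statistics use the population (1/n) variance so the result
#' has unit SD in the same convention.
#'
#' @param x Numeric array (any shape).
#' @return Array of the same shape with mean 0 and SD 1 (or all zeros).
#' @export
zscore_normalize <- function(x) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v == 0) {
    warning("constant volume: z-score normalization returns all zeros")
    out <- array(0, dim = dim(x))
    attributes(out) <- attributes(x)
    if (is.null(dim(out))) dim(out) <- dim(x)
    return(out)
  }
  (x - mu) / sqrt(v)
}

#' Z-score normalize every modality of a case
#'
#' Normalization statistics are computed per modality per case over all
#' voxels of the (cropped) volume.  A brain mask taken on the raw
#' intensities (any nonzero voxel in any modality) is attached so that
#' slice filtering still works after air voxels stop being exactly zero.
#'
#' @param case A [case_sample].
#' @return The normalized [case_sample] with a `brain_mask` attribute.
#' @export
normalize_case <- function(case) {
  stopifnot(inherits(case, "case_sample"))
  mask <- Reduce(`|`, lapply(case$volumes, function(v) v != 0))
  vols <- lapply(case$volumes, zscore_normalize)
  out <- case_sample(case$case_id, vols, labels = case$labels, spacing = case$spacing)
  attr(out, "brain_mask") <- mask
  out
}

#' Decompose a case into axial slice samples
#'
#' Produces one sample per retained axial (Z) index.  Each sample's
#' image is an `H x W x 4` array with fixed channel order T1, T1c, T2,
#' FLAIR.  With `keep_empty = FALSE` only slices with brain content
#' (at least one voxel inside the brain mask) are retained; prediction
#' pipelines keep every slice.
#'
#' @param case A [case_sample] (typically cropped and normalized).
#' @param keep_empty Keep slices with no brain content? Default `TRUE`.
#' @param brain_mask Optional logical 3-D array marking brain voxels;
#'   defaults to the `brain_mask` attribute left by [normalize_case()],
#'   falling back to nonzero voxels of the stored images.
#' @return List of `slice_sample` objects (fields `image`, `labels`,
#'   `case_id`, `slice_index`).
#' @export
extract_slices <- function(case, keep_empty = TRUE, brain_mask = NULL) {
  stopifnot(inherits(case, "case_sample"))
  shp <- dim(case$volumes[[1L]])
  if (is.null(brain_mask)) brain_mask <- attr(case, "brain_mask")
  if (is.null(brain_mask))
    brain_mask <- Reduce(`|`, lapply(case$volumes, function(v) v != 0))
  out <- vector("list", shp[3L])
  kept <- logical(shp[3L])
  for (z in seq_len(shp[3L])) {
    if (!keep_empty && !any(brain_mask[, , z])) next
    img <- array(0, dim = c(shp[1L], shp[2L], 4L))
    for (j in seq_along(MODALITIES)) img[, , j] <- case$volumes[[MODALITIES[j]]][, , z]
    out[[z]] <- structure(
      list(image = img,
           labels = if (!is.null(case$labels)) case$labels[, , z] else NULL,
           case_id = case$case_id, slice_index = z),
      class = "slice_sample"
    )
    kept[z] <- TRUE
  }
  out[kept]
}

#' Reassemble axial slices into volumes
#'
#' Inverse of [extract_slices()] over a full set of slices: restacks
#' images (and labels, when present) along Z in `slice_index` order.
#'
#' @param slices List of `slice_sample` objects covering every Z index.
#' @return List with `volumes` (named list of four 3-D arrays) and
#'   `labels` (3-D array or `NULL`).
#' @export
reassemble_slices <- function(slices) {
  idx <- vapply(slices, function(s) s$slice_index, integer(1))
  slices <- slices[order(idx)]
  shp <- dim(slices[[1L]]$image)
  nz <- length(slices)
  vols <- lapply(seq_len(4L), function(j) {
    v <- array(0, dim = c(shp[1L], shp[2L], nz))
    for (i in seq_len(nz)) v[, , i] <- slices[[i]]$image[, , j]
    v
  })
  names(vols) <- MODALITIES
  labels <- NULL
  if (!is.null(slices[[1L]]$labels)) {
    labels <- array(0L, dim = c(shp[1L], shp[2L], nz))
    for (i in seq_len(nz)) labels[, , i] <- slices[[i]]$labels
  }
  list(volumes = vols, labels = labels)
}

rot90_once <- function(m) t(m[nrow(m):1L, , drop = FALSE])

apply_plane_transform <- function(m, flip_h, flip_v, k_rot) {
  if (flip_h) m <- m[nrow(m):1L, , drop = FALSE]
  if (flip_v) m <- m[, ncol(m):1L, drop = FALSE]
  k_rot <- k_rot %% 4L
  for (i in seq_len(k_rot)) m <- rot90_once(m)
  m
}

#' Spatially augment a slice sample
#'
#' Applies a random (or explicitly requested) combination of
#' horizontal/vertical flips and 90-degree rotations.  Image channels
#' and labels undergo the identical spatial map, so right-angle
#' transforms are label-exact (no interpolation) and preserve the
#' per-slice count of every label.
#'
#' @param slice A `slice_sample`.
#' @param seed Integer seed drawing the random transform; the same seed
#'   always yields the same output.
#' @param flip_h,flip_v,k_rot Explicit transform (used when `seed` is
#'   `NULL`): flips along the two in-plane axes and number of
#'   90-degree rotations.
#' @return The augmented `slice_sample`.
#' @export
augment <- function(slice, seed = NULL, flip_h = FALSE, flip_v = FALSE,
                    k_rot = 0L) {
  stopifnot(inherits(slice, "slice_sample"))
  if (!is.null(seed)) {
    rs <- sample_transform(seed)
    flip_h <- rs$flip_h; flip_v <- rs$flip_v; k_rot <- rs$k_rot
  }
  img <- slice$image
  out <- NULL
  for (j in seq_len(dim(img)[3L])) {
    tr <- apply_plane_transform(img[, , j], flip_h, flip_v, k_rot)
    if (is.null(out)) out <- array(0, dim = c(dim(tr), dim(img)[3L]))
    out[, , j] <- tr
  }
  slice$image <- out
  if (!is.null(slice$labels))
    slice$labels <- apply_plane_transform(slice$labels, flip_h, flip_v, k_rot)
  slice
}

sample_transform <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  list(flip_h = runif(1) < 0.5, flip_v = runif(1) < 0.5,
       k_rot = sample(0:3, 1L))
}
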