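## Synthetic multimodal brain-tumor phantoms.
##
## Each phantom is an ellipsoidal "brain" inside a dark background with,
## usually, one tumor built from nested ellipsoidal sub-regions sharing
## a common center: an edema shell (label 2) around a core partitioned
## into a necrotic center (1), a non-enhancing band (3) and an enhancing
## rim (4).  All nested surfaces are level sets of one perturbed
## ellipsoidal distance field, so the nesting enhancing <= core <=
## complete holds by construction.  Modality intensities follow a fixed
## table mimicking clinical contrast (T1c-bright enhancing rim,
## FLAIR-bright edema, T1-dark necrosis) plus Gaussian noise.

#' Phantom generation parameters
#'
#' @param volume_shape Integer 3-vector; default `c(64, 64, 32)` (test
#'   scale; up to `c(176, 176, 155)` for paper-scale volumes).
#' @param brain_axes_frac Semi-axes of the brain ellipsoid as fractions
#'   of each half-dimension.
#' @param tumor_probability Probability that a case carries a tumor.
#' @param edema_radius_frac Range (min, max) of the edema semi-axis as
#'   a fraction of the smallest volume dimension.
#' @param core_frac Core radius as a fraction of the edema radius.
#' @param necrosis_frac Necrotic-center radius as a fraction of the
#'   core radius.
#' @param enhancing_frac Inner radius of the enhancing rim as a
#'   fraction of the core radius (the rim spans from this to the core
#'   boundary).
#' @param perturb_amp Amplitude of the low-frequency boundary
#'   perturbation (fraction of the local radius).
#' @param intensity_table 6 x 4 numeric matrix of mean intensities,
#'   rows `air`, `brain`, `necrosis`, `edema`, `nonenhancing`,
#'   `enhancing`, columns T1, T1c, T2, FLAIR.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(volume_shape = c(64L, 64L, 32L),
                           brain_axes_frac = c(0.80, 0.80, 0.85),
                           tumor_probability = 0.95,
                           edema_radius_frac = c(0.16, 0.26),
                           core_frac = 0.62,
                           necrosis_frac = 0.40,
                           enhancing_frac = 0.72,
                           perturb_amp = 0.08,
                           intensity_table = default_intensity_table(),
                           noise_sd = 10) {
  if (length(volume_shape) != 3L || any(volume_shape < 8L))
    stop("volume_shape must be 3 dimensions of at least 8 voxels")
  if (!(necrosis_frac < enhancing_frac && enhancing_frac < 1))
    stop("radii must nest: necrosis_frac < enhancing_frac < 1")
  if (!(core_frac > 0 && core_frac < 1))
    stop("core_frac must lie in (0, 1) so the edema shell surrounds the core")
  stopifnot(length(edema_radius_frac) == 2L,
            edema_radius_frac[1L] <= edema_radius_frac[2L],
            noise_sd > 0)
  it <- intensity_table
  if (!identical(dim(it), c(6L, 4L)))
    stop("intensity_table must be 6 tissues x 4 modalities")
  structure(list(
    volume_shape = as.integer(volume_shape),
    brain_axes_frac = brain_axes_frac,
    tumor_probability = tumor_probability,
    edema_radius_frac = edema_radius_frac,
    core_frac = core_frac, necrosis_frac = necrosis_frac,
    enhancing_frac = enhancing_frac, perturb_amp = perturb_amp,
    intensity_table = it, noise_sd = noise_sd
  ), class = "phantom_params")
}

#' Default tissue-by-modality mean intensity table
#'
#' Arbitrary but fixed values chosen to mimic clinical contrast:
#' enhancing rim bright on T1c, edema bright on FLAIR/T2, necrosis dark
#' on T1.  Units are arbitrary scanner units; separations are several
#' multiples of the default noise SD so the segmentation task is
#' learnable.
#'
#' @return 6 x 4 matrix, rows air/brain/necrosis/edema/nonenhancing/
#'   enhancing, columns T1/T1c/T2/FLAIR.
#' @export
default_intensity_table <- function() {
  m <- rbind(
    air          = c(0,   0,   0,   0),
    brain        = c(100, 100, 80,  70),
    necrosis     = c(40,  45,  110, 90),
    edema        = c(80,  85,  120, 130),
    nonenhancing = c(60,  70,  100, 105),
    enhancing    = c(90,  160, 95,  100)
  )
  colnames(m) <- c("T1", "T1c", "T2", "FLAIR")
  m
}

## Normalized squared ellipsoidal distance field for center ctr and
## semi-axes ax, on the voxel grid of shape shp.  Returns an array where
## the surface {d = 1} is the ellipsoid boundary.
ellipsoid_field <- function(shp, ctr, ax) {
  x <- (seq_len(shp[1L]) - ctr[1L]) / ax[1L]
  y <- (seq_len(shp[2L]) - ctr[2L]) / ax[2L]
  z <- (seq_len(shp[3L]) - ctr[3L]) / ax[3L]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

## Smooth low-frequency multiplicative boundary perturbation in [1-amp, 1+amp].
perturb_field <- function(shp, amp) {
  ph <- runif(6L, 0, 2 * pi)
  fr <- runif(3L, 1, 2.2)
  x <- seq_len(shp[1L]) / shp[1L]; y <- seq_len(shp[2L]) / shp[2L]
  z <- seq_len(shp[3L]) / shp[3L]
  fx <- sin(2 * pi * fr[1L] * x + ph[1L]) + 0.5 * sin(4 * pi * x + ph[4L])
  fy <- sin(2 * pi * fr[2L] * y + ph[2L]) + 0.5 * sin(4 * pi * y + ph[5L])
  fz <- sin(2 * pi * fr[3L] * z + ph[3L]) + 0.5 * sin(4 * pi * z + ph[6L])
  f <- outer(outer(fx, fy, `+`), fz, `+`) / 4.5
  1 + amp * f
}

#' Generate one multimodal phantom case
#'
#' Deterministic given `seed`: the same seed always reproduces the
#' identical case bitwise.
#'
#' @param params A [phantom_params].
#' @param seed Integer seed.
#' @param case_id Case identifier (default derived from the seed).
#' @return A [case_sample] with labels.
#' @export
generate_case <- function(params = phantom_params(), seed = 1L,
                          case_id = sprintf("phantom_%05d", seed)) {
  stopifnot(inherits(params, "phantom_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shp <- params$volume_shape
  half <- shp / 2
  brain_ax <- params$brain_axes_frac * half
  brain_ctr <- half + runif(3L, -0.03, 0.03) * shp
  brain <- ellipsoid_field(shp, brain_ctr, brain_ax) *
    perturb_field(shp, params$perturb_amp / 2) < 1
  labels <- array(0L, dim = shp)
  if (runif(1L) < params$tumor_probability) {
    r_ed <- runif(1L, params$edema_radius_frac[1L], params$edema_radius_frac[2L]) *
      min(shp)
    ## center placed so the whole edema ellipsoid stays inside the brain
    margin <- 1 - 1.15 * r_ed / min(brain_ax)
    margin <- max(margin, 0.05)
    repeat {
      u <- runif(3L, -margin, margin)
      if (sum(u^2 / margin^2) <= 1) break
    }
    ctr <- brain_ctr + u * brain_ax
    anis <- runif(3L, 0.8, 1.2)
    d <- ellipsoid_field(shp, ctr, r_ed * anis / mean(anis)) *
      perturb_field(shp, params$perturb_amp)
    ## one shared field, nested thresholds: necro < enh_inner < core < edema
    t_core <- params$core_frac^2
    t_necro <- t_core * params$necrosis_frac^2
    t_enh <- t_core * params$enhancing_frac^2
    labels[d < 1] <- 2L                      # edema shell (trimmed below)
    labels[d < t_core] <- 3L                 # non-enhancing band
    labels[d >= t_enh & d < t_core] <- 4L    # enhancing rim
    labels[d < t_necro] <- 1L                # necrotic center
    labels[!brain] <- 0L                     # clip anything leaking outside
  }
  tissue <- array(1L, dim = shp)             # 1 = air row
  tissue[brain] <- 2L                        # brain
  tissue[labels == 1L] <- 3L
  tissue[labels == 2L] <- 4L
  tissue[labels == 3L] <- 5L
  tissue[labels == 4L] <- 6L
  vols <- lapply(seq_len(4L), function(m) {
    mu <- params$intensity_table[tissue, m]
    v <- array(mu + rnorm(length(mu), sd = params$noise_sd), dim = shp)
    v[tissue == 1L] <- 0                     # clean air background
    v
  })
  names(vols) <- MODALITIES
  case_sample(case_id, vols, labels = labels)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_cases` complete cases in the BRATS-style layout (one
#' directory per case, one file per modality plus a ground-truth file
#' `OT`), readable back via [index_dataset()] and [read_case()].
#'
#' @param n_cases Number of cases.
#' @param params A [phantom_params].
#' @param seed Integer seed; case i uses `seed + i - 1`.
#' @param out_dir Output directory (created if needed).
#' @param format `"mha"` (default) or `"nifti"`.
#' @return `out_dir`, invisibly.
#' @export
generate_dataset <- function(n_cases, params = phantom_params(), seed = 1L,
                             out_dir, format = c("mha", "nifti")) {
  format <- match.arg(format)
  ext <- if (format == "mha") "mha" else "nii"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_cases)) {
    cs <- generate_case(params, seed = seed + i - 1L)
    cdir <- file.path(out_dir, cs$case_id)
    dir.create(cdir, showWarnings = FALSE)
    for (m in MODALITIES) {
      tok <- if (m == "FLAIR") "Flair" else m
      write_volume(cs$volumes[[m]],
                   file.path(cdir, sprintf("%s_%s.%s", cs$case_id, tok, ext)),
                   format = format, spacing = cs$spacing)
    }
    write_labelmap(cs$labels,
                   file.path(cdir, sprintf("%s_OT.%s", cs$case_id, ext)),
                   format = format, spacing = cs$spacing)
  }
  invisible(out_dir)
}

#' Generate a list of phantom cases in memory
#'
#' @inheritParams generate_dataset
#' @return List of [case_sample] objects.
#' @export
generate_cohort <- function(n_cases, params = phantom_params(), seed = 1L) {
  lapply(seq_len(n_cases), function(i) generate_case(params, seed = seed + i - 1L))
}
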