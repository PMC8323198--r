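#' @useDynLib msffn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif predict coef
#' @importFrom utils write.csv head
NULL

MODALITIES <- c("T1", "T1c", "T2", "FLAIR")
LABEL_SET <- 0:4

#' Construct a multimodal MRI case
#'
#' Bundles the four co-registered sequences of one case (T1, T1c, T2,
#' FLAIR) with an optional ground-truth label volume.  All volumes must
#' share an identical 3-D shape; axial slices are taken along the third
#' (Z) axis.
#'
#' @param case_id Character scalar identifying the case.
#' @param volumes Named list of four 3-D numeric arrays, names `T1`,
#'   `T1c`, `T2`, `FLAIR`.
#' @param labels Optional 3-D integer array with values in `0:4`
#'   (0 background, 1 necrosis, 2 edema, 3 non-enhancing, 4 enhancing).
#' @param spacing Numeric vector of 3 positive voxel sizes in mm.
#' @return An object of class `case_sample`.
#' @export
case_sample <- function(case_id, volumes, labels = NULL, spacing = c(1, 1, 1)) {
  if (!is.character(case_id) || length(case_id) != 1L)
    stop("`case_id` must be a single string")
  if (!is.list(volumes) || !setequal(names(volumes), MODALITIES))
    stop("`volumes` must be a named list with elements T1, T1c, T2, FLAIR")
  volumes <- volumes[MODALITIES]
  shp <- dim(volumes[[1L]])
  for (m in MODALITIES) {
    v <- volumes[[m]]
    if (!is.numeric(v) || length(dim(v)) != 3L)
      stop("modality ", m, " must be a 3-D numeric array")
    if (!identical(dim(v), shp))
      stop("modality ", m, " shape differs from T1: all volumes must be co-registered")
  }
  if (!is.null(labels)) {
    labels <- validate_labels(labels)
    if (!identical(dim(labels), shp))
      stop("label volume shape differs from the modality volumes")
  }
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel sizes")
  structure(
    list(case_id = case_id, volumes = volumes, labels = labels,
         spacing = as.numeric(spacing)),
    class = "case_sample"
  )
}

#' @export
print.case_sample <- function(x, ...) {
  shp <- dim(x$volumes[[1L]])
  cat("<case_sample> ", x$case_id, ": ", paste(shp, collapse = " x "),
      ", 4 modalities",
      if (!is.null(x$labels)) ", labeled" else ", unlabeled", "\n", sep = "")
  invisible(x)
}

validate_labels <- function(labels) {
  if (length(dim(labels)) != 3L)
    stop("label volume must have exactly 3 axes")
  bad <- setdiff(unique(as.vector(labels)), LABEL_SET)
  if (length(bad))
    stop("label volume contains invalid value(s): ",
         paste(bad, collapse = ", "), " (allowed: 0..4)")
  storage.mode(labels) <- "integer"
  labels
}

## ---- MetaImage (MHA) ----------------------------------------------------
## Minimal MetaImage support: uncompressed, local data, the element types
## BRATS-style pipelines use.  Header is plain "Key = Value" text followed
## by raw little-endian voxel data.

MHA_TYPES <- c(
  MET_UCHAR = "uchar", MET_CHAR = "char", MET_SHORT = "short",
  MET_USHORT = "ushort", MET_INT = "int",
  MET_FLOAT = "float", MET_DOUBLE = "double"
)

#' Read a MetaImage (.mha) volume
#'
#' @param path Path to an uncompressed `.mha` file with local data.
#' @return A 3-D array with attribute `spacing` (voxel size per axis).
#' @export
read_mha <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("unexpected end of MHA header in ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L) stop("malformed MHA header line: ", line)
    hdr[[kv[2L]]] <- trimws(kv[3L])
    if (kv[2L] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only ElementDataFile = LOCAL is supported")
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MHA data is not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  if (length(dims) != 3L) stop("expected a 3-D volume, got DimSize = ", hdr$DimSize)
  type <- hdr$ElementType
  if (!type %in% names(MHA_TYPES)) stop("unsupported ElementType: ", type)
  n <- prod(dims)
  swap <- FALSE
  msb <- hdr$BinaryDataByteOrderMSB
  if (is.null(msb)) msb <- hdr$ElementByteOrderMSB
  if (!is.null(msb) && toupper(msb) == "TRUE") swap <- .Platform$endian == "little"
  endian <- if (swap) "big" else "little"
  data <- switch(
    MHA_TYPES[[type]],
    uchar  = as.integer(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    char   = readBin(con, "integer", n, size = 1L, signed = TRUE),
    short  = readBin(con, "integer", n, size = 2L, signed = TRUE, endian = endian),
    ushort = readBin(con, "integer", n, size = 2L, signed = FALSE, endian = endian),
    int    = readBin(con, "integer", n, size = 4L, endian = endian),
    float  = readBin(con, "numeric", n, size = 4L, endian = endian),
    double = readBin(con, "numeric", n, size = 8L, endian = endian)
  )
  if (length(data) != n) stop("truncated MHA data in ", path)
  arr <- array(data, dim = dims)
  spacing <- hdr$ElementSpacing
  attr(arr, "spacing") <- if (is.null(spacing)) c(1, 1, 1)
                          else as.numeric(strsplit(spacing, "\\s+")[[1L]])
  arr
}

#' Write a MetaImage (.mha) volume
#'
#' @param x 3-D numeric or integer array.
#' @param path Output path.
#' @param spacing Voxel size per axis in mm.
#' @param element_type `"uchar"` (labels), `"float"` or `"double"`.
#' @return `path`, invisibly.
#' @export
write_mha <- function(x, path, spacing = c(1, 1, 1),
                      element_type = c("float", "uchar", "short", "double")) {
  element_type <- match.arg(element_type)
  if (length(dim(x)) != 3L) stop("`x` must be a 3-D array")
  met <- names(MHA_TYPES)[match(element_type, MHA_TYPES)]
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    "Offset = 0 0 0",
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    paste("ElementSpacing =", paste(format(spacing, trim = TRUE), collapse = " ")),
    paste("DimSize =", paste(dim(x), collapse = " ")),
    paste("ElementType =", met),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  v <- as.vector(x)
  switch(element_type,
    uchar  = writeBin(as.integer(v), con, size = 1L, endian = "little"),
    short  = writeBin(as.integer(v), con, size = 2L, endian = "little"),
    float  = writeBin(as.numeric(v), con, size = 4L, endian = "little"),
    double = writeBin(as.numeric(v), con, size = 8L, endian = "little")
  )
  invisible(path)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_mha_path <- function(path) grepl("\\.mha$", path, ignore.case = TRUE)

#' Read one volume (intensity image or label map)
#'
#' Reads an MHA or NIfTI-1 volume.  Axis order on disk is preserved:
#' the array axes are (X, Y, Z) exactly as stored, no reorientation is
#' applied.  Label reads are validated against the allowed value set
#' `0:4`.
#'
#' @param path Path to a `.mha`, `.nii` or `.nii.gz` file.
#' @param kind `"intensity"` (float data) or `"label"` (values 0..4).
#' @return A 3-D array with `spacing` attribute; labels have integer
#'   storage mode.
#' @export
read_volume <- function(path, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_mha_path(path)) {
    arr <- read_mha(path)
  } else if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim = dim(img))
    attr(arr, "spacing") <- RNifti::pixdim(img)[seq_len(3L)]
  } else {
    stop("unsupported volume format (expect .mha, .nii or .nii.gz): ", path)
  }
  if (kind == "label") {
    sp <- attr(arr, "spacing")
    arr <- validate_labels(arr)
    attr(arr, "spacing") <- sp
  }
  arr
}

#' Write a label map to disk
#'
#' Labels are stored as unsigned 8-bit integers, the smallest type
#' holding the BRATS label set `{0..4}`.  `read_volume()` of the written
#' file reproduces the input voxel-for-voxel.
#'
#' @param labels 3-D integer array with values in `0:4`.
#' @param path Output file path.
#' @param format `"mha"` or `"nifti"`; defaults to the extension of
#'   `path`, falling back to MHA.
#' @param spacing Voxel size per axis in mm.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(labels, path, format = NULL, spacing = c(1, 1, 1)) {
  labels <- validate_labels(labels)
  if (is.null(format)) {
    format <- if (is_nifti_path(path)) "nifti" else "mha"
  }
  format <- match.arg(format, c("mha", "nifti"))
  if (format == "mha") {
    write_mha(labels, path, spacing = spacing, element_type = "uchar")
  } else {
    img <- RNifti::asNifti(labels, internal = FALSE)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
  }
  invisible(path)
}

#' Write an intensity volume to disk
#'
#' @param x 3-D numeric array.
#' @inheritParams write_labelmap
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, format = NULL, spacing = c(1, 1, 1)) {
  if (is.null(format)) {
    format <- if (is_nifti_path(path)) "nifti" else "mha"
  }
  format <- match.arg(format, c("mha", "nifti"))
  if (format == "mha") {
    write_mha(x, path, spacing = spacing, element_type = "float")
  } else {
    img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)),
                           internal = FALSE)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path, datatype = "float")
  }
  invisible(path)
}

## ---- dataset indexing ---------------------------------------------------

match_modality_file <- function(files, token) {
  ## BRATS-style matching: any file whose name contains the modality token.
  ## Guard T1 against matching T1c by excluding files that carry the T1c token.
  pat <- paste0("(^|[._-])", token, "([._-]|$)")
  hit <- grepl(pat, tools::file_path_sans_ext(basename(files), compression = TRUE),
               ignore.case = TRUE)
  if (tolower(token) == "t1") {
    t1c <- grepl("(^|[._-])t1c([._-]|$)",
                 tools::file_path_sans_ext(basename(files), compression = TRUE),
                 ignore.case = TRUE)
    hit <- hit & !t1c
  }
  files[hit]
}

#' Index a BRATS-style dataset directory
#'
#' Expects one sub-directory per case, each containing one volume file
#' per modality (file name carrying the modality token `T1`, `T1c`,
#' `T2` or `Flair`) and optionally a ground-truth file (token `OT`).
#' Cases missing a modality are reported, never silently dropped.
#'
#' @param root Dataset root directory.
#' @return A list with `cases` (one descriptor per complete case:
#'   `case_id`, per-modality `paths`, optional `label_path`) and
#'   `skipped` (data frame of incomplete cases and what they lack).
#' @export
index_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  case_dirs <- list.dirs(root, recursive = FALSE)
  cases <- list()
  skipped <- data.frame(case_id = character(), missing = character(),
                        stringsAsFactors = FALSE)
  for (d in case_dirs) {
    files <- list.files(d, pattern = "\\.(mha|nii|nii\\.gz)$",
                        recursive = TRUE, full.names = TRUE, ignore.case = TRUE)
    paths <- character(0)
    missing <- character(0)
    for (m in MODALITIES) {
      token <- if (m == "FLAIR") "Flair" else m
      hit <- match_modality_file(files, token)
      if (length(hit) >= 1L) paths[[m]] <- hit[[1L]] else missing <- c(missing, m)
    }
    if (length(missing)) {
      skipped <- rbind(skipped, data.frame(
        case_id = basename(d), missing = paste(missing, collapse = ","),
        stringsAsFactors = FALSE))
      next
    }
    ot <- match_modality_file(files, "OT")
    cases[[length(cases) + 1L]] <- list(
      case_id = basename(d),
      paths = paths,
      label_path = if (length(ot)) ot[[1L]] else NULL
    )
  }
  if (!length(case_dirs)) warning("dataset root contains no case directories: ", root)
  if (nrow(skipped)) warning(nrow(skipped), " incomplete case(s) skipped; see $skipped")
  list(cases = cases, skipped = skipped)
}

#' Load one indexed case from disk
#'
#' @param descriptor One element of `index_dataset()$cases`.
#' @return A [case_sample].
#' @export
read_case <- function(descriptor) {
  vols <- lapply(descriptor$paths, read_volume, kind = "intensity")
  names(vols) <- names(descriptor$paths)
  spacing <- attr(vols[[1L]], "spacing")
  labels <- if (!is.null(descriptor$label_path))
    read_volume(descriptor$label_path, kind = "label") else NULL
  case_sample(descriptor$case_id, vols, labels = labels, spacing = spacing)
}
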