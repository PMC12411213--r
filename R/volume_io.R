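#' @useDynLib nwuct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang abort .data
NULL

HU_SENTINEL <- -1024

#' CT volume container
#'
#' A 3-D scalar field in Hounsfield units together with its geometry: voxel
#' spacing in mm, a 4x4 affine mapping 0-based voxel indices to world
#' coordinates (mm), and the canonical orientation code. All pipeline
#' functions assume volumes are in right-anterior-superior (RAS) orientation,
#' which `read_nifti()` and `read_dicom_series()` guarantee.
#'
#' @param data 3-D numeric array of intensities in HU.
#' @param affine 4x4 numeric matrix mapping voxel index `(i,j,k,1)` (0-based,
#'   index `(0,0,0)` at that voxel's world centre) to world mm.
#' @param orientation three-letter orientation code, normally `"RAS"`.
#' @return An object of class `ct_volume` with fields `data`, `spacing`,
#'   `affine`, `orientation`.
#' @export
ct_volume <- function(data, affine = NULL, orientation = "RAS") {
  if (length(dim(data)) != 3L) {
    abort(sprintf("`data` must be a 3-D array, got dimensions [%s]",
                  paste(dim(data), collapse = ", ")),
          class = "nwuct_dim_error")
  }
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12) {
    abort("`affine` must be an invertible 4x4 matrix",
          class = "nwuct_affine_error")
  }
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) {
    abort("voxel spacing must be strictly positive", class = "nwuct_affine_error")
  }
  structure(list(data = data, spacing = spacing, affine = affine,
                 orientation = orientation),
            class = "ct_volume")
}

#' Label volume container
#'
#' Integer region codes on the grid of a reference [ct_volume]. Code 0 is
#' background. `code_map` is a tibble with columns `code`, `region`,
#' `hemisphere` describing each non-zero code.
#'
#' @param labels 3-D integer array of non-negative codes.
#' @param affine 4x4 voxel-to-world affine (same convention as [ct_volume]).
#' @param code_map tibble mapping codes to region names and hemispheres, or
#'   `NULL` for an anonymous mask.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, affine = NULL, code_map = NULL) {
  if (length(dim(labels)) != 3L) {
    abort("`labels` must be a 3-D array", class = "nwuct_dim_error")
  }
  if (any(labels < 0)) abort("label codes must be non-negative",
                             class = "nwuct_label_error")
  storage.mode(labels) <- "integer"
  vol <- ct_volume(array(0, dim = dim(labels)), affine)
  structure(list(data = labels, spacing = vol$spacing, affine = vol$affine,
                 orientation = vol$orientation, code_map = code_map),
            class = c("label_volume", "ct_volume"))
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, orientation %s\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$orientation))
  rng <- range(x$data)
  cat(sprintf("  intensity range [%.1f, %.1f]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

## ---- affine helpers (0-based voxel index <-> world mm) ----

#' Map voxel indices to world coordinates
#'
#' @param vol a [ct_volume] (or a bare 4x4 affine).
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, idx) {
  affine <- if (is.matrix(vol)) vol else vol$affine
  idx <- matrix(idx, ncol = 3)
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#' @rdname voxel_to_world
#' @param world n x 3 matrix of world coordinates in mm.
#' @export
world_to_voxel <- function(vol, world) {
  affine <- if (is.matrix(vol)) vol else vol$affine
  world <- matrix(world, ncol = 3)
  t(solve(affine) %*% rbind(t(world), 1))[, 1:3, drop = FALSE]
}

## grid of all 0-based voxel indices for a volume dim
grid_indices <- function(dm) {
  cbind(rep(seq_len(dm[1]) - 1, times = dm[2] * dm[3]),
        rep(rep(seq_len(dm[2]) - 1, each = dm[1]), times = dm[3]),
        rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2]))
}

## ---- NIfTI I/O ----

#' Read a NIfTI volume
#'
#' Loads a single 3-D NIfTI-1/2 image, reorients it to canonical RAS, and
#' maps non-finite scanner padding values to the sentinel -1024 HU.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param label if `TRUE`, return a [label_volume] (integer data).
#' @return A [ct_volume] (or [label_volume]).
#' @export
read_nifti <- function(path, label = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("NIfTI file not found: %s", path), class = "nwuct_io_error")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(
                    sprintf("cannot read '%s' as NIfTI: %s", path,
                            conditionMessage(e)),
                    class = "nwuct_format_error"))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- RNifti::asNifti(img[, , , 1], reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L) {
    abort(sprintf("expected a 3-D volume, got shape [%s]",
                  paste(d, collapse = ", ")), class = "nwuct_dim_error")
  }
  RNifti::orientation(img) <- "RAS"
  affine <- unname(unclass(RNifti::xform(img)))[1:4, 1:4]
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  if (label) {
    label_volume(data, affine)
  } else {
    data[!is.finite(data)] <- HU_SENTINEL
    ct_volume(data, affine)
  }
}

#' Write a volume to NIfTI
#'
#' Intensity volumes are stored as float64 and label volumes as int32, so
#' that [read_nifti()] reproduces `data`, `spacing` and `affine` exactly.
#'
#' @param vol a [ct_volume] or [label_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$data)
  aff <- vol$affine
  attr(aff, "code") <- 2L
  # sform only: qform's quaternion+pixdim encoding cannot hold a general
  # affine and would take precedence over the sform on re-read
  RNifti::`sform<-`(img, aff) -> img
  dt <- if (inherits(vol, "label_volume")) "int32" else "double"
  tryCatch(RNifti::writeNifti(img, path, datatype = dt),
           error = function(e) abort(
             sprintf("failed writing NIfTI '%s': %s", path,
                     conditionMessage(e)),
             class = "nwuct_io_error"))
  invisible(path)
}
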