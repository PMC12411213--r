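## Synthetic head-CT phantom with known ground truth. Lesions are
## multiplicative density reductions over whole atlas regions — lesion HU =
## (1 - w) * base HU — so the constructed ipsilateral/contralateral density
## ratio equals exactly 1 - w before noise, and downstream NWU estimates test
## the pipeline rather than the phantom. Artifacts are blobs at intensities
## outside the 20-50 HU window (calcification 90 HU, hemorrhage 70 HU,
## encephalomalacia 10 HU).

ARTIFACT_HU <- c(calcification = 90, hemorrhage = 70, encephalomalacia = 10)

#' Phantom specification
#'
#' @param lesions list of lesions, each `list(region =, w =)` with
#'   water-uptake fraction `w` in `[0, 1]` applied to the whole region on the
#'   lesioned side.
#' @param side lesioned hemisphere (`"left"` or `"right"`).
#' @param artifacts list of artifacts, each
#'   `list(type =, region =, side =, hu =, radius_mm =)`; `type` is one of
#'   `"calcification"`, `"hemorrhage"`, `"encephalomalacia"` and fills in the
#'   default HU; `side` defaults to the lesion side.
#' @param noise_sd additive Gaussian HU noise standard deviation.
#' @param pose an [affine_transform] simulating scanner positioning (applied
#'   last, by resampling); `NULL` for identity.
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(lesions = list(), side = c("left", "right"),
                         artifacts = list(), noise_sd = 0, pose = NULL,
                         seed = 1L) {
  side <- match.arg(side)
  for (l in lesions) {
    if (!is.list(l) || is.null(l$region) || is.null(l$w)) {
      rlang::abort("each lesion must be list(region =, w =)",
                   class = "nwuct_parameter_error")
    }
    if (!l$region %in% ASPECTS_REGIONS) {
      rlang::abort(sprintf("unknown lesion region '%s'", l$region),
                   class = "nwuct_parameter_error")
    }
    if (l$w < 0 || l$w > 1) {
      rlang::abort("lesion water-uptake fraction w must be in [0, 1]",
                   class = "nwuct_parameter_error")
    }
  }
  if (noise_sd < 0) {
    rlang::abort("noise_sd must be >= 0", class = "nwuct_parameter_error")
  }
  if (!is.null(pose)) stopifnot(inherits(pose, "affine_transform"))
  structure(list(lesions = lesions, side = side, artifacts = artifacts,
                 noise_sd = noise_sd, pose = pose, seed = as.integer(seed)),
            class = "phantom_spec")
}

## sphere mask centred on the region voxel nearest the region centroid (for
## curved cortical sectors the centroid itself can fall outside the mask)
artifact_blob <- function(atlas, region, side, radius_mm) {
  code <- region_code(atlas, region, side)
  labs <- atlas$region_labels
  idx <- arrayInd(which(labs$data == code), dim(labs$data))
  w <- voxel_to_world(labs, idx - 1)
  ctr <- colMeans(w)
  ctr <- w[which.min(rowSums(sweep(w, 2, ctr)^2)), ]
  dm <- dim(labs$data)
  ax <- world_axes(dm, labs$spacing)
  X <- array(ax[[1]], dm)
  Y <- array(rep(ax[[2]], each = dm[1]), dm)
  Z <- array(rep(ax[[3]], each = dm[1] * dm[2]), dm)
  (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= radius_mm^2
}

#' Generate a synthetic head-CT phantom with known truth
#'
#' Starts from the atlas template, applies lesions (multiplicative density
#' reduction by `1 - w` over whole regions on the lesioned side), inserts
#' artifact blobs at their specified HU, applies the pose by resampling, and
#' finally adds voxelwise Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @param atlas a `region_atlas`; its template supplies the tissue
#'   intensities and geometry.
#' @return A list with `volume` (the phantom [ct_volume], in scanner pose)
#'   and `truth` (class `phantom_truth`: `true_regional_nwu` — `100 w` for
#'   lesioned regions, 0 elsewhere — `true_side`, `brain_mask` and
#'   `region_labels` in phantom pose, `applied_pose`, and any `warnings`
#'   recorded, e.g. lesion HU leaving the 20-50 window).
#' @export
generate_phantom <- function(spec, atlas) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(atlas, "region_atlas"))
  data <- atlas$template$data
  labs <- atlas$region_labels$data
  warnings <- character(0)
  true_nwu <- stats::setNames(rep(0, length(ASPECTS_REGIONS)), ASPECTS_REGIONS)
  for (l in spec$lesions) {
    code <- region_code(atlas, l$region, spec$side)
    m <- labs == code
    data[m] <- data[m] * (1 - l$w)
    true_nwu[l$region] <- 100 * l$w
    if (any(data[m] < DEFAULT_HU_WINDOW[1])) {
      warnings <- c(warnings, sprintf(
        "lesion in %s (w = %.2f) drives %d voxels below the 20 HU window edge",
        l$region, l$w, sum(data[m] < DEFAULT_HU_WINDOW[1])))
    }
  }
  for (a in spec$artifacts) {
    type <- match.arg(a$type, names(ARTIFACT_HU))
    hu <- if (!is.null(a$hu)) a$hu else ARTIFACT_HU[[type]]
    side <- if (!is.null(a$side)) a$side else spec$side
    radius <- if (!is.null(a$radius_mm)) a$radius_mm else 6
    blob <- artifact_blob(atlas, a$region, side, radius)
    data[blob] <- hu
  }
  vol <- ct_volume(data, atlas$template$affine)
  brain <- atlas$brain_mask
  regions <- atlas$region_labels
  if (!is.null(spec$pose)) {
    pull <- invert_transform(spec$pose)
    vol <- resample_volume(vol, pull, atlas$template)
    brain <- resample_volume(brain, pull, atlas$template)
    regions <- resample_volume(regions, pull, atlas$template)
  }
  if (spec$noise_sd > 0) {
    vol$data <- vol$data + with_seed(spec$seed, {
      array(stats::rnorm(length(vol$data), sd = spec$noise_sd), dim(vol$data))
    })
  }
  truth <- structure(list(
    true_regional_nwu = true_nwu,
    true_side = spec$side,
    brain_mask = brain,
    region_labels = regions,
    applied_pose = if (is.null(spec$pose)) {
      affine_transform(diag(4), "rigid")
    } else spec$pose,
    warnings = warnings,
    spec = spec
  ), class = "phantom_truth")
  list(volume = vol, truth = truth)
}
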