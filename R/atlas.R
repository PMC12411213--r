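## Synthetic atlas: schematic head geometry with the ten paired
## anterior-circulation ASPECTS regions, exactly mirror-symmetric about the
## mid-sagittal plane x = 0. Geometry is anatomically schematic by design:
## exact ground truth and exact left/right symmetry matter more than realism
## for validating the bilateral density comparison.

ASPECTS_REGIONS <- c("caudate", "lentiform_nucleus", "internal_capsule",
                     "insula", "M1", "M2", "M3", "M4", "M5", "M6")

## world-mm geometry constants (right hemisphere; left is the mirror image)
ATLAS_GEOM <- list(
  brain_semi = c(60, 78, 55),      # brain ellipsoid semi-axes
  skull_outer = 1.12,              # skull shell: rho in (1, skull_outer]
  deep = list(                      # deep structures: center / semi-axes, mm
    caudate           = list(c = c(14, 18, 10),  s = c(6, 11, 8)),
    lentiform_nucleus = list(c = c(22, 6, 2),    s = c(8, 11, 9)),
    internal_capsule  = list(c = c(19, -10, 6),  s = c(6, 10, 9)),
    insula            = list(c = c(34, 8, 0),    s = c(5, 13, 9))
  ),
  ribbon = c(0.62, 0.95),          # cortical ribbon, normalized radius
  ribbon_min_x = 10,               # keep cortex off the midline, mm
  band_z = c(-28, 4, 40),          # ganglionic (M1-3) / supraganglionic (M4-6)
  sector_phi = pi / 6,             # anterior / lateral / posterior split
  ventricle = list(c = c(7, 4, 6), s = c(3.5, 16, 7))
)

atlas_code_map <- function() {
  tibble::tibble(
    code = c(seq_along(ASPECTS_REGIONS), seq_along(ASPECTS_REGIONS) + 10L),
    region = rep(ASPECTS_REGIONS, 2),
    hemisphere = rep(c("left", "right"), each = length(ASPECTS_REGIONS))
  )
}

## centred symmetric affine: world x of voxel i is (i - (n-1)/2) * dx, so the
## plane x = 0 falls midway between mirror voxel pairs and reflection is an
## exact voxel permutation
centered_affine <- function(shape, spacing) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- -(shape - 1) / 2 * spacing
  a
}

world_axes <- function(shape, spacing) {
  lapply(1:3, function(ax) (seq_len(shape[ax]) - 1 - (shape[ax] - 1) / 2) *
           spacing[ax])
}

#' Build the packaged synthetic region atlas
#'
#' Constructs a deterministic, exactly mirror-symmetric synthetic head atlas:
#' an ellipsoidal brain (white matter 33 HU, cortical and deep gray 38 HU,
#' ventricular CSF 8 HU) inside a bone shell (1000 HU), with the ten paired
#' ASPECTS regions (caudate, lentiform nucleus, internal capsule, insula,
#' M1-M6) defined geometrically: deep structures as medial ellipsoids and
#' M1-M6 as cortical sectors split by axial band and in-plane angle. A mild
#' seeded intensity texture (mirrored so symmetry is exact) is added to the
#' parenchyma.
#'
#' @param shape grid dimensions; the x (left-right) extent must be even so
#'   reflection across the midline is an exact voxel permutation.
#' @param spacing voxel size in mm.
#' @param seed integer seed for the intensity texture.
#' @param tissue_hu named list of tissue intensities (HU); see defaults.
#' @return An object of class `region_atlas` with fields `template`
#'   ([ct_volume]), `region_labels` ([label_volume] with 20 codes),
#'   `brain_mask` ([label_volume]), and `midline_axis` (always 1, the plane
#'   x = 0).
#' @export
build_synthetic_atlas <- function(shape = c(96, 112, 80),
                                  spacing = c(2, 2, 2),
                                  seed = 42L,
                                  tissue_hu = list(white = 33, gray = 38,
                                                   csf = 8, bone = 1000,
                                                   air = -1000),
                                  texture_sd = 1.5) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 32)) {
    rlang::abort("atlas shape must be >= 32 along every axis",
                 class = "nwuct_construction_error")
  }
  if (shape[1] %% 2 != 0) {
    rlang::abort("atlas x-extent must be even for an exact midline reflection",
                 class = "nwuct_construction_error")
  }
  g <- ATLAS_GEOM
  half_fov <- shape * spacing / 2
  if (any(half_fov < g$brain_semi * g$skull_outer + 2 * spacing)) {
    rlang::abort("grid too small to contain the head geometry",
                 class = "nwuct_construction_error")
  }
  ax <- world_axes(shape, spacing)
  dm <- shape
  X <- array(ax[[1]], dm)
  Y <- array(rep(ax[[2]], each = dm[1]), dm)
  Z <- array(rep(ax[[3]], each = dm[1] * dm[2]), dm)
  AX <- abs(X)

  rho2 <- (X / g$brain_semi[1])^2 + (Y / g$brain_semi[2])^2 +
    (Z / g$brain_semi[3])^2
  brain <- rho2 <= 1
  skull <- rho2 > 1 & rho2 <= g$skull_outer^2

  ell <- function(p) {
    ((AX - p$c[1]) / p$s[1])^2 + ((Y - p$c[2]) / p$s[2])^2 +
      ((Z - p$c[3]) / p$s[3])^2 <= 1
  }

  labels <- array(0L, dm)
  assign_pair <- function(labels, mask, idx) {
    free <- labels == 0L & mask & brain
    labels[free & X < 0] <- idx
    labels[free & X > 0] <- idx + 10L
    labels
  }
  for (i in seq_along(g$deep)) {
    labels <- assign_pair(labels, ell(g$deep[[i]]), i)
  }
  rho <- sqrt(rho2)
  ribbon <- rho >= g$ribbon[1] & rho <= g$ribbon[2] & AX >= g$ribbon_min_x
  phi <- atan2(Y, AX)
  sectors <- list(phi > g$sector_phi,
                  abs(phi) <= g$sector_phi,
                  phi < -g$sector_phi)
  for (band in 1:2) {
    in_band <- Z >= g$band_z[band] + (band - 1) * 1e-9 & Z <= g$band_z[band + 1]
    if (band == 2) in_band <- Z > g$band_z[2] & Z <= g$band_z[3]
    for (s in 1:3) {
      idx <- 4L + (band - 1L) * 3L + s   # M1..M3 then M4..M6
      labels <- assign_pair(labels, ribbon & in_band & sectors[[s]], idx)
    }
  }
  counts <- tabulate(labels, nbins = 20L)
  if (any(counts == 0)) {
    rlang::abort("grid too small: some regions received no voxels",
                 class = "nwuct_construction_error")
  }

  ## template intensities
  hu <- array(tissue_hu$air, dm)
  hu[brain] <- tissue_hu$white
  gray <- (labels %in% c(1, 2, 4, 11, 12, 14)) | (ribbon & brain)
  hu[gray & brain] <- tissue_hu$gray
  vent <- ell(g$ventricle) & labels == 0L & brain
  hu[vent] <- tissue_hu$csf
  hu[skull] <- tissue_hu$bone

  ## mirrored seeded texture on the parenchyma (keeps exact symmetry)
  if (texture_sd > 0) {
    tex <- with_seed(seed, {
      array(stats::rnorm(dm[1] / 2 * dm[2] * dm[3], sd = texture_sd),
            c(dm[1] / 2, dm[2], dm[3]))
    })
    tex <- smooth_array(tex, sigma_vox = 4 / spacing)
    full <- array(0, dm)
    full[seq_len(dm[1] / 2), , ] <- tex
    full[dm[1]:(dm[1] / 2 + 1), , ] <- tex
    parenchyma <- brain & !vent
    hu[parenchyma] <- hu[parenchyma] + full[parenchyma]
  }

  affine <- centered_affine(shape, spacing)
  structure(list(
    template = ct_volume(hu, affine),
    region_labels = label_volume(labels, affine, code_map = atlas_code_map()),
    brain_mask = label_volume(array(as.integer(brain), dm), affine),
    midline_axis = 1L
  ), class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas> %s voxels, %d region pairs, midline plane x = 0\n",
              paste(dim(x$template$data), collapse = "x"),
              nrow(x$region_labels$code_map) / 2))
  invisible(x)
}

#' Region voxel counts and volumes
#'
#' @param atlas a `region_atlas`.
#' @return A tibble with one row per region pair: codes, voxel counts and
#'   mm^3 volumes for each hemisphere.
#' @export
region_volumes <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  cm <- atlas$region_labels$code_map
  vox_mm3 <- prod(atlas$region_labels$spacing)
  counts <- tabulate(atlas$region_labels$data, nbins = max(cm$code))
  if (any(counts[cm$code] == 0)) {
    bad <- cm$region[counts[cm$code] == 0]
    rlang::abort(sprintf("atlas regions with no voxels: %s",
                         paste(unique(bad), collapse = ", ")),
                 class = "nwuct_schema_error")
  }
  left <- cm[cm$hemisphere == "left", ]
  right <- cm[cm$hemisphere == "right", ]
  right <- right[match(left$region, right$region), ]
  tibble::tibble(
    region = left$region,
    left_code = left$code, right_code = right$code,
    voxels_left = counts[left$code], voxels_right = counts[right$code],
    mm3_left = counts[left$code] * vox_mm3,
    mm3_right = counts[right$code] * vox_mm3
  )
}

#' Reflect a volume or mask across the atlas midline
#'
#' Flips the array across the mid-sagittal plane x = 0. The atlas grid is
#' built symmetric about that plane, so reflection is an exact voxel
#' permutation and applying it twice is the identity.
#'
#' @param vol a [ct_volume] or [label_volume] on the atlas grid.
#' @param atlas the `region_atlas` defining the midline convention.
#' @return An object of the same type as `vol`.
#' @export
reflect_across_midline <- function(vol, atlas) {
  stopifnot(inherits(vol, "ct_volume"))
  a <- vol$affine
  nx <- dim(vol$data)[1]
  centred <- abs(a[1, 4] + a[1, 1] * (nx - 1) / 2) < 1e-6 &&
    all(abs(a[2:3, 1]) < 1e-9) && all(abs(a[1, 2:3]) < 1e-9)
  if (!centred) {
    rlang::abort("volume grid is not symmetric about the midline plane x = 0",
                 class = "nwuct_affine_error")
  }
  out <- vol
  out$data <- vol$data[nx:1, , , drop = FALSE]
  out
}

#' Save / load an atlas directory
#'
#' The directory layout is `template.nii.gz`, `regions.nii.gz`,
#' `brain_mask.nii.gz` and `codes.json` (code / region / hemisphere map plus
#' the midline axis). A user-supplied real atlas in the same layout is a
#' drop-in replacement for the synthetic one.
#'
#' @param atlas a `region_atlas`.
#' @param dir directory to write to / read from.
#' @return `load_atlas` returns a `region_atlas`; `save_atlas` returns `dir`
#'   invisibly.
#' @export
save_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_nifti(atlas$template, file.path(dir, "template.nii.gz"))
  write_nifti(atlas$region_labels, file.path(dir, "regions.nii.gz"))
  write_nifti(atlas$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  jsonlite::write_json(
    list(midline_axis = atlas$midline_axis,
         codes = atlas$region_labels$code_map),
    file.path(dir, "codes.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_atlas
#' @export
load_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "codes.json"),
                              simplifyVector = TRUE)
  cm <- tibble::as_tibble(meta$codes)
  if (!all(c("code", "region", "hemisphere") %in% names(cm))) {
    rlang::abort("codes.json lacks code/region/hemisphere columns",
                 class = "nwuct_schema_error")
  }
  regions <- read_nifti(file.path(dir, "regions.nii.gz"), label = TRUE)
  present <- setdiff(unique(as.vector(regions$data)), 0L)
  missing <- setdiff(present, cm$code)
  if (length(missing) > 0) {
    rlang::abort(sprintf("label codes missing from codes.json: %s",
                         paste(missing, collapse = ", ")),
                 class = "nwuct_schema_error")
  }
  regions$code_map <- cm
  structure(list(
    template = read_nifti(file.path(dir, "template.nii.gz")),
    region_labels = regions,
    brain_mask = read_nifti(file.path(dir, "brain_mask.nii.gz"), label = TRUE),
    midline_axis = as.integer(meta$midline_axis)
  ), class = "region_atlas")
}

## run code under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
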