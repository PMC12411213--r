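## Preprocessing chain: field-of-view selection, voxel smoothing, skull
## stripping, affine registration to the atlas, resampling onto the atlas
## grid.

## ---- array primitives (separable shift-and-add) ----

## shift a 3-D array by k along axis, padding with `fill` (or clamping to the
## edge value when fill is NULL)
shift_array <- function(arr, axis, k, fill = NULL) {
  n <- dim(arr)[axis]
  src <- seq_len(n) - k
  if (is.null(fill)) {
    src <- pmin(pmax(src, 1L), n)
    switch(axis,
           arr[src, , , drop = FALSE],
           arr[, src, , drop = FALSE],
           arr[, , src, drop = FALSE])
  } else {
    keep <- src >= 1L & src <= n
    out <- array(fill, dim(arr))
    idx_dst <- which(keep)
    idx_src <- src[keep]
    switch(axis,
           out[idx_dst, , ] <- arr[idx_src, , , drop = FALSE],
           out[, idx_dst, ] <- arr[, idx_src, , drop = FALSE],
           out[, , idx_dst] <- arr[, , idx_src, drop = FALSE])
    out
  }
}

## separable Gaussian smoothing; sigma_vox per axis, edge-replicated
smooth_array <- function(arr, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(arr))
    for (j in seq_along(w)) {
      acc <- acc + w[j] * shift_array(arr, axis, j - r - 1L)
    }
    arr <- acc
  }
  arr
}

## box dilation/erosion with per-axis radius
dilate_box <- function(mask, r = 1L) {
  r <- rep(as.integer(r), length.out = 3)
  for (axis in 1:3) {
    if (r[axis] == 0) next
    acc <- mask
    for (k in seq_len(r[axis])) {
      acc <- acc | shift_array(mask, axis, k, fill = FALSE) |
        shift_array(mask, axis, -k, fill = FALSE)
    }
    mask <- acc
  }
  mask
}

erode_box <- function(mask, r = 1L) {
  !dilate_box(!mask, r)
}

## fill interior cavities: background components not connected to the border
fill_holes <- function(mask) {
  lab <- cpp_label_components(!mask, dim(mask))
  dim(lab) <- dim(mask)
  border_labs <- unique(c(lab[c(1, dim(lab)[1]), , ], lab[, c(1, dim(lab)[2]), ],
                          lab[, , c(1, dim(lab)[3])]))
  border_labs <- setdiff(border_labs, 0L)
  mask | !(lab %in% c(0L, border_labs))
}

largest_component <- function(mask) {
  lab <- cpp_label_components(mask, dim(mask))
  if (attr(lab, "n_components") == 0) return(NULL)
  out <- lab == 1L
  dim(out) <- dim(mask)
  out
}

## ---- field of view ----

#' Select the head field of view
#'
#' Crops the volume to the tight bounding box (plus `margin` voxels) around
#' the largest connected component of voxels above `air_threshold`, updating
#' the affine so world coordinates of retained voxels are unchanged.
#'
#' @param vol a [ct_volume].
#' @param air_threshold HU threshold separating head from air background.
#' @param margin extra voxels kept on every side (clipped at the grid edge).
#' @return A list with `volume` (the cropped [ct_volume]) and `crop_bounds`
#'   (2 x 3 matrix of 1-based inclusive index ranges into the input).
#' @export
select_field_of_view <- function(vol, air_threshold = -500, margin = 2L) {
  stopifnot(inherits(vol, "ct_volume"))
  fg <- vol$data > air_threshold
  if (!any(fg)) {
    rlang::abort("no voxels above the air threshold; empty foreground",
                 class = "nwuct_foreground_error")
  }
  comp <- largest_component(fg)
  idx <- arrayInd(which(comp), dim(comp))
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dim(vol$data))
  cropped <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  affine <- vol$affine
  affine[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% (lo - 1)
  list(volume = ct_volume(cropped, affine),
       crop_bounds = rbind(lo = lo, hi = hi))
}

## ---- smoothing ----

#' Gaussian voxel smoothing
#'
#' Separable Gaussian smoothing with a physical standard deviation in mm,
#' converted to voxel units through the spacing. The default, half the
#' in-plane voxel size, denoises mildly without blurring region boundaries.
#'
#' @param vol a [ct_volume].
#' @param sigma_mm per-axis standard deviation in mm (recycled to length 3);
#'   0 returns the input unchanged.
#' @return A smoothed [ct_volume].
#' @export
ct_smooth <- function(vol, sigma_mm = 0.5 * vol$spacing[1]) {
  stopifnot(inherits(vol, "ct_volume"))
  sigma_mm <- rep(sigma_mm, length.out = 3)
  if (any(sigma_mm < 0)) {
    rlang::abort("smoothing sigma must be >= 0", class = "nwuct_parameter_error")
  }
  if (all(sigma_mm == 0)) return(vol)
  out <- vol
  out$data <- smooth_array(vol$data, sigma_mm / vol$spacing)
  out
}

## ---- skull stripping ----

#' Skull stripping (brain extraction)
#'
#' Extracts the brain as the largest connected component of voxels inside
#' `brain_window` that lies interior to the bone shell (i.e. not reachable
#' from the image border without crossing bone), followed by morphological
#' closing and hole filling. Bone voxels are never included.
#'
#' @param vol a [ct_volume] in HU.
#' @param bone_threshold HU at or above which a voxel counts as bone.
#' @param brain_window inclusive HU window for brain-candidate voxels.
#' @param closing_radius radius (voxels) of the morphological closing.
#' @return A [label_volume] with 1 = brain.
#' @export
skull_strip <- function(vol, bone_threshold = 300, brain_window = c(0, 100),
                        closing_radius = 1L) {
  stopifnot(inherits(vol, "ct_volume"))
  bone <- vol$data >= bone_threshold
  lab <- cpp_label_components(!bone, dim(vol$data))
  dim(lab) <- dim(vol$data)
  border_labs <- setdiff(unique(c(lab[c(1, dim(lab)[1]), , ],
                                  lab[, c(1, dim(lab)[2]), ],
                                  lab[, , c(1, dim(lab)[3])])), 0L)
  interior <- !bone & !(lab %in% border_labs)
  cand <- interior & vol$data >= brain_window[1] & vol$data <= brain_window[2]
  if (!any(cand)) {
    rlang::abort("no brain-candidate voxels interior to a bone shell",
                 class = "nwuct_extraction_error")
  }
  mask <- largest_component(cand)
  if (closing_radius > 0) {
    mask <- erode_box(dilate_box(mask, closing_radius), closing_radius)
  }
  mask <- fill_holes(mask)
  mask <- mask & !bone
  label_volume(array(as.integer(mask), dim(mask)), vol$affine)
}

## ---- affine transforms ----

#' World-to-world affine transform
#'
#' @param matrix 4x4 world-to-world transform in mm.
#' @param dof_class `"rigid"` or `"affine"`; rigid transforms must have an
#'   orthonormal rotation block with determinant +1 (checked to 1e-6).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, dof_class = c("affine", "rigid")) {
  dof_class <- match.arg(dof_class)
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4)) || abs(det(matrix)) < 1e-12) {
    rlang::abort("transform matrix must be an invertible 4x4 matrix",
                 class = "nwuct_affine_error")
  }
  if (dof_class == "rigid") {
    R <- matrix[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0) {
      rlang::abort("rigid transform block is not a proper rotation",
                   class = "nwuct_affine_error")
    }
  }
  structure(list(matrix = matrix, dof_class = dof_class),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> (%s)\n", x$dof_class))
  print(round(x$matrix, 5))
  invisible(x)
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

## build a 4x4 from parameters about a centre
## theta: rigid = (rx, ry, rz, tx, ty, tz); affine adds (log sx, log sy,
## log sz, shear xy, xz, yz)
params_to_matrix <- function(theta, center, dof_class) {
  R <- rotation_matrix(theta[1:3])
  t <- theta[4:6]
  A <- R
  if (dof_class == "affine") {
    S <- diag(exp(theta[7:9]))
    H <- diag(3)
    H[1, 2] <- theta[10]; H[1, 3] <- theta[11]; H[2, 3] <- theta[12]
    A <- R %*% H %*% S
  }
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- center - A %*% center + t
  M
}

#' Build an affine transform from interpretable parameters
#'
#' @param rotation_deg rotations about x, y, z in degrees.
#' @param translation translation in mm.
#' @param scale per-axis scale factors.
#' @param shear shear coefficients (xy, xz, yz).
#' @param center centre of rotation/scaling in world mm.
#' @return An [affine_transform].
#' @export
make_transform <- function(rotation_deg = c(0, 0, 0), translation = c(0, 0, 0),
                           scale = c(1, 1, 1), shear = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  theta <- c(rotation_deg * pi / 180, translation, log(scale), shear)
  rigid <- all(scale == 1) && all(shear == 0)
  M <- params_to_matrix(theta, center, "affine")
  affine_transform(M, if (rigid) "rigid" else "affine")
}

#' Invert / compose transforms
#' @param x,a,b [affine_transform] objects.
#' @return An [affine_transform]. `compose_transforms(a, b)` applies `b`
#'   first, then `a`.
#' @export
invert_transform <- function(x) {
  affine_transform(solve(x$matrix), x$dof_class)
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(a, b) {
  cls <- if (a$dof_class == "rigid" && b$dof_class == "rigid") "rigid" else "affine"
  affine_transform(a$matrix %*% b$matrix, cls)
}

#' Apply a transform to world points
#' @param transform an [affine_transform].
#' @param pts n x 3 matrix of world coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3)
  t(transform$matrix %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
}

## ---- registration ----

#' Registration settings
#'
#' @param dof_class `"affine"` (12 dof, rigid-first staging) or `"rigid"`.
#' @param pyramid_sigmas_mm per-level smoothing of both volumes, coarse to
#'   fine, in mm (length = number of levels).
#' @param max_points per-level cap on the number of atlas-mask sample points.
#' @param max_iter per-level Nelder-Mead iteration cap.
#' @param init `"centroid_axes"` (intensity centroid + principal axes) or
#'   `"centroid"` (translation only).
#' @param mask_dilation voxels of dilation applied to the fixed mask before
#'   sampling the metric. Including the high-contrast skull interface anchors
#'   scale and translation; with a brain-only mask the optimizer can shrink
#'   the transform to keep samples inside homogeneous parenchyma.
#' @param background HU assigned to out-of-field samples.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(dof_class = c("affine", "rigid"),
                                pyramid_sigmas_mm = c(4, 2, 0),
                                max_points = c(4000, 8000, 20000),
                                max_iter = c(500, 500, 500),
                                init = c("centroid_axes", "centroid"),
                                mask_dilation = 3L,
                                background = -1024) {
  structure(list(dof_class = match.arg(dof_class),
                 pyramid_sigmas_mm = pyramid_sigmas_mm,
                 max_points = rep(max_points,
                                  length.out = length(pyramid_sigmas_mm)),
                 max_iter = rep(max_iter,
                                length.out = length(pyramid_sigmas_mm)),
                 init = match.arg(init),
                 mask_dilation = as.integer(mask_dilation),
                 background = background),
            class = "registration_config")
}

mask_centroid_axes <- function(vol, mask) {
  idx <- arrayInd(which(mask != 0), dim(vol$data))
  w <- voxel_to_world(vol, idx - 1)
  ctr <- colMeans(w)
  cov <- stats::cov(w)
  list(centroid = ctr, eig = eigen(cov, symmetric = TRUE))
}

## deterministic subsample: every k-th index
subsample_idx <- function(n, max_n) {
  if (n <= max_n) return(seq_len(n))
  stride <- ceiling(n / max_n)
  seq(1L, n, by = stride)
}

#' Register a subject CT to the atlas
#'
#' Intensity-based affine registration: minimizes the mean squared intensity
#' difference over the atlas brain mask through a multi-resolution pyramid
#' (Gaussian-smoothed copies of both volumes, coarse to fine), optimizing a
#' rigid transform first and, if `config$dof_class == "affine"`, releasing
#' scales and shears afterwards. Initialization is deterministic: intensity
#' centroids and (optionally) mask principal axes. Non-convergence is
#' reported through the `converged` flag, not an exception, so batch runs
#' continue.
#'
#' @param subject subject [ct_volume] (in scanner space).
#' @param subject_mask brain mask for the subject ([label_volume] or array).
#' @param atlas a `region_atlas` (or a [ct_volume] template).
#' @param atlas_mask optional mask overriding the atlas brain mask.
#' @param config a [registration_config()].
#' @return A list with `transform` (an [affine_transform] mapping atlas world
#'   coordinates to subject world coordinates, i.e. the pull-back used by
#'   [resample_volume()]) and `report` (final metric, convergence flag,
#'   per-level metric trace).
#' @export
register_to_atlas <- function(subject, subject_mask, atlas, atlas_mask = NULL,
                              config = registration_config()) {
  fixed <- if (inherits(atlas, "region_atlas")) atlas$template else atlas
  if (is.null(atlas_mask)) {
    if (!inherits(atlas, "region_atlas")) {
      rlang::abort("atlas_mask is required when atlas is a bare volume",
                   class = "nwuct_mask_error")
    }
    atlas_mask <- atlas$brain_mask
  }
  fmask <- if (inherits(atlas_mask, "ct_volume")) atlas_mask$data else atlas_mask
  mmask <- if (inherits(subject_mask, "ct_volume")) subject_mask$data else subject_mask
  if (!any(fmask != 0) || !any(mmask != 0)) {
    rlang::abort("empty brain mask supplied to registration",
                 class = "nwuct_mask_error")
  }

  fx <- mask_centroid_axes(fixed, fmask)
  mv <- mask_centroid_axes(subject, mmask)
  center <- fx$centroid
  t0 <- mv$centroid - fx$centroid
  R0 <- diag(3)
  if (config$init == "centroid_axes") {
    ef <- fx$eig$values
    # principal axes are unstable when eigenvalues nearly coincide
    if (min(abs(diff(ef))) / max(ef) > 0.05) {
      Vf <- fx$eig$vectors
      Vm <- mv$eig$vectors
      best <- diag(3); best_tr <- -Inf
      for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
        s3 <- s1 * s2 * sign(det(Vm) * det(Vf))
        Rc <- Vm %*% diag(c(s1, s2, s3)) %*% t(Vf)
        if (det(Rc) > 0 && sum(diag(Rc)) > best_tr) {
          best <- Rc; best_tr <- sum(diag(Rc))
        }
      }
      R0 <- best
    }
  }
  theta <- c(as.vector(rotation_to_euler(R0)), t0, rep(0, 6))

  fsamp <- fmask != 0
  if (config$mask_dilation > 0) {
    fsamp <- dilate_box(fsamp, config$mask_dilation)
  }
  fidx_all <- which(fsamp)
  fw_all <- voxel_to_world(fixed, arrayInd(fidx_all, dim(fixed$data)) - 1)
  A_mov_inv <- solve(subject$affine)
  bg <- config$background
  n_lev <- length(config$pyramid_sigmas_mm)
  trace <- numeric(0)
  conv <- TRUE
  for (lev in seq_len(n_lev)) {
    s <- config$pyramid_sigmas_mm[lev]
    fsm <- if (s > 0) smooth_array(fixed$data, s / fixed$spacing) else fixed$data
    msm <- if (s > 0) smooth_array(subject$data, s / subject$spacing) else subject$data
    keep <- subsample_idx(length(fidx_all), config$max_points[lev])
    pts <- fw_all[keep, , drop = FALSE]
    fint <- fsm[fidx_all[keep]]
    mdim <- dim(subject$data)
    objective <- function(th, dof) {
      M <- params_to_matrix(th[seq_len(if (dof == "rigid") 6 else 12)],
                            center, dof)
      moved <- M %*% rbind(t(pts), 1)
      vox <- A_mov_inv %*% moved
      samp <- cpp_sample_trilinear(msm, mdim, t(vox[1:3, , drop = FALSE]), bg)
      mean((samp - fint)^2)
    }
    stages <- if (config$dof_class == "affine" && lev > 1) {
      c("rigid", "affine")
    } else "rigid"
    for (dof in stages) {
      np <- if (dof == "rigid") 6L else 12L
      ps <- c(rep(0.03, 3), rep(3, 3), rep(0.03, 3), rep(0.02, 3))[seq_len(np)]
      # Nelder-Mead with restarts: a fresh simplex around the previous
      # optimum escapes premature simplex collapse in 12 dof
      val_old <- Inf
      for (restart in 1:4) {
        fit <- stats::optim(theta[seq_len(np)], objective, dof = dof,
                            method = "Nelder-Mead",
                            control = list(maxit = config$max_iter[lev],
                                           parscale = ps, reltol = 1e-8))
        theta[seq_len(np)] <- fit$par
        conv <- fit$convergence == 0
        if (val_old - fit$value < 1e-4 * (abs(fit$value) + 1e-8)) {
          conv <- TRUE  # objective plateaued across restarts
          break
        }
        val_old <- fit$value
      }
      trace <- c(trace, fit$value)
    }
  }
  final_dof <- if (config$dof_class == "affine" && n_lev > 1) "affine" else "rigid"
  M <- params_to_matrix(theta[seq_len(if (final_dof == "rigid") 6 else 12)],
                        center, final_dof)
  list(transform = affine_transform(M, final_dof),
       report = list(registration_metric_final = trace[length(trace)],
                     metric_trace = trace, converged = conv))
}

## recover (rx, ry, rz) from R = Rz Ry Rx
rotation_to_euler <- function(R) {
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz)
}

## ---- resampling ----

#' Resample a volume through a transform onto a target grid
#'
#' Samples `vol` at the locations of `target` voxels mapped through
#' `transform` (target world -> source world). Intensity volumes use
#' trilinear interpolation with out-of-field voxels set to -1024 HU; label
#' volumes use nearest-neighbour with background 0.
#'
#' @param vol source [ct_volume] or [label_volume].
#' @param transform an [affine_transform] (identity if `NULL`).
#' @param target a [ct_volume] (or `region_atlas`) defining the output grid.
#' @param interpolation `"linear"` or `"nearest"`; default chosen by type.
#' @return A volume of the same type as `vol` on the target grid.
#' @export
resample_volume <- function(vol, transform, target,
                            interpolation = NULL) {
  if (inherits(target, "region_atlas")) target <- target$template
  stopifnot(inherits(vol, "ct_volume"), inherits(target, "ct_volume"))
  is_label <- inherits(vol, "label_volume")
  if (is.null(interpolation)) {
    interpolation <- if (is_label) "nearest" else "linear"
  }
  M <- if (is.null(transform)) diag(4) else transform$matrix
  dm <- dim(target$data)
  idx <- grid_indices(dm)
  vox <- solve(vol$affine) %*% M %*% target$affine %*%
    rbind(t(idx), 1)
  coords <- t(vox[1:3, , drop = FALSE])
  if (interpolation == "nearest") {
    bg <- if (is_label) 0 else HU_SENTINEL
    out <- cpp_sample_nearest(as.double(vol$data), dim(vol$data), coords, bg)
  } else {
    out <- cpp_sample_trilinear(as.double(vol$data), dim(vol$data), coords,
                                HU_SENTINEL)
  }
  dim(out) <- dm
  if (is_label) {
    label_volume(array(as.integer(round(out)), dm), target$affine,
                 code_map = vol$code_map)
  } else {
    ct_volume(out, target$affine)
  }
}
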