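## Net water uptake: bilateral density comparison under the 20-50 HU window.
##
## NWU_r (%) = (1 - D_ipsilateral[r] / D_contralateral[r]) * 100, where D is
## the mean density over a region's voxels after excluding voxels outside
## 20-50 HU (encephalomalacia, calcification, acute hemorrhage). The printed
## one-line form of the equation ("1 - (D_i/D_c) x 100") is read with the
## subtraction applied before the percentage scaling, matching the NWU
## literature; the literal left-to-right reading would yield values near
## -8500%.

DEFAULT_HU_WINDOW <- c(20, 50)

check_window <- function(window) {
  if (length(window) != 2 || !is.numeric(window) || window[1] > window[2]) {
    rlang::abort("HU window must be c(low, high) with low <= high",
                 class = "nwuct_parameter_error")
  }
  window
}

#' Valid-voxel mask under the HU exclusion window
#'
#' Keeps mask voxels whose HU lies inside the closed window (both endpoints
#' included), automatically excluding encephalomalacia, calcification and
#' acute hemorrhage from density calculations.
#'
#' @param vol a [ct_volume].
#' @param mask logical/0-1 array or [label_volume] on the same grid.
#' @param window inclusive HU window, default `c(20, 50)`.
#' @return Logical array of valid voxels.
#' @export
filter_hu_window <- function(vol, mask, window = DEFAULT_HU_WINDOW) {
  check_window(window)
  m <- if (inherits(mask, "ct_volume")) mask$data else mask
  if (!all(dim(m) == dim(vol$data))) {
    rlang::abort("mask grid does not match the volume grid",
                 class = "nwuct_dim_error")
  }
  m != 0 & vol$data >= window[1] & vol$data <= window[2]
}

## region mask, optionally eroded to guard against partial-volume mixing at
## region boundaries after smoothing and interpolation (applied identically
## to both hemispheres, so it is unbiased for the bilateral ratio)
region_mask <- function(atlas, code, erosion_vox = 0L) {
  m <- atlas$region_labels$data == code
  if (erosion_vox > 0) {
    m2 <- erode_box(m, erosion_vox)
    if (any(m2)) m <- m2  # never erode a small region to nothing
  }
  m
}

region_code <- function(atlas, region, side) {
  cm <- atlas$region_labels$code_map
  code <- cm$code[cm$region == region & cm$hemisphere == side]
  if (length(code) != 1) {
    rlang::abort(sprintf("region '%s' (%s) not present in the atlas",
                         region, side), class = "nwuct_schema_error")
  }
  code
}

#' Mean regional density after HU-window filtering
#'
#' @param vol a [ct_volume] on the atlas grid.
#' @param atlas a `region_atlas`.
#' @param region region name (e.g. `"insula"`).
#' @param side `"left"` or `"right"`.
#' @param window inclusive HU window.
#' @param erosion_vox voxels of boundary erosion applied to the region mask
#'   before sampling (0 = the full anatomical mask). Erosion discards the
#'   partial-volume layer mixed by smoothing and interpolation; it is
#'   applied identically on both sides and never empties a region.
#' @return One-row tibble: `region`, `side`, `mean_hu` (NA when no voxel
#'   survives the window), `valid_voxels`, `total_voxels` (anatomical mask
#'   size, before erosion).
#' @export
region_density <- function(vol, atlas, region, side,
                           window = DEFAULT_HU_WINDOW, erosion_vox = 0L) {
  code <- region_code(atlas, region, side)
  mask <- region_mask(atlas, code, erosion_vox)
  valid <- filter_hu_window(vol, mask, window)
  nv <- sum(valid)
  tibble::tibble(region = region, side = side,
                 mean_hu = if (nv > 0) mean(vol$data[valid]) else NA_real_,
                 valid_voxels = nv,
                 total_voxels = sum(atlas$region_labels$data == code))
}

#' Aggregate per-region NWU to summary scores
#'
#' The conventional average is the arithmetic mean over regions with a
#' defined NWU; the weighted average weights each defined region by its
#' anatomical volume in mm^3.
#'
#' @param per_region_nwu numeric vector of regional NWU values in percent
#'   (NA = undefined region, excluded from both averages).
#' @param volumes_mm3 region volumes used as weights.
#' @return List with `average` and `weighted_average`.
#' @export
aggregate_nwu <- function(per_region_nwu, volumes_mm3) {
  stopifnot(length(per_region_nwu) == length(volumes_mm3))
  ok <- !is.na(per_region_nwu)
  if (!any(ok)) {
    rlang::abort("no region has a defined NWU", class = "nwuct_computation_error")
  }
  list(average = mean(per_region_nwu[ok]),
       weighted_average = sum(per_region_nwu[ok] * volumes_mm3[ok]) /
         sum(volumes_mm3[ok]))
}

#' Compute net water uptake for the ten ASPECTS regions
#'
#' For each region pair the mean density of the ipsilateral mask is compared
#' to its contralateral mirror: `NWU = (1 - D_ipsi / D_contra) * 100`.
#' Values are not clamped (negative NWU is possible under noise). With
#' `side = "auto"` the ipsilateral hemisphere is the single side whose
#' candidate average NWU over defined regions is larger — one laterality
#' choice for all ten regions, since per-region max-picking would bias NWU
#' upward under noise. Regions where either side has no valid voxels (or a
#' zero contralateral density under a custom window) are excluded from both
#' averages and listed in `regions_excluded`.
#'
#' @param vol a [ct_volume] already registered and resampled to the atlas
#'   grid.
#' @param atlas a `region_atlas`.
#' @param side `"left"`, `"right"`, or `"auto"`.
#' @param window inclusive HU window, default `c(20, 50)`.
#' @param weight `"anatomical"` (region mask volume in mm^3, the default) or
#'   `"valid"` (post-filter valid-voxel volume) for the weighted average.
#' @param erosion_vox voxels of region-boundary erosion before density
#'   sampling (see [region_density()]); the default of 1 discards the layer
#'   subject to partial-volume mixing from smoothing and interpolation.
#' @return An object of class `nwu_result`: per-region densities and NWU,
#'   the chosen `ipsilateral_side`, `average_nwu`, `weighted_average_nwu`,
#'   and `regions_excluded`.
#' @export
compute_nwu <- function(vol, atlas, side = c("auto", "left", "right"),
                        window = DEFAULT_HU_WINDOW,
                        weight = c("anatomical", "valid"),
                        erosion_vox = 1L) {
  side <- match.arg(side)
  weight <- match.arg(weight)
  check_window(window)
  stopifnot(inherits(vol, "ct_volume"), inherits(atlas, "region_atlas"))
  if (!all(dim(vol$data) == dim(atlas$region_labels$data))) {
    rlang::abort("volume is not on the atlas grid; resample it first",
                 class = "nwuct_dim_error")
  }
  dens <- dplyr::bind_rows(lapply(ASPECTS_REGIONS, function(r) {
    dplyr::bind_rows(
      region_density(vol, atlas, r, "left", window, erosion_vox),
      region_density(vol, atlas, r, "right", window, erosion_vox))
  }))
  vox_mm3 <- prod(atlas$region_labels$spacing)

  nwu_for <- function(ipsi) {
    contra <- if (ipsi == "left") "right" else "left"
    di <- dens$mean_hu[dens$side == ipsi][match(ASPECTS_REGIONS,
                                                dens$region[dens$side == ipsi])]
    dc <- dens$mean_hu[dens$side == contra][match(ASPECTS_REGIONS,
                                                  dens$region[dens$side == contra])]
    out <- (1 - di / dc) * 100
    out[is.na(di) | is.na(dc) | dc == 0] <- NA_real_
    out
  }
  pick <- side
  if (side == "auto") {
    cand <- vapply(c("left", "right"),
                   function(s) {
                     v <- nwu_for(s)
                     if (all(is.na(v))) -Inf else mean(v, na.rm = TRUE)
                   }, 0)
    pick <- if (cand["right"] > cand["left"]) "right" else "left"
  }
  nwu <- nwu_for(pick)
  if (all(is.na(nwu))) {
    rlang::abort("NWU undefined in all 10 regions", class = "nwuct_computation_error")
  }
  ipsi_rows <- dens[dens$side == pick, ]
  ipsi_rows <- ipsi_rows[match(ASPECTS_REGIONS, ipsi_rows$region), ]
  w_mm3 <- (if (weight == "anatomical") ipsi_rows$total_voxels
            else ipsi_rows$valid_voxels) * vox_mm3
  agg <- aggregate_nwu(nwu, w_mm3)
  structure(list(
    per_region = tibble::tibble(region = ASPECTS_REGIONS, nwu = nwu,
                                weight_mm3 = w_mm3),
    densities = dens,
    ipsilateral_side = pick,
    average_nwu = agg$average,
    weighted_average_nwu = agg$weighted_average,
    regions_excluded = ASPECTS_REGIONS[is.na(nwu)],
    window = window, side_requested = side
  ), class = "nwu_result")
}

#' @export
print.nwu_result <- function(x, ...) {
  cat(sprintf("<nwu_result> ipsilateral side: %s\n", x$ipsilateral_side))
  cat(sprintf("  average NWU %.2f%%, volume-weighted %.2f%%\n",
              x$average_nwu, x$weighted_average_nwu))
  if (length(x$regions_excluded)) {
    cat("  excluded regions:", paste(x$regions_excluded, collapse = ", "), "\n")
  }
  print(x$per_region)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a NWU result into a per-region tibble
#' @param x an `nwu_result`.
#' @param ... unused.
#' @return Tibble with region, side densities, valid-voxel counts, and NWU.
#' @export
tidy.nwu_result <- function(x, ...) {
  contra <- if (x$ipsilateral_side == "left") "right" else "left"
  d_i <- x$densities[x$densities$side == x$ipsilateral_side, ]
  d_c <- x$densities[x$densities$side == contra, ]
  tibble::tibble(
    region = x$per_region$region,
    nwu = x$per_region$nwu,
    density_ipsi = d_i$mean_hu[match(x$per_region$region, d_i$region)],
    density_contra = d_c$mean_hu[match(x$per_region$region, d_c$region)],
    valid_ipsi = d_i$valid_voxels[match(x$per_region$region, d_i$region)],
    valid_contra = d_c$valid_voxels[match(x$per_region$region, d_c$region)],
    weight_mm3 = x$per_region$weight_mm3
  )
}

#' One-row summary of a NWU result
#' @param x an `nwu_result`.
#' @param ... unused.
#' @export
glance.nwu_result <- function(x, ...) {
  tibble::tibble(ipsilateral_side = x$ipsilateral_side,
                 average_nwu = x$average_nwu,
                 weighted_average_nwu = x$weighted_average_nwu,
                 n_regions_defined = sum(!is.na(x$per_region$nwu)))
}

#' Plot regional NWU values
#' @param object an `nwu_result`.
#' @param ... unused.
#' @return A ggplot barchart of the ten regional NWU values.
#' @export
autoplot.nwu_result <- function(object, ...) {
  df <- tidy.nwu_result(object)
  df$region <- factor(df$region, levels = rev(ASPECTS_REGIONS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nwu, y = .data$region)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$average_nwu, linetype = 2) +
    ggplot2::labs(x = "Net water uptake (%)", y = NULL,
                  title = sprintf("Ipsilateral side: %s; average NWU %.1f%%",
                                  object$ipsilateral_side,
                                  object$average_nwu)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
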