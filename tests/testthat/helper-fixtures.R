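# shared fixtures, built once per test run

.fixtures <- new.env()

# compact atlas used throughout the suite; `plain` disables the intensity
# texture for tests that need piecewise-constant tissue
test_atlas <- function(plain = FALSE) {
  key <- if (plain) "atlas_plain" else "atlas"
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_synthetic_atlas(
      shape = c(64, 80, 56), spacing = c(2.5, 2.5, 2.5),
      texture_sd = if (plain) 0 else 1.5)
  }
  .fixtures[[key]]
}

# tiny hand-checkable atlas: an 8x8x8 grid with one region pair whose voxel
# coordinates (and therefore counts and densities) are enumerable by hand
toy_atlas <- function() {
  dm <- c(8L, 8L, 8L)
  affine <- diag(c(2, 2, 2, 1))
  affine[1:3, 4] <- -(dm - 1) / 2 * 2
  labels <- array(0L, dm)
  labels[2:3, 4:5, 4:5] <- 1L    # left caudate: 2*2*2 = 8 voxels
  labels[6:7, 4:5, 4:5] <- 11L   # right caudate: 8 voxels
  cm <- tibble::tibble(code = c(1L, 11L), region = "caudate",
                       hemisphere = c("left", "right"))
  template <- array(0, dm)
  structure(list(
    template = ct_volume(template, affine),
    region_labels = label_volume(labels, affine, code_map = cm),
    brain_mask = label_volume(array(1L, dm), affine),
    midline_axis = 1L
  ), class = "region_atlas")
}

# mean displacement (mm) between two transforms over the atlas brain mask
mean_displacement <- function(t_a, t_b, atlas, stride = 41L) {
  idx <- which(atlas$brain_mask$data != 0)
  idx <- idx[seq(1, length(idx), by = stride)]
  pts <- voxel_to_world(atlas$brain_mask,
                        arrayInd(idx, dim(atlas$brain_mask$data)) - 1)
  d <- apply_transform(t_a, pts) - apply_transform(t_b, pts)
  mean(sqrt(rowSums(d^2)))
}

# brute-force AUROC over all positive-negative pairs
pair_count_auroc <- function(scores, labels) {
  p <- scores[labels == 1]
  n <- scores[labels == 0]
  mean(outer(p, n, function(a, b) (a > b) + 0.5 * (a == b)))
}
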