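## Minimal classic single-frame CT DICOM support (little-endian, explicit or
## implicit VR). Covers exactly what the pipeline needs: geometry, HU rescale
## calibration, and 16-bit pixel data. Multi-frame/enhanced DICOM, other
## transfer syntaxes, and compressed pixel data are out of scope.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

## VRs carrying a 4-byte length (explicit VR encoding)
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

read_u16 <- function(con) {
  readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
}
read_u32 <- function(con) {
  lo <- read_u16(con); hi <- read_u16(con)
  if (length(lo) == 0 || length(hi) == 0) return(numeric(0))
  hi * 65536 + lo
}

## parse one data element; returns list(tag, vr, bytes) or NULL at EOF
dcm_read_element <- function(con, explicit) {
  group <- read_u16(con)
  if (length(group) == 0) return(NULL)
  elem <- read_u16(con)
  if (explicit) {
    vr <- rawToChar(readBin(con, "raw", 2L))
    if (vr %in% LONG_VRS) {
      readBin(con, "raw", 2L)  # reserved
      len <- read_u32(con)
    } else {
      len <- read_u16(con)
    }
  } else {
    vr <- NA_character_
    len <- read_u32(con)
  }
  if (len >= 4294967295) {
    rlang::abort("undefined-length DICOM elements are not supported",
                 class = "nwuct_format_error")
  }
  bytes <- if (len > 0) readBin(con, "raw", len) else raw(0)
  list(tag = dcm_tag(group, elem), group = group, vr = vr, bytes = bytes)
}

dcm_string <- function(bytes) {
  bytes <- bytes[bytes != as.raw(0)]  # strip UI null padding
  sub(" +$", "", rawToChar(bytes))
}
dcm_ds <- function(bytes) {
  as.numeric(strsplit(dcm_string(bytes), "\\\\")[[1]])
}
dcm_us <- function(bytes) {
  readBin(bytes, "integer", length(bytes) / 2L, size = 2L,
          endian = "little", signed = FALSE)
}

## parse a single DICOM file into a named list of the tags the reader needs
dcm_parse_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 132L)
  if (length(pre) == 132 && rawToChar(pre[129:132]) == "DICM") {
    # file meta group: always explicit VR little endian
    ts <- TS_EXPLICIT_LE
    repeat {
      pos <- seek(con, NA)
      el <- dcm_read_element(con, explicit = TRUE)
      if (is.null(el)) break
      if (el$group != 0x0002) { seek(con, pos); break }
      if (el$tag == "0002,0010") ts <- dcm_string(el$bytes)
    }
  } else {
    seek(con, 0)  # headerless: assume implicit VR little endian dataset
    ts <- TS_IMPLICIT_LE
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2"   = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    rlang::abort(sprintf("unsupported transfer syntax '%s' in %s", ts, path),
                 class = "nwuct_format_error"))
  out <- list()
  repeat {
    el <- dcm_read_element(con, explicit)
    if (is.null(el)) break
    out[[el$tag]] <- el
    if (el$tag == "7FE0,0010") break
  }
  out
}

dcm_need <- function(elems, tag, what, path, cls = "nwuct_format_error") {
  if (is.null(elems[[tag]])) {
    rlang::abort(sprintf("DICOM file %s lacks %s (%s)", path, what, tag),
                 class = cls)
  }
  elems[[tag]]$bytes
}

#' Read a classic DICOM CT series as a CT volume
#'
#' Reads all single-frame CT slices in `dir` (one series), sorts them by
#' position along the slice normal, rescales stored pixel values to
#' Hounsfield units via the rescale slope/intercept tags, and returns the
#' volume reoriented to canonical RAS.
#'
#' @param dir directory containing the slice files.
#' @param pattern optional filename regexp (default: every regular file).
#' @return A [ct_volume] in HU.
#' @export
read_dicom_series <- function(dir, pattern = NULL) {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2) {
    rlang::abort(sprintf("need at least 2 DICOM slices in %s, found %d",
                         dir, length(files)), class = "nwuct_series_error")
  }
  slices <- lapply(files, function(path) {
    el <- dcm_parse_file(path)
    uid <- dcm_string(dcm_need(el, "0020,000E", "SeriesInstanceUID", path,
                               "nwuct_series_error"))
    rows <- dcm_us(dcm_need(el, "0028,0010", "Rows", path))
    cols <- dcm_us(dcm_need(el, "0028,0011", "Columns", path))
    ipp <- dcm_ds(dcm_need(el, "0020,0032", "ImagePositionPatient", path))
    iop <- dcm_ds(dcm_need(el, "0020,0037", "ImageOrientationPatient", path))
    ps <- dcm_ds(dcm_need(el, "0028,0030", "PixelSpacing", path))
    if (is.null(el[["0028,1053"]]) || is.null(el[["0028,1052"]])) {
      rlang::abort(sprintf("DICOM file %s lacks rescale slope/intercept; HU calibration impossible", path),
                   class = "nwuct_calibration_error")
    }
    slope <- dcm_ds(el[["0028,1053"]]$bytes)
    intercept <- dcm_ds(el[["0028,1052"]]$bytes)
    bits <- dcm_us(dcm_need(el, "0028,0100", "BitsAllocated", path))
    if (bits != 16) {
      rlang::abort(sprintf("only 16-bit pixel data supported (%s has %d)",
                           path, bits), class = "nwuct_format_error")
    }
    pixrep <- if (!is.null(el[["0028,0103"]])) dcm_us(el[["0028,0103"]]$bytes) else 0L
    pix <- dcm_need(el, "7FE0,0010", "PixelData", path)
    vals <- readBin(pix, "integer", rows * cols, size = 2L,
                    endian = "little", signed = pixrep == 1L)
    list(uid = uid, rows = rows, cols = cols, ipp = ipp, iop = iop,
         ps = ps, hu = slope * vals + intercept)
  })
  uids <- vapply(slices, `[[`, "", "uid")
  if (length(unique(uids)) != 1L) {
    rlang::abort(sprintf("directory mixes %d DICOM series",
                         length(unique(uids))), class = "nwuct_series_error")
  }
  s1 <- slices[[1]]
  c1 <- s1$iop[1:3]  # direction of increasing column index (LPS)
  c2 <- s1$iop[4:6]  # direction of increasing row index (LPS)
  normal <- c(c1[2] * c2[3] - c1[3] * c2[2],
              c1[3] * c2[1] - c1[1] * c2[3],
              c1[1] * c2[2] - c1[2] * c2[1])
  proj <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(proj)
  slices <- slices[ord]
  proj <- proj[ord]
  dz <- diff(proj)
  if (any(abs(dz - mean(dz)) > 1e-3 * abs(mean(dz)) + 1e-6)) {
    rlang::abort("non-uniform slice spacing in DICOM series",
                 class = "nwuct_series_error")
  }
  data <- array(0, dim = c(s1$cols, s1$rows, length(slices)))
  for (k in seq_along(slices)) {
    data[, , k] <- matrix(slices[[k]]$hu, nrow = s1$cols)
  }
  aff_lps <- cbind(c(c1 * s1$ps[2], 0),   # PixelSpacing = (row, column)
                   c(c2 * s1$ps[1], 0),
                   c(normal * mean(dz), 0),
                   c(slices[[1]]$ipp, 1))
  aff_ras <- diag(c(-1, -1, 1, 1)) %*% aff_lps
  canonicalize_ras(data, aff_ras)
}

## reorient array+affine to canonical RAS via RNifti
canonicalize_ras <- function(data, affine) {
  img <- RNifti::asNifti(data)
  attr(affine, "code") <- 2L
  RNifti::`sform<-`(img, affine) -> img
  RNifti::orientation(img) <- "RAS"
  out <- as.array(img)
  attributes(out) <- list(dim = dim(out))
  out[!is.finite(out)] <- HU_SENTINEL
  ct_volume(out, unname(unclass(RNifti::xform(img)))[1:4, 1:4])
}

## ---- writer (used to build synthetic test series) ----

dcm_write_element <- function(con, group, elem, vr, bytes) {
  if (length(bytes) %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  writeBin(as.integer(c(group, elem)), con, size = 2L, endian = "little")
  writeChar(vr, con, nchars = 2L, eos = NULL)
  if (vr %in% LONG_VRS) {
    writeBin(as.integer(c(0L)), con, size = 2L, endian = "little")
    writeBin(length(bytes), con, size = 4L, endian = "little")
  } else {
    writeBin(length(bytes), con, size = 2L, endian = "little")
  }
  writeBin(bytes, con)
}

dcm_str_bytes <- function(x) charToRaw(paste(x, collapse = "\\"))

#' Write a CT volume as a synthetic classic DICOM series
#'
#' Emits one explicit-VR little-endian single-frame CT file per axial slice,
#' with geometry and HU rescale tags set so that [read_dicom_series()]
#' reproduces the volume. Intended for generating synthetic test data; the
#' volume must be RAS axis-aligned (diagonal affine with positive spacing).
#'
#' @param vol a [ct_volume].
#' @param dir output directory (created if needed).
#' @param slope,intercept HU rescale calibration to encode; stored pixel
#'   values are `(HU - intercept)/slope`, rounded, as signed 16-bit.
#' @param series_uid series instance UID string.
#' @param shuffle if `TRUE`, filenames are assigned in a scrambled order
#'   (slice order must be recovered from positions, not names).
#' @return Invisibly, the written file paths.
#' @export
write_dicom_series <- function(vol, dir, slope = 1, intercept = -1024,
                               series_uid = "1.2.826.0.1.3680043.2.9999.1",
                               shuffle = FALSE) {
  stopifnot(inherits(vol, "ct_volume"))
  A <- vol$affine
  if (max(abs(A[1:3, 1:3] - diag(vol$spacing))) > 1e-9) {
    rlang::abort("write_dicom_series requires an RAS axis-aligned volume",
                 class = "nwuct_affine_error")
  }
  dm <- dim(vol$data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- seq_len(dm[3])
  fname_order <- if (shuffle) rev(idx) else idx
  paths <- character(dm[3])
  for (k in idx) {
    path <- file.path(dir, sprintf("slice_%03d.dcm", fname_order[k]))
    paths[k] <- path
    con <- file(path, "wb")
    # preamble + magic
    writeBin(raw(128), con)
    writeChar("DICM", con, eos = NULL)
    # file meta group (explicit VR LE)
    ts <- charToRaw(TS_EXPLICIT_LE)
    meta_len <- 8L + length(ts) + length(ts) %% 2L
    dcm_write_element(con, 0x0002, 0x0000, "UL",
                      writeBin(meta_len, raw(), size = 4L, endian = "little"))
    dcm_write_element(con, 0x0002, 0x0010, "UI", ts)
    # dataset
    dcm_write_element(con, 0x0008, 0x0060, "CS", charToRaw("CT"))
    dcm_write_element(con, 0x0020, 0x000E, "UI", charToRaw(series_uid))
    dcm_write_element(con, 0x0020, 0x0013, "IS", dcm_str_bytes(k))
    # world position of voxel (0, 0, k-1), RAS -> LPS
    w0 <- voxel_to_world(vol, c(0, 0, k - 1))
    ipp <- c(-w0[1], -w0[2], w0[3])
    dcm_write_element(con, 0x0020, 0x0032, "DS",
                      dcm_str_bytes(sprintf("%.6f", ipp)))
    dcm_write_element(con, 0x0020, 0x0037, "DS",
                      dcm_str_bytes(sprintf("%.6f", c(-1, 0, 0, 0, -1, 0))))
    dcm_write_element(con, 0x0028, 0x0010, "US",
                      writeBin(as.integer(dm[2]), raw(), size = 2L,
                               endian = "little"))
    dcm_write_element(con, 0x0028, 0x0011, "US",
                      writeBin(as.integer(dm[1]), raw(), size = 2L,
                               endian = "little"))
    dcm_write_element(con, 0x0028, 0x0030, "DS",
                      dcm_str_bytes(sprintf("%.6f",
                                            c(vol$spacing[2], vol$spacing[1]))))
    for (tag_val in list(c(0x0100, 16L), c(0x0101, 16L), c(0x0102, 15L),
                         c(0x0103, 1L))) {
      dcm_write_element(con, 0x0028, tag_val[1], "US",
                        writeBin(as.integer(tag_val[2]), raw(), size = 2L,
                                 endian = "little"))
    }
    dcm_write_element(con, 0x0028, 0x1052, "DS",
                      dcm_str_bytes(format(intercept)))
    dcm_write_element(con, 0x0028, 0x1053, "DS", dcm_str_bytes(format(slope)))
    stored <- as.integer(round((vol$data[, , k] - intercept) / slope))
    if (any(stored < -32768 | stored > 32767)) {
      close(con)
      rlang::abort("stored pixel values exceed int16 range",
                   class = "nwuct_calibration_error")
    }
    pix <- writeBin(as.vector(stored), raw(), size = 2L, endian = "little")
    dcm_write_element(con, 0x7FE0, 0x0010, "OW", pix)
    close(con)
  }
  invisible(paths)
}
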