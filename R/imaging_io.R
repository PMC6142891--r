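#' Load a 3D volume from a NIfTI file
#'
#' The pipeline assumes the volume has already been skull-stripped and
#' affine-aligned to a standard space (e.g. MNI152) by external tools; no
#' resampling is performed here.
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return an object of class `cc_volume` with fields `voxels` (3D array),
#'   `spacing` (per-axis mm) and `shape`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop_format("expected a 3D volume, got %dD data in %s",
                length(dim(arr)), path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
  structure(list(voxels = arr, spacing = spacing, shape = dim(arr)),
            class = "cc_volume")
}

#' Save a 3D volume to NIfTI
#' @param v a `cc_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path) {
  img <- RNifti::asNifti(v$voxels)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract the midsagittal plane
#'
#' For a standard-space-aligned volume the midsagittal plane is the median
#' slice along the first (x) axis. With an even extent nx the lower median
#' `floor(nx / 2)` (0-based; R index `floor(nx / 2) + 1`) is taken, a
#' deterministic convention.
#'
#' @param v a `cc_volume`.
#' @return a `cc_slice` with origin (1, 1).
#' @export
extract_msp <- function(v) {
  nx <- dim(v$voxels)[1]
  idx <- nx %/% 2L + 1L
  slice(v$voxels[idx, , ])
}

#' Percentile intensity normalization
#'
#' Linearly maps the `p_low`-th percentile to 0 and the `p_high`-th to 255;
#' values outside are clipped to \[0, 255\]. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param s a `cc_slice` or matrix.
#' @param p_low,p_high percentiles in \[0, 100\], `p_low < p_high`;
#'   defaults 2 and 98.
#' @return a normalized `cc_slice` (same origin).
#' @export
normalize_intensity <- function(s, p_low = 2, p_high = 98) {
  s <- as_slice(s)
  if (p_low >= p_high) stop_input("p_low must be < p_high")
  q <- stats::quantile(s$pixels, c(p_low, p_high) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1])
    stop_degenerate("cannot normalize: percentile window is constant")
  out <- clamp((s$pixels - q[1]) / (q[2] - q[1]) * 255, 0, 255)
  slice(out, s$origin)
}

#' Crop a rectangular analysis window
#'
#' @param s a `cc_slice` or matrix.
#' @param bbox integer vector `(row0, col0, height, width)`, 1-based top-left
#'   corner; the crop spans rows `row0 .. row0 + height - 1`.
#' @return a `cc_slice` whose `origin` records the crop position within the
#'   parent (composed with the parent's own origin).
#' @export
crop <- function(s, bbox) {
  s <- as_slice(s)
  if (length(bbox) != 4L) stop_input("bbox must be (row0, col0, height, width)")
  r0 <- bbox[1]; c0 <- bbox[2]; h <- bbox[3]; w <- bbox[4]
  H <- nrow(s$pixels); W <- ncol(s$pixels)
  if (r0 < 1 || c0 < 1 || h < 1 || w < 1 || r0 + h - 1 > H || c0 + w - 1 > W)
    stop_input("bbox (%d,%d,%d,%d) out of bounds for %d x %d slice",
               r0, c0, h, w, H, W)
  slice(s$pixels[r0:(r0 + h - 1), c0:(c0 + w - 1), drop = FALSE],
        origin = s$origin + c(r0, c0) - 1L)
}

## ---- 2D slice / mask file I/O (PNG and 2D NIfTI) -------------------------

is_png <- function(path) grepl("\\.png$", path, ignore.case = TRUE)

read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]  # grayscale stored as RGB(A)
  a * 255
}

#' Read a 2D slice from PNG or NIfTI
#'
#' 8-bit grayscale PNG values are mapped to \[0, 255\]; NIfTI data must be 2D
#' (an H x W x 1 volume is squeezed).
#'
#' @param path path to a `.png`, `.nii` or `.nii.gz` file.
#' @return a `cc_slice`.
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  if (is_png(path)) return(slice(read_gray_png(path)))
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) == 3L && d[3] == 1L) arr <- arr[, , 1]
  if (length(dim(arr)) != 2L)
    stop_format("expected a 2D slice in %s", path)
  slice(arr)
}

#' Read a binary mask from PNG or NIfTI
#'
#' PNG convention: 0 = background, 255 = foreground; any value >= 127.5 maps
#' to foreground.
#'
#' @param path path to a `.png`, `.nii` or `.nii.gz` file.
#' @return a `cc_mask`.
#' @export
read_mask <- function(path) {
  s <- read_slice(path)
  mask(s$pixels >= 127.5)
}

#' Write a slice to PNG or 2D NIfTI
#' @param s a `cc_slice` or matrix; values are clipped to \[0, 255\] for PNG.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_slice <- function(s, path) {
  s <- as_slice(s)
  if (is_png(path)) {
    png::writePNG(clamp(s$pixels, 0, 255) / 255, path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(s$pixels), path)
  }
  invisible(path)
}

#' Write a mask to PNG (0/255) or 2D NIfTI (0/1)
#' @param m a `cc_mask` or 0/1 matrix.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path) {
  m <- as_mask(m)
  if (is_png(path)) {
    png::writePNG(m$labels * 1.0, path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(m$labels), path)
  }
  invisible(path)
}

#' Read an atlas cohort from a directory
#'
#' Expects paired files `<id>_image.<ext>` and `<id>_mask.<ext>` with
#' `ext` one of png, nii, nii.gz (the layout [cmd_simulate()] writes).
#'
#' @param dir directory containing the pairs.
#' @return a list of `cc_atlas`, sorted by id.
#' @export
read_atlas_dir <- function(dir) {
  if (!dir.exists(dir)) stop_input("no such directory: %s", dir)
  imgs <- list.files(dir, pattern = "_image\\.(png|nii|nii\\.gz)$")
  if (length(imgs) == 0L) stop_input("no '<id>_image.*' files in %s", dir)
  out <- lapply(imgs, function(f) {
    id <- sub("_image\\.(png|nii|nii\\.gz)$", "", f)
    ext <- sub(".*_image\\.", "", f)
    mf <- file.path(dir, paste0(id, "_mask.", ext))
    if (!file.exists(mf)) stop_input("missing mask for atlas '%s'", id)
    atlas(id, read_slice(file.path(dir, f)), read_mask(mf))
  })
  sort_atlases(out)
}
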