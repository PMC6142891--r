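#' 2D image slice
#'
#' The unit the whole method operates on: a cropped midsagittal-plane image.
#' Pixel values are arbitrary on construction; after [normalize_intensity()]
#' they lie in \[0, 255\]. `origin` records the 1-based (row, col) position of
#' this crop's top-left pixel within its parent slice, so parent coordinates
#' of any pixel are recoverable exactly.
#'
#' @param pixels numeric matrix (H x W), H, W >= 1.
#' @param origin integer vector (row, col), 1-based offset within the parent
#'   slice; `c(1, 1)` for an uncropped slice.
#' @return an object of class `cc_slice` with fields `pixels` and `origin`.
#' @export
slice <- function(pixels, origin = c(1L, 1L)) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_input("slice pixels must be a non-empty numeric matrix")
  if (length(origin) != 2L || any(origin < 1L))
    stop_input("origin must be a 1-based (row, col) pair")
  structure(list(pixels = pixels, origin = as.integer(origin)),
            class = "cc_slice")
}

#' @export
print.cc_slice <- function(x, ...) {
  cat(sprintf("<cc_slice %d x %d, origin (%d, %d), range [%.3g, %.3g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$origin[1], x$origin[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Coerce to a slice
#' @param x a `cc_slice` or numeric matrix.
#' @return a `cc_slice`.
#' @export
as_slice <- function(x) {
  if (inherits(x, "cc_slice")) return(x)
  slice(x)
}

#' Binary label mask
#'
#' Labels are 0 (background) and 1 (foreground, corpus callosum). A mask is
#' always paired with a slice of identical shape.
#'
#' @param labels matrix with values in \{0, 1\} (logical accepted).
#' @return an object of class `cc_mask` with field `labels` (integer matrix).
#' @export
mask <- function(labels) {
  labels <- as.matrix(labels)
  if (is.logical(labels)) labels <- labels * 1L
  if (!all(labels %in% c(0L, 1L)))
    stop_input("mask labels must be 0/1")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "cc_mask")
}

#' @export
print.cc_mask <- function(x, ...) {
  cat(sprintf("<cc_mask %d x %d, %d foreground pixels>\n",
              nrow(x$labels), ncol(x$labels), sum(x$labels)))
  invisible(x)
}

#' Coerce to a mask
#' @param x a `cc_mask`, logical matrix, or 0/1 numeric matrix.
#' @return a `cc_mask`.
#' @export
as_mask <- function(x) {
  if (inherits(x, "cc_mask")) return(x)
  mask(x)
}

#' Atlas: an intensity slice paired with its expert label mask
#'
#' Cohorts of atlases drive both the voting prior and the patch dictionaries.
#'
#' @param id character identifier, unique within a cohort.
#' @param image a `cc_slice` (or matrix).
#' @param mask a `cc_mask` (or 0/1 matrix) of the same shape.
#' @return an object of class `cc_atlas`.
#' @export
atlas <- function(id, image, mask) {
  image <- as_slice(image)
  mask <- as_mask(mask)
  if (!identical(dim(image$pixels), dim(mask$labels)))
    stop_input("atlas image and mask shapes differ")
  structure(list(id = as.character(id), image = image, mask = mask),
            class = "cc_atlas")
}

#' @export
print.cc_atlas <- function(x, ...) {
  cat(sprintf("<cc_atlas '%s' %d x %d, %d foreground pixels>\n",
              x$id, nrow(x$image$pixels), ncol(x$image$pixels),
              sum(x$mask$labels)))
  invisible(x)
}

## Internal accessors: tolerate raw matrices so that hot paths can skip
## class dispatch.
px <- function(x) if (inherits(x, "cc_slice")) x$pixels else as.matrix(x)
lb <- function(x) if (inherits(x, "cc_mask")) x$labels else {
  m <- as.matrix(x); storage.mode(m) <- "integer"; m
}

## Sort a list of atlases by id; the canonical cohort order used everywhere
## deterministic ordering matters (dictionary columns, tie-breaks).
sort_atlases <- function(atlases) {
  ids <- vapply(atlases, function(a) a$id, character(1))
  atlases[order(ids, method = "radix")]
}
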