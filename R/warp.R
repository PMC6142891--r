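## Warping interface
##
## True deformable registration is delegated to external tools; the package
## consumes their output. Built-ins: identity (for pre-aligned cohorts, the
## default) and exhaustive small-translation search; precomputed displacement
## fields can be loaded from 2-channel NIfTI files. Masks are always
## resampled nearest-neighbour so warped labels stay in {0, 1}.

shift_replicate <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  m[clamp(seq_len(H) - dr, 1L, H), clamp(seq_len(W) - dc, 1L, W), drop = FALSE]
}

#' Identity warp
#' @param a a `cc_atlas` (the moving image/mask pair).
#' @param target the target `cc_slice` (unused).
#' @return `a`, unchanged.
#' @export
warp_identity <- function(a, target) a

#' Exhaustive small-translation warp
#'
#' Searches integer shifts in `[-max_shift, max_shift]^2` for the one
#' maximizing the global Pearson correlation between the shifted atlas image
#' and the target, then applies it to image and mask (integer shifts, so
#' label resampling is exact). Ties resolve to the smallest shift in
#' row-major scan order.
#'
#' @param a a `cc_atlas`.
#' @param target the target `cc_slice` or matrix.
#' @param max_shift maximum absolute shift in pixels.
#' @return the shifted `cc_atlas`; the chosen shift is attribute `"shift"`.
#' @export
warp_translate <- function(a, target, max_shift = 3L) {
  t <- px(target); im <- px(a$image)
  best <- c(0L, 0L); best_score <- -Inf
  for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
    s <- shift_replicate(im, dr, dc)
    if (stats::sd(s) == 0 || stats::sd(t) == 0) next
    sc <- stats::cor(as.vector(s), as.vector(t))
    if (sc > best_score) { best_score <- sc; best <- c(dr, dc) }
  }
  out <- atlas(a$id, slice(shift_replicate(im, best[1], best[2])),
               mask(shift_replicate(lb(a$mask), best[1], best[2])))
  attr(out, "shift") <- best
  out
}

## Bilinear sampling of `m` at fractional (row, col) positions, edge-clamped.
bilinear_sample <- function(m, rows, cols) {
  H <- nrow(m); W <- ncol(m)
  rows <- clamp(rows, 1, H); cols <- clamp(cols, 1, W)
  r0 <- pmin(floor(rows), H - 1L); c0 <- pmin(floor(cols), W - 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

#' Apply a precomputed displacement field
#'
#' Pullback convention: output pixel (r, c) samples the atlas at
#' (r + d_row, c + d_col). Image resampled bilinearly, mask
#' nearest-neighbour.
#'
#' @param a a `cc_atlas`.
#' @param disp H x W x 2 array of (row, col) displacements in pixels.
#' @return the warped `cc_atlas`.
#' @export
warp_displacement <- function(a, disp) {
  im <- px(a$image); H <- nrow(im); W <- ncol(im)
  if (!identical(dim(disp)[1:2], c(H, W)) || dim(disp)[3] != 2L)
    stop_input("displacement field must be %d x %d x 2", H, W)
  rr <- matrix(seq_len(H), H, W) + disp[, , 1]
  cc <- matrix(rep(seq_len(W), each = H), H, W) + disp[, , 2]
  wi <- matrix(bilinear_sample(im, as.vector(rr), as.vector(cc)), H, W)
  nn <- cbind(clamp(round(as.vector(rr)), 1, H), clamp(round(as.vector(cc)), 1, W))
  wm <- matrix(lb(a$mask)[nn], H, W)
  atlas(a$id, slice(wi), mask(wm))
}

#' Resolve a warp specification to a warping function
#'
#' @param spec `"identity"`, `"translate"`, or `"file:<dir>"` where `<dir>`
#'   holds per-atlas `<id>_warp.nii[.gz]` 2-channel displacement fields.
#' @return a function `(atlas, target) -> warped atlas`.
#' @export
make_warper <- function(spec = "identity") {
  if (identical(spec, "identity")) return(warp_identity)
  if (identical(spec, "translate")) return(warp_translate)
  if (grepl("^file:", spec)) {
    dir <- sub("^file:", "", spec)
    return(function(a, target) {
      f <- file.path(dir, paste0(a$id, "_warp.nii"))
      if (!file.exists(f)) f <- paste0(f, ".gz")
      if (!file.exists(f)) stop_input("no displacement field for atlas '%s'", a$id)
      warp_displacement(a, as.array(RNifti::readNifti(f)))
    })
  }
  stop_input("unknown warp spec '%s'", spec)
}
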