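#' Image gradients: magnitude and direction
#'
#' Central differences in the interior, one-sided at the borders.
#' Direction is `atan2(g_row, g_col)` shifted to \[0, 2 pi); pixels with zero
#' gradient get direction 0 by convention.
#'
#' @param s a `cc_slice` or matrix with both dimensions >= 3.
#' @return list with `magnitude` and `direction` matrices.
#' @export
compute_gradients <- function(s) {
  m <- px(s)
  H <- nrow(m); W <- ncol(m)
  if (H < 3L || W < 3L) stop_input("need at least a 3 x 3 image")
  denr <- c(1, rep(2, H - 2), 1)
  denc <- c(1, rep(2, W - 2), 1)
  gr <- (m[c(2:H, H), , drop = FALSE] - m[c(1, 1:(H - 1)), , drop = FALSE]) / denr
  gc <- sweep(m[, c(2:W, W), drop = FALSE] - m[, c(1, 1:(W - 1)), drop = FALSE],
              2, denc, "/")
  mag <- sqrt(gr^2 + gc^2)
  dir <- atan2(gr, gc)
  dir[dir < 0] <- dir[dir < 0] + 2 * pi
  dir[mag == 0] <- 0
  list(magnitude = mag, direction = dir)
}

## Channel images for one slice under a channel mode.
channel_images <- function(s, channels = "intensity+grad") {
  m <- px(s)
  if (identical(channels, "intensity")) return(list(intensity = m))
  g <- compute_gradients(m)
  list(intensity = m, magnitude = g$magnitude, direction = g$direction)
}

#' Pooled per-channel scaling statistics
#'
#' Min/max of each feature channel pooled over a set of atlases (normally the
#' selected dictionary atlases). Both dictionary and target patches are
#' scaled with the same statistics so that intensity and gradient channels
#' contribute comparably to inner products.
#'
#' @param atlases list of `cc_atlas`.
#' @param channels `"intensity+grad"` (3 channels) or `"intensity"`.
#' @return list with vectors `min` and `max`, one entry per channel.
#' @export
channel_stats <- function(atlases, channels = "intensity+grad") {
  chs <- lapply(atlases, function(a) channel_images(a$image, channels))
  nch <- length(chs[[1]])
  lo <- vapply(seq_len(nch), function(k)
    min(vapply(chs, function(x) min(x[[k]]), numeric(1))), numeric(1))
  hi <- vapply(seq_len(nch), function(k)
    max(vapply(chs, function(x) max(x[[k]]), numeric(1))), numeric(1))
  list(min = lo, max = hi, channels = channels)
}

## Vectorized multi-centre patch extraction.
##
## chs:     list of channel matrices (same shape)
## stats:   channel_stats() output (min/max per channel)
## centers: n x 2 matrix of 1-based (row, col)
## p:       odd patch width
##
## Returns a (n_channels * p^2) x n matrix: channels stacked in order, each
## channel's pixels in row-major raster order (row varies slowest), each
## channel min-max scaled to [0, 1] with the pooled statistics, and each
## whole column L2-normalized (all-zero columns left as zero). The pre-
## normalization norms are returned as attribute "norms".
patch_matrix <- function(chs, stats, centers, p) {
  h <- (p - 1L) %/% 2L
  n <- nrow(centers)
  nch <- length(chs)
  Hp <- nrow(chs[[1]]) + 2L * h
  ## offsets in padded linear index, row-major raster order (dc fastest)
  offs <- as.vector(t(outer(-h:h, (-h:h) * Hp, "+")))
  li <- (centers[, 1] + h) + (centers[, 2] + h - 1L) * Hp
  idx <- outer(offs, li, "+")
  out <- matrix(0, nch * p * p, n)
  for (k in seq_len(nch)) {
    rng <- stats$max[k] - stats$min[k]
    ch <- if (rng > 0) (chs[[k]] - stats$min[k]) / rng else chs[[k]] * 0
    pad <- pad_replicate(ch, h)
    out[((k - 1L) * p * p + 1L):(k * p * p), ] <- pad[idx]
  }
  nrm <- sqrt(.colSums(out * out, nrow(out), n))
  nz <- nrm > 0
  if (any(nz)) out[, nz] <- out[, nz, drop = FALSE] *
      rep(1 / nrm[nz], each = nrow(out))
  attr(out, "norms") <- nrm
  out
}

#' Extract one multi-channel feature patch
#'
#' Concatenates the patch's intensity, gradient-magnitude and
#' gradient-direction channels (in that order, each in row-major raster
#' order), min-max scales each channel with the supplied pooled statistics,
#' and L2-normalizes the whole vector. Borders are edge-replicated.
#'
#' @param s a `cc_slice` or matrix.
#' @param grads output of [compute_gradients()] for `s`, or `NULL` to
#'   compute it (ignored in `"intensity"` mode).
#' @param center (row, col), 1-based.
#' @param p odd patch width.
#' @param stats [channel_stats()] output; defaults to statistics of `s`
#'   itself.
#' @param channels `"intensity+grad"` or `"intensity"`.
#' @return list of class `cc_feature_patch`: unit `values` vector of length
#'   `n_channels * p^2` and the pre-normalization `norm`.
#' @export
extract_feature_patch <- function(s, grads = NULL, center, p,
                                  stats = NULL, channels = "intensity+grad") {
  if (p %% 2L == 0L) stop_input("patch width must be odd")
  m <- px(s)
  chs <- if (identical(channels, "intensity")) list(intensity = m) else {
    if (is.null(grads)) grads <- compute_gradients(m)
    list(intensity = m, magnitude = grads$magnitude, direction = grads$direction)
  }
  if (is.null(stats))
    stats <- list(min = vapply(chs, min, numeric(1)),
                  max = vapply(chs, max, numeric(1)))
  pm <- patch_matrix(chs, stats, matrix(center, 1, 2), p)
  structure(list(values = pm[, 1], norm = attr(pm, "norms")[1]),
            class = "cc_feature_patch")
}
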