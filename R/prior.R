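#' Local normalized cross-correlation between two patches
#'
#' Pearson correlation of the two vectorized `(2 half + 1)^2` windows centred
#' at `center`. Windows reaching past the border use edge-replicated padding,
#' the package-wide border convention.
#'
#' @param a,b `cc_slice`s or matrices of the same shape.
#' @param center (row, col), 1-based.
#' @param half patch half-width; the window is `(2 half + 1)` pixels square.
#' @return correlation in \[-1, 1\].
#' @export
local_ncc <- function(a, b, center, half) {
  a <- px(a); b <- px(b)
  if (!identical(dim(a), dim(b))) stop_input("shapes differ")
  pa <- pad_replicate(a, half); pb <- pad_replicate(b, half)
  rr <- (center[1]):(center[1] + 2 * half)
  cc <- (center[2]):(center[2] + 2 * half)
  va <- as.vector(pa[rr, cc]); vb <- as.vector(pb[rr, cc])
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop_degenerate("zero-variance window: correlation undefined")
  stats::cor(va, vb)
}

## Mean local NCC over a grid of centres with stride = patch width;
## zero-variance windows contribute 0 (constant background patches carry no
## similarity information).
mean_ncc_score <- function(target, image, half) {
  t <- px(target); im <- px(image)
  H <- nrow(t); W <- ncol(t)
  stride <- 2L * half + 1L
  centers_r <- seq(1L + half, H, by = stride)
  centers_c <- seq(1L + half, W, by = stride)
  pt <- pad_replicate(t, half); pi <- pad_replicate(im, half)
  total <- 0; nwin <- 0L
  for (r in centers_r) for (c in centers_c) {
    rr <- r:(r + 2L * half); cc <- c:(c + 2L * half)
    va <- as.vector(pt[rr, cc]); vb <- as.vector(pi[rr, cc])
    v <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) 0 else stats::cor(va, vb)
    total <- total + v; nwin <- nwin + 1L
  }
  total / nwin
}

#' Select atlases by mean local cross-correlation
#'
#' Each (already warped) atlas receives one global score: the mean of local
#' NCC values over a grid covering the crop with stride equal to the patch
#' width. The top `n_select` scores win; ties break by atlas id
#' (lexicographic), so the order is total and deterministic.
#'
#' @param target the target `cc_slice` or matrix.
#' @param warped list of `cc_atlas` warped to the target.
#' @param n_select number to keep, `<= length(warped)`.
#' @param half patch half-width (default 3, i.e. 7 x 7 patches).
#' @return the selected atlases, best first; scores in attribute `"scores"`.
#' @export
select_atlases_ncc <- function(target, warped, n_select, half = 3L) {
  if (length(warped) == 0L) stop_input("empty atlas cohort")
  if (n_select > length(warped)) stop_input("n_select exceeds cohort size")
  ids <- vapply(warped, function(a) a$id, character(1))
  scores <- vapply(warped, function(a) mean_ncc_score(target, a$image, half),
                   numeric(1))
  ord <- order(-scores, ids, method = "radix")
  out <- warped[ord[seq_len(n_select)]]
  attr(out, "scores") <- scores[ord[seq_len(n_select)]]
  out
}

#' Fuse atlas labels into a voting probability map
#'
#' Per-voxel foreground probability is the fraction of masks labelling the
#' voxel foreground (the Kronecker-delta vote); the background probability is
#' its complement.
#'
#' @param masks list of `cc_mask` (or 0/1 matrices) of identical shape.
#' @return an object of class `cc_probmap`: `p_fg` (matrix in \[0, 1\]) and
#'   `n_voters`.
#' @export
vote <- function(masks) {
  if (length(masks) == 0L) stop_input("need at least one mask")
  mats <- lapply(masks, lb)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop_input("mask shapes differ")
  p <- Reduce(`+`, mats) / length(mats)
  structure(list(p_fg = p, n_voters = length(mats)), class = "cc_probmap")
}

#' @export
print.cc_probmap <- function(x, ...) {
  cat(sprintf("<cc_probmap %d x %d from %d voters, %d uncertain voxels>\n",
              nrow(x$p_fg), ncol(x$p_fg), x$n_voters,
              sum(x$p_fg > 0 & x$p_fg < 1)))
  invisible(x)
}

#' Threshold a probability map (prior-only baseline)
#'
#' Labels foreground where `p_fg >= 0.5`. The tie at exactly 0.5 goes to
#' foreground so that this baseline is the exact uninformative-likelihood
#' special case of the Bayesian decision rule (whose comparison is `>=`).
#'
#' @param pm a `cc_probmap`.
#' @return a `cc_mask`.
#' @export
piemv_segment <- function(pm) {
  mask(pm$p_fg >= 0.5)
}
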