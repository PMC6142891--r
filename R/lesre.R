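#' Select atlases by sum of squared intensity differences
#'
#' Scores each atlas by the sum over the crop of squared intensity
#' differences to the target; the `k` smallest scores are kept, ties broken
#' by atlas id.
#'
#' @param target the target `cc_slice` or matrix.
#' @param cohort list of `cc_atlas` of the same shape.
#' @param k number to keep, `<= length(cohort)`.
#' @return selected atlases, most similar first; scores in attribute
#'   `"scores"`.
#' @export
select_atlases_ssd <- function(target, cohort, k) {
  if (length(cohort) == 0L) stop_input("empty atlas cohort")
  if (k > length(cohort)) stop_input("k exceeds cohort size")
  t <- px(target)
  ids <- vapply(cohort, function(a) a$id, character(1))
  scores <- vapply(cohort, function(a) sum((t - px(a$image))^2), numeric(1))
  ord <- order(scores, ids, method = "radix")
  out <- cohort[ord[seq_len(k)]]
  attr(out, "scores") <- scores[ord[seq_len(k)]]
  out
}

#' Build labelled patch dictionaries at one voxel
#'
#' Every location j in the `(2 search_half + 1)^2` search window around
#' `center` of every selected (pre-aligned) atlas contributes its feature
#' patch: to the foreground dictionary if the atlas mask at j is 1, else to
#' the background dictionary. Columns are ordered canonically by
#' (atlas id, row, col). Window locations falling outside the canvas are
#' dropped.
#'
#' @param selected list of `cc_atlas` (dictionary atlases).
#' @param center (row, col), 1-based.
#' @param search_half search-window half-width (3 gives the 7 x 7 window).
#' @param p odd patch width.
#' @param stats pooled [channel_stats()]; defaults to statistics of
#'   `selected`.
#' @param channels `"intensity+grad"` or `"intensity"`.
#' @return list with `D_f` and `D_b`, each of class `cc_dictionary`:
#'   `columns` (unit-norm matrix, possibly 0 columns), `label`, and `source`
#'   (data frame: atlas id, row, col per column).
#' @export
build_dictionaries <- function(selected, center, search_half, p,
                               stats = NULL, channels = "intensity+grad") {
  selected <- sort_atlases(selected)
  if (is.null(stats)) stats <- channel_stats(selected, channels)
  d <- dim(px(selected[[1]]$image))
  rr <- (center[1] - search_half):(center[1] + search_half)
  cc <- (center[2] - search_half):(center[2] + search_half)
  rr <- rr[rr >= 1 & rr <= d[1]]; cc <- cc[cc >= 1 & cc <= d[2]]
  locs <- as.matrix(expand.grid(col = cc, row = rr))[, c("row", "col"), drop = FALSE]
  locs <- locs[order(locs[, 1], locs[, 2]), , drop = FALSE]
  cols <- list(); labs <- integer(0); src <- list()
  for (a in selected) {
    chs <- channel_images(a$image, channels)
    pm <- patch_matrix(chs, stats, locs, p)
    cols[[length(cols) + 1L]] <- pm
    labs <- c(labs, lb(a$mask)[locs])
    src[[length(src) + 1L]] <- data.frame(atlas = a$id, row = locs[, 1],
                                          col = locs[, 2])
  }
  M <- do.call(cbind, cols)
  source <- do.call(rbind, src)
  new_dict <- function(keep, label) {
    structure(list(columns = M[, keep, drop = FALSE], label = label,
                   source = source[keep, , drop = FALSE]),
              class = "cc_dictionary")
  }
  list(D_f = new_dict(labs == 1L, "f"), D_b = new_dict(labs == 0L, "b"))
}

#' @export
print.cc_dictionary <- function(x, ...) {
  cat(sprintf("<cc_dictionary '%s', %d columns of length %d>\n",
              x$label, ncol(x$columns), nrow(x$columns)))
  invisible(x)
}

#' Orthogonal matching pursuit
#'
#' Greedy sparse coding: at each iteration the unselected column with the
#' largest absolute inner product with the current residual joins the
#' support, all coefficients on the support are refit by least squares, and
#' the residual is updated. Stops at the sparsity limit, when the residual
#' norm drops to `tol`, or when no column has a nonzero projection. The
#' least-squares refit guarantees a non-increasing residual norm.
#'
#' @param y target vector, a `cc_feature_patch`, or single-column matrix.
#' @param D a `cc_dictionary` or column matrix; an empty dictionary yields
#'   the defined limit: empty support and residual norm `||y||`.
#' @param sparsity maximum number of nonzero coefficients, >= 1.
#' @param tol residual-norm stopping threshold.
#' @return list of class `cc_sparse_fit`: `support` (column indices in
#'   selection order), `coefficients`, `residual_norm`, and
#'   `residual_path` (norm after each iteration, starting at `||y||`).
#' @export
omp <- function(y, D, sparsity = 5L, tol = 1e-6) {
  if (inherits(y, "cc_feature_patch")) y <- y$values
  y <- as.numeric(y)
  M <- if (inherits(D, "cc_dictionary")) D$columns else as.matrix(D)
  if (sparsity < 1L) stop_input("sparsity must be >= 1")
  rn <- sqrt(sum(y * y))
  path <- rn
  support <- integer(0); coefs <- numeric(0)
  if (ncol(M) > 0L) {
    r <- y
    while (length(support) < min(sparsity, ncol(M)) && rn > tol) {
      proj <- abs(crossprod(M, r))
      proj[support] <- -1
      j <- which.max(proj)
      if (proj[j] <= 1e-12) break
      support <- c(support, j)
      fit <- qr.coef(qr(M[, support, drop = FALSE]), y)
      fit[is.na(fit)] <- 0
      r <- y - M[, support, drop = FALSE] %*% fit
      rn <- sqrt(sum(r * r))
      path <- c(path, rn)
      coefs <- as.numeric(fit)
    }
  }
  structure(list(support = support, coefficients = coefs,
                 residual_norm = rn, residual_path = path),
            class = "cc_sparse_fit")
}

## Evaluation voxel sets --------------------------------------------------

## Voxels whose search window could contain a foreground dictionary atom.
## Outside this set D_f is empty, so eps_f = ||y|| = 1 >= eps_b and the
## label is provably background without running the solver.
fg_window_voxels <- function(selected, search_half) {
  u <- Reduce(`|`, lapply(selected, function(a) lb(a$mask) == 1L))
  which(dilate_square(u, search_half), arr.ind = TRUE)
}

resolve_voxels <- function(target, selected, cfg, voxels) {
  if (!is.null(voxels)) {
    v <- as.matrix(voxels)
    colnames(v) <- NULL
    return(v)
  }
  d <- dim(px(target))
  switch(cfg$lesre$eval,
    full = as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]))),
    fg_window = ,
    uncertain_band = {
      v <- fg_window_voxels(selected, cfg$lesre$search %/% 2L)
      colnames(v) <- NULL
      v
    },
    stop_input("unknown lesre.eval mode '%s'", cfg$lesre$eval))
}

#' Per-voxel sparse-representation error fields
#'
#' For each evaluated voxel, builds the foreground and background
#' dictionaries from the search windows of the selected atlases, sparsely
#' codes the target's feature patch against each with OMP, and records the
#' two residual norms and their clamped ratio `eps_f / eps_b`. Voxels
#' outside the evaluation set are marked not computed. Fully deterministic.
#'
#' Ratio conventions: a zero denominator with nonzero numerator maps to
#' `ratio_max`, a zero numerator to `ratio_min` (via the clamp), and the
#' degenerate 0/0 case to 1.
#'
#' @param target the target `cc_slice` or matrix.
#' @param selected dictionary atlases (e.g. from [select_atlases_ssd()]).
#' @param cfg a [bibs_config()]; uses `lesre$search`, `lesre$patch`,
#'   `lesre$sparsity`, `lesre$tol`, `lesre$channels`, `lesre$eval` and
#'   `bayes$ratio_min` / `bayes$ratio_max`.
#' @param voxels optional n x 2 matrix of (row, col) voxels to evaluate;
#'   when `NULL` the set implied by `cfg$lesre$eval` is used
#'   (`"full"` = whole crop; `"fg_window"` / `"uncertain_band"` = voxels
#'   whose search window meets at least one atlas foreground label — pass
#'   the band explicitly for true prior-band evaluation).
#' @return list of class `cc_error_field`: matrices `eps_f`, `eps_b`,
#'   `ratio`, logical `computed`.
#' @export
error_field <- function(target, selected, cfg = bibs_config(), voxels = NULL) {
  t <- px(target)
  H <- nrow(t); W <- ncol(t)
  selected <- sort_atlases(selected)
  p <- cfg$lesre$patch
  sh <- cfg$lesre$search %/% 2L
  channels <- cfg$lesre$channels
  vox <- resolve_voxels(target, selected, cfg, voxels)

  eps_f <- matrix(NA_real_, H, W); eps_b <- matrix(NA_real_, H, W)
  ratio <- matrix(NA_real_, H, W)
  computed <- matrix(FALSE, H, W)
  out <- structure(list(eps_f = eps_f, eps_b = eps_b, ratio = ratio,
                        computed = computed), class = "cc_error_field")
  if (nrow(vox) == 0L) return(out)

  stats <- channel_stats(selected, channels)

  ## dictionary-atom locations: union of all search windows, clipped
  need <- matrix(FALSE, H, W)
  need[vox] <- TRUE
  need <- dilate_square(need, sh)
  locs <- which(need, arr.ind = TRUE)
  locs <- locs[order(locs[, 1], locs[, 2]), , drop = FALSE]
  nloc <- nrow(locs)
  locpos <- matrix(NA_integer_, H, W)
  locpos[locs] <- seq_len(nloc)

  ## one patch matrix per atlas over the needed locations; concatenated with
  ## atlases in id order so column order is the canonical (id, row, col) sort
  mats <- vector("list", length(selected))
  labs <- vector("list", length(selected))
  for (i in seq_along(selected)) {
    chs <- channel_images(selected[[i]]$image, channels)
    mats[[i]] <- patch_matrix(chs, stats, locs, p)
    labs[[i]] <- lb(selected[[i]]$mask)[locs]
  }
  P <- do.call(cbind, mats)
  lab <- unlist(labs)
  na <- length(selected)

  ## target feature patches at all evaluated voxels
  tch <- channel_images(t, channels)
  Y <- patch_matrix(tch, stats, vox, p)

  off <- -sh:sh
  for (v in seq_len(nrow(vox))) {
    r <- vox[v, 1]; c <- vox[v, 2]
    wr <- r + off; wr <- wr[wr >= 1 & wr <= H]
    wc <- c + off; wc <- wc[wc >= 1 & wc <= W]
    wpos <- locpos[wr, wc]
    wpos <- wpos[!is.na(wpos)]
    cols <- as.vector(outer(wpos, (seq_len(na) - 1L) * nloc, "+"))
    wl <- lab[cols]
    y <- Y[, v]
    ef <- omp(y, P[, cols[wl == 1L], drop = FALSE],
              cfg$lesre$sparsity, cfg$lesre$tol)$residual_norm
    eb <- omp(y, P[, cols[wl == 0L], drop = FALSE],
              cfg$lesre$sparsity, cfg$lesre$tol)$residual_norm
    out$eps_f[r, c] <- ef
    out$eps_b[r, c] <- eb
    out$ratio[r, c] <- if (eb == 0) {
      if (ef == 0) 1 else cfg$bayes$ratio_max
    } else clamp(ef / eb, cfg$bayes$ratio_min, cfg$bayes$ratio_max)
    out$computed[r, c] <- TRUE
  }
  out
}

#' @export
print.cc_error_field <- function(x, ...) {
  cat(sprintf("<cc_error_field %d x %d, %d computed voxels>\n",
              nrow(x$ratio), ncol(x$ratio), sum(x$computed)))
  invisible(x)
}

#' Label from reconstruction errors alone (likelihood-only baseline)
#'
#' Foreground where `eps_f < eps_b`; ties and uncomputed voxels go to
#' background.
#'
#' @param ef a `cc_error_field`.
#' @return a `cc_mask`.
#' @export
lesre_label <- function(ef) {
  m <- ef$computed & !is.na(ef$eps_f) & (ef$eps_f < ef$eps_b)
  m[is.na(m)] <- FALSE
  mask(m)
}
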