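# Independent oracles, kept deliberately naive.

# Best least-squares residual norm over every support of size <= sparsity:
# the exhaustive counterpart of greedy matching pursuit.
exhaustive_ls_residual <- function(y, D, sparsity) {
  best <- sqrt(sum(y^2))  # empty support
  n <- ncol(D)
  for (k in seq_len(min(sparsity, n))) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      fit <- qr.coef(qr(D[, s, drop = FALSE]), y)
      fit[is.na(fit)] <- 0
      r <- y - D[, s, drop = FALSE] %*% fit
      best <- min(best, sqrt(sum(r^2)))
    }
  }
  best
}

# Hole count by direct enumeration: 8-connected background components that
# never touch the image border.
count_holes_direct <- function(m) {
  m <- if (inherits(m, "cc_mask")) m$labels else m
  bg <- m == 0L
  lab <- bibseg:::label_components(bg, 8L)
  if (lab$n == 0L) return(0L)
  border <- unique(c(lab$labels[1, ], lab$labels[nrow(m), ],
                     lab$labels[, 1], lab$labels[, ncol(m)]))
  length(setdiff(seq_len(lab$n), border))
}
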