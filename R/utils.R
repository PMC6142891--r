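#' @keywords internal
"_PACKAGE"

## Condition helpers: each pipeline failure mode carries a class so that the
## command-line wrapper can map it onto a stable exit code and tests can
## assert on the class rather than on message text.

stop_input <- function(msg, ...) {
  stop(structure(class = c("cc_input_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_format <- function(msg, ...) {
  stop(structure(class = c("cc_format_error", "cc_input_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_degenerate <- function(msg, ...) {
  stop(structure(class = c("cc_degenerate_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_calibration <- function(msg, ...) {
  stop(structure(class = c("cc_calibration_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_geometry <- function(msg, ...) {
  stop(structure(class = c("cc_geometry_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_metric <- function(msg, ...) {
  stop(structure(class = c("cc_metric_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Edge-replicate padding by h pixels on every side; the single border
## convention used by every patch-based operation in the package.
pad_replicate <- function(m, h) {
  if (h == 0L) return(m)
  ri <- c(rep(1L, h), seq_len(nrow(m)), rep(nrow(m), h))
  ci <- c(rep(1L, h), seq_len(ncol(m)), rep(ncol(m), h))
  m[ri, ci, drop = FALSE]
}

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. Keeps phantom generation reproducible
## without clobbering user RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Binary dilation of a logical matrix by a (2h+1) square structuring element.
dilate_square <- function(m, h) {
  if (h == 0L) return(m)
  out <- matrix(FALSE, nrow(m), ncol(m))
  H <- nrow(m); W <- ncol(m)
  for (dr in -h:h) {
    rs <- clamp(seq_len(H) + dr, 1L, H)
    shifted <- m[rs, , drop = FALSE]
    for (dc in -h:h) {
      cs <- clamp(seq_len(W) + dc, 1L, W)
      out <- out | shifted[, cs, drop = FALSE]
    }
  }
  out
}
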