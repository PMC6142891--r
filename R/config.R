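config_defaults <- function() {
  list(
    prior = list(n_select = 10L,   # atlases fused into the voting prior
                 patch = 7L,       # NCC selection patch width (7 x 7)
                 warp = "identity"),
    lesre = list(n_select = 30L,   # dictionary atlas count
                 search = 7L,      # search window width (7 x 7)
                 patch = 13L,      # feature patch width (13 x 13)
                 sparsity = 5L,
                 tol = 1e-6,
                 channels = "intensity+grad",
                 eval = "uncertain_band"),
    bayes = list(ratio_min = 1e-3, ratio_max = 1e3,
                 min_calib_samples = 50L),
    io = list(crop_bbox = NULL),
    seed = 1L)
}

#' Pipeline configuration
#'
#' Nested configuration with validated defaults. The dictionary-stage
#' defaults (30 atlases, 7 x 7 search window, 13 x 13 patches) and the
#' prior-stage defaults (10 atlases, 7 x 7 patches) are the operating points
#' the method performs best at; all are overridable. Unknown keys are
#' rejected. The resolved configuration has a stable content hash
#' ([config_hash()]) that is stamped into every output.
#'
#' @param ... overrides as nested named lists, e.g.
#'   `bibs_config(lesre = list(patch = 9))`.
#' @return an object of class `bibs_config`.
#' @export
bibs_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- merge_config(cfg, over, path = "")
  validate_config(cfg)
  structure(cfg, class = "bibs_config")
}

merge_config <- function(base, over, path) {
  if (length(over) == 0L) return(base)
  nms <- names(over)
  if (is.null(nms) || any(nms == ""))
    stop_input("config overrides must be named")
  for (k in nms) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stop_input("unknown config key '%s'", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(over[[k]]))
        stop_input("config key '%s' must be a named list", full)
      base[[k]] <- merge_config(base[[k]], over[[k]], full)
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, msg, ...) if (!ok) stop_input(msg, ...)
  chk(cfg$prior$n_select >= 1, "prior.n_select must be >= 1")
  chk(cfg$prior$patch %% 2 == 1 && cfg$prior$patch >= 3,
      "prior.patch must be odd and >= 3")
  chk(is.character(cfg$prior$warp), "prior.warp must be a string")
  chk(cfg$lesre$n_select >= 1, "lesre.n_select must be >= 1")
  chk(cfg$lesre$search %% 2 == 1 && cfg$lesre$search >= 1,
      "lesre.search must be odd and >= 1")
  chk(cfg$lesre$patch %% 2 == 1 && cfg$lesre$patch >= 3,
      "lesre.patch must be odd and >= 3")
  chk(cfg$lesre$sparsity >= 1, "lesre.sparsity must be >= 1")
  chk(cfg$lesre$tol >= 0, "lesre.tol must be >= 0")
  chk(cfg$lesre$channels %in% c("intensity", "intensity+grad"),
      "lesre.channels must be 'intensity' or 'intensity+grad'")
  chk(cfg$lesre$eval %in% c("uncertain_band", "fg_window", "full"),
      "lesre.eval must be 'uncertain_band', 'fg_window' or 'full'")
  chk(cfg$bayes$ratio_min > 0 && cfg$bayes$ratio_max > cfg$bayes$ratio_min,
      "bayes ratio clamp bounds invalid")
  chk(cfg$bayes$min_calib_samples >= 2, "bayes.min_calib_samples must be >= 2")
  chk(is.null(cfg$io$crop_bbox) || length(cfg$io$crop_bbox) == 4L,
      "io.crop_bbox must be NULL or (row0, col0, height, width)")
  invisible(cfg)
}

#' Read a YAML configuration file
#'
#' Keys present in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a [bibs_config()].
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(bibs_config())
  if (!file.exists(path)) stop_input("no such config file: %s", path)
  bibs_config(yaml::read_yaml(path))
}

#' Content hash of a resolved configuration
#'
#' FNV-1a 32-bit hash of the canonical JSON serialization; equal hashes mean
#' equal resolved configurations, and every pipeline output is stamped with
#' it for reproducibility bookkeeping.
#'
#' @param cfg a [bibs_config()].
#' @return an 8-character hex string.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  bytes <- utf8ToInt(as.character(s))
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    ## xor on doubles via two 16-bit halves (bitwXor needs < 2^31)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- bitwXor(lo, b) + hi * 65536
    ## 32-bit modular multiply in doubles, split to stay within 2^53
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
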