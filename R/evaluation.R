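#' Dice overlap index
#'
#' `2 |A intersect B| / (|A| + |B|) x 100`, in percent.
#'
#' @param a,b `cc_mask`s (or 0/1 matrices) of the same shape, not both empty.
#' @return Dice index in \[0, 100\].
#' @export
dice <- function(a, b) {
  a <- lb(a); b <- lb(b)
  if (!identical(dim(a), dim(b))) stop_input("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) stop_metric("Dice undefined: both masks empty")
  2 * sum(a & b) / (na + nb) * 100
}

## Flood-fill component labelling of a logical matrix under 4- or
## 8-connectivity. Small and allocation-light; masks here are a few
## thousand pixels.
label_components <- function(m, connectivity = 4L) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nbr <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(c(-1L, 0L, 1L), 3)[-5], rep(c(-1L, 0L, 1L), each = 3)[-5])
  }
  comp <- 0L
  stack <- integer(H * W)
  for (start in which(m)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- comp
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- ((cur - 1L) %% H) + 1L
      c <- ((cur - 1L) %/% H) + 1L
      for (k in seq_len(nrow(nbr))) {
        rr <- r + nbr[k, 1]; cc <- c + nbr[k, 2]
        if (rr < 1L || rr > H || cc < 1L || cc > W) next
        idx <- rr + (cc - 1L) * H
        if (m[idx] && lab[idx] == 0L) {
          lab[idx] <- comp
          top <- top + 1L
          stack[top] <- idx
        }
      }
    }
  }
  list(labels = lab, n = comp)
}

#' Count foreground connected components
#'
#' 4-connected foreground, the package-wide topology convention
#' (paired with 8-connected background for holes).
#'
#' @param m a `cc_mask` or logical/0-1 matrix.
#' @return number of components (0 for an empty mask).
#' @export
count_components <- function(m) {
  label_components(lb(m) == 1L, 4L)$n
}

#' Euler number of a binary mask
#'
#' Components minus holes under the Jordan-consistent (4-connected
#' foreground, 8-connected background) convention. Holes are 8-connected
#' background components not connected to the border (counted after padding
#' with a background ring). A single hole-free region has Euler number 1.
#'
#' @param m a `cc_mask` or logical/0-1 matrix.
#' @return integer Euler number.
#' @export
euler_number <- function(m) {
  fg <- lb(m) == 1L
  comp <- label_components(fg, 4L)$n
  bg_pad <- matrix(TRUE, nrow(fg) + 2L, ncol(fg) + 2L)
  bg_pad[2:(nrow(fg) + 1L), 2:(ncol(fg) + 1L)] <- !fg
  holes <- label_components(bg_pad, 8L)$n - 1L
  comp - holes
}

## Per-target stage artifacts shared by the harness methods.
loo_target_artifacts <- function(tgt, others, cfg, need_lesre) {
  st <- prior_stage(tgt$image, others, cfg)
  k <- min(cfg$lesre$n_select, length(others))
  ssd <- select_atlases_ssd(tgt$image, st$warped, k)
  vox <- st$band
  if (need_lesre) {
    sh <- cfg$lesre$search %/% 2L
    fgwin <- fg_window_voxels(ssd, sh)
    sel <- matrix(FALSE, nrow(px(tgt$image)), ncol(px(tgt$image)))
    sel[fgwin] <- TRUE
    sel[vox] <- TRUE
    vox <- which(sel, arr.ind = TRUE)
    colnames(vox) <- NULL
  }
  ef <- error_field(tgt$image, ssd, cfg, voxels = vox)
  list(st = st, ssd = ssd, ef = ef)
}

#' Leave-one-out evaluation harness
#'
#' Each cohort member in turn is the target and the rest are atlases; every
#' requested method is run and Dice, component count and Euler number are
#' recorded against the member's ground truth. When `BIbS` is requested the
#' gamma likelihood is calibrated once from the same leave-one-out error
#' fields (ratios pooled over the uncertain band by true label) and shared
#' across targets. Deterministic given cohort and configuration.
#'
#' @param cohort a `cc_cohort` or list of >= 3 `cc_atlas`.
#' @param methods subset of `c("PIEMV", "LESRE", "OLD_LESRE", "BIbS")`.
#' @param config a [bibs_config()].
#' @param verbose print per-target progress?
#' @return a data frame of class `cc_eval` with one row per
#'   (target, method): `target_id`, `method`, `dice_pct`, `n_components`,
#'   `euler`, `config_hash`. Per-target stage errors are recorded as `NA`
#'   rows and the run continues.
#' @export
leave_one_out <- function(cohort,
                          methods = c("PIEMV", "LESRE", "OLD_LESRE", "BIbS"),
                          config = bibs_config(), verbose = FALSE) {
  atlases <- if (inherits(cohort, "cc_cohort")) cohort$atlases else cohort
  if (length(atlases) < 3L) stop_input("leave-one-out needs >= 3 atlases")
  methods <- match.arg(methods, several.ok = TRUE)
  need_lesre <- "LESRE" %in% methods
  hash <- config_hash(config)
  n <- length(atlases)

  arts <- vector("list", n)
  arts_old <- vector("list", n)
  rf <- list(); rb <- list()
  for (i in seq_len(n)) {
    tgt <- atlases[[i]]
    others <- atlases[-i]
    arts[[i]] <- tryCatch(
      loo_target_artifacts(tgt, others, config, need_lesre),
      error = function(e) e)
    if (!inherits(arts[[i]], "error") && "BIbS" %in% methods) {
      ef <- arts[[i]]$ef
      truth <- lb(tgt$mask)
      in_band <- matrix(FALSE, nrow(truth), ncol(truth))
      in_band[arts[[i]]$st$band] <- TRUE
      use <- ef$computed & in_band
      rf[[i]] <- ef$ratio[use & truth == 1L]
      rb[[i]] <- ef$ratio[use & truth == 0L]
    }
    if ("OLD_LESRE" %in% methods) {
      cfg_old <- config
      cfg_old$lesre$channels <- "intensity"
      arts_old[[i]] <- tryCatch(
        loo_target_artifacts(tgt, others, cfg_old, need_lesre = TRUE),
        error = function(e) e)
    }
    if (verbose) message(sprintf("target %d/%d ('%s') done", i, n, tgt$id))
  }

  gm <- NULL
  if ("BIbS" %in% methods)
    gm <- new_bibs_model(unlist(rf), unlist(rb), config, atlases)

  rows <- list()
  for (i in seq_len(n)) {
    tgt <- atlases[[i]]
    truth <- tgt$mask
    for (mth in methods) {
      art <- if (mth == "OLD_LESRE") arts_old[[i]] else arts[[i]]
      res <- tryCatch({
        if (inherits(art, "error")) stop(art)
        seg <- switch(mth,
          PIEMV = piemv_segment(art$st$pm),
          LESRE = lesre_label(art$ef),
          OLD_LESRE = lesre_label(art$ef),
          BIbS = decide(art$ef, art$st$pm, gm)$mask)
        data.frame(target_id = tgt$id, method = mth,
                   dice_pct = dice(seg, truth),
                   n_components = count_components(seg),
                   euler = euler_number(seg),
                   config_hash = hash, stringsAsFactors = FALSE)
      }, error = function(e) {
        warning(sprintf("target '%s', method %s failed: %s",
                        tgt$id, mth, conditionMessage(e)), call. = FALSE)
        data.frame(target_id = tgt$id, method = mth, dice_pct = NA_real_,
                   n_components = NA_integer_, euler = NA_integer_,
                   config_hash = hash, stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cc_eval", "data.frame")
  attr(out, "model") <- gm
  out
}

#' Summarize a leave-one-out run
#'
#' Per-method mean/sd/n of the Dice index, plus paired one-sided t-tests of
#' the comparisons the method is designed around (full Bayesian vs each
#' single-information baseline, and gradient-augmented vs intensity-only
#' likelihood), where both methods are present. The tests are descriptive
#' statistics of the synthetic run.
#'
#' @param object a `cc_eval` data frame from [leave_one_out()].
#' @param ... unused.
#' @return list with elements `methods` (data frame: method, mean, sd, n)
#'   and `tests` (data frame: comparison, p_value).
#' @export
summary.cc_eval <- function(object, ...) {
  sp <- split(object$dice_pct, object$method)
  tab <- data.frame(method = names(sp),
                    mean = vapply(sp, function(x) mean(x, na.rm = TRUE), numeric(1)),
                    sd = vapply(sp, function(x) stats::sd(x, na.rm = TRUE), numeric(1)),
                    n = vapply(sp, function(x) sum(!is.na(x)), integer(1)),
                    row.names = NULL)
  paired_p <- function(a, b) {  # H1: mean(a) > mean(b), paired by target
    da <- object[object$method == a, ]; db <- object[object$method == b, ]
    x <- da$dice_pct[match(db$target_id, da$target_id)]
    ok <- !is.na(x) & !is.na(db$dice_pct)
    if (sum(ok) < 3) return(NA_real_)
    stats::t.test(x[ok], db$dice_pct[ok], paired = TRUE,
                  alternative = "greater")$p.value
  }
  tests <- list()
  have <- function(...) all(c(...) %in% object$method)
  if (have("BIbS", "LESRE"))
    tests[["BIbS > LESRE"]] <- paired_p("BIbS", "LESRE")
  if (have("BIbS", "PIEMV"))
    tests[["BIbS > PIEMV"]] <- paired_p("BIbS", "PIEMV")
  if (have("LESRE", "OLD_LESRE"))
    tests[["LESRE > OLD_LESRE"]] <- paired_p("LESRE", "OLD_LESRE")
  list(methods = tab,
       tests = data.frame(comparison = names(tests),
                          p_value = unlist(tests, use.names = FALSE)))
}

#' Parameter sweep of the Bayesian pipeline
#'
#' Re-runs [leave_one_out()] (BIbS only) for each value of one parameter,
#' holding the others fixed.
#'
#' @param cohort a `cc_cohort` or list of `cc_atlas`.
#' @param parameter `"n_atlases"` (dictionary atlas count), `"search"`
#'   (search window width) or `"patch"` (patch width).
#' @param values grid of values to try.
#' @param config base [bibs_config()].
#' @param verbose print progress?
#' @return data frame with columns `parameter`, `value`, `mean_dice`,
#'   `sd_dice`, `n`.
#' @export
sweep_parameter <- function(cohort, parameter = c("n_atlases", "search", "patch"),
                            values, config = bibs_config(), verbose = FALSE) {
  parameter <- match.arg(parameter)
  rows <- lapply(values, function(v) {
    cfg <- config
    key <- switch(parameter, n_atlases = "n_select", search = "search",
                  patch = "patch")
    cfg$lesre[[key]] <- v
    rec <- leave_one_out(cohort, methods = "BIbS", config = cfg,
                         verbose = verbose)
    data.frame(parameter = parameter, value = v,
               mean_dice = mean(rec$dice_pct, na.rm = TRUE),
               sd_dice = stats::sd(rec$dice_pct, na.rm = TRUE),
               n = sum(!is.na(rec$dice_pct)))
  })
  do.call(rbind, rows)
}

#' Write / read an evaluation table as CSV
#' @param records a `cc_eval` data frame.
#' @param path CSV path.
#' @return `path` (write) or the `cc_eval` data frame (read).
#' @export
write_eval_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eval_csv
#' @export
read_eval_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cc_eval", "data.frame")
  out
}
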