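#' Construct a gamma likelihood model
#'
#' Per-class shape/scale parameters of the reconstruction-error-ratio
#' distribution; usually produced by [bibs_fit()], but constructible directly
#' (e.g. to study the uninformative-likelihood limit).
#'
#' @param alpha_f,beta_f foreground shape and scale, > 0.
#' @param alpha_b,beta_b background shape and scale, > 0.
#' @param n_samples_f,n_samples_b calibration sample counts.
#' @param fit_method identifier of the fitting procedure.
#' @return an object of class `cc_gamma_model`.
#' @export
gamma_model <- function(alpha_f, beta_f, alpha_b, beta_b,
                        n_samples_f = 0L, n_samples_b = 0L,
                        fit_method = "manual") {
  if (any(c(alpha_f, beta_f, alpha_b, beta_b) <= 0))
    stop_input("gamma parameters must be strictly positive")
  structure(list(alpha_f = alpha_f, beta_f = beta_f,
                 alpha_b = alpha_b, beta_b = beta_b,
                 n_samples_f = as.integer(n_samples_f),
                 n_samples_b = as.integer(n_samples_b),
                 fit_method = fit_method),
            class = "cc_gamma_model")
}

#' @export
print.cc_gamma_model <- function(x, ...) {
  cat("Gamma likelihood of the reconstruction-error ratio\n")
  cat(sprintf("  foreground: alpha = %.4g, beta = %.4g (mean %.4g, n = %d)\n",
              x$alpha_f, x$beta_f, x$alpha_f * x$beta_f, x$n_samples_f))
  cat(sprintf("  background: alpha = %.4g, beta = %.4g (mean %.4g, n = %d)\n",
              x$alpha_b, x$beta_b, x$alpha_b * x$beta_b, x$n_samples_b))
  cat(sprintf("  fit: %s\n", x$fit_method))
  invisible(x)
}

## Prior stage shared by calibration, segmentation and the harness:
## warp -> NCC atlas selection -> vote. Returns the selected atlases, the
## probability map and the uncertain-band voxel list.
prior_stage <- function(target, cohort, cfg) {
  warper <- make_warper(cfg$prior$warp)
  warped <- lapply(cohort, warper, target = target)
  n_sel <- min(cfg$prior$n_select, length(warped))
  half <- (cfg$prior$patch - 1L) %/% 2L
  sel <- select_atlases_ncc(target, warped, n_sel, half)
  pm <- vote(lapply(sel, function(a) a$mask))
  band <- which(pm$p_fg > 0 & pm$p_fg < 1, arr.ind = TRUE)
  colnames(band) <- NULL
  list(warped = warped, selected = sel, pm = pm, band = band)
}

#' Calibrate the Bayesian segmentation model on an atlas cohort
#'
#' The central fitting function. Each cohort member in turn is treated as a
#' target and its reconstruction-error-ratio field is computed from the
#' remaining members (leave-one-out, so a target never reconstructs itself);
#' the ratios are pooled by the member's true label over the uncertain band
#' of its voting prior, and a gamma distribution is fit to each pooled set
#' by maximum likelihood.
#'
#' @param cohort a `cc_cohort` or list of `cc_atlas` (>= 2 members).
#' @param config a [bibs_config()].
#' @param verbose print per-member progress?
#' @return an object of class `c("bibs_model", "cc_gamma_model")` carrying
#'   the fitted parameters, the pooled calibration ratios, the resolved
#'   configuration and its hash, and the cohort (used as the default atlas
#'   set by [predict.bibs_model()]).
#' @seealso [segment_bibs()], [decide()], [predict.bibs_model()]
#' @export
bibs_fit <- function(cohort, config = bibs_config(), verbose = FALSE) {
  atlases <- if (inherits(cohort, "cc_cohort")) cohort$atlases else cohort
  if (length(atlases) < 2L)
    stop_calibration("calibration needs a cohort of at least 2 atlases")
  ratios_f <- list(); ratios_b <- list()
  for (i in seq_along(atlases)) {
    tgt <- atlases[[i]]
    others <- atlases[-i]
    st <- prior_stage(tgt$image, others, config)
    k <- min(config$lesre$n_select, length(others))
    ssd <- select_atlases_ssd(tgt$image, st$warped, k)
    ef <- error_field(tgt$image, ssd, config, voxels = st$band)
    truth <- lb(tgt$mask)
    comp <- ef$computed
    ratios_f[[i]] <- ef$ratio[comp & truth == 1L]
    ratios_b[[i]] <- ef$ratio[comp & truth == 0L]
    if (verbose)
      message(sprintf("calibrated member %d/%d ('%s'): %d fg / %d bg ratios",
                      i, length(atlases), tgt$id,
                      length(ratios_f[[i]]), length(ratios_b[[i]])))
  }
  new_bibs_model(unlist(ratios_f), unlist(ratios_b), config, atlases)
}

new_bibs_model <- function(rf, rb, config, atlases) {
  min_n <- config$bayes$min_calib_samples
  if (length(rf) < min_n || length(rb) < min_n)
    stop_calibration("too few calibration ratios (fg %d, bg %d; need %d per class)",
                     length(rf), length(rb), min_n)
  ff <- fit_gamma(rf, min_n)
  fb <- fit_gamma(rb, min_n)
  gm <- gamma_model(ff$alpha, ff$beta, fb$alpha, fb$beta,
                    length(rf), length(rb), fit_method = "mle_newton")
  gm$ratios_f <- rf
  gm$ratios_b <- rb
  gm$config <- config
  gm$config_hash <- config_hash(config)
  gm$cohort <- atlases
  class(gm) <- c("bibs_model", class(gm))
  gm
}

#' Bayesian per-voxel decision
#'
#' Combines the error-ratio likelihood with the voting prior. On voxels with
#' `0 < p_fg < 1` and a computed ratio, the label is foreground iff
#' `p(eps | f) p_fg >= p(eps | b) p_bg`, evaluated in log space (the tie goes
#' to foreground). Voxels with `p_fg` 0 or 1 follow the prior outright;
#' uncertain voxels without a computed ratio fall back to the prior
#' threshold rule.
#'
#' @param ef a `cc_error_field` for the target.
#' @param pm the target's `cc_probmap` prior.
#' @param gm a `cc_gamma_model` (or fitted `bibs_model`).
#' @return list of class `cc_decision`: `mask` (`cc_mask`), `log_odds`
#'   (matrix, `NA` off the full-Bayes set) and `decided_by` (character
#'   matrix, `"prior_only"` or `"full_bayes"`).
#' @export
decide <- function(ef, pm, gm) {
  p <- pm$p_fg
  if (!identical(dim(p), dim(ef$ratio)))
    stop_input("prior and error field shapes differ")
  lab <- matrix(0L, nrow(p), ncol(p))
  decided_by <- matrix("prior_only", nrow(p), ncol(p))
  log_odds <- matrix(NA_real_, nrow(p), ncol(p))

  certain <- p == 0 | p == 1
  lab[certain] <- as.integer(p[certain] == 1)

  band <- !certain
  full <- band & ef$computed
  if (any(full)) {
    x <- ef$ratio[full]
    ## grouped as (log likelihood ratio) + (log prior odds) so that equal
    ## class likelihoods cancel exactly and the rule reduces to the vote
    lo <- (gamma_logpdf(x, gm$alpha_f, gm$beta_f) -
             gamma_logpdf(x, gm$alpha_b, gm$beta_b)) +
      (log(p[full]) - log(1 - p[full]))
    bad <- is.nan(lo)
    lab[full] <- as.integer(lo >= 0)
    if (any(bad)) {  # both densities zero: likelihood uninformative
      idx <- which(full)[bad]
      lab[idx] <- as.integer(p[idx] >= 0.5)
    }
    log_odds[full] <- lo
    decided_by[full] <- "full_bayes"
  }
  fallback <- band & !ef$computed
  lab[fallback] <- as.integer(p[fallback] >= 0.5)

  structure(list(mask = mask(lab), log_odds = log_odds,
                 decided_by = decided_by),
            class = "cc_decision")
}

#' @export
print.cc_decision <- function(x, ...) {
  cat(sprintf("<cc_decision %d x %d: %d foreground, %d full-Bayes voxels>\n",
              nrow(x$log_odds), ncol(x$log_odds), sum(x$mask$labels),
              sum(x$decided_by == "full_bayes")))
  invisible(x)
}

#' Segment a target slice with the full Bayesian pipeline
#'
#' Orchestrates warp, NCC atlas selection, label voting, SSD atlas
#' selection, error-field computation over the uncertain band, and the
#' Bayesian decision. Deterministic given inputs and configuration.
#'
#' @param target the target `cc_slice` or matrix.
#' @param cohort list of `cc_atlas` (must not contain the target).
#' @param gm a calibrated `cc_gamma_model` / `bibs_model`; `NULL` calibrates
#'   one from `cohort` first.
#' @param config a [bibs_config()] (defaults to `gm$config` when available).
#' @return list of class `cc_segmentation`: the `cc_decision` fields plus
#'   `prob_map`, `error_field` and `config_hash`.
#' @export
segment_bibs <- function(target, cohort, gm = NULL, config = NULL) {
  if (inherits(cohort, "cc_cohort")) cohort <- cohort$atlases
  if (is.null(config))
    config <- if (!is.null(gm$config)) gm$config else bibs_config()
  if (is.null(gm)) gm <- bibs_fit(cohort, config)
  st <- prior_stage(target, cohort, config)
  k <- min(config$lesre$n_select, length(cohort))
  ssd <- select_atlases_ssd(target, st$warped, k)
  ef <- error_field(target, ssd, config, voxels = st$band)
  dec <- decide(ef, st$pm, gm)
  structure(c(dec, list(prob_map = st$pm, error_field = ef,
                        config_hash = config_hash(config))),
            class = c("cc_segmentation", "cc_decision"))
}

## ---- bibs_model methods --------------------------------------------------

#' @export
print.bibs_model <- function(x, ...) {
  cat(sprintf("Bayesian corpus-callosum segmentation model (%d atlases)\n",
              length(x$cohort)))
  print.cc_gamma_model(x)
  cat(sprintf("  config hash: %s\n", x$config_hash))
  invisible(x)
}

#' @export
summary.bibs_model <- function(object, ...) {
  out <- list(
    coefficients = coef(object),
    mean_ratio_f = mean(object$ratios_f),
    mean_ratio_b = mean(object$ratios_b),
    n_samples = c(f = object$n_samples_f, b = object$n_samples_b),
    n_atlases = length(object$cohort),
    config_hash = object$config_hash)
  class(out) <- "summary.bibs_model"
  out
}

#' @export
print.summary.bibs_model <- function(x, ...) {
  cat("Bayesian corpus-callosum segmentation model\n\n")
  cat(sprintf("Atlases: %d   calibration ratios: %d foreground, %d background\n",
              x$n_atlases, x$n_samples["f"], x$n_samples["b"]))
  cat("\nGamma likelihood (shape alpha, scale beta):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nObserved mean error ratio: foreground %.4f, background %.4f\n",
              x$mean_ratio_f, x$mean_ratio_b))
  cat(sprintf("Config hash: %s\n", x$config_hash))
  invisible(x)
}

#' @export
coef.bibs_model <- function(object, ...) {
  c(alpha_f = object$alpha_f, beta_f = object$beta_f,
    alpha_b = object$alpha_b, beta_b = object$beta_b)
}

#' Segment a target with a fitted model
#'
#' @param object a fitted `bibs_model`.
#' @param target the target `cc_slice` or matrix.
#' @param cohort atlas set to use; defaults to the model's calibration
#'   cohort minus any atlas whose image is pixel-identical to the target.
#' @param method `"bibs"` (full Bayesian), `"piemv"` (prior-only) or
#'   `"lesre"` (likelihood-only).
#' @param ... unused.
#' @return a `cc_segmentation` for `"bibs"`, else a `cc_mask`.
#' @export
predict.bibs_model <- function(object, target, cohort = NULL,
                               method = c("bibs", "piemv", "lesre"), ...) {
  method <- match.arg(method)
  t <- px(target)
  if (is.null(cohort)) {
    cohort <- Filter(function(a) !identical(px(a$image), t), object$cohort)
  } else if (inherits(cohort, "cc_cohort")) cohort <- cohort$atlases
  cfg <- object$config
  if (method == "bibs") return(segment_bibs(target, cohort, object, cfg))
  st <- prior_stage(target, cohort, cfg)
  if (method == "piemv") return(piemv_segment(st$pm))
  k <- min(cfg$lesre$n_select, length(cohort))
  ssd <- select_atlases_ssd(target, st$warped, k)
  cfg$lesre$eval <- "fg_window"
  lesre_label(error_field(target, ssd, cfg))
}

#' Plot the calibrated likelihood
#'
#' Histograms of the pooled calibration error ratios per class with the
#' fitted gamma densities overlaid (log10 ratio axis).
#'
#' @param x a fitted `bibs_model`.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.bibs_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  panel <- function(r, a, b, main) {
    graphics::hist(r, breaks = 40, freq = FALSE, main = main,
                   xlab = "error ratio eps_f / eps_b", ...)
    xs <- seq(max(min(r), 1e-6), max(r), length.out = 400)
    graphics::lines(xs, gamma_pdf(xs, a, b), lwd = 2)
  }
  panel(x$ratios_f, x$alpha_f, x$beta_f, "foreground voxels")
  panel(x$ratios_b, x$alpha_b, x$beta_b, "background voxels")
  invisible(x)
}

#' Simulate error ratios from the fitted likelihood
#'
#' @param object a fitted `bibs_model`.
#' @param nsim draws per class.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with columns `class` (`"f"`/`"b"`) and `ratio`.
#' @export
simulate.bibs_model <- function(object, nsim = 1000L, seed = NULL, ...) {
  draw <- function() data.frame(
    class = rep(c("f", "b"), each = nsim),
    ratio = c(stats::rgamma(nsim, shape = object$alpha_f, scale = object$beta_f),
              stats::rgamma(nsim, shape = object$alpha_b, scale = object$beta_b)))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

## ---- model serialization -------------------------------------------------

#' Write / read a gamma model as JSON
#' @param gm a `cc_gamma_model` (or `bibs_model`; only the gamma parameters,
#'   sample counts, fit method and config hash are serialized).
#' @param path JSON file path.
#' @return `path` (write) or a `cc_gamma_model` (read).
#' @export
write_gamma_model <- function(gm, path) {
  obj <- list(alpha_f = gm$alpha_f, beta_f = gm$beta_f,
              alpha_b = gm$alpha_b, beta_b = gm$beta_b,
              n_samples_f = gm$n_samples_f, n_samples_b = gm$n_samples_b,
              fit_method = gm$fit_method,
              config_hash = if (!is.null(gm$config_hash)) gm$config_hash else NA)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gamma_model
#' @export
read_gamma_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  gm <- gamma_model(o$alpha_f, o$beta_f, o$alpha_b, o$beta_b,
                    o$n_samples_f, o$n_samples_b, o$fit_method)
  gm$config_hash <- o$config_hash
  gm
}
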