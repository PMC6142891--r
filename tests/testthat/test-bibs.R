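make_pm <- function(p) structure(list(p_fg = p, n_voters = 10L),
                                 class = "cc_probmap")
make_ef <- function(ratio, computed = !is.na(ratio)) {
  structure(list(eps_f = ratio, eps_b = ratio * 0 + 1, ratio = ratio,
                 computed = computed), class = "cc_error_field")
}

test_that("with identical class likelihoods the decision reduces to majority vote", {
  gm <- gamma_model(2, 1, 2, 1)
  p <- matrix(c(0.6, 0.4, 0.5, 0.9), 2, 2)
  ef <- make_ef(matrix(0.7, 2, 2))
  out <- decide(ef, make_pm(p), gm)
  expect_identical(out$mask$labels, matrix(as.integer(p >= 0.5), 2, 2))
  expect_true(all(out$decided_by == "full_bayes"))
})

test_that("a degenerate prior forces the label regardless of the ratio", {
  gm <- gamma_model(2, 0.2, 2, 2)
  p <- matrix(c(1, 0, 1, 0), 2, 2)
  ef <- make_ef(matrix(c(1000, 0.001, 0.001, 1000), 2, 2))
  out <- decide(ef, make_pm(p), gm)
  expect_identical(out$mask$labels, matrix(as.integer(p == 1), 2, 2))
  expect_true(all(out$decided_by == "prior_only"))
  expect_true(all(is.na(out$log_odds)))
})

test_that("the decision matches hand-evaluated gamma densities", {
  # fg: alpha 2, scale 0.2; bg: alpha 2, scale 2; ratio 0.1, p_fg 0.5
  gm <- gamma_model(2, 0.2, 2, 2)
  ef <- make_ef(matrix(0.1, 1, 1))
  out <- decide(ef, make_pm(matrix(0.5, 1, 1)), gm)
  expect_identical(out$mask$labels[1, 1], 1L)
  dens_f <- 0.1 * exp(-0.5) / 0.2^2     # x e^{-x/b} / (Gamma(2) b^2)
  dens_b <- 0.1 * exp(-0.05) / 2^2
  expect_equal(out$log_odds[1, 1], log(dens_f) - log(dens_b), tolerance = 1e-12)
  expect_gt(dens_f, dens_b)

  # large ratio flips to background at even prior
  ef2 <- make_ef(matrix(3, 1, 1))
  expect_identical(decide(ef2, make_pm(matrix(0.5, 1, 1)), gm)$mask$labels[1, 1], 0L)
})

test_that("uncomputed uncertain voxels fall back to the prior threshold", {
  gm <- gamma_model(2, 0.2, 2, 2)
  ef <- make_ef(matrix(NA_real_, 2, 1), computed = matrix(FALSE, 2, 1))
  out <- decide(ef, make_pm(matrix(c(0.7, 0.3), 2, 1)), gm)
  expect_identical(as.vector(out$mask$labels), c(1L, 0L))
  expect_true(all(out$decided_by == "prior_only"))
})

test_that("the decision is monotone in the prior and in the ratio", {
  gm <- gamma_model(1.8, 0.3, 2.5, 1.5)  # fg mean < bg mean
  ratios <- c(0.01, 0.1, 0.5, 1, 2, 10, 100)
  priors <- seq(0.05, 0.95, by = 0.1)
  for (r in ratios) {
    labs <- vapply(priors, function(p)
      decide(make_ef(matrix(r, 1, 1)), make_pm(matrix(p, 1, 1)), gm)$mask$labels[1, 1],
      integer(1))
    expect_true(all(diff(labs) >= 0))  # raising p_fg never flips 1 -> 0
  }
  # density ratio f/b monotone decreasing here: smaller ratio never flips 1 -> 0
  for (p in priors) {
    labs <- vapply(ratios, function(r)
      decide(make_ef(matrix(r, 1, 1)), make_pm(matrix(p, 1, 1)), gm)$mask$labels[1, 1],
      integer(1))
    expect_true(all(diff(labs) <= 0))
  }
})

test_that("calibration pools ratios by true label and recovers planted parameters", {
  co <- small_cohort(8)
  cfg <- small_config()
  gm <- bibs_fit(co, cfg)
  expect_s3_class(gm, "bibs_model")
  expect_gt(gm$n_samples_f, cfg$bayes$min_calib_samples)
  expect_gt(gm$n_samples_b, cfg$bayes$min_calib_samples)
  # foreground ratios are systematically smaller: fitted means ordered
  expect_lt(gm$alpha_f * gm$beta_f, gm$alpha_b * gm$beta_b)
  # order invariance of the cohort
  gm2 <- bibs_fit(rev(co$atlases), cfg)
  expect_equal(coef(gm), coef(gm2), tolerance = 1e-12)

  # parameter recovery from synthetic gamma draws through the same fitter
  set.seed(123)
  planted <- fit_gamma(rgamma(1e4, shape = 2, scale = 0.5))
  expect_lt(abs(planted$alpha - 2) / 2, 0.1)
  expect_lt(abs(planted$beta - 0.5) / 0.5, 0.1)

  expect_error(bibs_fit(co$atlases[1], cfg), class = "cc_calibration_error")
})

test_that("model methods print, summarize, serialize and simulate coherently", {
  co <- small_cohort(8)
  gm <- bibs_fit(co, small_config())
  expect_output(print(gm), "Gamma likelihood")
  sm <- summary(gm)
  expect_lt(sm$mean_ratio_f, sm$mean_ratio_b)
  expect_named(coef(gm), c("alpha_f", "beta_f", "alpha_b", "beta_b"))

  tmp <- withr::local_tempfile(fileext = ".json")
  write_gamma_model(gm, tmp)
  back <- read_gamma_model(tmp)
  expect_equal(back$alpha_f, gm$alpha_f, tolerance = 1e-12)
  expect_identical(back$config_hash, gm$config_hash)

  sims <- simulate(gm, nsim = 500, seed = 1)
  expect_identical(nrow(sims), 1000L)
  expect_lt(mean(sims$ratio[sims$class == "f"]),
            mean(sims$ratio[sims$class == "b"]))

  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(gm))
})

test_that("a cohort of exact target copies yields Dice 100 for every method", {
  copies <- copies_cohort(5)
  truth <- copies[[1]]$mask
  target <- copies[[1]]$image
  cfg <- small_config()
  gm <- gamma_model(2, 0.3, 2, 1.5)  # any valid likelihood: prior is degenerate

  seg <- segment_bibs(target, copies, gm, cfg)
  expect_equal(dice(seg$mask, truth), 100)

  st <- bibseg:::prior_stage(target, copies, cfg)
  expect_equal(dice(piemv_segment(st$pm), truth), 100)

  ssd <- select_atlases_ssd(target, st$warped, length(copies))
  cfg2 <- cfg; cfg2$lesre$eval <- "fg_window"
  expect_equal(dice(lesre_label(error_field(target, ssd, cfg2)), truth), 100)
})

test_that("segmentation is bit-identical across reruns with equal config hashes", {
  co <- small_cohort(6)
  cfg <- small_config()
  gm <- gamma_model(2, 0.3, 2, 1.5)
  s1 <- segment_bibs(co$atlases[[1]]$image, co$atlases[-1], gm, cfg)
  s2 <- segment_bibs(co$atlases[[1]]$image, co$atlases[-1], gm, cfg)
  expect_identical(s1$config_hash, s2$config_hash)
  expect_identical(s1$mask$labels, s2$mask$labels)
  expect_identical(s1$log_odds, s2$log_odds)
})

test_that("predict dispatches the three methods from a fitted model", {
  co <- small_cohort(8)
  gm <- bibs_fit(co, small_config())
  tgt <- co$atlases[[1]]
  segb <- predict(gm, tgt$image)  # excludes the identical cohort member
  expect_s3_class(segb, "cc_segmentation")
  segp <- predict(gm, tgt$image, method = "piemv")
  segl <- predict(gm, tgt$image, method = "lesre")
  expect_s3_class(segp, "cc_mask")
  expect_gt(dice(segb$mask, tgt$mask), 70)
  expect_gt(dice(segl, tgt$mask), 70)
})
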