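test_that("SSD atlas selection matches brute-force scores", {
  co <- small_cohort(10)
  target <- co$atlases[[1]]$image
  # self-copy scores zero and ranks first
  pool <- c(list(atlas("aaa_self", target, co$atlases[[1]]$mask)),
            co$atlases[-1])
  sel <- select_atlases_ssd(target, pool, 3)
  expect_identical(sel[[1]]$id, "aaa_self")
  expect_equal(attr(sel, "scores")[1], 0)

  # constant images differing by 1 over M voxels score M
  c1 <- atlas("c1", matrix(5, 8, 8) + diag(8), mask(matrix(0L, 8, 8)))
  expect_equal(sum((matrix(5, 8, 8) - c1$image$pixels)^2), 8)

  # selection equals the k smallest hand-computed scores
  scores <- vapply(pool, function(a) sum((target$pixels - a$image$pixels)^2),
                   numeric(1))
  ids <- vapply(pool, function(a) a$id, character(1))
  sel3 <- vapply(select_atlases_ssd(target, pool, 3), function(a) a$id,
                 character(1))
  expect_identical(sel3, ids[order(scores, ids)][1:3])
  expect_error(select_atlases_ssd(target, list(), 1), class = "cc_input_error")
})

test_that("gradients use central differences with the stated conventions", {
  const <- compute_gradients(matrix(7, 5, 5))
  expect_true(all(const$magnitude == 0))
  expect_true(all(const$direction == 0))  # zero-gradient convention

  colramp <- compute_gradients(matrix(rep(1:6, each = 5), 5, 6))
  expect_true(all(abs(colramp$magnitude[2:4, 2:5] - 1) < 1e-12))
  expect_true(all(abs(colramp$direction[2:4, 2:5]) < 1e-12))

  rowramp <- compute_gradients(matrix(rep(1:6, times = 5), 6, 5))
  expect_true(all(abs(rowramp$direction[2:5, 2:4] - pi / 2) < 1e-12))
  expect_true(all(rowramp$direction >= 0 & rowramp$direction < 2 * pi))
})

test_that("feature patches have the stated length, unit norm, and raster layout", {
  set.seed(5)
  img <- matrix(runif(400, 0, 255), 20, 20)
  fp <- extract_feature_patch(img, NULL, c(10, 10), 3L)
  expect_s3_class(fp, "cc_feature_patch")
  expect_length(fp$values, 27)  # 3 channels x 3^2
  expect_equal(sqrt(sum(fp$values^2)), 1, tolerance = 1e-9)

  # intensity-only mode
  fpi <- extract_feature_patch(img, NULL, c(10, 10), 5L, channels = "intensity")
  expect_length(fpi$values, 25)

  # translation invariance on constant regions (zero gradients)
  flat <- matrix(3, 20, 20); flat[1, 1] <- 9  # keep channel ranges nonzero
  f1 <- extract_feature_patch(flat, NULL, c(10, 10), 3L)
  f2 <- extract_feature_patch(flat, NULL, c(12, 14), 3L)
  expect_equal(f1$values, f2$values)
})

test_that("dictionaries split search-window patches by atlas label with exact counts", {
  co <- small_cohort(5)
  sel <- co$atlases[1:3]
  # 3 atlases, 7x7 window: |D_f| + |D_b| = 49 * 3 at an interior voxel
  d <- build_dictionaries(sel, c(24, 32), 3L, 5L)
  expect_identical(ncol(d$D_f$columns) + ncol(d$D_b$columns), 49L * 3L)
  # counts equal the mask labels inside the windows
  n_fg <- sum(vapply(sel, function(a)
    sum(a$mask$labels[21:27, 29:35]), integer(1)))
  expect_identical(ncol(d$D_f$columns), n_fg)

  # all-background window yields an empty foreground dictionary
  d0 <- build_dictionaries(sel, c(3, 3), 1L, 5L)
  expect_identical(ncol(d0$D_f$columns), 0L)
  expect_identical(ncol(d0$D_b$columns), 9L * 3L)

  # deep-foreground centre has foreground atoms
  inner <- which(!bibseg:::dilate_square(co$atlases[[1]]$mask$labels == 0L, 1L),
                 arr.ind = TRUE)
  dfg <- build_dictionaries(sel, c(inner[1, 1], inner[1, 2]), 3L, 5L)
  expect_gt(ncol(dfg$D_f$columns), 0L)

  # columns are unit norm and sources are tracked
  nrm <- sqrt(colSums(d$D_b$columns^2))
  expect_true(all(abs(nrm - 1) < 1e-9))
  expect_identical(nrow(d$D_b$source), ncol(d$D_b$columns))
})

test_that("OMP recovers exact atoms and respects the orthogonality limit", {
  D <- random_dictionary(27, 10, seed = 1)
  fit <- omp(D[, 4], D, sparsity = 1L)
  expect_identical(fit$support, 4L)
  expect_equal(fit$coefficients, 1, tolerance = 1e-10)
  expect_lt(fit$residual_norm, 1e-10)

  # y orthogonal to every column: residual stays at ||y|| = 1
  Q <- qr.Q(qr(cbind(D[, 1:3], rnorm(27))))
  y_orth <- Q[, 4]
  fit2 <- omp(y_orth, Q[, 1:3], sparsity = 3L)
  expect_equal(fit2$residual_norm, 1, tolerance = 1e-9)

  # empty dictionary: defined limit
  fit3 <- omp(D[, 1], matrix(0, 27, 0), sparsity = 2L)
  expect_identical(fit3$support, integer(0))
  expect_equal(fit3$residual_norm, 1)
})

test_that("OMP never beats the exhaustive-subset oracle and matches it on orthogonal dictionaries", {
  set.seed(42)
  for (rep in 1:25) {
    D <- random_dictionary(27, sample(4:12, 1), seed = 1000 + rep)
    y <- rnorm(27); y <- y / sqrt(sum(y^2))
    s <- sample(1:3, 1)
    fit <- omp(y, D, sparsity = s, tol = 0)
    best <- exhaustive_ls_residual(y, D, s)
    expect_gte(fit$residual_norm, best - 1e-9)
    # residual path is monotone non-increasing
    expect_true(all(diff(fit$residual_path) <= 1e-12))

    Q <- qr.Q(qr(D))  # orthonormal columns: greedy is optimal
    fitq <- omp(y, Q, sparsity = s, tol = 0)
    expect_equal(fitq$residual_norm, exhaustive_ls_residual(y, Q, s),
                 tolerance = 1e-9)
  }
})

test_that("error fields separate true foreground from background and are deterministic", {
  co <- small_cohort(8)
  cfg <- small_config()
  target <- co$atlases[[1]]
  sel <- select_atlases_ssd(target$image, co$atlases[-1], 5)
  vox <- which(bibseg:::dilate_square(target$mask$labels == 1L, 2L),
               arr.ind = TRUE)
  ef <- error_field(target$image, sel, cfg, voxels = vox)
  expect_true(all(ef$computed[vox]))
  expect_true(all(ef$eps_f[ef$computed] >= 0))
  expect_true(all(ef$ratio[ef$computed] >= cfg$bayes$ratio_min &
                    ef$ratio[ef$computed] <= cfg$bayes$ratio_max))
  truth <- target$mask$labels
  mf <- mean(ef$ratio[ef$computed & truth == 1L])
  mb <- mean(ef$ratio[ef$computed & truth == 0L])
  expect_lt(mf, mb)  # foreground reconstructs better from D_f

  ef2 <- error_field(target$image, sel, cfg, voxels = vox)
  expect_identical(ef$ratio, ef2$ratio)  # bit-identical rerun

  # permuting atlas order changes nothing (canonical column order)
  ef3 <- error_field(target$image, sel[c(3, 1, 5, 2, 4)], cfg, voxels = vox)
  expect_identical(ef$ratio, ef3$ratio)
})

test_that("a self-atlas gives zero foreground error at interior foreground voxels", {
  co <- small_cohort(6)
  target <- co$atlases[[1]]
  sel <- c(list(atlas("aaa_self", target$image, target$mask)), co$atlases[2:4])
  inner <- which(bibseg:::dilate_square(target$mask$labels == 0L, 1L) == FALSE,
                 arr.ind = TRUE)  # strictly interior foreground
  vox <- inner[1:min(4, nrow(inner)), , drop = FALSE]
  cfg <- small_config()
  ef <- error_field(target$image, sel, cfg, voxels = vox)
  expect_true(all(ef$eps_f[vox] < 1e-6))
  expect_true(all(ef$ratio[vox] == cfg$bayes$ratio_min))
})

test_that("likelihood-only labelling applies the argmin rule with background ties", {
  ef <- structure(list(
    eps_f = matrix(c(0.2, 0.5, 0.3, NA), 2, 2),
    eps_b = matrix(c(0.5, 0.2, 0.3, NA), 2, 2),
    ratio = matrix(1, 2, 2),
    computed = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)),
    class = "cc_error_field")
  out <- lesre_label(ef)
  expect_identical(as.vector(out$labels), c(1L, 0L, 0L, 0L))
  # all voxels uncomputed -> all background
  ef$computed[] <- FALSE
  expect_true(all(lesre_label(ef)$labels == 0L))
})
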