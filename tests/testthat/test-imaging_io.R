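test_that("volumes round-trip through NIfTI and reject non-3D data", {
  tmp <- withr::local_tempdir()
  arr <- array(seq_len(5 * 4 * 4), dim = c(5, 4, 4))
  f <- file.path(tmp, "vol.nii.gz")
  save_volume(structure(list(voxels = arr, spacing = c(1, 1, 1),
                             shape = dim(arr)), class = "cc_volume"), f)
  v <- load_volume(f)
  expect_equal(v$voxels, arr, ignore_attr = TRUE)
  expect_identical(v$shape, c(5L, 4L, 4L))

  f4 <- file.path(tmp, "vol4d.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(3, 3, 3, 2))), f4)
  expect_error(load_volume(f4), class = "cc_format_error")
  expect_error(load_volume(file.path(tmp, "absent.nii")),
               class = "cc_input_error")
})

test_that("midsagittal extraction takes the lower-median x slice", {
  arr <- array(0, dim = c(5, 4, 4)); arr[3, , ] <- 7
  v <- structure(list(voxels = arr), class = "cc_volume")
  expect_true(all(extract_msp(v)$pixels == 7))

  arr6 <- array(rnorm(6 * 4 * 4), dim = c(6, 4, 4))
  v6 <- structure(list(voxels = arr6), class = "cc_volume")
  expect_equal(extract_msp(v6)$pixels, arr6[4, , ])  # floor(6/2) 0-based -> 4th

  vc <- structure(list(voxels = array(3, dim = c(5, 4, 4))), class = "cc_volume")
  expect_true(all(extract_msp(vc)$pixels == 3))
})

test_that("percentile normalization maps the 2nd/98th percentiles to 0/255", {
  s <- slice(matrix(0:100, 101, 3))  # percentiles of 0..100 are exact
  out <- normalize_intensity(s)
  expect_equal(out$pixels[s$pixels == 2][1], 0)
  expect_equal(out$pixels[s$pixels == 98][1], 255)
  expect_equal(out$pixels[s$pixels == 50][1], 127.5)
  expect_true(min(out$pixels) >= 0 && max(out$pixels) <= 255)

  # endpoints spanning exactly [p2, p98] map to the full range
  v <- seq(2, 98, length.out = 49)
  out2 <- normalize_intensity(slice(matrix(v, 7, 7)), 0, 100)
  expect_equal(min(out2$pixels), 0)
  expect_equal(max(out2$pixels), 255)

  expect_error(normalize_intensity(slice(matrix(5, 4, 4))),
               class = "cc_degenerate_error")
})

test_that("normalization is idempotent away from the clipped tails", {
  set.seed(3)
  s <- slice(matrix(rnorm(400, 100, 30), 20, 20))
  once <- normalize_intensity(s)
  twice <- normalize_intensity(once)
  # the second pass can only re-stretch by the mass clipped into the tails:
  # its percentile window [q2', q98'] is within the clip effect of [0, 255]
  q <- quantile(once$pixels, c(0.02, 0.98), names = FALSE)
  clip_effect <- max(q[1] - 0, 255 - q[2])
  expect_lte(max(abs(once$pixels - twice$pixels)), 2 * clip_effect + 1e-9)
  expect_gt(cor(as.vector(once$pixels), as.vector(twice$pixels)), 0.999)
  # exact idempotence when re-normalizing with the full range
  expect_equal(normalize_intensity(once, 0, 100)$pixels, once$pixels)
})

test_that("crop keeps exact origin bookkeeping and rejects bad boxes", {
  ramp <- matrix(1:16, 4, 4)
  s <- slice(ramp)
  full <- crop(s, c(1, 1, 4, 4))
  expect_equal(full$pixels, ramp)
  expect_identical(full$origin, c(1L, 1L))

  sub <- crop(s, c(2, 2, 2, 2))
  expect_equal(sub$pixels, ramp[2:3, 2:3])
  expect_identical(sub$origin, c(2L, 2L))
  # parent coordinates recoverable exactly for every cropped pixel
  for (r in 1:2) for (c in 1:2)
    expect_equal(sub$pixels[r, c], ramp[sub$origin[1] + r - 1,
                                        sub$origin[2] + c - 1])
  # nested crops compose origins
  sub2 <- crop(sub, c(2, 1, 1, 2))
  expect_identical(sub2$origin, c(3L, 2L))

  expect_error(crop(s, c(3, 3, 3, 1)), class = "cc_input_error")
  expect_error(crop(s, c(0, 1, 2, 2)), class = "cc_input_error")
})

test_that("2D slices and masks round-trip through PNG and NIfTI", {
  tmp <- withr::local_tempdir()
  img <- matrix(as.double(0:255), 16, 16)
  m <- matrix(0L, 16, 16); m[4:9, 6:12] <- 1L

  fp <- file.path(tmp, "s.png")
  write_slice(slice(img), fp)
  expect_equal(read_slice(fp)$pixels, img, tolerance = 0.5)  # 8-bit quantization
  fm <- file.path(tmp, "m.png")
  write_mask(mask(m), fm)
  expect_identical(read_mask(fm)$labels, m)

  fn <- file.path(tmp, "s.nii.gz")
  write_slice(slice(img), fn)
  expect_equal(read_slice(fn)$pixels, img, ignore_attr = TRUE)
})

test_that("atlas directories read back as sorted image/mask pairs", {
  tmp <- withr::local_tempdir()
  co <- small_cohort(4)
  for (a in co$atlases) {
    write_slice(a$image, file.path(tmp, paste0(a$id, "_image.png")))
    write_mask(a$mask, file.path(tmp, paste0(a$id, "_mask.png")))
  }
  back <- read_atlas_dir(tmp)
  expect_length(back, 4)
  expect_identical(vapply(back, function(a) a$id, character(1)),
                   sprintf("phantom_%03d", 0:3))
  expect_identical(back[[2]]$mask$labels, co$atlases[[2]]$mask$labels)
})
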