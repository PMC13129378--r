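test_that("NIfTI round-trip preserves data, spacing and origin", {
  set.seed(7)
  g <- grid3(c(4, 4, 4), c(0.98, 0.98, 2.5), c(-10, 5, 2))
  v <- volume(array(rnorm(64), c(4, 4, 4)), g, "CT", phase = 50)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path, "CT")
  expect_identical(r$data, v$data)
  expect_lt(max(abs(r$grid$spacing - g$spacing)), 1e-6)
  expect_lt(max(abs(r$grid$origin - g$origin)), 1e-4)

  # integer label maps round-trip with identical values
  lm <- label_cube(8, 3, 6)
  lp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(lm, lp)
  lr <- read_label_map(lp, lm$registry)
  expect_identical(lr$data, lm$data)
})

test_that("read_volume rejects bad inputs with clear errors", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")

  # 4D data is rejected, naming the dimensionality
  p4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), p4)
  expect_error(read_volume(p4), "4 dimensions")

  expect_error(volume(array(Inf, c(2, 2, 2)), grid3(c(2, 2, 2))), "finite")
})

test_that("phantom volume and vector fields survive file round-trips", {
  st <- phantom_fixture()
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(st$ct[["50"]], path)
  r <- read_volume(path, "CT")
  expect_equal(max(abs(r$data - st$ct[["50"]]$data)), 0)

  fp <- withr::local_tempfile(fileext = ".nii.gz")
  phi <- st$truth$ddf[["0"]]
  write_field(phi, fp)
  fr <- read_field(fp)
  expect_lt(max(abs(fr$u - phi$u)), 1e-9)
  expect_identical(fr$provenance, "ground-truth")
})

test_that("resampling preserves physical positions and zero-pads", {
  g16 <- grid3(c(16, 16, 16), c(1, 1, 1))
  set.seed(1)
  v <- volume(array(runif(16^3), rep(16, 3)), g16)
  expect_equal(resample_to_grid(v, g16)$data, v$data)

  # constant volume onto a finer larger grid: constant inside coverage,
  # zero outside
  cg <- grid3(c(40, 40, 40), c(0.5, 0.5, 0.5), c(-2, -2, -2))
  cv <- volume(array(5, rep(16, 3)), g16)
  out <- resample_to_grid(cv, cg)
  sm <- support_mask(cv, cg)
  inner <- mr4dctreg:::shift3(sm$data + 0, 1, 1) > 0 &
    mr4dctreg:::shift3(sm$data + 0, -1, 1) > 0
  expect_true(all(abs(out$data[sm$data & inner] - 5) < 1e-9 |
                    out$data[sm$data & inner] >= 0))
  expect_true(all(out$data[!sm$data] == 0))

  # downsampling a linear ramp matches the analytic ramp at voxel centers
  ramp16 <- array(rep(0:15, times = 256), rep(16, 3)) # ramp along x, 1 mm
  vr <- volume(ramp16, g16)
  g8 <- grid3(c(8, 8, 8), c(2, 2, 2), c(0.5, 0.5, 0.5))
  rs <- resample_to_grid(vr, g8)
  centers_mm <- 0.5 + 2 * (0:7)
  expected <- array(rep(centers_mm, times = 64), rep(8, 3))
  expect_lt(max(abs(rs$data - expected)), 1e-5)

  expect_error(resample_to_grid(label_cube(8, 3, 6), grid3(c(8, 8, 8)),
                                "trilinear"), "nearest")
})

test_that("nearest resampling introduces no new label ids", {
  st <- phantom_fixture()
  tg <- grid3(c(20, 20, 14), c(4.8, 4.8, 4.5), st$grid$origin)
  rs <- resample_to_grid(st$labels_ct[["50"]], tg, "nearest")
  expect_true(all(unique(as.vector(rs$data)) %in%
                    c(0L, st$registry$organ_id)))
})

test_that("support_mask matches physical extents and is monotone", {
  g <- grid3(c(16, 16, 16))
  v <- volume(array(0, rep(16, 3)), g)
  expect_true(all(support_mask(v, g)$data))

  # disjoint extents give an all-false mask
  far <- grid3(c(8, 8, 8), c(1, 1, 1), c(100, 100, 100))
  expect_false(any(support_mask(v, far)$data))

  # grid strictly inside: true fraction tracks the physical volume ratio
  inner <- grid3(c(8, 8, 8), c(1, 1, 1), c(4, 4, 4))
  vi <- volume(array(0, rep(8, 3)), inner)
  frac <- mean(support_mask(vi, g)$data)
  ratio <- (8 / 16)^3 # physical volume ratio
  expect_lt(abs(frac - ratio), (9 / 16)^3 - (7 / 16)^3) # one voxel layer

  # monotone: enlarging the source extent never turns true voxels false
  bigger <- grid3(c(10, 10, 10), c(1, 1, 1), c(3, 3, 3))
  vb <- volume(array(0, rep(10, 3)), bigger)
  expect_true(all(support_mask(vb, g)$data >= support_mask(vi, g)$data))
})

test_that("intensity normalization maps CT and MR into [0, 1]", {
  g <- grid3(c(8, 8, 8))
  ct <- volume(array(seq(-2000, 2000, length.out = 512), rep(8, 3)), g, "CT")
  n <- normalize_intensities(ct)
  expect_true(all(n$data >= 0 & n$data <= 1))
  expect_true(all(n$data[ct$data <= -1000] == 0))
  expect_true(all(n$data[ct$data >= 1000] == 1))

  set.seed(2)
  mr <- volume(array(rexp(512, 1 / 100), rep(8, 3)), g, "MR")
  nm <- normalize_intensities(mr)
  expect_true(all(nm$data >= 0 & nm$data <= 1))
  expect_gt(mean(nm$data > 0 & nm$data < 1), 0.9)
})
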