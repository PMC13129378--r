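test_that("scaling-and-squaring reproduces closed forms", {
  g <- grid3(c(24, 24, 24))
  # zero velocity integrates to the exact zero displacement
  z <- integrate_svf(velocity_field(array(0, c(24, 24, 24, 3)), g))
  expect_identical(max(abs(z$u)), 0)
  expect_identical(z$provenance, "integrated")

  # constant velocity: the flow of a constant field is a translation
  u <- array(0, c(24, 24, 24, 3))
  u[, , , 3] <- 1.5
  phi <- integrate_svf(velocity_field(u, g))
  interior <- interior_mask(c(24, 24, 24), 3)
  expect_lt(max(abs(phi$u[, , , 3][interior] - 1.5)), 1e-4)
  expect_lt(max(abs(phi$u[, , , 1][interior])), 1e-4)
})

test_that("scaling-and-squaring agrees with a 256-step Euler oracle", {
  v <- smooth_svf(24, amp = 3, sigma = 4, seed = 0)
  phi <- integrate_svf(v)
  oracle <- euler_integrate(v, 256)
  expect_lt(max(abs(phi$u - oracle$u)), 0.1)
})

test_that("integration is near-diffeomorphic and invertible for smooth SVFs", {
  interior <- interior_mask(c(24, 24, 24), 3)
  for (seed in 0:4) {
    v <- smooth_svf(24, amp = 3, sigma = 4, seed = seed)
    phi <- integrate_svf(v)
    jr <- jacobian_report(phi)
    expect_lt(jr$foldings_fraction, 0.001)
    inv <- integrate_svf(velocity_field(-v$u, v$grid))
    resid <- compose_fields(phi, inv)$u
    mag <- sqrt(rowSums(array(resid^2, c(24^3, 3))))
    expect_lt(max(mag[interior]), 0.05)
  }
})

test_that("warp matches shift and conserves label ids", {
  img <- smooth_image(16)
  g <- grid3(rep(16, 3))
  v <- volume(img, g)
  zf <- mr4dctreg:::zero_field(g)
  expect_identical(warp(v, zf)$data, img)

  # integer translation equals an array shift with zero fill, exactly
  u <- array(0, c(16, 16, 16, 3))
  u[, , , 1] <- 2
  shifted <- warp(v, displacement_field(u, g, "ground-truth"))
  expect_identical(shifted$data[1:14, , ], img[3:16, , ])
  expect_true(all(shifted$data[15:16, , ] == 0))

  lm <- label_cube(16)
  wl <- warp(lm, displacement_field(u, g, "ground-truth"), "nearest")
  expect_true(all(unique(as.vector(wl$data)) %in% c(0L, 1L)))
  expect_error(warp(lm, zf, "trilinear"), "nearest")
})

test_that("composition acts as the function-composition of warps", {
  g <- grid3(rep(16, 3))
  zf <- mr4dctreg:::zero_field(g)
  u1 <- array(0, c(16, 16, 16, 3)); u1[, , , 1] <- 2
  u2 <- array(0, c(16, 16, 16, 3)); u2[, , , 2] <- 3
  p1 <- displacement_field(u1, g, "ground-truth")
  p2 <- displacement_field(u2, g, "ground-truth")

  expect_equal(compose_fields(zf, p1)$u, p1$u)
  expect_equal(compose_fields(p1, zf)$u, p1$u)

  comp <- compose_fields(p1, p2)
  interior <- interior_mask(c(16, 16, 16), 4)
  expect_lt(max(abs(comp$u[, , , 1][interior] - 2)), 1e-9)
  expect_lt(max(abs(comp$u[, , , 2][interior] - 3)), 1e-9)

  # sequential warping vs composed warping on a smooth image
  img <- smooth_image(16, seed = 3)
  v <- volume(img, g)
  s1 <- smooth_svf(16, amp = 1.5, sigma = 3, seed = 11)
  s2 <- smooth_svf(16, amp = 1.5, sigma = 3, seed = 12)
  f1 <- integrate_svf(s1)
  f2 <- integrate_svf(s2)
  seq_warp <- warp(warp(v, f1), f2)
  once <- warp(v, compose_fields(f1, f2))
  single_err <- mean(abs(warp(v, f1)$data - v$data)) # interpolation scale
  expect_lt(mean(abs(seq_warp$data - once$data)), 2 * single_err)
})

test_that("composition is associative within interpolation tolerance", {
  fs <- lapply(21:23, function(s) integrate_svf(smooth_svf(16, 1, 3, s)))
  a <- compose_fields(compose_fields(fs[[1]], fs[[2]]), fs[[3]])
  b <- compose_fields(fs[[1]], compose_fields(fs[[2]], fs[[3]]))
  interior <- interior_mask(c(16, 16, 16), 3)
  for (c in 1:3) {
    expect_lt(max(abs((a$u - b$u)[, , , c][interior])), 0.05)
  }
})

test_that("field upsampling preserves physical displacement", {
  g2 <- grid3(c(8, 8, 8), c(2, 2, 2))
  u <- array(1, c(8, 8, 8, 3))
  phi <- displacement_field(u, g2, "integrated")
  expect_equal(upsample_field(phi, g2)$u, u)

  g1 <- grid3(c(16, 16, 16), c(1, 1, 1), c(-0.5, -0.5, -0.5))
  up <- upsample_field(phi, g1)
  expect_equal(dim(up$u)[1:3], c(16L, 16L, 16L))
  # 1 voxel @ 2 mm = 2 voxels @ 1 mm, everywhere (border-clamped sampling)
  expect_lt(max(abs(up$u - 2)), 1e-9)

  # trilinear interpolation reproduces a linear ramp exactly (interior)
  ur <- array(0, c(8, 8, 8, 3))
  ur[, , , 1] <- array(rep(0:7, times = 64), rep(8, 3)) * 0.1
  pr <- displacement_field(ur, g2, "integrated")
  upr <- upsample_field(pr, g1)
  ix <- 3:14 # target voxels whose source support is interior
  xpos_mm <- -0.5 + (ix - 1) * 1
  expected_vox <- (xpos_mm / 2) * 0.1 * 2
  got <- upr$u[ix, 8, 8, 1]
  expect_lt(max(abs(got - expected_vox)), 1e-9)

  bad <- grid3(c(16, 16, 16), c(1, 1, 1), c(30, 30, 30))
  expect_error(upsample_field(phi, bad), "extent")
})

test_that("jacobian report matches analytic determinants", {
  g <- grid3(rep(16, 3))
  jr0 <- jacobian_report(mr4dctreg:::zero_field(g))
  expect_identical(unique(as.vector(jr0$det)), 1)
  expect_identical(jr0$foldings_fraction, 0)
  expect_identical(jr0$std_log_jacobian, 0)

  # uniform 10% expansion: interior det = 1.1^3
  u <- array(0, c(16, 16, 16, 3))
  for (c in 1:3) {
    idx <- slice.index(u[, , , c, drop = TRUE], c) - 1
    u[, , , c] <- 0.1 * idx
  }
  jr <- jacobian_report(displacement_field(u, g, "ground-truth"))
  interior <- interior_mask(c(16, 16, 16), 1)
  expect_lt(max(abs(jr$det[interior] - 1.331)), 1e-6)

  # pure translation: det exactly 1, StdLJ 0
  ut <- array(0, c(16, 16, 16, 3)); ut[, , , 2] <- 4.7
  jt <- jacobian_report(displacement_field(ut, g, "ground-truth"))
  expect_lt(max(abs(jt$det - 1)), 1e-12)
  expect_identical(jt$std_log_jacobian, 0)
})

test_that("constructed folds are counted exactly", {
  g <- grid3(rep(12, 3))
  u <- array(0, c(12, 12, 12, 3))
  # flip one cell: a strong negative x-gradient creates det <= 0 there
  u[6, 6, 6, 1] <- -3
  det <- mr4dctreg:::jacobian_det(u)
  k <- sum(det <= 0) # brute-force count of folded voxels
  expect_gt(k, 0)
  jr <- jacobian_report(displacement_field(u, g, "ground-truth"))
  expect_equal(jr$foldings_fraction, k / 12^3)

  # masked variant counts only mask voxels
  mk <- array(FALSE, rep(12, 3)); mk[5:7, 5:7, 5:7] <- TRUE
  jm <- jacobian_report(displacement_field(u, g, "ground-truth"),
                        binary_mask(mk, g))
  expect_equal(jm$foldings_fraction_mask, sum(det <= 0 & mk) / sum(mk))
})

test_that("central-difference adjoint satisfies the inner-product identity", {
  set.seed(4)
  a <- array(rnorm(10^3), rep(10, 3))
  b <- array(rnorm(10^3), rep(10, 3))
  for (ax in 1:3) {
    lhs <- sum(mr4dctreg:::axis_cdiff(a, ax) * b)
    rhs <- sum(a * mr4dctreg:::axis_cdiff_adjoint(b, ax))
    expect_lt(abs(lhs - rhs), 1e-9)
  }
})
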