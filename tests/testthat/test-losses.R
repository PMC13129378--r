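# explicit-loop oracle for windowed squared NCC (small inputs only)
lncc_bruteforce <- function(f, m, window, eps = 1e-5) {
  r <- (window - 1) / 2
  d <- dim(f)
  acc <- 0
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    xs <- max(1, x - r):min(d[1], x + r)
    ys <- max(1, y - r):min(d[2], y + r)
    zs <- max(1, z - r):min(d[3], z + r)
    fp <- as.vector(f[xs, ys, zs])
    mp <- as.vector(m[xs, ys, zs])
    n <- length(fp)
    cross <- sum(fp * mp) - sum(fp) * sum(mp) / n
    vf <- max(sum(fp^2) - sum(fp)^2 / n, 0)
    vm <- max(sum(mp^2) - sum(mp)^2 / n, 0)
    acc <- acc + cross^2 / (vf * vm + eps)
  }
  1 - acc / prod(d)
}

test_that("lncc is zero at its optimum and affine-invariant", {
  img <- smooth_image(16, seed = 5)
  expect_lt(lncc(img, img, window = 9), 1e-6)
  expect_lt(lncc(img, 2 * img + 0.1, window = 9), 1e-5)
})

test_that("lncc matches the explicit-loop oracle", {
  set.seed(8)
  f <- array(runif(16^3), rep(16, 3))
  m <- array(runif(16^3), rep(16, 3))
  expect_lt(abs(lncc(f, m, window = 5) - lncc_bruteforce(f, m, 5)), 1e-6)
})

test_that("mutual information recovers entropy and vanishes for noise", {
  # 4-level quantized image vs itself: MI = H(levels)
  set.seed(9)
  levels <- c(0.125, 0.375, 0.625, 0.875)
  probs <- c(0.4, 0.3, 0.2, 0.1)
  img <- array(sample(levels, 32^3, TRUE, probs), rep(32, 3))
  h <- -sum(probs * log(probs))
  freq <- table(img) / length(img) # empirical frequencies of the draw
  h_emp <- -sum(freq * log(freq))
  mi <- -neg_mutual_information(img, img, bins = 32)
  expect_lt(abs(mi - h_emp), 0.02)
  expect_lt(abs(mi - h), 0.05)

  # independent noise: MI near zero
  a <- array(runif(32^3), rep(32, 3))
  b <- array(runif(32^3), rep(32, 3))
  expect_lt(-neg_mutual_information(a, b, bins = 32), 0.05)
})

test_that("masked losses equal unmasked losses on the voxel subset", {
  set.seed(10)
  f <- array(runif(16^3), rep(16, 3))
  m <- array(runif(16^3), rep(16, 3))
  g <- grid3(rep(16, 3))
  mk <- array(FALSE, rep(16, 3)); mk[4:13, 4:13, 4:13] <- TRUE
  mask <- binary_mask(mk, g)

  # MI on mask == MI on the extracted voxel subset (as a flat region)
  sub_f <- array(f[mk], c(sum(mk), 1, 1))
  sub_m <- array(m[mk], c(sum(mk), 1, 1))
  expect_lt(abs(neg_mutual_information(f, m, 32, mask) -
                  neg_mutual_information(sub_f, sub_m, 32)), 1e-6)

  # all-true masks change nothing
  full <- binary_mask(array(TRUE, rep(16, 3)), g)
  expect_equal(lncc(f, m, 5, full), lncc(f, m, 5))
  expect_equal(neg_mutual_information(f, m, 32, full),
               neg_mutual_information(f, m, 32))
  expect_error(neg_mutual_information(f, m, 32,
                                      binary_mask(array(FALSE, rep(16, 3)),
                                                  g)),
               "empty mask")
})

test_that("losses are symmetric in their image arguments", {
  set.seed(11)
  f <- array(runif(12^3), rep(12, 3))
  m <- array(runif(12^3), rep(12, 3))
  expect_lt(abs(lncc(f, m, 5) - lncc(m, f, 5)), 1e-6)
  expect_lt(abs(neg_mutual_information(f, m) -
                  neg_mutual_information(m, f)), 1e-9)
})

test_that("soft dice matches counted overlaps", {
  d <- c(16, 16, 16)
  cube <- array(0, c(d, 1))
  cube[5:12, 5:12, 5:12, 1] <- 1 # 8^3 = 512 voxels
  half <- array(0, c(d, 1))
  half[5:8, 5:12, 5:12, 1] <- 1 # front half: 256 voxels
  expect_lt(abs(soft_dice_loss(cube, cube)), 1e-5)
  expect_lt(abs(soft_dice_loss(cube, half) - (1 - 2 * 256 / 768)), 1e-4)

  disj <- array(0, c(d, 1))
  disj[1:4, 1:4, 1:4, 1] <- 1
  expect_gt(soft_dice_loss(cube, disj), 0.999)

  # organ empty on both sides contributes zero loss
  two <- array(0, c(d, 2))
  two[, , , 1] <- cube[, , , 1]
  expect_lt(soft_dice_loss(two, two), 1e-5)
})

test_that("field penalties match analytic values", {
  g <- grid3(rep(16, 3))
  expect_identical(detjac_penalty(mr4dctreg:::zero_field(g)), 0)
  expect_identical(gradient_l2_penalty(mr4dctreg:::zero_field(g)), 0)

  # translations are free under both penalties
  ut <- array(0, c(16, 16, 16, 3)); ut[, , , 1] <- 3.3
  pt <- displacement_field(ut, g, "ground-truth")
  expect_lt(detjac_penalty(pt), 1e-12)
  expect_identical(gradient_l2_penalty(pt), 0)

  # uniform 10% expansion: interior per-voxel (1.331 - 1)^2
  u <- array(0, c(16, 16, 16, 3))
  for (c in 1:3) u[, , , c] <- 0.1 * (slice.index(u[, , , c, drop = TRUE], c) - 1)
  det <- mr4dctreg:::jacobian_det(u)
  interior <- interior_mask(c(16, 16, 16), 1)
  expect_lt(abs(mean((det[interior] - 1)^2) - (1.331 - 1)^2), 1e-6)

  # linear ramp u_z = 0.2 z: brute-force forward-difference oracle
  ur <- array(0, c(16, 16, 16, 3))
  ur[, , , 3] <- 0.2 * (slice.index(ur[, , , 3, drop = TRUE], 3) - 1)
  got <- gradient_l2_penalty(displacement_field(ur, g, "ground-truth"))
  brute <- 0
  nfam <- 0
  for (comp in 1:3) for (ax in 1:3) {
    arr <- ur[, , , comp, drop = TRUE]
    dd <- apply(arr, setdiff(1:3, ax), diff) # all forward differences
    brute <- brute + mean(dd^2)
    nfam <- nfam + 1
  }
  expect_lt(abs(got - brute / nfam), 1e-9)
  expect_lt(abs(got - 0.04 / 9), 1e-9)
})

test_that("loss gradients agree with finite differences at probe voxels", {
  set.seed(12)
  f <- array(runif(10^3), rep(10, 3))
  m <- array(runif(10^3), rep(10, 3))
  eps <- 1e-6
  probes <- sample(10^3, 5)

  lg <- mr4dctreg:::lncc_grad(f, m, window = 5)
  ng <- mr4dctreg:::nmi_grad(f, m, bins = 16)
  for (i in probes) {
    m2 <- m; m2[i] <- m2[i] + eps
    fd <- (lncc(f, m2, 5) - lg$value) / eps
    expect_lt(abs(fd - lg$gmoving[i]) / max(abs(fd), 1e-3), 1e-2)
    fd <- (neg_mutual_information(f, m2, 16) - ng$value) / eps
    expect_lt(abs(fd - ng$gmoving[i]) / max(abs(fd), 1e-3), 1e-2)
  }

  u <- array(rnorm(10^3 * 3, sd = 0.2), c(10, 10, 10, 3))
  dj <- mr4dctreg:::detjac_penalty_grad(u)
  gl <- mr4dctreg:::gradient_l2_grad(u)
  for (i in sample(length(u), 5)) {
    u2 <- u; u2[i] <- u2[i] + eps
    fd <- (mean((mr4dctreg:::jacobian_det(u2) - 1)^2) - dj$value) / eps
    expect_lt(abs(fd - dj$gu[i]), 1e-4)
    fd <- (mr4dctreg:::gradient_l2_impl(u2, FALSE)$value - gl$value) / eps
    expect_lt(abs(fd - gl$gu[i]), 1e-6)
  }
})
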