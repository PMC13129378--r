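test_that("phantom generation is deterministic and well-formed", {
  cfg <- phantom_config(seed = 2)
  a <- make_anatomy(cfg)
  b <- make_anatomy(cfg)
  expect_identical(a$ct50$data, b$ct50$data)
  expect_identical(a$labels$data, b$labels$data)

  # every registry organ occupies at least one voxel; labels are a partition
  for (id in a$labels$registry$organ_id) {
    expect_gt(sum(a$labels$data == id), 0)
  }

  s1 <- make_study(cfg)
  s2 <- make_study(cfg)
  expect_identical(s1$ct[["0"]]$data, s2$ct[["0"]]$data)
  expect_identical(s1$mr$data, s2$mr$data)
})

test_that("liver volume scales with the grid", {
  vols <- vapply(c(32, 48, 64), function(n) {
    cfg <- phantom_config(grid = grid3(c(n, n, round(n * 2 / 3)),
                                       c(2, 2, 2)), seed = 3)
    an <- make_anatomy(cfg)
    liver <- an$labels$registry$organ_id[an$labels$registry$name == "liver"]
    sum(an$labels$data == liver) / prod(cfg$grid$shape)
  }, numeric(1))
  expect_lt(max(abs(vols - mean(vols))) / mean(vols), 0.05)
})

test_that("motion vanishes at the reference phase and peaks at phase 0", {
  cfg <- phantom_config(seed = 5)
  expect_identical(max(abs(make_motion(cfg, 50)$u)), 0)
  m <- vapply(c(0, 16, 33, 50, 66, 83), function(ph) {
    mean(abs(make_motion(cfg, ph)$u[, , , 3]))
  }, numeric(1))
  expect_identical(m[4], 0)
  expect_true(all(m[1] >= m[-1]))

  st <- phantom_fixture()
  expect_identical(max(abs(st$truth$ddf[["50"]]$u)), 0)
  expect_identical(st$ct[["50"]]$data, make_anatomy(st$config)$ct50$data)
})

test_that("integrated motion moves the diaphragm apex by a(phase) * A", {
  st <- phantom_fixture()
  A_vox <- st$config$amplitude / st$grid$spacing[3]
  liver <- st$registry$organ_id[st$registry$name == "liver"]
  for (ph in c("0", "16")) {
    lab <- st$labels_ct[[ph]]$data
    ijk <- which(lab == liver, arr.ind = TRUE)
    top <- ijk[ijk[, 3] == max(ijk[, 3]), , drop = FALSE]
    lm <- top[ceiling(nrow(top) / 2), ]
    u <- st$truth$ddf[[ph]]$u[lm[1], lm[2], lm[3], ]
    a <- mr4dctreg:::phase_amplitude(as.numeric(ph))
    expect_lt(abs(sqrt(sum(u^2)) - a * A_vox), 0.5)
  }
})

test_that("ground-truth fields are near-diffeomorphic and invertible", {
  st <- phantom_fixture()
  ref <- st$labels_ct[["50"]]
  for (ph in c("0", "16", "33", "66", "83")) {
    jr <- jacobian_report(st$truth$ddf[[ph]])
    expect_lt(jr$foldings_fraction, 0.001)
    inv <- integrate_svf(velocity_field(-st$truth$svf[[ph]]$u, st$grid))
    back <- warp(st$labels_ct[[ph]], inv, "nearest")
    dc <- per_organ_dice(back, ref)
    expect_true(all(dc >= 0.97, na.rm = TRUE),
                info = sprintf("phase %s: min dice %.4f", ph,
                               min(dc, na.rm = TRUE)))
  }
})

test_that("MR contrast genuinely differs from CT", {
  org <- phantom_organs()
  expect_lt(abs(cor(org$hu, org$mr, method = "spearman")), 0.5)

  # perfect-alignment configuration transfers labels exactly
  cfg <- phantom_config(mr_misalignment = rigid_params(),
                        mr_fov_crop = 1.0, seed = 6)
  an <- make_anatomy(cfg)
  mrp <- make_mr(cfg, an$ct50, an$labels)
  expect_identical(mrp$labels_mr$data, an$labels$data)
})

test_that("MR field of view matches the configured crop", {
  st <- phantom_fixture()
  sm <- support_mask(st$mr, st$grid)
  expect_lt(abs(mean(sm$data) - st$config$mr_fov_crop), 0.05)
  # flags: the lungs are partially cut, the supervised organs are not
  reg <- st$registry
  expect_true(all(reg$full_fov[reg$supervised]))
  expect_false(any(reg$full_fov[grepl("lung", reg$name)]))
})

test_that("binning artifacts appear only at positive artifact rate", {
  base <- make_study(phantom_config(artifact_rate = 0, seed = 7))
  jumps <- vapply(setdiff(names(base$ct), "50"), function(ph) {
    d <- base$ct[[ph]]$data
    max(abs(d[, , -1] - d[, , -dim(d)[3]]))
  }, numeric(1))
  # without artifacts, inter-slice jumps are bounded by anatomy contrast
  # plus noise; a duplicated shifted slab cannot exceed this bound
  bound <- diff(range(base$ct[["50"]]$data)) +
    6 * base$config$noise_sd
  expect_true(all(jumps <= bound))

  art <- make_study(phantom_config(artifact_rate = 1, seed = 7))
  differs <- vapply(setdiff(names(art$ct), "50"), function(ph) {
    !identical(art$ct[[ph]]$data, base$ct[[ph]]$data)
  }, logical(1))
  expect_true(all(differs))
})

test_that("cohorts give distinct, seeded subjects", {
  co <- phantom_cohort(2, phantom_config(seed = 0), seed = 42)
  co2 <- phantom_cohort(2, phantom_config(seed = 0), seed = 42)
  expect_identical(co$subj01$mr$data, co2$subj01$mr$data)
  expect_false(identical(co$subj01$ct[["0"]]$data,
                         co$subj02$ct[["0"]]$data))
})
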