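test_that("dice matches counted overlaps and handles empty masks", {
  g <- grid3(rep(16, 3))
  cube <- array(FALSE, rep(16, 3)); cube[5:12, 5:12, 5:12] <- TRUE
  half <- array(FALSE, rep(16, 3)); half[5:8, 5:12, 5:12] <- TRUE
  a <- binary_mask(cube, g)
  b <- binary_mask(half, g)
  expect_identical(dice(a, a), 1)
  expect_lt(abs(dice(a, b) - 2 * 256 / 768), 1e-6)
  expect_identical(dice(a, b), dice(b, a))

  empty <- binary_mask(array(FALSE, rep(16, 3)), g)
  expect_identical(dice(empty, empty), 1)
  expect_identical(dice(a, empty), 0)
  disj <- binary_mask(array(c(TRUE, rep(FALSE, 16^3 - 1)), rep(16, 3)), g)
  expect_identical(dice(a, disj), 0)
})

test_that("hausdorff95 matches analytic plate distances and units", {
  g <- grid3(c(20, 20, 20), c(1, 1, 1))
  p1 <- array(FALSE, rep(20, 3)); p1[5:15, 5:15, 8] <- TRUE
  p2 <- array(FALSE, rep(20, 3)); p2[5:15, 5:15, 13] <- TRUE
  a <- binary_mask(p1, g)
  b <- binary_mask(p2, g)
  expect_identical(hausdorff95(a, a), 0)
  h <- hausdorff95(a, b)
  expect_lt(abs(h - 5), sqrt(3) + 1e-9) # within one voxel diagonal

  # doubling the spacing doubles the distance exactly
  g2 <- grid3(c(20, 20, 20), c(2, 2, 2))
  h2 <- hausdorff95(binary_mask(p1, g2), binary_mask(p2, g2))
  expect_equal(h2, 2 * h)

  # symmetry, and the 95th percentile never exceeds the maximum
  set.seed(13)
  r1 <- array(runif(20^3) < 0.2, rep(20, 3)); r1[1] <- TRUE
  r2 <- array(runif(20^3) < 0.2, rep(20, 3)); r2[2] <- TRUE
  m1 <- binary_mask(r1, g); m2 <- binary_mask(r2, g)
  expect_equal(hausdorff95(m1, m2), hausdorff95(m2, m1))
  expect_lte(hausdorff95(m1, m2), hausdorff95(m1, m2, percentile = 100))
  expect_true(is.na(hausdorff95(m1, binary_mask(array(FALSE, rep(20, 3)),
                                                g))))
})

test_that("exact Wilcoxon p-values match exhaustive sign enumeration", {
  # all-positive differences, n = 6: two-sided p = 2/2^6
  d <- c(0.11, 0.23, 0.08, 0.17, 0.29, 0.05)
  p <- mr4dctreg:::paired_wilcoxon_p(d, rep(0, 6))
  expect_equal(p, 2 / 64)

  # exhaustive enumeration oracle over all sign assignments
  enum_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    stat <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    stats <- as.matrix(signs) %*% r
    # two-sided exact p: probability of a statistic at least as extreme
    lo <- mean(stats <= stat)
    hi <- mean(stats >= stat)
    min(1, 2 * min(lo, hi))
  }
  set.seed(14)
  for (i in 1:4) {
    d <- round(rnorm(7), 3)
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    expect_equal(mr4dctreg:::paired_wilcoxon_p(d, rep(0, length(d))),
                 enum_p(d), tolerance = 1e-12)
  }

  # identical samples: all differences dropped, p = 1
  expect_identical(mr4dctreg:::paired_wilcoxon_p(1:6 / 10, 1:6 / 10), 1)
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  adj <- p.adjust(p, method = "BH")
  expect_equal(adj, c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_true(all(diff(sort(adj)) >= -1e-15))
  expect_true(all(adj >= p))
})

test_that("compare_methods reduces to patient medians and stars bands", {
  set.seed(15)
  mk <- function(method, shift) {
    tidyr::expand_grid(subject = sprintf("s%02d", 1:8),
                       phase = c("0", "50"),
                       organ = c("liver", "spleen")) |>
      dplyr::mutate(method = method,
                    dsc = pmin(1, pmax(0, 0.6 + shift +
                                         runif(dplyr::n(), 0, 0.05))))
  }
  rec <- dplyr::bind_rows(mk("rigid", 0), mk("dl", 0.2))
  cmp <- compare_methods(rec, "dsc")
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$n_subjects, 8L)
  expect_lt(cmp$p_value, 0.01)
  expect_gte(cmp$p_adjusted, cmp$p_value)
  expect_true(cmp$stars %in% c("**", "***", "****"))

  # a method compared with itself is not significant
  rec2 <- dplyr::bind_rows(mk("a", 0.1),
                           dplyr::mutate(mk("a", 0.1), method = "b"))
  # same generator, same seed structure -> differences are tiny noise
  cmp2 <- compare_methods(dplyr::bind_rows(
    dplyr::mutate(rec2, dsc = rep(rec2$dsc[seq_len(nrow(rec2) / 2)], 2))),
    "dsc")
  expect_identical(cmp2$p_value, 1)
  expect_identical(cmp2$stars, "ns")
})

test_that("star bands follow the conventional thresholds", {
  expect_identical(mr4dctreg:::star_band(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
                   c("ns", "*", "**", "***", "****"))
})

test_that("self-evaluation is the metric fixed point", {
  st <- phantom_fixture()
  r_rigid <- propagate_rigid(st, seed = 1)
  # substitute the truth as the prediction: every organ must be perfect
  r_perfect <- r_rigid
  r_perfect$method <- "perfect"
  r_perfect$warped_labels <- st$labels_ct
  for (k in names(r_perfect$fields)) {
    r_perfect$fields[[k]] <- mr4dctreg:::zero_field(st$grid)
  }
  rec <- evaluate_result(r_perfect, st$labels_ct, subject = "s1")
  organs <- dplyr::filter(rec, !organ %in% c("seen", "unseen", "all"))
  expect_true(all(organs$dsc == 1))
  expect_true(all(organs$h95_mm == 0))
  expect_true(all(organs$foldings_pct == 0))

  # aggregates are unweighted means of the per-organ rows
  agg_all <- dplyr::filter(rec, organ == "all")
  per_phase <- organs |>
    dplyr::group_by(phase) |>
    dplyr::summarise(m = mean(dsc))
  expect_equal(agg_all$dsc, per_phase$m[match(agg_all$phase,
                                              per_phase$phase)])

  # rigid baseline: all phase fields identical, zero foldings
  rec_r <- evaluate_result(r_rigid, st$labels_ct, subject = "s1")
  expect_true(all(abs(rec_r$foldings_pct) < 1e-6))
})

test_that("masked MI record is consistent with the loss module", {
  st <- phantom_fixture()
  r <- propagate_rigid(st, seed = 1)
  fixed <- lapply(st$ct, normalize_intensities)
  rec <- evaluate_result(r, st$labels_ct, fixed = fixed, subject = "s1")
  row <- dplyr::filter(rec, phase == "50")[1, ]
  direct <- -neg_mutual_information(fixed[["50"]], r$warped_mr[["50"]],
                                    mask = r$omega)
  expect_equal(row$mi_overlap, direct, tolerance = 1e-9)
  expect_false(identical(row$mi_overlap, row$mi_whole))
})

test_that("binned improvement reduces to global means for one bin", {
  rec <- tidyr::expand_grid(subject = c("a", "b"), phase = "0",
                            organ = c("liver", "spleen")) |>
    dplyr::mutate(method = "dl", dsc = c(0.71, 0.72, 0.73, 0.74),
                  mi_overlap = 0.5)
  rig <- dplyr::mutate(rec, method = "rigid",
                       dsc = c(0.62, 0.63, 0.64, 0.65))
  tab <- binned_improvement(rec, rig, bin_width = 0.1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$mean_dsc, mean(rec$dsc))
  expect_equal(tab$bin, 0.6)

  # a method identical to rigid reproduces the rigid bin means
  tab2 <- binned_improvement(dplyr::mutate(rig, method = "same"), rig)
  expect_equal(tab2$mean_dsc, tab2$mean_rigid_dsc)
})
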