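working_grid_small <- grid3(c(24, 24, 16), c(4, 4, 4))

sampler_fixture <- function(pairing) {
  memo(paste0("sampler_", pairing), function() {
    studies <- memo("cohort2", function() {
      phantom_cohort(2, phantom_config(seed = 0), seed = 10)
    })
    pair_sampler(studies, pairing, working_grid = working_grid_small,
                 seed = 1)
  })
}

test_that("objectives sit near their optimum on degenerate pairs", {
  g <- working_grid_small
  net <- build_network(network_config(g, levels = 3, base_channels = 8,
                                      seed = 1))
  st <- phantom_fixture()
  ws <- mr4dctreg:::study_working_set(st, g)
  ct50 <- volume(ws$ct[["50"]], g)

  # identical images and labels with a near-identity network
  loss <- temporal_objective(ct50, ct50, ws$labels[["50"]],
                             ws$labels[["50"]], net)
  expect_lt(as.numeric(loss), 0.05)
  expect_named(attr(loss, "terms"),
               c("similarity", "regularization", "dice"))

  # multi-modal degenerate pair: MR as a contrast remap of aligned anatomy
  cfg0 <- phantom_config(mr_misalignment = rigid_params(),
                         mr_fov_crop = 1.0, seed = 3)
  st0 <- make_study(cfg0)
  ws0 <- mr4dctreg:::study_working_set(st0, g)
  loss_mm <- multimodal_objective(volume(ws0$ct[["50"]], g),
                                  volume(ws0$mr, g), ws0$labels[["50"]],
                                  ws0$labels_mr, ws0$omega, net)
  terms <- attr(loss_mm, "terms")
  expect_lt(terms[["dice"]], 0.05)
  expect_lt(terms[["regularization"]], 1e-4)
})

test_that("default weights follow the per-model configuration", {
  expect_equal(mr4dctreg:::default_weights("temporal")$lambda, 0.3)
  expect_equal(mr4dctreg:::default_weights("temporal")$gamma, 0.7)
  expect_equal(mr4dctreg:::default_weights("multimodal")$lambda, 0.5)
  expect_equal(mr4dctreg:::default_weights("multimodal")$gamma, 0.5)
  expect_equal(mr4dctreg:::default_weights("direct")$lambda, 0.5)
  expect_equal(mr4dctreg:::default_weights("direct")$gamma, 0.5)
  expect_error(loss_weights(-1, 0), ">= 0")
})

test_that("all three loss terms carry gradient (no dead terms)", {
  g <- grid3(c(8, 8, 8), c(4, 4, 4))
  net <- build_network(network_config(g, levels = 2, base_channels = 4,
                                      seed = 2))
  set.seed(16)
  d3 <- g$shape
  pair <- list(fixed = array(runif(prod(d3)), d3),
               moving = array(runif(prod(d3)), d3),
               fixed_probs = array(runif(prod(d3)), c(d3, 1)),
               moving_probs = array(runif(prod(d3)), c(d3, 1)),
               mask = NULL)
  # make the field non-trivial so the regularizer has signal
  net$params$head$w[] <- rnorm(length(net$params$head$w), sd = 0.05)
  w <- loss_weights(0.3, 0.7)
  res <- mr4dctreg:::svf_objective_core(net, pair, w, "lncc", "detjac",
                                        5L, 16L, want_grads = TRUE)
  gmag <- function(gr) max(abs(unlist(gr)))
  expect_gt(gmag(res$grads), 0)

  # perturbing any weight changes the loss: each term is live
  for (wts in list(loss_weights(1, 0), loss_weights(0, 1))) {
    r2 <- mr4dctreg:::svf_objective_core(net, pair, wts, "lncc", "detjac",
                                         5L, 16L, want_grads = FALSE)
    expect_false(isTRUE(all.equal(r2$loss, res$loss)))
  }
})

test_that("short training runs are deterministic and reduce the loss", {
  samp <- sampler_fixture("ct50-to-phase")
  tc <- train_config("temporal", working_grid = working_grid_small,
                     iterations = 25, base_channels = 8, seed = 5,
                     val_every = 25)
  tr1 <- train_network(samp, tc)
  tr2 <- train_network(samp, tc)
  expect_identical(tr1$final_net$params, tr2$final_net$params)
  expect_identical(tr1$log$loss, tr2$log$loss)

  # retained checkpoint never has worse validation loss than iteration 0
  expect_lte(min(tr1$val_log$val_loss), tr1$val_log$val_loss[1])
  expect_equal(nrow(tr1$log), 25L)

  gl <- glance(tr1)
  expect_identical(gl$model_kind, "temporal")
  expect_equal(gl$lambda, 0.3)
})

test_that("qc_filter keeps exactly the candidates above threshold", {
  g <- grid3(rep(16, 3))
  ref <- label_cube(16, 5, 12)
  good <- ref
  ok <- label_cube(16, 6, 12) # shifted face: dice ~ 0.9
  poor <- label_cube(16, 10, 12) # small overlap
  res <- qc_filter(list(a = good, b = ok, c = poor),
                   list(ref, ref, ref), threshold = 0.5)
  expect_equal(res$report$mean_dice[1], 1)
  expect_true(res$report$kept[2])
  expect_false(res$report$kept[3])
  expect_equal(res$kept, c(1L, 2L))

  expect_equal(qc_filter(list(poor), list(ref), threshold = 0)$kept, 1L)
  expect_equal(qc_filter(list(good), list(ref), threshold = 1)$kept, 1L)
  expect_error(qc_filter(list(good), list(ref, ref)), "paired")
})

test_that("patient splits are exact, disjoint and seeded", {
  ids <- sprintf("p%03d", 1:170)
  sp <- patient_split(ids, c(122, 32, 16) / 170, seed = 7)
  expect_equal(lengths(sp), c(train = 122L, val = 32L, test = 16L))
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(unlist(sp), ids)
  expect_identical(patient_split(ids, c(122, 32, 16) / 170, seed = 7), sp)

  folds <- k_fold(ids, 5, seed = 8)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), ids)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  }
  expect_error(k_fold(ids[1:3], 5), "fewer subjects")
})
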