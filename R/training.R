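#' Training configuration
#'
#' Bundles the model kind, loss weights (Table-style defaults: temporal
#' lambda 0.3 / gamma 0.7, multi-modal and direct 0.5 / 0.5), working grid,
#' optimization settings and seeds. The optimizer is Adam with batch size
#' one; sampling and initialization are fully seeded.
#'
#' @param model_kind `"temporal"`, `"multimodal"` or `"direct"` (the direct
#'   model applies the multi-modal objective to (MR, CT-phase) pairs for
#'   every phase — mutual information is the only similarity valid across
#'   modalities at all phases).
#' @param working_grid a [grid3()]: resolution at which fields are predicted.
#' @param iterations optimization steps.
#' @param weights a [loss_weights()]; defaults by model kind.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization and pair sampling.
#' @param levels,base_channels,attention_gates,velocity_scale forwarded to
#'   [network_config()].
#' @param lncc_window,mi_bins similarity-loss settings.
#' @param val_every validation cadence (iterations); the checkpoint with the
#'   best validation loss is retained.
#' @return A list of class `mr4dct_trainconfig`.
#' @export
train_config <- function(model_kind = c("temporal", "multimodal", "direct"),
                         working_grid = grid3(c(24, 24, 16), c(4, 4, 4)),
                         iterations = 300L,
                         weights = NULL,
                         learning_rate = 1e-3,
                         seed = 0L,
                         levels = 3L,
                         base_channels = 16L,
                         attention_gates = TRUE,
                         velocity_scale = 1,
                         lncc_window = 9L,
                         mi_bins = 32L,
                         val_every = 25L) {
  model_kind <- match.arg(model_kind)
  weights <- weights %||% default_weights(model_kind)
  structure(list(model_kind = model_kind, working_grid = working_grid,
                 iterations = as.integer(iterations), weights = weights,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 attention_gates = isTRUE(attention_gates),
                 velocity_scale = velocity_scale,
                 lncc_window = as.integer(lncc_window),
                 mi_bins = as.integer(mi_bins),
                 val_every = as.integer(val_every)),
            class = "mr4dct_trainconfig")
}

# soft per-organ probability channels of a label map, resampled to a grid
soft_probs_on_grid <- function(lm, organ_ids, target) {
  out <- array(0, c(target$shape, length(organ_ids)))
  for (k in seq_along(organ_ids)) {
    ind <- (lm$data == organ_ids[k]) + 0.0
    out[, , , k] <- resample_array(ind, lm$grid, target)
  }
  out
}

# per-subject working-resolution tensors for training and inference
study_working_set <- function(study, working_grid, rigid = NULL,
                              use_true_rigid = TRUE) {
  g <- study$grid
  reg <- study$registry
  sup_ids <- reg$organ_id[reg$supervised & reg$full_fov]
  ct_work <- lapply(study$ct, function(v) {
    resample_array(normalize_intensities(v)$data, g, working_grid)
  })
  labels_work <- lapply(study$labels_ct, function(lm) {
    soft_probs_on_grid(lm, sup_ids, working_grid)
  })
  mrn <- normalize_intensities(study$mr)
  mr_ct <- resample_to_grid(mrn, g)
  support <- support_mask(study$mr, g)
  if (is.null(rigid)) {
    rigid <- if (use_true_rigid) {
      fld <- rigid_to_field(study$truth$rigid, g)
      list(params = study$truth$rigid, field = fld,
           omega = warp(support, fld, "nearest"))
    } else {
      rigid_align(mr_ct, normalize_intensities(study$ct[["50"]]),
                  seed = study$config$seed, support = support)
    }
  }
  mr_rigid <- warp(mr_ct, rigid$field, "trilinear")
  mr_work <- resample_array(mr_rigid$data, g, working_grid)
  # MR labels transported to the rigidly-aligned CT frame
  lab_mr_ct <- resample_to_grid(study$labels_mr, g, "nearest")
  lab_mr_rigid <- warp(lab_mr_ct, rigid$field, "nearest")
  labels_mr_work <- soft_probs_on_grid(lab_mr_rigid, sup_ids, working_grid)
  omega_work <- resample_array(rigid$omega$data + 0.0, g, working_grid,
                               nearest = TRUE) > 0.5
  list(ct = ct_work, labels = labels_work, mr = mr_work,
       labels_mr = labels_mr_work, omega = omega_work,
       rigid = rigid, support = support, sup_ids = sup_ids)
}

#' Build a training pair sampler over phantom studies
#'
#' Enumerates registration pairs at the working resolution with
#' patient-level train/validation disjointness. Pairings: `"ct50-to-phase"`
#' (temporal: fixed CT-phase, moving CT-50), `"mr-to-ct50"` (multi-modal),
#' `"mr-to-any-phase"` (direct). For training phantoms the generator's true
#' rigid parameters pre-align the MR (the supervision labels are ground
#' truth anyway); held-out evaluation must run [rigid_align()].
#'
#' @param studies named list of [make_study()] results.
#' @param pairing pairing rule, see above.
#' @param working_grid a [grid3()].
#' @param val_subjects names (or indices) of validation subjects.
#' @param seed integer seed.
#' @param use_true_rigid pre-align MR with the generator's rigid truth?
#' @return A list of class `mr4dct_sampler` with `train` / `val` pair lists.
#' @export
pair_sampler <- function(studies,
                         pairing = c("ct50-to-phase", "mr-to-ct50",
                                     "mr-to-any-phase"),
                         working_grid = grid3(c(24, 24, 16), c(4, 4, 4)),
                         val_subjects = NULL,
                         seed = 0L,
                         use_true_rigid = TRUE) {
  pairing <- match.arg(pairing)
  assert_that(length(studies) > 0, "empty study list")
  nm <- names(studies) %||% as.character(seq_along(studies))
  if (is.numeric(val_subjects)) val_subjects <- nm[val_subjects]
  val_subjects <- val_subjects %||% character(0)
  pairs <- list()
  for (s in seq_along(studies)) {
    st <- studies[[s]]
    ws <- study_working_set(st, working_grid, use_true_rigid = use_true_rigid)
    phases <- as.character(st$phases)
    add <- function(fixed, moving, fprobs, mprobs, mask, phase) {
      pairs[[length(pairs) + 1]] <<- list(
        subject = nm[s], phase = phase, fixed = fixed, moving = moving,
        fixed_probs = fprobs, moving_probs = mprobs, mask = mask)
    }
    if (pairing == "ct50-to-phase") {
      for (ph in setdiff(phases, "50")) {
        add(ws$ct[[ph]], ws$ct[["50"]], ws$labels[[ph]], ws$labels[["50"]],
            NULL, ph)
      }
    } else if (pairing == "mr-to-ct50") {
      add(ws$ct[["50"]], ws$mr, ws$labels[["50"]], ws$labels_mr, ws$omega,
          "50")
    } else {
      for (ph in phases) {
        add(ws$ct[[ph]], ws$mr, ws$labels[[ph]], ws$labels_mr, ws$omega, ph)
      }
    }
  }
  is_val <- vapply(pairs, function(p) p$subject %in% val_subjects, logical(1))
  structure(list(train = pairs[!is_val], val = pairs[is_val],
                 pairing = pairing, working_grid = working_grid,
                 seed = as.integer(seed)),
            class = "mr4dct_sampler")
}

#' @export
print.mr4dct_sampler <- function(x, ...) {
  cat(sprintf("<pair sampler (%s): %d train / %d val pairs>\n", x$pairing,
              length(x$train), length(x$val)))
  invisible(x)
}

# shared objective core: predict SVF, integrate, warp, assemble loss terms
# and (optionally) parameter gradients
svf_objective_core <- function(net, pair, w, sim, reg, lncc_window, mi_bins,
                               want_grads = FALSE, steps = 7L) {
  d3 <- dim(pair$fixed)
  x <- array(0, c(d3, 2L))
  x[, , , 1] <- pair$fixed
  x[, , , 2] <- pair$moving
  fw <- net_forward(net, x, keep_cache = want_grads)
  integ <- integrate_svf_fwd(fw$v, steps)
  phi_u <- integ$u
  mov4 <- array(pair$moving, c(d3, 1L))
  warped <- cpp_warp_linear(mov4, phi_u, 0L)
  warped3 <- array(warped, d3)
  msk <- pair$mask

  if (sim == "lncc") {
    sim_res <- lncc_impl(pair$fixed, warped3, lncc_window, msk, 1e-5,
                         want_grad = want_grads)
  } else {
    sim_res <- nmi_impl(pair$fixed, warped3, mi_bins, msk,
                        want_grad = want_grads)
  }
  wprobs <- cpp_warp_linear(pair$moving_probs, phi_u, 0L)
  dice_res <- soft_dice_impl(pair$fixed_probs, wprobs, NULL, 1e-5,
                             want_grad = want_grads)
  reg_res <- if (reg == "detjac") {
    if (want_grads) detjac_penalty_grad(phi_u) else
      list(value = mean((jacobian_det(phi_u) - 1)^2))
  } else {
    gradient_l2_impl(phi_u, want_grad = want_grads)
  }
  loss <- sim_res$value + w$lambda * reg_res$value +
    w$gamma * dice_res$value
  terms <- c(similarity = sim_res$value, regularization = reg_res$value,
             dice = dice_res$value)
  if (!want_grads) {
    return(list(loss = loss, terms = terms))
  }
  g_warped <- array(sim_res$gmoving, c(d3, 1L))
  bw_img <- cpp_warp_linear_bwd(mov4, phi_u, g_warped, 0L)
  bw_probs <- cpp_warp_linear_bwd(pair$moving_probs, phi_u,
                                  w$gamma * dice_res$gmoving, 0L)
  g_phi <- bw_img$gdisp + bw_probs$gdisp + w$lambda * reg_res$gu
  g_v <- integrate_svf_bwd(integ$cache, g_phi, steps)
  grads <- net_backward(net, fw$cache, g_v)
  list(loss = loss, terms = terms, grads = grads)
}

objective_spec <- function(model_kind) {
  if (model_kind == "temporal") {
    list(sim = "lncc", reg = "detjac")
  } else {
    list(sim = "nmi", reg = "gradl2")
  }
}

#' Temporal (mono-modal) training objective
#'
#' `LNCC(CT-phase, CT-50 warped) + lambda * DetJac penalty + gamma * soft
#' Dice` on the supervised-organ probability channels, with the field
#' predicted by the network from the image pair and shared by images and
#' labels. Default weights lambda 0.3, gamma 0.7.
#'
#' @param ct_phi,ct50 fixed / moving [volume()]s on the working grid,
#'   intensities in `[0, 1]`.
#' @param labels_phi,labels50 [label_map()]s (or 4D probability arrays) on
#'   the working grid.
#' @param net a [build_network()] network.
#' @param weights a [loss_weights()].
#' @param window LNCC window.
#' @return Scalar loss with a `terms` attribute.
#' @export
temporal_objective <- function(ct_phi, ct50, labels50, labels_phi, net,
                               weights = default_weights("temporal"),
                               window = 9L) {
  pair <- objective_pair(ct_phi, ct50, labels_phi, labels50, net, NULL)
  res <- svf_objective_core(net, pair, weights, "lncc", "detjac", window,
                            32L, want_grads = FALSE)
  structure(res$loss, terms = res$terms)
}

#' Multi-modal training objective
#'
#' `-MI(CT-50, MR warped; inside the overlap mask) + lambda * first-order
#' gradient penalty + gamma * soft Dice` on the supervised-organ channels;
#' the MR must already be rigidly pre-aligned and the overlap mask comes
#' from [rigid_align()]. Default weights lambda 0.5, gamma 0.5.
#'
#' @param ct50,mr fixed / moving [volume()]s on the working grid.
#' @param labels50,labels_mr [label_map()]s or probability arrays.
#' @param omega [binary_mask()] (or logical array): the overlap region.
#' @param net a [build_network()] network.
#' @param weights a [loss_weights()].
#' @param bins mutual-information bins.
#' @return Scalar loss with a `terms` attribute.
#' @export
multimodal_objective <- function(ct50, mr, labels50, labels_mr, omega, net,
                                 weights = default_weights("multimodal"),
                                 bins = 32L) {
  pair <- objective_pair(ct50, mr, labels50, labels_mr, net, omega)
  res <- svf_objective_core(net, pair, weights, "nmi", "gradl2", 9L, bins,
                            want_grads = FALSE)
  structure(res$loss, terms = res$terms)
}

objective_pair <- function(fixed, moving, fixed_labels, moving_labels, net,
                           omega) {
  g <- net$cfg$input_grid
  to_arr <- function(v) {
    if (inherits(v, "mr4dct_volume")) {
      assert_that(same_grid(v$grid, g), "volume not on the working grid")
      v$data
    } else {
      as.array(v)
    }
  }
  to_probs <- function(l) {
    if (inherits(l, "mr4dct_labelmap")) {
      sup <- l$registry$organ_id[l$registry$supervised & l$registry$full_fov]
      one_hot(l, sup)
    } else {
      as.array(l)
    }
  }
  msk <- if (is.null(omega)) NULL else as_mask_array(omega, g$shape)
  list(fixed = to_arr(fixed), moving = to_arr(moving),
       fixed_probs = to_probs(fixed_labels),
       moving_probs = to_probs(moving_labels), mask = msk)
}

#' Train a registration network
#'
#' Seeded Adam loop over the sampler's training pairs (batch size one, one
#' uniformly drawn pair per iteration); every `val_every` iterations the
#' mean validation loss is computed and the best-validation checkpoint is
#' retained (falling back to training loss when the sampler has no
#' validation pairs). Two runs with the same seed produce identical
#' parameters.
#'
#' @param sampler a [pair_sampler()] whose pairing matches the model kind.
#' @param cfg a [train_config()].
#' @return A list of class `mr4dct_trained`: `net` (best checkpoint),
#'   `final_net`, `log` (tibble: iteration, loss terms), `val_log`.
#' @export
train_network <- function(sampler, cfg) {
  stopifnot(inherits(sampler, "mr4dct_sampler"),
            inherits(cfg, "mr4dct_trainconfig"))
  assert_that(length(sampler$train) > 0, "sampler has no training pairs")
  ospec <- objective_spec(cfg$model_kind)
  netcfg <- network_config(cfg$working_grid, levels = cfg$levels,
                           base_channels = cfg$base_channels,
                           attention_gates = cfg$attention_gates,
                           velocity_scale = cfg$velocity_scale,
                           seed = derive_seed(cfg$seed, 1))
  net <- build_network(netcfg)
  state <- adam_init(net$params)
  logs <- vector("list", cfg$iterations)
  val_rows <- list()
  best <- list(params = net$params, val = Inf, iteration = 0L)

  eval_pairs <- function(pairs) {
    mean(vapply(pairs, function(p) {
      svf_objective_core(net, p, cfg$weights, ospec$sim, ospec$reg,
                         cfg$lncc_window, cfg$mi_bins,
                         want_grads = FALSE)$loss
    }, numeric(1)))
  }

  with_seed(derive_seed(cfg$seed, 2), {
    val_pairs <- if (length(sampler$val) > 0) sampler$val else sampler$train
    v0 <- eval_pairs(val_pairs)
    best <- list(params = net$params, val = v0, iteration = 0L)
    val_rows[[1]] <- tibble::tibble(iteration = 0L, val_loss = v0)
    for (it in seq_len(cfg$iterations)) {
      p <- sampler$train[[sample.int(length(sampler$train), 1)]]
      res <- svf_objective_core(net, p, cfg$weights, ospec$sim, ospec$reg,
                                cfg$lncc_window, cfg$mi_bins,
                                want_grads = TRUE)
      upd <- adam_step(net$params, res$grads, state,
                       lr = cfg$learning_rate)
      net$params <- upd$params
      state <- upd$state
      logs[[it]] <- tibble::tibble(
        iteration = it, subject = p$subject, phase = p$phase,
        similarity = res$terms[["similarity"]],
        regularization = res$terms[["regularization"]],
        dice = res$terms[["dice"]], loss = res$loss)
      if (it %% cfg$val_every == 0 || it == cfg$iterations) {
        v <- eval_pairs(val_pairs)
        val_rows[[length(val_rows) + 1]] <-
          tibble::tibble(iteration = it, val_loss = v)
        if (v <= best$val) {
          best <- list(params = net$params, val = v, iteration = it)
        }
      }
    }
  })
  final_net <- net
  net$params <- best$params
  structure(list(net = net, final_net = final_net,
                 log = dplyr::bind_rows(logs),
                 val_log = dplyr::bind_rows(val_rows),
                 best_iteration = best$iteration, cfg = cfg),
            class = "mr4dct_trained")
}

#' @export
print.mr4dct_trained <- function(x, ...) {
  cat(sprintf("<trained %s model: %d iterations, best val loss %.4f @ %d>\n",
              x$cfg$model_kind, x$cfg$iterations,
              min(x$val_log$val_loss), x$best_iteration))
  invisible(x)
}

#' Quality-control filter for automatic segmentations
#'
#' Keeps candidates whose mean per-organ Dice against the paired reference
#' is at least `threshold`; failed automatic segmentations are reported
#' with their scores so they can be excluded from training and evaluation.
#'
#' @param candidate_labels,reference_labels paired lists of [label_map()]s
#'   on matching grids.
#' @param threshold Dice threshold in (0, 1]; default 0.5.
#' @return A list: `kept` (indices), `report` (tibble: id, mean_dice,
#'   kept).
#' @export
qc_filter <- function(candidate_labels, reference_labels, threshold = 0.5) {
  assert_that(length(candidate_labels) == length(reference_labels),
              "candidate and reference lists must be paired")
  ids <- names(candidate_labels) %||% as.character(seq_along(candidate_labels))
  scores <- vapply(seq_along(candidate_labels), function(i) {
    cand <- candidate_labels[[i]]
    ref <- reference_labels[[i]]
    assert_that(same_grid(cand$grid, ref$grid), "label grids mismatch")
    organ_ids <- union(setdiff(unique(as.vector(ref$data)), 0L),
                       setdiff(unique(as.vector(cand$data)), 0L))
    if (length(organ_ids) == 0) return(1)
    mean(vapply(organ_ids, function(id) {
      a <- cand$data == id
      b <- ref$data == id
      if (!any(a) && !any(b)) return(1)
      2 * sum(a & b) / (sum(a) + sum(b))
    }, numeric(1)))
  }, numeric(1))
  kept <- which(scores >= threshold)
  list(kept = kept,
       report = tibble::tibble(id = ids, mean_dice = scores,
                               kept = scores >= threshold))
}

#' Patient-level data splitting
#'
#' Exact, disjoint, seeded partitions at the patient level — no subject
#' appears in more than one split, so no image of a test patient can leak
#' into training.
#'
#' @param subject_ids vector of ids.
#' @param fractions length-3 (train, val, test) fractions summing to 1.
#' @param seed integer seed.
#' @return A list with `train`, `val`, `test` id vectors.
#' @export
patient_split <- function(subject_ids, fractions = c(0.7, 0.2, 0.1),
                          seed = 0L) {
  assert_that(abs(sum(fractions) - 1) < 1e-8, "fractions must sum to 1")
  n <- length(subject_ids)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_test <- n - n_train - n_val
  assert_that(n_test >= 0, "fractions leave no room for the test split")
  perm <- with_seed(seed, sample(subject_ids))
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}

#' @rdname patient_split
#' @param k number of folds (>= 2).
#' @return For `k_fold()`: a list of `k` disjoint id vectors whose union is
#'   the input set.
#' @export
k_fold <- function(subject_ids, k, seed = 0L) {
  assert_that(k >= 2, "k must be >= 2")
  assert_that(length(subject_ids) >= k, "fewer subjects than folds")
  perm <- with_seed(seed, sample(subject_ids))
  split(perm, rep_len(seq_len(k), length(perm)))
}
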