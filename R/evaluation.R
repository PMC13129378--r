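#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty
#' and 0 when exactly one is.
#'
#' @param a,b [binary_mask()]s (or logical arrays) on the same grid.
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(a, b) {
  da <- if (inherits(a, "mr4dct_mask")) a$data else as.array(a)
  db <- if (inherits(b, "mr4dct_mask")) b$data else as.array(b)
  if (inherits(a, "mr4dct_mask") && inherits(b, "mr4dct_mask")) {
    assert_that(same_grid(a$grid, b$grid), "dice requires matching grids")
  }
  assert_that(all(dim(da) == dim(db)), "dice requires matching dimensions")
  na <- sum(da)
  nb <- sum(db)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  2 * sum(da & db) / (na + nb)
}

# boundary voxels: mask minus its 6-connected erosion
surface_voxels <- function(m) {
  er <- m
  for (ax in 1:3) {
    er <- er & shift3(m + 0, 1, ax) > 0 & shift3(m + 0, -1, ax) > 0
  }
  m & !er
}

#' 95th percentile Hausdorff distance (mm)
#'
#' Pooled symmetric convention: surface voxels of each mask (mask minus its
#' erosion) are extracted, surface-to-surface distances are computed in
#' both directions with an exact anisotropic Euclidean distance transform,
#' and the 95th percentile is taken over the pooled set of both directed
#' distance samples.
#'
#' @param a,b non-empty [binary_mask()]s on the same grid.
#' @param percentile percentile of the pooled distances (default 95).
#' @return Distance in mm; `NA` if either mask is empty.
#' @export
hausdorff95 <- function(a, b, percentile = 95) {
  stopifnot(inherits(a, "mr4dct_mask"), inherits(b, "mr4dct_mask"))
  assert_that(same_grid(a$grid, b$grid), "grids must match")
  if (!any(a$data) || !any(b$data)) return(NA_real_)
  sa <- surface_voxels(a$data)
  sb <- surface_voxels(b$data)
  sp <- a$grid$spacing
  dta <- sqrt(cpp_edt_sq(sa + 0.0, sp)) # distance to surface of a
  dtb <- sqrt(cpp_edt_sq(sb + 0.0, sp))
  pooled <- c(dtb[sa], dta[sb])
  as.numeric(quantile(pooled, percentile / 100, names = FALSE))
}

#' Evaluate a propagation result against reference labels
#'
#' Computes, per phase and organ: Dice, H95 (mm), and — once per phase —
#' mutual information between the fixed CT and the warped MR (whole image
#' and restricted to the overlap region), folding percentage and
#' log-Jacobian standard deviation of the end-to-end field (globally and
#' within the union of reference organ masks). Organs only partially inside
#' the overlap region are compared within it. Aggregate rows (`"seen"`,
#' `"unseen"`, `"all"`) carry unweighted means of the per-organ Dice/H95.
#'
#' @param result a `mr4dct_result` from [propagate].
#' @param truth named list phase -> reference [label_map()].
#' @param omega optional [binary_mask()] overlap region (defaults to the
#'   result's).
#' @param fixed optional named list phase -> fixed CT [volume()] with
#'   intensities in `[0, 1]` for the MI records.
#' @param subject subject id recorded in the output.
#' @return A tibble of metric records (one row per phase x organ plus
#'   aggregates).
#' @export
evaluate_result <- function(result, truth, omega = NULL, fixed = NULL,
                            subject = "subject") {
  stopifnot(inherits(result, "mr4dct_result"))
  omega <- omega %||% result$omega
  rows <- list()
  for (k in names(result$fields)) {
    if (!k %in% names(truth)) {
      warn(sprintf("no reference labels for phase %s; skipped", k))
      next
    }
    ref <- truth[[k]]
    pred <- result$warped_labels[[k]]
    regy <- ref$registry
    g <- ref$grid
    om <- omega$data

    mi_whole <- mi_overlap <- NA_real_
    if (!is.null(fixed) && k %in% names(fixed)) {
      wm <- result$warped_mr[[k]]
      mi_whole <- -neg_mutual_information(fixed[[k]], wm)
      mi_overlap <- -neg_mutual_information(fixed[[k]], wm,
                                            mask = binary_mask(om, g))
    }
    organ_mask_union <- array(ref$data > 0, dim(ref$data))
    jr <- jacobian_report(result$fields[[k]],
                          binary_mask(organ_mask_union, g))

    per_organ <- lapply(seq_len(nrow(regy)), function(i) {
      id <- regy$organ_id[i]
      in_fov <- regy$full_fov[i]
      ra <- ref$data == id
      pa <- pred$data == id
      if (!in_fov) { # partially covered: compare inside the overlap only
        ra <- ra & om
        pa <- pa & om
      }
      if (!any(ra)) {
        return(NULL)
      }
      h <- hausdorff95(binary_mask(ra, g), binary_mask(pa, g))
      tibble::tibble(
        subject = subject, phase = k, method = result$method,
        organ = regy$name[i], supervised = regy$supervised[i],
        dsc = dice(ra, pa), h95_mm = h,
        mi_whole = mi_whole, mi_overlap = mi_overlap,
        foldings_pct = 100 * jr$foldings_fraction,
        stdlj = jr$std_log_jacobian,
        foldings_mask_pct = 100 * jr$foldings_fraction_mask,
        stdlj_mask = jr$std_log_jacobian_mask)
    })
    per_organ <- dplyr::bind_rows(per_organ)
    rows[[k]] <- per_organ
    agg <- function(sel, tag) {
      sub <- per_organ[sel, , drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      out <- sub[1, ]
      out$organ <- tag
      out$supervised <- NA
      out$dsc <- mean(sub$dsc)
      out$h95_mm <- mean(sub$h95_mm, na.rm = TRUE)
      out
    }
    rows[[paste0(k, "_agg")]] <- dplyr::bind_rows(
      agg(per_organ$supervised, "seen"),
      agg(!per_organ$supervised, "unseen"),
      agg(rep(TRUE, nrow(per_organ)), "all"))
  }
  dplyr::bind_rows(rows)
}

star_band <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns")
}

#' Paired method comparison with Wilcoxon signed-rank tests and BH-FDR
#'
#' The endpoint is reduced to a patient-level median (across phases and
#' organs) per subject and method; each requested method pair is compared
#' with a paired two-sided Wilcoxon signed-rank test (exact distribution
#' for n <= 25 without ties, zero differences dropped), and p-values are
#' adjusted across all pairs by the Benjamini-Hochberg step-up at the
#' given q. Stars follow the conventional bands (ns, *, **, ***, ****).
#'
#' @param records metric tibble from [evaluate_result()] (rows of several
#'   methods bound together); aggregate rows are excluded automatically.
#' @param endpoint column name to compare (e.g. `"dsc"`).
#' @param method_pairs list of length-2 character vectors; default all
#'   pairs present.
#' @param q FDR level (recorded in the output).
#' @return A tibble of class `mr4dct_comparison`: one row per pair with
#'   `p_value`, `p_adjusted`, `stars`, `n_subjects`, `median_a`,
#'   `median_b`.
#' @export
compare_methods <- function(records, endpoint = "dsc", method_pairs = NULL,
                            q = 0.05) {
  stopifnot(endpoint %in% names(records))
  methods <- unique(records$method)
  assert_that(length(methods) >= 2 || !is.null(method_pairs),
              "need at least two methods to compare")
  per_subject <- records |>
    dplyr::filter(!.data$organ %in% c("seen", "unseen", "all")) |>
    dplyr::group_by(.data$subject, .data$method) |>
    dplyr::summarise(value = median(.data[[endpoint]], na.rm = TRUE),
                     .groups = "drop")
  if (is.null(method_pairs)) {
    method_pairs <- utils::combn(methods, 2, simplify = FALSE)
  }
  rows <- lapply(method_pairs, function(mp) {
    wide <- per_subject |>
      dplyr::filter(.data$method %in% mp) |>
      tidyr::pivot_wider(names_from = "method", values_from = "value") |>
      tidyr::drop_na()
    a <- wide[[mp[1]]]
    b <- wide[[mp[2]]]
    p <- paired_wilcoxon_p(a, b)
    tibble::tibble(method_a = mp[1], method_b = mp[2],
                   endpoint = endpoint, n_subjects = length(a),
                   median_a = median(a), median_b = median(b),
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted <= q
  out$stars <- star_band(out$p_adjusted)
  class(out) <- c("mr4dct_comparison", class(out))
  attr(out, "q") <- q
  out
}

# paired two-sided signed-rank p: zero differences dropped, exact
# distribution when n <= 25 and no rank ties
paired_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = !exact)$p.value)
}

#' Binned improvement over the rigid baseline
#'
#' Groups per-organ records into bins of the Dice achieved by rigid
#' alignment alone and reports, per bin and method, the mean post-DIR Dice
#' and mean overlap-region MI — showing how much each deformable method
#' adds as a function of the initial alignment quality.
#'
#' @param records metric tibble with deformable methods' rows.
#' @param rigid_records metric tibble of the rigid baseline on the same
#'   subjects/phases/organs.
#' @param bin_width rigid-Dice bin width (default 0.1).
#' @return A tibble of class `mr4dct_binned`: bin, method, n, mean Dice,
#'   mean MI; empty bins are omitted.
#' @export
binned_improvement <- function(records, rigid_records, bin_width = 0.1) {
  keys <- c("subject", "phase", "organ")
  base <- rigid_records |>
    dplyr::filter(!.data$organ %in% c("seen", "unseen", "all")) |>
    dplyr::select(dplyr::all_of(keys), rigid_dsc = "dsc")
  joined <- records |>
    dplyr::filter(!.data$organ %in% c("seen", "unseen", "all")) |>
    dplyr::inner_join(base, by = keys) |>
    dplyr::mutate(bin = floor(.data$rigid_dsc / bin_width) * bin_width)
  out <- joined |>
    dplyr::group_by(.data$bin, .data$method) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_dsc = mean(.data$dsc),
                     mean_rigid_dsc = mean(.data$rigid_dsc),
                     mean_mi_overlap = mean(.data$mi_overlap, na.rm = TRUE),
                     .groups = "drop")
  class(out) <- c("mr4dct_binned", class(out))
  out
}
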