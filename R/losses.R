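#' Loss weights for the registration objectives
#'
#' `lambda` weights the field regularizer (Jacobian-determinant penalty for
#' the temporal objective, first-order gradient penalty for the multi-modal
#' objective); `gamma` weights the auxiliary weak Dice term. Defaults per
#' model kind: temporal 0.3 / 0.7, multi-modal and direct 0.5 / 0.5.
#'
#' @param lambda non-negative regularization weight.
#' @param gamma non-negative auxiliary Dice weight.
#' @return A list of class `mr4dct_weights`.
#' @export
loss_weights <- function(lambda, gamma) {
  assert_that(is.finite(lambda) && lambda >= 0, "lambda must be >= 0")
  assert_that(is.finite(gamma) && gamma >= 0, "gamma must be >= 0")
  structure(list(lambda = lambda, gamma = gamma), class = "mr4dct_weights")
}

default_weights <- function(model_kind) {
  switch(model_kind,
         temporal = loss_weights(0.3, 0.7),
         multimodal = loss_weights(0.5, 0.5),
         direct = loss_weights(0.5, 0.5),
         abort(sprintf("unknown model kind '%s'", model_kind)))
}

as_image_array <- function(x) {
  if (inherits(x, "mr4dct_volume")) x$data else as.array(x)
}

as_mask_array <- function(mask, dims) {
  if (is.null(mask)) return(NULL)
  m <- if (inherits(mask, "mr4dct_mask")) mask$data else as.array(mask)
  assert_that(all(dim(m) == dims), "mask dimensions mismatch")
  m
}

#' Local normalized cross-correlation loss
#'
#' Mono-modal similarity: within a cubic window around every voxel, the
#' squared normalized cross-correlation between the two images is computed
#' (squared, so the loss is insensitive to contrast sign), and the loss is
#' `1 - mean(NCC^2)` over (masked) voxels — 0 at perfect local affine
#' agreement, at most 1. Denominators are stabilized with `eps` so constant
#' windows never divide by zero.
#'
#' @param fixed,moving_warped [volume()]s or 3D arrays on the same grid.
#' @param window odd cubic window edge (>= 3), default 9.
#' @param mask optional [binary_mask()]; the mean runs over mask voxels.
#' @param eps variance stabilizer.
#' @return Scalar loss in `[0, 1]`.
#' @export
lncc <- function(fixed, moving_warped, window = 9L, mask = NULL,
                 eps = 1e-5) {
  lncc_impl(as_image_array(fixed), as_image_array(moving_warped),
            window, mask, eps, want_grad = FALSE)$value
}

lncc_grad <- function(farr, marr, window = 9L, mask = NULL, eps = 1e-5) {
  lncc_impl(farr, marr, window, mask, eps, want_grad = TRUE)
}

lncc_impl <- function(f, m, window, mask, eps, want_grad) {
  assert_that(window >= 3 && window %% 2 == 1,
              "window must be an odd integer >= 3")
  assert_that(all(dim(f) == dim(m)), "image dimensions mismatch")
  mk <- as_mask_array(mask, dim(f))
  r <- (window - 1L) %/% 2L
  ones <- array(1, dim(f))
  n <- cpp_boxsum(ones, r)
  Sf <- cpp_boxsum(f, r)
  Sm <- cpp_boxsum(m, r)
  Sff <- cpp_boxsum(f * f, r)
  Smm <- cpp_boxsum(m * m, r)
  Sfm <- cpp_boxsum(f * m, r)
  cross <- Sfm - Sf * Sm / n
  varf <- pmax(Sff - Sf^2 / n, 0)
  varm <- pmax(Smm - Sm^2 / n, 0)
  denom <- varf * varm + eps
  cc <- cross^2 / denom
  nvox <- if (is.null(mk)) length(cc) else sum(mk)
  assert_that(nvox > 0, "empty mask in lncc")
  value <- 1 - (if (is.null(mk)) mean(cc) else sum(cc[mk]) / nvox)
  if (!want_grad) return(list(value = value))
  # d(cc_w)/d m_j = A_w (f_j - Sf_w/n_w) + B_w (m_j - Sm_w/n_w) for j in w
  A <- 2 * cross / denom
  B <- -2 * cc * varf / denom
  if (!is.null(mk)) {
    A[!mk] <- 0
    B[!mk] <- 0
  }
  gm <- f * cpp_boxsum(A, r) - cpp_boxsum(A * Sf / n, r) +
    m * cpp_boxsum(B, r) - cpp_boxsum(B * Sm / n, r)
  gm <- -gm / nvox
  list(value = value, gmoving = gm)
}

#' Negative mutual information loss
#'
#' Multi-modal similarity from a differentiable joint histogram: intensities
#' in `[0, 1]` are softly assigned to `bins` Gaussian Parzen windows centered
#' on the bin centers (kernel width = bin width, weights normalized per
#' voxel), the joint density is accumulated over (masked) voxels, and the
#' mutual information in nats is returned negated so that lower is better.
#'
#' @param fixed,moving_warped [volume()]s or 3D arrays with values in `[0, 1]`.
#' @param bins number of Parzen bins, default 32.
#' @param mask optional [binary_mask()]; histogram restricted to its voxels.
#' @return `-MI` in nats (<= 0 whenever the images share information).
#' @export
neg_mutual_information <- function(fixed, moving_warped, bins = 32L,
                                   mask = NULL) {
  nmi_impl(as_image_array(fixed), as_image_array(moving_warped), bins, mask,
           want_grad = FALSE)$value
}

nmi_grad <- function(farr, marr, bins = 32L, mask = NULL) {
  nmi_impl(farr, marr, bins, mask, want_grad = TRUE)
}

parzen_weights <- function(v, bins, want_deriv = FALSE) {
  centers <- (seq_len(bins) - 0.5) / bins
  sigma <- 1 / bins
  d <- outer(v, centers, "-") # N x B
  g <- exp(-0.5 * (d / sigma)^2)
  G <- rowSums(g)
  W <- g / G
  if (!want_deriv) return(list(W = W))
  gp <- g * (-d / sigma^2) # d g_j / d v
  Gp <- rowSums(gp)
  dW <- (gp - W * Gp) / G
  list(W = W, dW = dW)
}

nmi_impl <- function(f, m, bins, mask, want_grad) {
  assert_that(all(dim(f) == dim(m)), "image dimensions mismatch")
  mk <- as_mask_array(mask, dim(f))
  idx <- if (is.null(mk)) seq_along(f) else which(mk)
  assert_that(length(idx) > 0, "empty mask in mutual information")
  fv <- as.vector(f)[idx]
  mv <- as.vector(m)[idx]
  N <- length(idx)
  pwf <- parzen_weights(fv, bins)
  pwm <- parzen_weights(mv, bins, want_deriv = want_grad)
  P <- crossprod(pwf$W, pwm$W) / N # B x B joint
  pf <- rowSums(P)
  pm <- colSums(P)
  eps <- 1e-12
  L <- log(pmax(P, eps)) - log(pmax(outer(pf, pm), eps))
  mi <- sum(P * L)
  if (!want_grad) return(list(value = -mi, mi = mi))
  # d(-MI)/d m_x = -(1/N) sum_ij L_ij Wf[x,i] dWm[x,j]
  gv <- -rowSums((pwf$W %*% L) * pwm$dW) / N
  gm <- array(0, dim(m))
  gm[idx] <- gv
  list(value = -mi, mi = mi, gmoving = gm)
}

#' Soft Dice loss over organ probability channels
#'
#' `1 - mean_k (2 * sum(p_k q_k) + eps) / (sum p_k + sum q_k + eps)` over
#' the supplied organ channels; an organ empty on both sides contributes
#' zero loss through the `eps` convention.
#'
#' @param fixed_probs,moving_probs 4D arrays `(X, Y, Z, K)` of per-organ
#'   probabilities in `[0, 1]` on the same grid.
#' @param organs integer vector of channel indices to include (default all).
#' @param eps stabilizer.
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(fixed_probs, moving_probs, organs = NULL,
                           eps = 1e-5) {
  soft_dice_impl(fixed_probs, moving_probs, organs, eps,
                 want_grad = FALSE)$value
}

soft_dice_grad <- function(fixed_probs, moving_probs, organs = NULL,
                           eps = 1e-5) {
  soft_dice_impl(fixed_probs, moving_probs, organs, eps, want_grad = TRUE)
}

soft_dice_impl <- function(p, q, organs, eps, want_grad) {
  p <- as.array(p)
  q <- as.array(q)
  assert_that(all(dim(p) == dim(q)), "probability array dimensions mismatch")
  K <- dim(p)[4]
  organs <- organs %||% seq_len(K)
  assert_that(length(organs) > 0, "organ subset must be non-empty")
  dices <- numeric(length(organs))
  gq <- if (want_grad) array(0, dim(q)) else NULL
  for (t in seq_along(organs)) {
    k <- organs[t]
    pk <- p[, , , k, drop = TRUE]
    qk <- q[, , , k, drop = TRUE]
    inter <- sum(pk * qk)
    tot <- sum(pk) + sum(qk)
    dices[t] <- (2 * inter + eps) / (tot + eps)
    if (want_grad) {
      gq[, , , k] <- -(2 * pk * (tot + eps) - (2 * inter + eps)) /
        (tot + eps)^2 / length(organs)
    }
  }
  list(value = 1 - mean(dices), dice = dices, gmoving = gq)
}

#' Jacobian-determinant penalty
#'
#' Mean over voxels of `(det(grad phi) - 1)^2` for `phi(x) = x + u(x)`,
#' using the same central-difference Jacobian as [jacobian_report()]. Zero
#' for any volume-preserving field (translations included); penalizes local
#' expansion/compression and foldings without penalizing large but
#' plausible displacements.
#'
#' @param phi a [displacement_field()].
#' @return Non-negative scalar.
#' @export
detjac_penalty <- function(phi) {
  stopifnot(inherits(phi, "mr4dct_field"))
  mean((jacobian_det(phi$u) - 1)^2)
}

detjac_penalty_grad <- function(u) {
  J <- jacobian_components(u)
  det <- J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
  N <- length(det)
  gdet <- 2 * (det - 1) / N
  # cofactor expansion: d det / d J[i][j]
  cof <- list(
    list(J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]],
         -(J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]),
         J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]]),
    list(-(J[[1]][[2]] * J[[3]][[3]] - J[[1]][[3]] * J[[3]][[2]]),
         J[[1]][[1]] * J[[3]][[3]] - J[[1]][[3]] * J[[3]][[1]],
         -(J[[1]][[1]] * J[[3]][[2]] - J[[1]][[2]] * J[[3]][[1]])),
    list(J[[1]][[2]] * J[[2]][[3]] - J[[1]][[3]] * J[[2]][[2]],
         -(J[[1]][[1]] * J[[2]][[3]] - J[[1]][[3]] * J[[2]][[1]]),
         J[[1]][[1]] * J[[2]][[2]] - J[[1]][[2]] * J[[2]][[1]])
  )
  gu <- array(0, dim(u))
  for (i in 1:3) {
    acc <- array(0, dim(u)[1:3])
    for (j in 1:3) {
      acc <- acc + axis_cdiff_adjoint(gdet * cof[[i]][[j]], j)
    }
    gu[, , , i] <- acc
  }
  list(value = mean((det - 1)^2), gu = gu)
}

#' First-order field regularization
#'
#' Mean squared forward-difference spatial derivative, averaged over the
#' nine (component, axis) derivative families. Zero for any constant
#' translation; discourages large or rough warps, matching the small-warp
#' prior of the multi-modal branch.
#'
#' @param phi a [displacement_field()].
#' @return Non-negative scalar.
#' @export
gradient_l2_penalty <- function(phi) {
  stopifnot(inherits(phi, "mr4dct_field"))
  gradient_l2_impl(phi$u, want_grad = FALSE)$value
}

gradient_l2_grad <- function(u) {
  gradient_l2_impl(u, want_grad = TRUE)
}

gradient_l2_impl <- function(u, want_grad) {
  d <- dim(u)[1:3]
  total <- 0
  gu <- if (want_grad) array(0, dim(u)) else NULL
  for (i in 1:3) {
    ui <- u[, , , i, drop = TRUE]
    for (j in 1:3) {
      nd <- prod(d) / d[j] * (d[j] - 1)
      if (nd == 0) next
      fd <- axis_fdiff(ui, j) # last slice along j is zero padding
      total <- total + sum(fd^2) / nd / 9
      if (want_grad) {
        w <- 2 * fd / nd / 9
        # adjoint of forward difference: u[t+1] += w[t]; u[t] -= w[t]
        gu[, , , i] <- gu[, , , i, drop = TRUE] + shift3(w, -1, j) - w
      }
    }
  }
  list(value = total, gu = gu)
}
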