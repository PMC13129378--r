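#' Configuration of the SVF registration network
#'
#' A 3D encoder-decoder (optionally with attention-gated skip connections)
#' mapping a 2-channel (fixed, moving) stack to a stationary velocity field.
#' Channel width doubles per level; the working grid must be divisible by
#' `2^(levels - 1)`. Capacity is configurable down to very small grids so
#' the full train/infer loop runs on CPU in minutes; the full-resolution
#' profile (128x128x64 working grid) is available but not needed for
#' desk-scale studies.
#'
#' @param input_grid a [grid3()]: the working resolution the network sees.
#' @param levels encoder depth (>= 2).
#' @param base_channels channels at the finest level.
#' @param attention_gates use attention gating on skip connections?
#' @param velocity_scale multiplier applied to the raw network output.
#' @param seed integer seed controlling parameter initialization.
#' @return A list of class `mr4dct_netconfig`.
#' @export
network_config <- function(input_grid, levels = 3L, base_channels = 16L,
                           attention_gates = TRUE, velocity_scale = 1,
                           seed = 0L) {
  assert_that(levels >= 2, "levels must be >= 2")
  div <- 2^(levels - 1)
  assert_that(all(input_grid$shape %% div == 0),
              sprintf("input grid dims must be divisible by %d", div))
  structure(list(input_grid = input_grid, levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 attention_gates = isTRUE(attention_gates),
                 velocity_scale = velocity_scale, seed = as.integer(seed)),
            class = "mr4dct_netconfig")
}

he_init <- function(k, cin, cout) {
  sdv <- sqrt(2 / (k^3 * cin))
  array(rnorm(k^3 * cin * cout, sd = sdv), c(k, k, k, cin, cout))
}

#' Build a registration network
#'
#' Parameters are initialized deterministically from the config seed. The
#' final layer starts near zero so an untrained network predicts a
#' near-identity deformation — registration networks must start from the
#' identity or early training destroys the moving image.
#'
#' @param cfg a [network_config()].
#' @return A list of class `mr4dct_network` with `cfg` and `params`.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "mr4dct_netconfig"))
  L <- cfg$levels
  ch <- cfg$base_channels * 2^(seq_len(L) - 1)
  params <- with_seed(cfg$seed, {
    p <- list(enc = list(), dec = list(), att = list())
    for (l in seq_len(L)) {
      cin <- if (l == 1) 2L else ch[l - 1]
      p$enc[[l]] <- list(w = he_init(3, cin, ch[l]), b = numeric(ch[l]))
    }
    for (l in seq_len(L - 1)) {
      p$dec[[l]] <- list(w = he_init(3, ch[l + 1] + ch[l], ch[l]),
                         b = numeric(ch[l]))
      if (cfg$attention_gates) {
        Fc <- max(1L, ch[l] %/% 2L)
        p$att[[l]] <- list(wg = he_init(1, ch[l + 1], Fc), bg = numeric(Fc),
                           wx = he_init(1, ch[l], Fc), bx = numeric(Fc),
                           wp = he_init(1, Fc, 1L), bp = 0)
      }
    }
    p$head <- list(w = array(rnorm(27 * ch[1] * 3, sd = 1e-5),
                             c(3, 3, 3, ch[1], 3)),
                   b = numeric(3))
    p
  })
  structure(list(cfg = cfg, params = params, channels = ch),
            class = "mr4dct_network")
}

#' @export
print.mr4dct_network <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 0))
  cat(sprintf("<svf network: %d levels, base %d, %s attention, %d params>\n",
              x$cfg$levels, x$cfg$base_channels,
              if (x$cfg$attention_gates) "with" else "no", np))
  invisible(x)
}

lrelu <- function(x, slope = 0.1) {
  pos <- x > 0
  x * (pos + slope * (1 - pos))
}

lrelu_grad <- function(pre, g, slope = 0.1) {
  pos <- pre > 0
  g * (pos + slope * (1 - pos))
}

# GEMM-backed 3D convolution (im2col for K = 3, plain channel matmul for
# K = 1); falls back to the direct kernel only through these wrappers so
# forward and backward always agree
conv3d_cols <- function(x, K, Cin) {
  if (K == 1) {
    col <- x
    dim(col) <- c(length(x) %/% Cin, Cin)
    col
  } else {
    cpp_im2col(x, K)
  }
}

conv3d_fwd <- function(x, w, b, col = NULL) {
  dw <- dim(w)
  K <- dw[1]
  d3 <- dim(x)[1:3]
  wm <- w
  dim(wm) <- c(K^3 * dw[4], dw[5])
  col <- col %||% conv3d_cols(x, K, dw[4])
  out <- col %*% wm
  out <- sweep(out, 2, b, "+")
  dim(out) <- c(d3, dw[5])
  out
}

conv3d_bwd <- function(x, w, gout, col = NULL) {
  dw <- dim(w)
  K <- dw[1]
  N <- prod(dim(x)[1:3])
  wm <- w
  dim(wm) <- c(K^3 * dw[4], dw[5])
  gm <- gout
  dim(gm) <- c(N, dw[5])
  col <- col %||% conv3d_cols(x, K, dw[4])
  gw <- crossprod(col, gm)
  dim(gw) <- dim(w)
  gcol <- gm %*% t(wm)
  gx <- if (K == 1) {
    dim(gcol) <- dim(x)
    gcol
  } else {
    cpp_col2im(gcol, dim(x), K)
  }
  list(gx = gx, gw = gw, gb = colSums(gm))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

cat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# forward pass; returns velocity (X,Y,Z,3) and a cache for backprop
net_forward <- function(net, x, keep_cache = FALSE) {
  p <- net$params
  L <- net$cfg$levels
  cache <- list(x = x, enc_pre = list(), enc = list(), pooled = list(),
                dec_pre = list(), dec = list(), up = list(), att = list(),
                cat = list(), enc_col = list(), dec_col = list())
  h <- x
  for (l in seq_len(L)) {
    col <- conv3d_cols(h, 3L, dim(h)[4])
    pre <- conv3d_fwd(h, p$enc[[l]]$w, p$enc[[l]]$b, col = col)
    act <- lrelu(pre)
    if (keep_cache) cache$enc_col[[l]] <- col
    cache$enc_pre[[l]] <- pre
    cache$enc[[l]] <- act
    if (l < L) {
      h <- cpp_avgpool2(act)
      cache$pooled[[l]] <- h
    }
  }
  h <- cache$enc[[L]]
  for (l in rev(seq_len(L - 1))) {
    up <- cpp_upsample2_nearest(h)
    cache$up[[l]] <- up
    skip <- cache$enc[[l]]
    if (net$cfg$attention_gates) {
      a <- p$att[[l]]
      g1 <- conv3d_fwd(up, a$wg, a$bg)
      x1 <- conv3d_fwd(skip, a$wx, a$bx)
      rpre <- g1 + x1
      r <- pmax(rpre, 0)
      psi <- conv3d_fwd(r, a$wp, a$bp)
      alpha <- sigmoid(psi)
      skip_g <- skip * as.vector(alpha) # broadcast 1-channel gate
      cache$att[[l]] <- list(rpre = rpre, r = r, alpha = alpha, skip = skip)
      skip <- skip_g
    }
    ct <- cat_channels(up, skip)
    cache$cat[[l]] <- ct
    col <- conv3d_cols(ct, 3L, dim(ct)[4])
    pre <- conv3d_fwd(ct, p$dec[[l]]$w, p$dec[[l]]$b, col = col)
    h <- lrelu(pre)
    if (keep_cache) cache$dec_col[[l]] <- col
    cache$dec_pre[[l]] <- pre
    cache$dec[[l]] <- h
  }
  head_col <- conv3d_cols(h, 3L, dim(h)[4])
  v <- conv3d_fwd(h, p$head$w, p$head$b, col = head_col) *
    net$cfg$velocity_scale
  cache$final_in <- h
  if (keep_cache) cache$head_col <- head_col
  list(v = v, cache = if (keep_cache) cache else NULL)
}

# backward pass: gradient of loss wrt all parameters given gv = dL/dv
net_backward <- function(net, cache, gv) {
  p <- net$params
  L <- net$cfg$levels
  gr <- list(enc = vector("list", L), dec = vector("list", L - 1),
             att = vector("list", L - 1), head = NULL)
  gv <- gv * net$cfg$velocity_scale
  bw <- conv3d_bwd(cache$final_in, p$head$w, gv, col = cache$head_col)
  gr$head <- list(w = bw$gw, b = bw$gb)
  gh <- bw$gx
  for (l in seq_len(L - 1)) {
    gpre <- lrelu_grad(cache$dec_pre[[l]], gh)
    bw <- conv3d_bwd(cache$cat[[l]], p$dec[[l]]$w, gpre,
                     col = cache$dec_col[[l]])
    gr$dec[[l]] <- list(w = bw$gw, b = bw$gb)
    cu <- dim(cache$up[[l]])[4]
    gup <- bw$gx[, , , seq_len(cu), drop = FALSE]
    gskip <- bw$gx[, , , cu + seq_len(dim(bw$gx)[4] - cu), drop = FALSE]
    if (net$cfg$attention_gates) {
      a <- p$att[[l]]
      at <- cache$att[[l]]
      galpha_full <- gskip * at$skip
      galpha <- array(rowSums(galpha_full, dims = 3), dim(at$alpha))
      gskip <- gskip * as.vector(at$alpha)
      gpsi <- galpha * at$alpha * (1 - at$alpha)
      bwp <- conv3d_bwd(at$r, a$wp, gpsi)
      grr <- bwp$gx * (at$rpre > 0)
      bwg <- conv3d_bwd(cache$up[[l]], a$wg, grr)
      bwx <- conv3d_bwd(at$skip, a$wx, grr)
      gr$att[[l]] <- list(wg = bwg$gw, bg = bwg$gb, wx = bwx$gw,
                          bx = bwx$gb, wp = bwp$gw, bp = bwp$gb)
      gup <- gup + bwg$gx
      gskip <- gskip + bwx$gx
    }
    # gradient into the encoder activation at level l (skip path)
    cache$enc_grad_extra <- cache$enc_grad_extra %||% vector("list", L)
    cache$enc_grad_extra[[l]] <- gskip
    # gradient up the decoder chain
    gh <- cpp_upsample2_nearest_bwd(gup)
    cache$dec_up_grad <- cache$dec_up_grad %||% vector("list", L)
    cache$dec_up_grad[[l]] <- gh
    if (l < L - 1) {
      gh <- gh # continues as gradient wrt dec[[l+1]] activation
    }
  }
  # walk encoder backwards, combining decoder-chain and skip gradients
  genc <- vector("list", L)
  # gradient wrt enc[[L]] activation comes from the deepest upsample
  genc[[L]] <- if (L >= 2) cache$dec_up_grad[[L - 1]] else gv
  for (l in rev(seq_len(L))) {
    g_act <- genc[[l]]
    if (l <= L - 1) {
      extra <- cache$enc_grad_extra[[l]]
      if (!is.null(extra)) g_act <- g_act + extra
    }
    gpre <- lrelu_grad(cache$enc_pre[[l]], g_act)
    xin <- if (l == 1) cache$x else cache$pooled[[l - 1]]
    bw <- conv3d_bwd(xin, p$enc[[l]]$w, gpre, col = cache$enc_col[[l]])
    gr$enc[[l]] <- list(w = bw$gw, b = bw$gb)
    if (l > 1) {
      genc[[l - 1]] <- cpp_avgpool2_bwd(bw$gx, dim(cache$enc[[l - 1]]))
    }
  }
  gr
}

#' Predict a stationary velocity field for an image pair
#'
#' Stacks the fixed and moving volumes channel-wise and runs the network.
#' Both volumes must live on the network's working grid with intensities in
#' `[0, 1]`. Inference is deterministic for fixed parameters.
#'
#' @param net a [build_network()] result.
#' @param fixed,moving [volume()]s on `cfg$input_grid`.
#' @return A [velocity_field()] on the working grid.
#' @export
predict_svf <- function(net, fixed, moving) {
  stopifnot(inherits(net, "mr4dct_network"))
  g <- net$cfg$input_grid
  assert_that(same_grid(fixed$grid, g) && same_grid(moving$grid, g),
              "inputs must be resampled to the network working grid")
  x <- cat_channels(array(fixed$data, c(dim(fixed$data), 1L)),
                    array(moving$data, c(dim(moving$data), 1L)))
  v <- net_forward(net, x)$v
  velocity_field(v, g)
}

# --- decoder chain bookkeeping fix ------------------------------------------
# net_backward above walks decoder levels from fine (l = 1) to coarse; the
# gradient entering level l's upsample is the gradient wrt the activation of
# the level-(l+1) decoder output (or the bottom encoder). The loop is run in
# that order on purpose: gh after processing level l IS the gradient wrt
# dec[[l+1]] (or enc[[L]]) activation used in the next iteration.

# --- parameter flattening / Adam -------------------------------------------

params_map <- function(params, f) {
  rapply(params, f, classes = "ANY", how = "replace")
}

params_zip <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- params_zip(a[[nm]], b[[nm]], f)
    }
    out
  } else {
    f(a, b)
  }
}

adam_init <- function(params) {
  list(m = params_map(params, function(x) x * 0),
       v = params_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- params_zip(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_zip(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- params_map(state$m, function(m) m / bc1)
  vhat <- params_map(state$v, function(v) v / bc2)
  upd <- params_zip(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  params <- params_zip(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

#' Save / load network checkpoints
#'
#' Parameters go to an RDS file; the configuration is serialized alongside
#' as JSON (`<path>.json`) so a checkpoint is self-describing.
#'
#' @param net a network.
#' @param path checkpoint path.
#' @return `path` (save) or the reloaded network (load).
#' @export
save_network <- function(net, path) {
  saveRDS(net$params, path)
  cfg <- net$cfg
  jsonlite::write_json(
    list(shape = cfg$input_grid$shape, spacing = cfg$input_grid$spacing,
         origin = cfg$input_grid$origin, levels = cfg$levels,
         base_channels = cfg$base_channels,
         attention_gates = cfg$attention_gates,
         velocity_scale = cfg$velocity_scale, seed = cfg$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- network_config(
    grid3(meta$shape, meta$spacing, meta$origin), levels = meta$levels,
    base_channels = meta$base_channels,
    attention_gates = meta$attention_gates,
    velocity_scale = meta$velocity_scale, seed = meta$seed)
  net <- build_network(cfg)
  net$params <- readRDS(path)
  net
}
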