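#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif quantile median sd setNames
NULL

# run code under a local RNG state so package functions never disturb the
# caller's .Random.seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derive a child seed (stable, below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_number3 <- function(x) is.numeric(x) && length(x) == 3 && all(is.finite(x))

# index-based shift of a 3D array along one axis, zero-filled
shift3 <- function(a, by, axis) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- seq_len(d[axis]) + by
  keep <- src >= 1 & src <= d[axis]
  out <- array(0, d)
  dst <- idx
  dst[[axis]] <- which(keep)
  from <- idx
  from[[axis]] <- src[keep]
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[from[[1]], from[[2]], from[[3]]]
  out
}

# central difference with one-sided stencils at the two faces
axis_cdiff <- function(a, axis) {
  d <- dim(a)
  L <- d[axis]
  if (L == 1) return(array(0, d))
  out <- (shift3(a, 1, axis) - shift3(a, -1, axis)) / 2
  idx <- lapply(d, seq_len)
  lo <- idx; lo[[axis]] <- 1L
  lo2 <- idx; lo2[[axis]] <- 2L
  hi <- idx; hi[[axis]] <- L
  hi2 <- idx; hi2[[axis]] <- L - 1L
  out[lo[[1]], lo[[2]], lo[[3]]] <-
    a[lo2[[1]], lo2[[2]], lo2[[3]]] - a[lo[[1]], lo[[2]], lo[[3]]]
  out[hi[[1]], hi[[2]], hi[[3]]] <-
    a[hi[[1]], hi[[2]], hi[[3]]] - a[hi2[[1]], hi2[[2]], hi2[[3]]]
  out
}

# adjoint of axis_cdiff (verified by inner-product identity in the tests)
axis_cdiff_adjoint <- function(g, axis) {
  d <- dim(g)
  L <- d[axis]
  out <- array(0, d)
  if (L == 1) return(out)
  idx <- lapply(d, seq_len)
  sel <- function(i) {
    ix <- idx
    ix[[axis]] <- i
    ix
  }
  if (L > 2) {
    interior <- 2:(L - 1)
    gi <- g
    # u[t+1] += g[t]/2 ; u[t-1] -= g[t]/2 for interior t
    up <- sel(interior + 1L)
    it <- sel(interior)
    dn <- sel(interior - 1L)
    out[up[[1]], up[[2]], up[[3]]] <- out[up[[1]], up[[2]], up[[3]]] +
      gi[it[[1]], it[[2]], it[[3]]] / 2
    out[dn[[1]], dn[[2]], dn[[3]]] <- out[dn[[1]], dn[[2]], dn[[3]]] -
      gi[it[[1]], it[[2]], it[[3]]] / 2
  }
  l1 <- sel(1L); l2 <- sel(2L); hL <- sel(L); hL1 <- sel(L - 1L)
  out[l2[[1]], l2[[2]], l2[[3]]] <- out[l2[[1]], l2[[2]], l2[[3]]] +
    g[l1[[1]], l1[[2]], l1[[3]]]
  out[l1[[1]], l1[[2]], l1[[3]]] <- out[l1[[1]], l1[[2]], l1[[3]]] -
    g[l1[[1]], l1[[2]], l1[[3]]]
  out[hL[[1]], hL[[2]], hL[[3]]] <- out[hL[[1]], hL[[2]], hL[[3]]] +
    g[hL[[1]], hL[[2]], hL[[3]]]
  out[hL1[[1]], hL1[[2]], hL1[[3]]] <- out[hL1[[1]], hL1[[2]], hL1[[3]]] -
    g[hL[[1]], hL[[2]], hL[[3]]]
  out
}

# forward difference along an axis: d[t] = u[t+1] - u[t], length L-1 slab
# returned padded with a zero slice at the end (callers mask it out)
axis_fdiff <- function(a, axis) {
  d <- dim(a)
  L <- d[axis]
  out <- shift3(a, 1, axis) - a
  idx <- lapply(d, seq_len)
  last <- idx
  last[[axis]] <- L
  out[last[[1]], last[[2]], last[[3]]] <- 0
  out
}

# smoothstep on [e0, e1]
smoothstep <- function(x, e0, e1) {
  t <- pmin(pmax((x - e0) / (e1 - e0), 0), 1)
  t * t * (3 - 2 * t)
}
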