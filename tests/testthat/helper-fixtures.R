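# shared fixtures; expensive objects are built once per test run

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, builder(), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# a smooth random SVF on a cubic grid: Gaussian-smoothed white noise per
# component, rescaled so max |u| = amp voxels
smooth_svf <- function(n = 24, amp = 3, sigma = 4, seed = 0) {
  set.seed(seed)
  g <- grid3(rep(n, 3))
  u <- array(0, c(rep(n, 3), 3))
  for (c in 1:3) {
    w <- mr4dctreg:::cpp_gauss_smooth(array(rnorm(n^3), rep(n, 3)), sigma)
    u[, , , c] <- w
  }
  u <- u / max(abs(u)) * amp
  velocity_field(u, g)
}

# dense Euler integration of a stationary velocity field (the independent
# oracle for scaling-and-squaring): x' = v(x), displacement accumulated in
# `steps` explicit steps with border-clamped sampling of v
euler_integrate <- function(v, steps = 256) {
  u <- v$u
  h <- 1 / steps
  phi <- array(0, dim(u))
  for (s in seq_len(steps)) {
    vs <- mr4dctreg:::cpp_warp_linear(u, phi, 1L)
    phi <- phi + h * vs
  }
  displacement_field(phi, v$grid, "ground-truth")
}

# interior mask (strip `b` boundary voxels) as a logical array
interior_mask <- function(shape, b = 3) {
  m <- array(FALSE, shape)
  m[(b + 1):(shape[1] - b), (b + 1):(shape[2] - b),
    (b + 1):(shape[3] - b)] <- TRUE
  m
}

# a small default-condition phantom study, shared across test files
phantom_fixture <- function() {
  memo("study_seed1", function() make_study(phantom_config(seed = 1)))
}

# a smooth synthetic image with texture (for warp/loss tests)
smooth_image <- function(n = 24, seed = 1) {
  set.seed(seed)
  base <- mr4dctreg:::cpp_gauss_smooth(array(rnorm(n^3), rep(n, 3)), 3)
  (base - min(base)) / (max(base) - min(base))
}

label_cube <- function(n = 16, lo = 5, hi = 12, id = 1L) {
  arr <- array(0L, rep(n, 3))
  arr[lo:hi, lo:hi, lo:hi] <- id
  label_map(arr, grid3(rep(n, 3)),
            organ_registry(id, "cube", supervised = TRUE))
}

per_organ_dice <- function(pred, ref) {
  ids <- ref$registry$organ_id
  vapply(ids, function(id) {
    a <- pred$data == id
    b <- ref$data == id
    if (!any(b) && !any(a)) return(NA_real_)
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
}
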