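## Shared fixtures built in code at test time.

## Quiet imaging: no noise, for exactness checks.
quiet_imaging <- function(...) imaging_params(noise_sd = 0, ...)

## Bisection oracle for the 1:1 equilibrium: solves
## Kd * x = (R - x)(L - x) on [0, min(R, L)].
bisect_complex <- function(R, L, Kd, tol = 1e-15) {
  f <- function(x) (R - x) * (L - x) - Kd * x
  lo <- 0; hi <- min(R, L)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(hi, 1e-300)) break
  }
  (lo + hi) / 2
}

## Brute-force integer-shift spatial cross-correlation (no FFT), the oracle
## for the registration module on small frames.
brute_shift <- function(a, b, max_shift = 6) {
  best <- c(dx = 0, dy = 0); best_v <- -Inf
  am <- a - mean(a); bm <- b - mean(b)
  ny <- nrow(a); nx <- ncol(a)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    v <- sum(bm[ys, xs] * am[ys - dy, xs - dx])
    if (v > best_v) { best_v <- v; best <- c(dx = dx, dy = dy) }
  }
  best
}

## Small static movie of filaments with per-frame noise.
make_static_movie <- function(n_frames = 6, shape = c(96, 96), noise_sd = 5,
                              rng_seed = 11) {
  im0 <- imaging_params(noise_sd = 0)
  layout <- fov_layout(5, shape = shape, imaging = im0, antibody_density = 900,
                       margin = 20, ext_len_range = c(1, 2), rng_seed = rng_seed)
  base <- render_fov_image(layout, im0, rng_seed = rng_seed)$channels$antibody
  mov <- array(0, c(shape, n_frames))
  set.seed(rng_seed + 1)
  for (f in seq_len(n_frames))
    mov[, , f] <- base + stats::rnorm(length(base), 0, noise_sd)
  mov
}
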