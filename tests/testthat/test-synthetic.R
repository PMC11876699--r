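test_that("simulator is deterministic and validates its inputs", {
  p <- dynamics_params()
  e1 <- simulate_dynamics(p, 5, 600, rng_seed = 3)
  e2 <- simulate_dynamics(p, 5, 600, rng_seed = 3)
  expect_identical(e1, e2)
  e3 <- simulate_dynamics(p, 5, 600, rng_seed = 4)
  expect_false(identical(e1$catastrophe_time, e3$catastrophe_time))
  expect_error(simulate_dynamics(p, 5, -1), "duration")
  expect_error(dynamics_params(v_plus = -1), "v_plus")
  expect_error(dynamics_params(lifetime_scale = 0), "lifetime_scale")
  expect_error(imaging_params(pixel_size = 0), "pixel_size")
})

test_that("gamma lifetime law: moments and degenerate limits behave", {
  ## near-deterministic limit: k -> infinity at fixed k*theta = 200 s
  p <- dynamics_params(lifetime_shape = 1e6, lifetime_scale = 200 / 1e6,
                       regrow_delay = 0)
  ev <- simulate_dynamics(p, 20, 1000, rng_seed = 1)
  lt <- ev$lifetime[!ev$censored]
  expect_true(all(abs(lt - 200) < 2))

  ## no catastrophe possible within the movie: every event censored, length
  ## at the end = v * duration
  p2 <- dynamics_params(lifetime_shape = 3, lifetime_scale = 1e6)
  ev2 <- simulate_dynamics(p2, 10, 300, rng_seed = 2)
  expect_true(all(ev2$censored))
  expect_equal(extension_length(ev2, 1, "plus", 300), 1.002 / 60 * 300)

  ## sample mean of many lifetimes within 3 SE of k*theta, cross-checked
  ## against an independent generator (sum of exponentials for integer k)
  p3 <- dynamics_params(lifetime_shape = 3, lifetime_scale = 67.5,
                        regrow_delay = 0)
  ev3 <- simulate_dynamics(p3, 600, 4000, rng_seed = 5)
  lt3 <- ev3$lifetime[!ev3$censored & ev3$end == "plus"]
  expect_gt(length(lt3), 1e4)
  se <- sqrt(3 * 67.5^2 / length(lt3))
  expect_lt(abs(mean(lt3) - 3 * 67.5), 3 * se)
  set.seed(99)
  indep <- rexp(2e4, 1 / 67.5) + rexp(2e4, 1 / 67.5) + rexp(2e4, 1 / 67.5)
  expect_lt(abs(mean(lt3) - mean(indep)),
            3 * sqrt(se^2 + var(indep) / length(indep)))
  ## variance close to k * theta^2
  expect_equal(var(lt3), 3 * 67.5^2, tolerance = 0.1)
})

test_that("censoring bookkeeping reconciles per seed and end", {
  ev <- simulate_dynamics(dynamics_params(), 20, 900, rng_seed = 6)
  for (mt in 1:20) for (end in c("plus", "minus")) {
    sub <- ev[ev$microtubule_id == mt & ev$end == end, ]
    expect_equal(sum(sub$censored) + sum(!sub$censored), nrow(sub))
    ## exactly the last nucleation episode may be censored
    expect_lte(sum(sub$censored), 1)
    if (nrow(sub) > 1) expect_true(all(diff(sub$onset_time) > 0))
  }
})

test_that("kymograph rendering: geometry, linearity, and affine intensity", {
  p <- dynamics_params(lifetime_scale = 1e6)  # single censored event per end
  ev <- simulate_dynamics(p, 1, 200, rng_seed = 1)
  im0 <- quiet_imaging(psf_sigma = 0)
  k <- render_kymograph(ev, im0, 1, rng_seed = 1)
  ## tip column at frame t is at round((seed_edge + v t) / pixel_size)
  tub <- k$channels$tubulin
  for (f in c(11, 51, 101)) {
    t <- k$times[f]
    lit <- which(tub[f, ] > im0$background + 1)
    x_tip <- k$origin + (max(lit) - 1) * im0$pixel_size
    expect_equal(x_tip, 1 + 1.002 / 60 * t, tolerance = im0$pixel_size)
  }
  ## zero gain in the tubulin channel leaves pure background
  imz <- quiet_imaging(channel_gains = c(seed = 175, tubulin = 0, antibody = 1))
  kz <- render_kymograph(ev, imz, 1, rng_seed = 1)
  expect_true(all(kz$channels$tubulin == imz$background))
  ## affine in gain and background
  imA <- quiet_imaging(background = 50,
                       channel_gains = c(seed = 175, tubulin = 100, antibody = 1))
  imB <- quiet_imaging(background = 80,
                       channel_gains = c(seed = 175, tubulin = 200, antibody = 1))
  kA <- render_kymograph(ev, imA, 1, rng_seed = 1)
  kB <- render_kymograph(ev, imB, 1, rng_seed = 1)
  expect_equal(kB$channels$tubulin, (kA$channels$tubulin - 50) * 2 + 80,
               tolerance = 1e-10)
  expect_error(render_kymograph(ev, im0, 99), "not found")
})

test_that("FOV rendering: pixel sums, zero-density limit, linearity, overlap flags", {
  im0 <- quiet_imaging()
  ## pixel-sum of an isolated microtubule equals density * length * gain
  lay <- fov_layout(1, shape = c(256, 256), imaging = im0,
                    antibody_density = 500, rng_seed = 3)
  fov <- render_fov_image(lay, im0, rng_seed = 1)
  len_um <- lay$seed_len + lay$len_minus + lay$len_plus
  total <- sum(fov$channels$antibody - im0$background)
  expect_equal(total, 500 * len_um * im0$channel_gains[["antibody"]],
               tolerance = 0.01)

  ## zero antibody density: channel is pure background (within noise)
  im <- imaging_params(noise_sd = 4)
  lay0 <- fov_layout(5, shape = c(256, 256), imaging = im,
                     antibody_density = 0, rng_seed = 4)
  fov0 <- render_fov_image(lay0, im, rng_seed = 2)
  expect_equal(mean(fov0$channels$antibody), im$background, tolerance = 0.01)

  ## doubling every density doubles the background-subtracted linescan means
  layA <- fov_layout(4, shape = c(384, 384), imaging = im0,
                     antibody_density = 400, rng_seed = 5)
  layB <- layA; layB$antibody_density <- 800
  fa <- render_fov_image(layA, im0, rng_seed = 1)
  fb <- render_fov_image(layB, im0, rng_seed = 1)
  va <- sapply(fa$ground_truth$traces, function(tr)
    subtract_background(linescan_profile(fa, tr), on_span = tr$on_span_px)$value)
  vb <- sapply(fb$ground_truth$traces, function(tr)
    subtract_background(linescan_profile(fb, tr), on_span = tr$on_span_px)$value)
  expect_equal(vb, 2 * va, tolerance = 1e-6)

  ## overlapping microtubules are flagged, not dropped
  layo <- fov_layout(40, shape = c(256, 256), imaging = im0,
                     antibody_density = 100, margin = 40, rng_seed = 6)
  expect_true(any(layo$overlaps))
  expect_equal(nrow(layo), 40)
})

test_that("drift application: identity, exact integer shifts, bounds", {
  mov <- make_static_movie(4, noise_sd = 0)
  zero <- data.frame(frame = 1:4, dx = 0, dy = 0)
  expect_identical(apply_drift(mov, zero, fill = 0), mov)
  ## integer per-frame track (3, -2): frame n shifted by exactly (3n, -2n)
  tr <- data.frame(frame = 1:4, dx = 3 * (0:3), dy = -2 * (0:3))
  out <- apply_drift(mov, tr, fill = 0)
  n <- dim(mov)[1]
  expect_equal(out[1:(n - 6), 10:n, 4], mov[7:n, 1:(n - 9), 4])
  expect_error(apply_drift(mov, data.frame(frame = 1:4, dx = c(0, 0, 0, 200),
                                           dy = 0), fill = 0), "exceeds")
  expect_error(apply_drift(mov, zero[1:2, ], fill = 0), "frame count")
})
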