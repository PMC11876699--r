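test_that("linescan sampling: constants, axis-aligned rows, rotation invariance", {
  ## constant image: profile is that constant everywhere
  img <- matrix(7.5, 64, 64)
  pr <- linescan_profile(img, list(x = c(10, 50), y = c(32, 32)), width = 2)
  expect_true(all(abs(pr$channels$value - 7.5) < 1e-12))

  ## axis-aligned width-2 line equals the mean of the two adjacent pixel rows
  img2 <- matrix(rep(1:64, each = 64), 64, 64, byrow = TRUE) * 0 +
    matrix(rep(seq(0, 630, by = 10), length.out = 64 * 64), 64, 64)
  img2 <- matrix(0, 64, 64)
  img2[31, ] <- 10; img2[32, ] <- 30; img2[33, ] <- 50; img2[34, ] <- 70
  pr2 <- linescan_profile(img2, list(x = c(5, 60), y = c(32.5, 32.5)), width = 2)
  expect_true(all(abs(pr2$channels$value - mean(c(30, 50))) < 1e-9))

  ## a microtubule rendered at 37 degrees reads within 2% of the axis-aligned one
  im0 <- quiet_imaging()
  one_mt <- function(theta_deg) {
    th <- theta_deg * pi / 180
    lay <- fov_layout(1, shape = c(256, 256), imaging = im0,
                      antibody_density = 600, rng_seed = 1)
    lay$theta <- th
    fov <- render_fov_image(lay, im0, rng_seed = 1)
    tr <- fov$ground_truth$traces[[1]]
    subtract_background(linescan_profile(fov, tr), on_span = tr$on_span_px)$value
  }
  v0 <- one_mt(0); v37 <- one_mt(37)
  expect_equal(v37 / v0, 1, tolerance = 0.02)

  ## polyline exiting the image is rejected with the vertex index
  expect_error(linescan_profile(img, list(x = c(10, 300), y = c(32, 32))),
               "vertex 2")
})

test_that("edge background subtraction recovers the plateau exactly and flags bad edges", {
  mk_profile <- function(v) {
    structure(list(arclength = seq_along(v) - 1,
                   channels = list(antibody = v), width = 2,
                   polyline = list(x = c(1, length(v)), y = c(1, 1))),
              class = "linescan_profile")
  }
  ## pure background: value 0
  sb0 <- subtract_background(mk_profile(rep(4, 50)), on_span = c(10, 40))
  expect_equal(sb0$value, 0)
  ## background + plateau s: value exactly s
  v <- c(rep(4, 8), rep(4 + 12.5, 34), rep(4, 8))
  sb <- subtract_background(mk_profile(v), on_span = c(10, 40))
  expect_equal(sb$value, 12.5)
  expect_false(sb$excluded)
  ## signal at the edges: flagged for exclusion with a reason
  bad <- c(rep(50, 8), rep(10, 34), rep(50, 8))
  sbb <- subtract_background(mk_profile(bad), on_span = c(10, 40))
  expect_true(sbb$excluded)
  expect_match(sbb$reason, "edge")
})

test_that("rendered microtubule intensities are recovered within 3% of ground truth", {
  im <- imaging_params(noise_sd = 4)
  lay <- fov_layout(8, shape = c(768, 768), imaging = im,
                    antibody_density = 3000, rng_seed = 7)
  fov <- render_fov_image(lay, im, rng_seed = 8)
  expected <- fov$ground_truth$expected_linescan
  vals <- sapply(fov$ground_truth$traces, function(tr)
    subtract_background(linescan_profile(fov, tr), on_span = tr$on_span_px)$value)
  free <- !lay$overlaps
  expect_gt(sum(free), 2)
  expect_lt(max(abs(vals[free] - expected[free]) / expected[free]), 0.03)
  expect_lt(abs(mean(vals[free] / expected[free]) - 1), 0.025)
})

test_that("FOV normalization: offsets, homogeneity, and zero-signal errors", {
  im0 <- quiet_imaging()
  lay <- fov_layout(6, shape = c(384, 384), imaging = im0,
                    antibody_density = 700, rng_seed = 9)
  fov <- render_fov_image(lay, im0, rng_seed = 9)
  q <- fov_normalized_intensity(fov)
  ## constant offsets on the antibody channel are absorbed by the background
  fov_off <- fov
  fov_off$channels$antibody <- fov$channels$antibody + 250
  q_off <- fov_normalized_intensity(fov_off)
  expect_equal(q_off$normalized, q$normalized, tolerance = 1e-9)
  ## doubling the antibody gain doubles, doubling the seed gain halves
  fov_ab2 <- fov; fov_ab2$channels$antibody <-
    (fov$channels$antibody - im0$background) * 2 + im0$background
  expect_equal(fov_normalized_intensity(fov_ab2)$normalized, 2 * q$normalized,
               tolerance = 1e-9)
  fov_seed2 <- fov
  fov_seed2$channels$seed <- (fov$channels$seed - im0$background) * 2 + im0$background
  expect_equal(fov_normalized_intensity(fov_seed2)$normalized, q$normalized / 2,
               tolerance = 1e-6)
  ## antibody channel of pure background: normalized 0
  fov_bg <- fov; fov_bg$channels$antibody <- matrix(im0$background, 384, 384)
  expect_equal(fov_normalized_intensity(fov_bg)$normalized, 0, tolerance = 1e-9)
  ## zero seed signal: explicit error, no silent division
  fov_z <- fov; fov_z$channels$seed <- matrix(im0$background, 384, 384)
  expect_error(fov_normalized_intensity(fov_z), "seed")
})

test_that("condition mean over FOVs equals the mean of FOV means and n totals reconcile", {
  r <- ptm_recovery_experiment(20, n_fov = 3, n_mts = 25, shape = c(512, 512),
                               rng_seed = 17)
  expect_equal(r$mean, mean(r$per_fov))
  for (q in r$quantifications) {
    expect_equal(q$n_microtubules + q$n_excluded, nrow(q$per_mt))
    expect_true(all(!q$per_mt$excluded | !is.na(q$per_mt$reason)))
  }
})

test_that("per-seed total signal: background correction and seed-count scaling", {
  im0 <- quiet_imaging()
  lay <- fov_layout(5, shape = c(384, 384), imaging = im0,
                    antibody_density = 800, rng_seed = 13)
  fov <- render_fov_image(lay, im0, rng_seed = 13)
  bg_region <- c(1, 20, 1, 20)
  ## pure-background channel gives ~0 per seed
  fov_bg <- fov; fov_bg$channels$antibody <- matrix(im0$background, 384, 384)
  expect_equal(per_seed_total_signal(fov_bg, 5, bg_region), 0, tolerance = 1e-6)
  ## equals sum(density * length * gain) / n_seeds on a noiseless rendering
  total_truth <- sum(lay$antibody_density *
                       (lay$seed_len + lay$len_minus + lay$len_plus) *
                       im0$channel_gains[["antibody"]])
  v5 <- per_seed_total_signal(fov, 5, bg_region)
  expect_equal(v5, total_truth / 5, tolerance = 0.05)
  ## declaring twice the seeds halves the per-seed value
  expect_equal(per_seed_total_signal(fov, 10, bg_region), v5 / 2)
  expect_error(per_seed_total_signal(fov, 5, NULL), "signal-free")
})
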