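test_that("tip extraction tracks the ground truth on a noiseless kymograph", {
  p <- dynamics_params(lifetime_scale = 1e6)  # one long event per end
  ev <- simulate_dynamics(p, 1, 300, rng_seed = 1)
  im0 <- quiet_imaging()
  k <- render_kymograph(ev, im0, 1, rng_seed = 1)
  traj <- extract_tip_trajectory(k)
  ok <- traj$right$quality == "ok"
  expect_gt(sum(ok), 100)
  err_px <- abs(traj$right$position[ok] - k$ground_truth$tip_plus[ok]) / im0$pixel_size
  expect_lt(max(err_px), 0.5)
  okl <- traj$left$quality == "ok"
  err_l <- abs(traj$left$position[okl] - k$ground_truth$tip_minus[okl]) / im0$pixel_size
  expect_lt(max(err_l), 0.5)
  expect_error(extract_tip_trajectory(k, seed_extent = c(-5, 10)), "outside")
})

test_that("all-background kymographs give a constant trajectory at the seed edge", {
  p <- dynamics_params(lifetime_scale = 1e6)
  ev <- simulate_dynamics(p, 1, 100, rng_seed = 1)
  im <- imaging_params(noise_sd = 3,
                       channel_gains = c(seed = 175, tubulin = 0, antibody = 1))
  k <- render_kymograph(ev, im, 1, rng_seed = 2)
  traj <- extract_tip_trajectory(k)
  expect_true(all(traj$right$quality == "none"))
  expect_true(all(traj$right$dist == 0))
  expect_equal(length(unique(traj$right$position)), 1)
})

test_that("tip localization is invariant to constant offsets and intensity scaling", {
  p <- dynamics_params(lifetime_scale = 1e6)
  ev <- simulate_dynamics(p, 1, 200, rng_seed = 2)
  k <- render_kymograph(ev, imaging_params(noise_sd = 5), 1, rng_seed = 3)
  traj <- extract_tip_trajectory(k)
  k_off <- k; k_off$channels$tubulin <- k$channels$tubulin + 500
  traj_off <- extract_tip_trajectory(k_off)
  expect_equal(traj_off$right$position, traj$right$position, tolerance = 1e-10)
  ## uniform scaling leaves every measurement unchanged
  k_sc <- k; k_sc$channels$tubulin <- k$channels$tubulin * 3.7
  ev_a <- analyze_kymograph(k)
  ev_b <- analyze_kymograph(k_sc)
  expect_equal(ev_a$speed, ev_b$speed, tolerance = 1e-10)
  expect_equal(ev_a$lifetime, ev_b$lifetime)
})

test_that("event segmentation: censoring, sawtooth cycles, and count recovery", {
  ## monotone noiseless trajectory over the whole movie: one censored event
  p <- dynamics_params(lifetime_scale = 1e6)
  ev <- simulate_dynamics(p, 1, 300, rng_seed = 1)
  k <- render_kymograph(ev, quiet_imaging(), 1, rng_seed = 1)
  traj <- extract_tip_trajectory(k)
  segs <- segment_growth_events(traj, "right")
  expect_equal(nrow(segs), 1)
  expect_true(segs$censored)

  ## sawtooth with 3 full growth/collapse cycles: 3 uncensored events
  saw <- data.frame(frame = 1:90, time = 2 * (0:89),
                    dist = rep(c(seq(0, 1.4, length.out = 28), 0, 0),
                               3)[1:90],
                    position = 0, quality = "ok")
  traj_saw <- structure(list(right = saw, left = saw[0, ],
                             pixel_size = 0.107, frame_interval = 2),
                        class = "tip_trajectory")
  segs_saw <- segment_growth_events(traj_saw, "right")
  expect_equal(nrow(segs_saw), 3)
  expect_true(all(!segs_saw$censored))

  ## empty trajectory: empty event list
  expect_equal(nrow(segment_growth_events(traj_saw, "left")), 0)

  ## on simulated data the per-seed event count is within +/-1 of the truth
  ## for nearly all seeds
  pp <- dynamics_params()
  evs <- simulate_dynamics(pp, 20, 900, rng_seed = 9)
  im <- imaging_params()
  hit <- vapply(1:20, function(mt) {
    k <- render_kymograph(evs, im, mt, rng_seed = 100 + mt)
    res <- analyze_kymograph(k)
    truth <- evs[evs$microtubule_id == mt, ]
    all(abs(c(sum(res$side == "right"), sum(res$side == "left")) -
              c(sum(truth$end == "plus"), sum(truth$end == "minus"))) <= 1)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("growth-speed estimation is exact on linear input and matches the OLS oracle", {
  ## exact linear trajectory at 1.000 um/min
  lin <- data.frame(frame = 1:100, time = 2 * (0:99),
                    dist = 1 / 60 * 2 * (0:99), position = 0, quality = "ok")
  traj <- structure(list(right = lin, left = lin[0, ], pixel_size = 0.107,
                         frame_interval = 2), class = "tip_trajectory")
  segs <- segment_growth_events(traj, "right")
  sp <- estimate_growth_speed(segs[1, ], traj)
  expect_equal(sp$speed, 1.000, tolerance = 1e-12)

  ## noisy event: slope equals the closed-form least-squares oracle
  set.seed(4)
  noisy <- lin
  noisy$dist <- noisy$dist + rnorm(100, 0, 0.02)
  traj_n <- structure(list(right = noisy, left = noisy[0, ], pixel_size = 0.107,
                           frame_interval = 2), class = "tip_trajectory")
  segs_n <- segment_growth_events(traj_n, "right")
  sp_n <- estimate_growth_speed(segs_n[1, ], traj_n)
  rows <- segs_n$onset_frame[1]:segs_n$cat_frame[1]
  t <- noisy$time[rows]; x <- noisy$dist[rows]
  slope_oracle <- sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
  expect_equal(sp_n$speed, slope_oracle * 60, tolerance = 1e-10)

  ## < 3 usable frames: dropped with a warning
  short <- lin[1:2, ]
  traj_s <- structure(list(right = short, left = short[0, ], pixel_size = 0.107,
                           frame_interval = 2), class = "tip_trajectory")
  fake <- data.frame(side = "right", onset_frame = 1, cat_frame = 2)
  expect_warning(res <- estimate_growth_speed(fake, traj_s), "dropped")
  expect_true(is.na(res$speed))
})

test_that("lifetimes conserve events and match the generating gamma law", {
  pp <- dynamics_params()
  evs <- simulate_dynamics(pp, 40, 1200, rng_seed = 10)
  im <- imaging_params()
  all_ev <- do.call(rbind, lapply(1:40, function(mt) {
    analyze_kymograph(render_kymograph(evs, im, mt, rng_seed = 200 + mt))
  }))
  lt <- extract_lifetimes(all_ev)
  expect_equal(length(lt) + attr(lt, "n_censored"), nrow(all_ev))
  expect_true(all(lt > 0))
  ## plus-end lifetimes consistent with the generating gamma law
  lt_plus <- all_ev$lifetime[!all_ev$censored & all_ev$end == "plus"]
  ks <- suppressWarnings(
    ks.test(lt_plus, pgamma, shape = pp$lifetime_shape,
            scale = pp$lifetime_scale))
  expect_gt(ks$p.value, 0.05)
})

test_that("polarity assignment: speed ordering, ties, and mirror invariance", {
  pol <- assign_polarity(list(right = c(1.0, 1.05), left = c(0.33, 0.37)))
  expect_equal(unname(pol$labels["right"]), "plus")
  expect_equal(unname(pol$labels["left"]), "minus")
  expect_false(pol$ambiguous)
  ## equal speeds: deterministic tie-break, flagged ambiguous
  tie <- assign_polarity(list(right = c(0.5, 0.7), left = c(0.7, 0.5)))
  expect_true(tie$ambiguous)
  tie2 <- assign_polarity(list(right = c(0.7, 0.5), left = c(0.5, 0.7)))
  expect_equal(unname(tie$labels["left"]), unname(tie2$labels["left"]))
  ## single-sided seeds are "unknown", never guessed
  single <- assign_polarity(list(right = c(1.0), left = numeric(0)))
  expect_true(all(single$labels == "unknown"))

  ## mirror invariance: flipping the kymograph left/right swaps the sides
  ## but keeps the same end labels per physical end
  p <- dynamics_params()
  ev <- simulate_dynamics(p, 1, 600, rng_seed = 12)
  k <- render_kymograph(ev, imaging_params(), 1, rng_seed = 12)
  res <- analyze_kymograph(k)
  k_m <- k
  npx <- ncol(k$channels$tubulin)
  k_m$channels <- lapply(k$channels, function(m) m[, npx:1])
  k_m$seed_extent <- sort(npx + 1 - k$seed_extent)
  res_m <- analyze_kymograph(k_m)
  get_speeds <- function(r, lab) sort(r$speed[r$end == lab])
  expect_equal(get_speeds(res_m, "plus"), get_speeds(res, "plus"), tolerance = 1e-6)
  expect_equal(get_speeds(res_m, "minus"), get_speeds(res, "minus"), tolerance = 1e-6)
})

test_that("speed estimator is unbiased at default noise", {
  r <- speed_recovery_experiment(1.002, "plus", n_events = 100, rng_seed = 31)
  expect_gte(r$n, 100)
  expect_lt(abs(r$mean - 1.002) / 1.002, 0.01)
})
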