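#' Growth-speed recovery experiment
#'
#' End-to-end synthetic benchmark for the kymograph pipeline: simulate
#' dynamic microtubules at a known growth speed for one end, render a
#' kymograph per microtubule, run tip extraction, event segmentation, speed
#' estimation and polarity assignment, and collect the estimated speeds of
#' the requested end.
#'
#' The non-target end keeps its default speed so polarity assignment is
#' exercised exactly as on real data.
#'
#' @param v_true generating growth speed (um/min) for the target end.
#' @param end `"plus"` or `"minus"`.
#' @param n_events minimum number of growth events to analyse.
#' @param duration movie duration (s).
#' @param params a [dynamics_params()]; the target end's speed is overridden
#'   by `v_true`.
#' @param imaging an [imaging_params()].
#' @param rng_seed integer seed.
#' @return List: `speeds` (um/min, one per analysed event of the target
#'   end), `mean`, `sem`, `n`, `v_true`, `n_seeds`.
#' @export
speed_recovery_experiment <- function(v_true, end = c("plus", "minus"),
                                      n_events = 300, duration = 600,
                                      params = dynamics_params(),
                                      imaging = imaging_params(),
                                      rng_seed = 1L) {
  end <- match.arg(end)
  if (end == "plus") params$v_plus <- v_true else params$v_minus <- v_true
  ## expected growth events per end per seed: one per lifetime+pause cycle
  cycle <- params$lifetime_shape * params$lifetime_scale + params$regrow_delay
  n_seeds <- ceiling(n_events / max(duration / cycle, 1))
  events <- simulate_dynamics(params, n_seeds = n_seeds, duration = duration,
                              rng_seed = rng_seed)
  speeds <- numeric(0)
  for (mt in seq_len(n_seeds)) {
    kymo <- render_kymograph(events, imaging, mt_id = mt,
                             rng_seed = rng_seed * 1000L + mt)
    res <- analyze_kymograph(kymo)
    speeds <- c(speeds, res$speed[res$end == end])
  }
  list(speeds = speeds, mean = mean(speeds),
       sem = stats::sd(speeds) / sqrt(length(speeds)),
       n = length(speeds), v_true = v_true, n_seeds = n_seeds)
}

#' Lifetime-statistic recovery experiment
#'
#' Draws lifetimes from a gamma law whose median equals `median_target`,
#' then runs the full statistic chain (maximum-likelihood gamma fit,
#' lifetime at half cumulative distribution, bootstrap interquartile-range
#' error).
#'
#' @param median_target generating gamma median (s).
#' @param shape generating gamma shape.
#' @param n sample size.
#' @param B bootstrap resamples.
#' @param rng_seed integer seed.
#' @return The `gamma_lifetime_fit`, with the generating truth attached as
#'   attributes `median_true`, `shape_true`, `scale_true`.
#' @export
lifetime_recovery_experiment <- function(median_target = 202.61, shape = 3,
                                         n = 300, B = 10000L, rng_seed = 1L) {
  scale <- median_target / stats::qgamma(0.5, shape = shape)
  set.seed(rng_seed)
  lifetimes <- stats::rgamma(n, shape = shape, scale = scale)
  fit <- lifetime_statistic(lifetimes, B = B, rng_seed = rng_seed + 1L)
  attr(fit, "median_true") <- median_target
  attr(fit, "shape_true") <- shape
  attr(fit, "scale_true") <- scale
  fit
}

#' Dissociation-constant recovery experiment
#'
#' Simulates repeated noisy two-fold dilution titrations at a known Kd and
#' refits each with the quadratic-depletion model, reporting the median
#' fitted Kd.
#'
#' @param kd_true generating dissociation constant (M).
#' @param top_conc top titrant concentration (M).
#' @param n_points dilution points (16 or 24 typical).
#' @param labeled_total constant labeled-species concentration (M).
#' @param noise_frac noise sd as a fraction of the response dynamic range.
#' @param n_rep number of simulated titrations.
#' @param rng_seed integer seed.
#' @return List: `kd_fits` (valid fitted Kds, M), `median_kd`, `kd_true`,
#'   `n_valid`, `n_rep`.
#' @export
kd_recovery_experiment <- function(kd_true, top_conc, n_points = 24,
                                   labeled_total = 50e-9, noise_frac = 0.05,
                                   n_rep = 100, rng_seed = 1L) {
  s_free <- 800; s_bound <- 900
  design <- titration_design(n_points = n_points, top_conc = top_conc,
                             Kd = kd_true, labeled_total = labeled_total,
                             signal_free = s_free, signal_bound = s_bound,
                             noise_sd = noise_frac * (s_bound - s_free))
  kds <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    tt <- simulate_titration(design, rng_seed = rng_seed * 1000L + r)
    fit <- fit_kd(tt, labeled_total = labeled_total)
    if (isTRUE(fit$valid)) kds[r] <- fit$Kd
  }
  valid <- kds[is.finite(kds)]
  list(kd_fits = valid, median_kd = stats::median(valid), kd_true = kd_true,
       n_valid = length(valid), n_rep = n_rep)
}

#' Polyglutamylation-score recovery experiment
#'
#' Renders a set of synthetic two-channel fields of view whose ground-truth
#' normalized antibody statistic equals `target_normalized` (per-microtubule
#' antibody densities are drawn with log-normal variability and rescaled per
#' FOV so the expected linescan statistic hits the target exactly), then
#' runs the linescan pipeline and reports the recovered per-FOV normalized
#' intensities.
#'
#' @param target_normalized ground-truth normalized intensity
#'   (100 x mean per-MT antibody / mean seed intensity).
#' @param n_fov number of fields of view.
#' @param n_mts microtubules per FOV.
#' @param target_seed_mean expected seed-mask mean intensity (counts).
#' @param density_cv coefficient of variation of per-MT antibody densities.
#' @param shape image shape (px).
#' @param imaging an [imaging_params()].
#' @param rng_seed integer seed.
#' @return List: `per_fov` (recovered normalized intensity per FOV), `mean`,
#'   `target`, `quantifications` (the per-FOV `fov_quantification` objects).
#' @export
ptm_recovery_experiment <- function(target_normalized, n_fov = 9, n_mts = 70,
                                    target_seed_mean = 175, density_cv = 0.4,
                                    shape = c(1024, 1024),
                                    imaging = imaging_params(),
                                    rng_seed = 1L) {
  kappa <- expected_linescan_value(1, imaging$channel_gains[["antibody"]], imaging)
  target_mt_mean <- target_normalized * target_seed_mean / 100
  per_fov <- numeric(n_fov)
  quants <- vector("list", n_fov)
  sdlog <- sqrt(log(1 + density_cv^2))
  for (k in seq_len(n_fov)) {
    seed_k <- rng_seed * 1000L + k
    set.seed(seed_k)
    w <- stats::rlnorm(n_mts, -sdlog^2 / 2, sdlog)
    dens <- w / mean(w) * target_mt_mean / kappa   # exact FOV-mean calibration
    layout <- fov_layout(n_mts, shape = shape, imaging = imaging,
                         antibody_density = dens,
                         target_seed_mean = target_seed_mean,
                         rng_seed = seed_k + 1L)
    fov <- render_fov_image(layout, imaging, rng_seed = seed_k + 2L)
    q <- fov_normalized_intensity(fov)
    per_fov[k] <- q$normalized
    quants[[k]] <- q
  }
  list(per_fov = per_fov, mean = mean(per_fov), target = target_normalized,
       quantifications = quants)
}

#' Drift estimation/correction round trip
#'
#' Renders a small two-channel movie of static filaments, applies a known
#' rigid drift, estimates it back by cross-correlation on one channel and
#' corrects all channels; reports the residual per-frame drift of the
#' corrected movie.
#'
#' @param drift_per_frame `c(dx, dy)` px per frame (may be subpixel).
#' @param n_frames number of frames.
#' @param shape image shape (px).
#' @param imaging an [imaging_params()].
#' @param rng_seed integer seed.
#' @return List: `track_true`, `track_est` (drift tracks), `max_error` (px,
#'   over frames), `residual_per_frame` (px/frame of the corrected movie).
#' @export
drift_recovery_experiment <- function(drift_per_frame = c(0.4, -0.3),
                                      n_frames = 12, shape = c(128, 128),
                                      imaging = imaging_params(),
                                      rng_seed = 1L) {
  quiet <- imaging; quiet$noise_sd <- 0
  layout <- fov_layout(6, shape = shape, imaging = quiet,
                       antibody_density = 800, margin = 25,
                       ext_len_range = c(1, 2), rng_seed = rng_seed)
  base <- render_fov_image(layout, quiet, rng_seed = rng_seed + 1L)
  movie <- list(
    seed = array(0, c(shape, n_frames)),
    antibody = array(0, c(shape, n_frames)))
  set.seed(rng_seed + 2L)
  for (f in seq_len(n_frames)) {  # fresh noise per frame on the same scene
    for (ch in names(movie))
      movie[[ch]][, , f] <- .add_noise(base$channels[[ch]], imaging)
  }
  track_true <- data.frame(frame = seq_len(n_frames),
                           dx = drift_per_frame[1] * (seq_len(n_frames) - 1),
                           dy = drift_per_frame[2] * (seq_len(n_frames) - 1))
  drifted <- apply_drift(movie, track_true, fill = imaging$background)
  track_est <- estimate_drift(drifted, channel = "seed")
  corrected <- correct_drift(drifted, track_est)
  residual <- estimate_drift(corrected, channel = "seed")
  per_frame_resid <- max(abs(diff(residual$dx)), abs(diff(residual$dy)))
  list(track_true = track_true, track_est = track_est,
       max_error = max(abs(track_est$dx - track_true$dx),
                       abs(track_est$dy - track_true$dy)),
       residual_per_frame = per_frame_resid)
}
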