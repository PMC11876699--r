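#' Ground-truth dynamic-instability parameters
#'
#' Parameters of the two-state (growth / instantaneous collapse) microtubule
#' model used by the simulator: per-end growth speeds, a gamma-distributed
#' catastrophe waiting time shared by both ends, and a re-nucleation pause at
#' the seed after each collapse.
#'
#' Defaults correspond to a buffer-control condition for dynamic microtubules
#' grown from stabilized seeds at 16 uM tubulin: plus end 1.002 um/min, minus
#' end 0.348 um/min, gamma shape 3 with the scale set so the distribution's
#' median is 202.61 s. Shrinkage is instantaneous back to the seed
#' (`shrink_speed = Inf`) since only growth segments are analysed.
#'
#' @param v_plus,v_minus growth speeds (um/min), > 0.
#' @param shrink_speed post-catastrophe depolymerisation speed (um/min);
#'   `Inf` collapses the extension within one frame.
#' @param lifetime_shape,lifetime_scale gamma law of the growth-event
#'   lifetime (shape dimensionless, scale seconds), both > 0.
#' @param regrow_delay pause at the seed before re-nucleation (s), >= 0.
#' @return Object of class `dynamics_params`.
#' @export
dynamics_params <- function(v_plus = 1.002, v_minus = 0.348,
                            shrink_speed = Inf,
                            lifetime_shape = 3,
                            lifetime_scale = 202.61 / stats::qgamma(0.5, shape = 3),
                            regrow_delay = 20) {
  num_pos <- function(x, name, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        (strict && x <= 0) || (!strict && x < 0))
      stop("invalid '", name, "': must be a ", if (strict) "positive" else "non-negative",
           " number", call. = FALSE)
  }
  num_pos(v_plus, "v_plus"); num_pos(v_minus, "v_minus")
  num_pos(shrink_speed, "shrink_speed")
  num_pos(lifetime_shape, "lifetime_shape"); num_pos(lifetime_scale, "lifetime_scale")
  num_pos(regrow_delay, "regrow_delay", strict = FALSE)
  structure(list(v_plus = v_plus, v_minus = v_minus, shrink_speed = shrink_speed,
                 lifetime_shape = lifetime_shape, lifetime_scale = lifetime_scale,
                 regrow_delay = regrow_delay), class = "dynamics_params")
}

#' Imaging model parameters
#'
#' Describes the synthetic microscope: pixel size and frame interval of a
#' typical 100x TIRF rig with an sCMOS camera, a Gaussian point-spread
#' function, a constant background and either Gaussian or Poisson noise.
#'
#' @param pixel_size um per pixel, > 0.
#' @param frame_interval seconds between frames, > 0.
#' @param psf_sigma Gaussian PSF sigma in pixels, >= 0 (0 = no blur).
#' @param background constant background level (counts).
#' @param noise_model `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise sd (counts), used when `noise_model = "gaussian"`.
#' @param channel_gains named numeric vector of per-channel gains
#'   (counts per unit linear density), all >= 0.
#' @return Object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size = 0.107, frame_interval = 2,
                           psf_sigma = 1.3, background = 100,
                           noise_model = c("gaussian", "poisson"),
                           noise_sd = 8,
                           channel_gains = c(seed = 175, tubulin = 150, antibody = 1)) {
  noise_model <- match.arg(noise_model)
  if (pixel_size <= 0) stop("invalid 'pixel_size': must be > 0")
  if (frame_interval <= 0) stop("invalid 'frame_interval': must be > 0")
  if (psf_sigma < 0) stop("invalid 'psf_sigma': must be >= 0")
  if (background < 0) stop("invalid 'background': must be >= 0")
  if (noise_sd < 0) stop("invalid 'noise_sd': must be >= 0")
  if (is.null(names(channel_gains)) || any(channel_gains < 0))
    stop("'channel_gains' must be a named vector of non-negative gains")
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 psf_sigma = psf_sigma, background = background,
                 noise_model = noise_model, noise_sd = noise_sd,
                 channel_gains = channel_gains), class = "imaging_params")
}

#' Simulate growth events of dynamic microtubules
#'
#' Generates a per-microtubule event table for seeds elongating at both ends:
#' each end alternates growth episodes (at its configured constant speed) with
#' instantaneous collapse back to the seed, the growth lifetime drawn from the
#' configured gamma law and a fixed re-nucleation pause between episodes.
#' Events still growing when the movie ends are flagged censored.
#'
#' @param params a [dynamics_params()].
#' @param n_seeds number of seeds (>= 1).
#' @param duration movie duration (s), > 0.
#' @param rng_seed integer seed; output is bit-identical for identical seeds.
#' @return Data frame (class `event_table`) with one row per growth event:
#'   `microtubule_id`, `end` ("plus"/"minus"), `onset_time` (s),
#'   `catastrophe_time` (s, `NA` when censored), `censored` (logical),
#'   `lifetime` (s, `NA` when censored), `speed` (um/min), `seed_anchor` (um).
#'   The parameters and seed are attached as attributes `params`, `rng_seed`,
#'   `duration`.
#' @export
simulate_dynamics <- function(params, n_seeds, duration, rng_seed = 1L) {
  stopifnot(inherits(params, "dynamics_params"))
  if (!is.numeric(duration) || duration <= 0) stop("invalid 'duration': must be > 0")
  if (n_seeds < 1) stop("invalid 'n_seeds': must be >= 1")
  set.seed(rng_seed)
  rows <- vector("list", n_seeds * 2L)
  i <- 0L
  for (mt in seq_len(n_seeds)) {
    for (end in c("plus", "minus")) {
      v <- if (end == "plus") params$v_plus else params$v_minus
      t <- 0
      onset <- numeric(0); cat_t <- numeric(0); cens <- logical(0)
      while (t < duration) {
        tau <- stats::rgamma(1, shape = params$lifetime_shape,
                             scale = params$lifetime_scale)
        if (t + tau >= duration) {
          onset <- c(onset, t); cat_t <- c(cat_t, NA_real_); cens <- c(cens, TRUE)
          break
        }
        onset <- c(onset, t); cat_t <- c(cat_t, t + tau); cens <- c(cens, FALSE)
        t <- t + tau + params$regrow_delay
      }
      i <- i + 1L
      rows[[i]] <- data.frame(
        microtubule_id = mt, end = end, onset_time = onset,
        catastrophe_time = cat_t, censored = cens,
        lifetime = cat_t - onset, speed = v, seed_anchor = 0)
    }
  }
  out <- do.call(rbind, rows[seq_len(i)])
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "rng_seed") <- as.integer(rng_seed)
  attr(out, "duration") <- duration
  class(out) <- c("event_table", "data.frame")
  out
}

#' Ground-truth extension length at given times
#'
#' Length of the extension beyond the seed for one end of one microtubule at
#' arbitrary times, under the instantaneous-collapse model.
#'
#' @param events an `event_table` from [simulate_dynamics()].
#' @param mt_id microtubule id.
#' @param end `"plus"` or `"minus"`.
#' @param times numeric vector of times (s).
#' @return Numeric vector of lengths (um), 0 between growth episodes.
#' @export
extension_length <- function(events, mt_id, end, times) {
  ev <- events[events$microtubule_id == mt_id & events$end == end, , drop = FALSE]
  len <- numeric(length(times))
  dur <- attr(events, "duration") %||% Inf
  for (j in seq_len(nrow(ev))) {
    stop_t <- if (ev$censored[j]) dur else ev$catastrophe_time[j]
    act <- times >= ev$onset_time[j] & times <= stop_t
    len[act] <- ev$speed[j] / 60 * (times[act] - ev$onset_time[j])
  }
  len
}
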