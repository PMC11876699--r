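## Axial profile of a blurred segment [a, b]: the exact 1-D convolution of an
## indicator with a Gaussian of sd `sigma` (same units as x). sigma = 0 gives
## the unblurred indicator (pixel centers inside [a, b]).
.segment_profile <- function(x, a, b, sigma) {
  if (sigma == 0) return(as.numeric(x >= a & x <= b))
  stats::pnorm((b - x) / sigma) - stats::pnorm((a - x) / sigma)
}

.add_noise <- function(img, imaging) {
  if (imaging$noise_model == "gaussian") {
    if (imaging$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, imaging$noise_sd)
  } else {
    img[] <- stats::rpois(length(img), pmax(img, 0))
  }
  img
}

#' Render a kymograph from a simulated event table
#'
#' Builds the space-time image of one microtubule: rows are frames, columns
#' are positions along the microtubule axis. The seed occupies a fixed central
#' segment (seed channel); growing extensions follow the event table at their
#' configured speeds (tubulin channel). Profiles are the exact convolution of
#' the segment with the Gaussian PSF, plus background and noise.
#'
#' The plateau intensity of a segment is `density * gain` counts for the
#' channel's gain.
#'
#' @param events an `event_table` from [simulate_dynamics()].
#' @param imaging an [imaging_params()].
#' @param mt_id microtubule id present in `events`.
#' @param seed_half_length half-length of the seed (um); the seed spans
#'   `[-seed_half_length, +seed_half_length]` around the anchor.
#' @param density linear density of the rendered lattice (default 1, so the
#'   plateau equals the channel gain).
#' @param margin space beyond the maximal excursion (um).
#' @param duration movie duration (s); defaults to the event table's.
#' @param rng_seed integer seed for the noise.
#' @return Object of class `kymograph`: list with `channels` (named list of
#'   frames x pixels matrices), `pixel_size`, `frame_interval`, `origin`
#'   (um position of column 1's center), `seed_extent` (column index range of
#'   the seed), `times`, and `ground_truth` (per-frame true tip positions, um,
#'   for both ends).
#' @export
render_kymograph <- function(events, imaging, mt_id, seed_half_length = 1,
                             density = 1, margin = 1, duration = NULL,
                             rng_seed = 1L) {
  stopifnot(inherits(imaging, "imaging_params"))
  if (!mt_id %in% events$microtubule_id)
    stop("microtubule id '", mt_id, "' not found in the event table")
  if (is.null(duration)) duration <- attr(events, "duration")
  ps <- imaging$pixel_size
  sh <- seed_half_length
  times <- seq(0, duration, by = imaging$frame_interval)
  len_p <- extension_length(events, mt_id, "plus", times)
  len_m <- extension_length(events, mt_id, "minus", times)

  xmin <- -sh - max(len_m) - margin
  xmax <- sh + max(len_p) + margin
  cols <- seq(floor(xmin / ps), ceiling(xmax / ps))
  x <- cols * ps                      # pixel-center positions, um
  sigma_um <- imaging$psf_sigma * ps
  gains <- imaging$channel_gains

  nf <- length(times)
  tip_p <- sh + len_p
  tip_m <- -sh - len_m
  ## tubulin channel: both extensions, vectorised over frames x pixels
  pn <- function(edge) stats::pnorm(outer(edge, x, "-") / sigma_um)
  if (sigma_um > 0) {
    tub <- (pn(tip_p) - pn(rep(sh, nf))) + (pn(rep(-sh, nf)) - pn(tip_m))
  } else {
    tub <- outer(tip_p, x, function(b, xx) as.numeric(xx >= sh & xx <= b)) +
      outer(tip_m, x, function(a, xx) as.numeric(xx >= a & xx <= -sh))
  }
  tub <- tub * density * gains[["tubulin"]]
  seed_prof <- .segment_profile(x, -sh, sh, sigma_um) * density * gains[["seed"]]
  seed <- matrix(seed_prof, nrow = nf, ncol = length(x), byrow = TRUE)

  set.seed(rng_seed)
  channels <- list(
    seed = .add_noise(seed + imaging$background, imaging),
    tubulin = .add_noise(tub + imaging$background, imaging))
  seed_cols <- which(x >= -sh & x <= sh)
  structure(list(
    channels = channels, pixel_size = ps,
    frame_interval = imaging$frame_interval,
    origin = x[1], seed_extent = range(seed_cols),
    times = times, mt_id = mt_id,
    ground_truth = list(tip_plus = tip_p, tip_minus = tip_m,
                        len_plus = len_p, len_minus = len_m)),
    class = "kymograph")
}

#' Expected linescan value for a rendered microtubule
#'
#' Analytic mean intensity a width-`width` linescan centered on an isolated,
#' infinitely long filament of the given linear density would measure on a
#' noiseless rendering (per arclength sample, background excluded). The
#' prediction includes the bilinear sampling of the measurement: reading the
#' pixel grid by bilinear interpolation convolves the profile with a tent
#' kernel of variance 1/6 px^2 (direction-independent), so the perpendicular
#' profile seen by the linescan is a Gaussian of sd
#' `sqrt(psf_sigma^2 + 1/6)`.
#'
#' @param density linear density (counts/um before PSF).
#' @param gain channel gain.
#' @param imaging an [imaging_params()].
#' @param width linescan width in px.
#' @return Expected background-subtracted linescan mean (counts).
#' @export
expected_linescan_value <- function(density, gain, imaging, width = 2) {
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2, by = 1)
  sigma_eff <- sqrt(imaging$psf_sigma^2 + 1 / 6)
  density * gain * imaging$pixel_size *
    mean(stats::dnorm(offsets, 0, sigma_eff))
}

## Rotated-frame coordinates of pixels around a segment; returns the index
## sub-grid and (s, r) coordinates (axial um, perpendicular px).
.segment_grid <- function(shape, cx, cy, theta, a_um, b_um, imaging, pad = 6) {
  ps <- imaging$pixel_size
  ends <- cbind(cx + c(a_um, b_um) / ps * cos(theta),
                cy + c(a_um, b_um) / ps * sin(theta))
  xr <- pmin(pmax(round(range(ends[, 1]) + c(-pad, pad)), 1), shape[2])
  yr <- pmin(pmax(round(range(ends[, 2]) + c(-pad, pad)), 1), shape[1])
  xs <- xr[1]:xr[2]; ys <- yr[1]:yr[2]
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  list(ys = ys, xs = xs,
       s = (dx * cos(theta) + dy * sin(theta)) * ps,
       r = -dx * sin(theta) + dy * cos(theta))
}

## Add a PSF-blurred segment to `img`. Pixel value model:
##   I = density * gain * pixel_size * axial_window(s) * dnorm(r; psf_sigma)
## so the pixel sum of an isolated segment is density * gain * length_um.
.add_segment <- function(img, cx, cy, theta, a_um, b_um, density, gain, imaging) {
  g <- .segment_grid(dim(img), cx, cy, theta, a_um, b_um, imaging)
  sigma_um <- imaging$psf_sigma * imaging$pixel_size
  axial <- .segment_profile(g$s, a_um, b_um, sigma_um)
  perp <- if (imaging$psf_sigma > 0) {
    stats::dnorm(g$r, 0, imaging$psf_sigma)
  } else as.numeric(abs(g$r) <= 0.5)
  img[g$ys, g$xs] <- img[g$ys, g$xs] +
    density * gain * imaging$pixel_size * axial * perp
  img
}

## Minimal distance between two 2-D segments (px), for overlap flagging.
.segment_distance <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  seg_int <- function(a, b, c, d) { # proper intersection test
    cross <- function(u, v) u[1] * v[2] - u[2] * v[1]
    d1 <- cross(d - c, a - c); d2 <- cross(d - c, b - c)
    d3 <- cross(b - a, c - a); d4 <- cross(b - a, d - a)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (seg_int(p1, p2, q1, q2)) return(0)
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2), pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}

#' Random field-of-view layout of seeded microtubules
#'
#' Places straight microtubules (a stabilized seed with collinear extensions
#' at both ends) at random positions and orientations inside the image,
#' assigns per-microtubule antibody densities, and calibrates the seed-channel
#' density so the expected mean seed-mask intensity equals
#' `target_seed_mean`. Microtubules closer than `overlap_dist` px to another
#' are flagged (not removed) in the returned layout.
#'
#' @param n_mts number of microtubules.
#' @param shape image shape `c(ny, nx)` in px.
#' @param imaging an [imaging_params()].
#' @param antibody_density per-MT antibody linear densities (counts/um),
#'   recycled to `n_mts`.
#' @param target_seed_mean target expected seed-mask mean intensity (counts,
#'   background-subtracted).
#' @param seed_len_range,ext_len_range uniform ranges (um) for seed length and
#'   for each extension length.
#' @param margin placement margin from the border (px).
#' @param overlap_dist distance (px) below which two microtubules are flagged
#'   as overlapping.
#' @param rng_seed integer seed.
#' @return Object of class `fov_layout`: data frame of microtubules plus
#'   attributes (`shape`, `imaging`, `target_seed_mean`).
#' @export
fov_layout <- function(n_mts, shape = c(1024, 1024), imaging = imaging_params(),
                       antibody_density = 1000, target_seed_mean = 175,
                       seed_len_range = c(1.5, 2.5), ext_len_range = c(2, 5),
                       margin = 60, overlap_dist = 6, rng_seed = 1L) {
  set.seed(rng_seed)
  if (n_mts < 1) stop("n_mts must be >= 1")
  antibody_density <- rep_len(antibody_density, n_mts)
  if (any(antibody_density < 0)) stop("antibody densities must be >= 0")
  mt <- data.frame(
    mt_id = seq_len(n_mts),
    cx = stats::runif(n_mts, margin, shape[2] - margin),
    cy = stats::runif(n_mts, margin, shape[1] - margin),
    theta = stats::runif(n_mts, 0, pi),
    seed_len = stats::runif(n_mts, seed_len_range[1], seed_len_range[2]),
    len_minus = stats::runif(n_mts, ext_len_range[1], ext_len_range[2]),
    len_plus = stats::runif(n_mts, ext_len_range[1], ext_len_range[2]),
    antibody_density = antibody_density)
  ## clamp so the full polymer (+ linescan margin) stays inside the image
  ps <- imaging$pixel_size
  half_span <- (mt$seed_len / 2 + pmax(mt$len_minus, mt$len_plus)) / ps + 15
  mt$cx <- pmin(pmax(mt$cx, half_span + 1), shape[2] - half_span - 1)
  mt$cy <- pmin(pmax(mt$cy, half_span + 1), shape[1] - half_span - 1)

  ## seed density calibrated per seed so expected mask mean = target
  gains <- imaging$channel_gains
  mt$seed_density <- NA_real_
  mt$seed_mask_mean_per_unit <- NA_real_
  for (i in seq_len(n_mts)) {
    m <- .seed_mask(shape, mt$cx[i], mt$cy[i], mt$theta[i], mt$seed_len[i], imaging)
    mt$seed_mask_mean_per_unit[i] <- m$mean_per_unit
    mt$seed_density[i] <- target_seed_mean / (gains[["seed"]] * m$mean_per_unit)
  }

  ## overlap flags
  ends <- function(i, ch) {
    a <- -(mt$seed_len[i] / 2 + mt$len_minus[i]) / ps
    b <- (mt$seed_len[i] / 2 + mt$len_plus[i]) / ps
    list(p1 = c(mt$cx[i] + a * cos(mt$theta[i]), mt$cy[i] + a * sin(mt$theta[i])),
         p2 = c(mt$cx[i] + b * cos(mt$theta[i]), mt$cy[i] + b * sin(mt$theta[i])))
  }
  segs <- lapply(seq_len(n_mts), ends)
  mt$overlaps <- FALSE
  if (n_mts > 1) {
    for (i in seq_len(n_mts - 1)) for (j in (i + 1):n_mts) {
      d <- .segment_distance(segs[[i]]$p1, segs[[i]]$p2, segs[[j]]$p1, segs[[j]]$p2)
      if (d < overlap_dist) mt$overlaps[c(i, j)] <- TRUE
    }
  }
  structure(mt, shape = shape, imaging = imaging,
            target_seed_mean = target_seed_mean, rng_seed = as.integer(rng_seed),
            class = c("fov_layout", "data.frame"))
}

## Seed mask (pixels within `halfwidth` px of the seed segment) and the mean
## rendered intensity per unit (density * gain) over that mask.
.seed_mask <- function(shape, cx, cy, theta, seed_len, imaging, halfwidth = 1.5) {
  a <- -seed_len / 2; b <- seed_len / 2
  g <- .segment_grid(shape, cx, cy, theta, a, b, imaging, pad = 6)
  inside <- abs(g$r) <= halfwidth & g$s >= a & g$s <= b
  sigma_um <- imaging$psf_sigma * imaging$pixel_size
  val <- imaging$pixel_size * .segment_profile(g$s, a, b, sigma_um) *
    (if (imaging$psf_sigma > 0) stats::dnorm(g$r, 0, imaging$psf_sigma)
     else as.numeric(abs(g$r) <= 0.5))
  idx_mat <- outer(g$ys, (g$xs - 1) * shape[1], "+")   # linear indices
  list(idx = idx_mat[inside], mean_per_unit = mean(val[inside]))
}

#' Render a multichannel field-of-view image
#'
#' Renders the seed channel (seed segments only) and the antibody channel
#' (whole polymer at the per-microtubule ground-truth antibody density), with
#' Gaussian PSF, constant background and noise. Ground truth (per-MT
#' polyline, densities, expected linescan values, seed masks, overlap flags)
#' is returned alongside.
#'
#' @param layout an [fov_layout()].
#' @param imaging an [imaging_params()]; defaults to the layout's.
#' @param rng_seed integer seed for the noise.
#' @return Object of class `fov_image`: `channels` (named list of matrices),
#'   `pixel_size`, `ground_truth` (the layout plus per-MT trace polylines and
#'   seed-mask indices).
#' @export
render_fov_image <- function(layout, imaging = NULL, rng_seed = 1L) {
  stopifnot(inherits(layout, "fov_layout"))
  if (is.null(imaging)) imaging <- attr(layout, "imaging")
  shape <- attr(layout, "shape")
  gains <- imaging$channel_gains
  ps <- imaging$pixel_size
  seed_img <- matrix(0, shape[1], shape[2])
  ab_img <- matrix(0, shape[1], shape[2])
  seed_masks <- vector("list", nrow(layout))
  traces <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    sl2 <- layout$seed_len[i] / 2
    a_full <- -(sl2 + layout$len_minus[i]); b_full <- sl2 + layout$len_plus[i]
    seed_img <- .add_segment(seed_img, layout$cx[i], layout$cy[i], layout$theta[i],
                             -sl2, sl2, layout$seed_density[i], gains[["seed"]], imaging)
    ab_img <- .add_segment(ab_img, layout$cx[i], layout$cy[i], layout$theta[i],
                           a_full, b_full, layout$antibody_density[i],
                           gains[["antibody"]], imaging)
    m <- .seed_mask(shape, layout$cx[i], layout$cy[i], layout$theta[i],
                    layout$seed_len[i], imaging)
    seed_masks[[i]] <- m$idx
    ## linescan trace polyline: polymer extended 12 px past both ends for the
    ## background edges; on-MT span inset 3 px from the tips so the partial
    ## PSF roll-off at the ends does not dilute the mean
    ext <- 12 * ps
    inset <- 3
    traces[[i]] <- list(
      mt_id = layout$mt_id[i],
      x = layout$cx[i] + c(a_full - ext, b_full + ext) / ps * cos(layout$theta[i]),
      y = layout$cy[i] + c(a_full - ext, b_full + ext) / ps * sin(layout$theta[i]),
      on_span_px = c(ext / ps + inset, (ext + b_full - a_full) / ps - inset))
  }
  set.seed(rng_seed)
  channels <- list(
    seed = .add_noise(seed_img + imaging$background, imaging),
    antibody = .add_noise(ab_img + imaging$background, imaging))
  expected <- expected_linescan_value(layout$antibody_density,
                                      gains[["antibody"]], imaging)
  structure(list(
    channels = channels, pixel_size = ps, imaging = imaging,
    ground_truth = list(layout = layout, traces = traces,
                        seed_masks = seed_masks,
                        expected_linescan = expected)),
    class = "fov_image")
}

## Bilinear translation of an image by (dx, dy) px; edges filled with `fill`.
.shift_image <- function(img, dx, dy, fill) {
  ny <- nrow(img); nx <- ncol(img)
  if (dx == 0 && dy == 0) return(img)
  xs <- seq_len(nx) - dx
  ys <- seq_len(ny) - dy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  get_col <- function(j) if (j >= 1 && j <= nx) img[, j] else rep(fill, ny)
  out <- matrix(fill, ny, nx)
  ## interpolate row-wise: out[i, j] = (1-fy)(1-fx) I[y0, x0] + ...
  row_ok0 <- y0 >= 1 & y0 <= ny
  row_ok1 <- (y0 + 1) >= 1 & (y0 + 1) <= ny
  I0 <- matrix(fill, ny, nx); I1 <- matrix(fill, ny, nx)
  for (j in seq_len(nx)) {
    c0 <- get_col(x0[j]); c1 <- get_col(x0[j] + 1)
    I0[, j] <- (1 - fx[j]) * c0 + fx[j] * c1
  }
  r0 <- matrix(fill, ny, nx); r1 <- matrix(fill, ny, nx)
  r0[row_ok0, ] <- I0[y0[row_ok0], ]
  r1[row_ok1, ] <- I0[y0[row_ok1] + 1, ]
  out <- (1 - fy) * r0 + fy * r1
  out
}

#' Apply rigid per-frame drift to a movie
#'
#' Translates each frame by its cumulative drift (bilinear interpolation for
#' subpixel shifts); uncovered edges are filled with the frame's median as a
#' background estimate. For multichannel movies, the same drift is applied to
#' every channel.
#'
#' @param movie a 3-D array `[ny, nx, nframes]`, or a named list of such
#'   arrays (one per channel).
#' @param drift_track data frame with columns `dx`, `dy`: cumulative
#'   displacement per frame, px (may be subpixel).
#' @param fill edge fill value; `NULL` uses each frame's median.
#' @return Movie of the same structure.
#' @export
apply_drift <- function(movie, drift_track, fill = NULL) {
  if (is.list(movie) && !is.array(movie))
    return(lapply(movie, apply_drift, drift_track = drift_track, fill = fill))
  stopifnot(length(dim(movie)) == 3)
  nf <- dim(movie)[3]
  if (nrow(drift_track) != nf)
    stop("drift track length (", nrow(drift_track), ") != frame count (", nf, ")")
  if (any(abs(drift_track$dx) >= dim(movie)[2]) ||
      any(abs(drift_track$dy) >= dim(movie)[1]))
    stop("drift exceeds the image size")
  out <- movie
  for (k in seq_len(nf)) {
    f <- if (is.null(fill)) stats::median(movie[, , k]) else fill
    out[, , k] <- .shift_image(movie[, , k], drift_track$dx[k], drift_track$dy[k], f)
  }
  out
}
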