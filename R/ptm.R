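## Bilinear interpolation of `img` at (x, y) in pixel-center coordinates
## (x = column, y = row, both 1-based). Points must lie inside the image.
.bilinear <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- pmin(pmax(floor(x), 1), nx - 1)
  y0 <- pmin(pmax(floor(y), 1), ny - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
}

#' Linescan along a microtubule trace
#'
#' Samples the image along a polyline at 1-px arclength steps; at each sample
#' the intensity is the mean over `width` pixels perpendicular to the local
#' tangent (offsets centered on the line, 1 px apart), each read by bilinear
#' interpolation. This reproduces a fixed-width linescan measurement.
#'
#' @param fov an `fov_image` (or a plain matrix, treated as one channel
#'   `"value"`).
#' @param polyline list or data frame with numeric `x`, `y` vertex
#'   coordinates (px, 1-based pixel centers).
#' @param width linescan width in px (>= 1).
#' @param step arclength sampling step (px).
#' @return Object of class `linescan_profile`: `arclength` (px),
#'   `channels` (named list of intensity vectors), `width`, `polyline`.
#' @export
linescan_profile <- function(fov, polyline, width = 2, step = 1) {
  channels <- if (inherits(fov, "fov_image")) fov$channels else list(value = fov)
  dims <- dim(channels[[1]])
  if (width < 1) stop("width must be >= 1")
  px <- as.numeric(polyline$x); py <- as.numeric(polyline$y)
  if (length(px) < 2) stop("polyline needs at least 2 vertices")
  pad <- width / 2 + 1
  bad <- which(px < pad | px > dims[2] - pad + 1 | py < pad | py > dims[1] - pad + 1)
  if (length(bad))
    stop("polyline vertex ", bad[1], " outside the usable image area")

  ## arclength-parameterised samples with local tangents
  seg_len <- sqrt(diff(px)^2 + diff(py)^2)
  cum <- c(0, cumsum(seg_len))
  s <- seq(0, cum[length(cum)], by = step)
  seg <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(seg_len))
  f <- (s - cum[seg]) / seg_len[seg]
  sx <- px[seg] + f * diff(px)[seg]
  sy <- py[seg] + f * diff(py)[seg]
  tx <- diff(px)[seg] / seg_len[seg]
  ty <- diff(py)[seg] / seg_len[seg]
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2, by = 1)

  sample_channel <- function(img) {
    acc <- 0
    for (o in offsets) acc <- acc + .bilinear(img, sx - o * ty, sy + o * tx)
    acc / length(offsets)
  }
  structure(list(arclength = s,
                 channels = lapply(channels, sample_channel),
                 width = width, polyline = list(x = px, y = py)),
            class = "linescan_profile")
}

#' Background-subtracted mean intensity of one microtubule
#'
#' The background is the mean of the outermost `edge_len` samples at both
#' ends of the linescan (which the trace extends beyond the microtubule, so
#' these samples are signal-free); the per-microtubule value is the mean over
#' the on-microtubule span minus that background. Microtubules whose edges
#' are not signal-free (edge mean above the on-span mean) are flagged for
#' exclusion rather than silently kept.
#'
#' @param profile a `linescan_profile`.
#' @param edge_len number of samples per end used for the background.
#' @param on_span arclength interval `c(lo, hi)` (px) of the on-microtubule
#'   region; `NULL` estimates it as the half-maximum extent of the smoothed
#'   profile.
#' @param channel channel to quantify.
#' @return List: `value` (background-subtracted mean, counts), `background`,
#'   `excluded` (logical), `reason`.
#' @export
subtract_background <- function(profile, edge_len = 5, on_span = NULL,
                                channel = "antibody") {
  stopifnot(inherits(profile, "linescan_profile"))
  v <- profile$channels[[channel]]
  if (is.null(v)) stop("channel '", channel, "' not present in the profile")
  n <- length(v)
  if (n < 2 * edge_len + 3) stop("profile too short for edge_len = ", edge_len)
  s <- profile$arclength
  bg <- mean(v[c(seq_len(edge_len), seq(n - edge_len + 1, n))])
  if (is.null(on_span)) {
    sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- v[is.na(sm)]
    half <- bg + (max(sm) - bg) / 2
    on <- which(sm >= half)
    if (length(on) < 2) {
      return(list(value = NA_real_, background = bg, excluded = TRUE,
                  reason = "no signal above half-maximum"))
    }
    on_span <- c(s[min(on)], s[max(on)])
  }
  on_idx <- which(s >= on_span[1] & s <= on_span[2])
  value <- mean(v[on_idx]) - bg
  if (bg > mean(v[on_idx])) {
    return(list(value = value, background = bg, excluded = TRUE,
                reason = "edge background above on-microtubule mean"))
  }
  list(value = value, background = bg, excluded = FALSE, reason = NA_character_)
}

#' Normalized antibody intensity of a field of view
#'
#' Per-microtubule background-subtracted antibody means are averaged over the
#' field of view (FOV) and normalized against the FOV's mean seed-channel
#' intensity:
#' `normalized = 100 * mean(per-MT antibody means) / mean(seed intensity)`.
#' The factor 100 is a reporting convention placing typical values on a
#' convenient scale. Per-microtubule normalized values are also returned for
#' dot plots. Excluded microtubules are enumerated with reasons.
#'
#' @param fov an `fov_image`.
#' @param traces list of per-MT traces (`x`, `y`, optional `on_span_px`);
#'   defaults to the rendered ground truth.
#' @param seed_masks list of linear pixel-index vectors, one per seed;
#'   defaults to the rendered ground truth.
#' @param width,edge_len linescan parameters.
#' @param channel,seed_channel channel names.
#' @return Object of class `fov_quantification`: `per_mt` data frame
#'   (`mt_id`, `value`, `normalized`, `excluded`, `reason`), `fov_mean`,
#'   `seed_mean`, `normalized`, `n_microtubules`, `n_seeds`, `n_excluded`.
#' @export
fov_normalized_intensity <- function(fov, traces = NULL, seed_masks = NULL,
                                     width = 2, edge_len = 5,
                                     channel = "antibody",
                                     seed_channel = "seed") {
  stopifnot(inherits(fov, "fov_image"))
  if (is.null(traces)) traces <- fov$ground_truth$traces
  if (is.null(seed_masks)) seed_masks <- fov$ground_truth$seed_masks
  if (length(traces) < 1) stop("need at least one microtubule trace")
  if (length(seed_masks) < 1) stop("need at least one seed")

  per <- lapply(traces, function(tr) {
    pr <- linescan_profile(fov, tr, width = width)
    on_span <- if (!is.null(tr$on_span_px)) tr$on_span_px else NULL
    sb <- subtract_background(pr, edge_len = edge_len, on_span = on_span,
                              channel = channel)
    data.frame(mt_id = tr$mt_id %||% NA, value = sb$value,
               excluded = sb$excluded, reason = sb$reason)
  })
  per <- do.call(rbind, per)

  simg <- fov$channels[[seed_channel]]
  all_mask <- unique(unlist(seed_masks))
  bg_seed <- stats::median(simg[-all_mask])
  seed_means <- vapply(seed_masks, function(idx) mean(simg[idx]) - bg_seed,
                       numeric(1))
  seed_mean <- mean(seed_means)
  if (!is.finite(seed_mean) || seed_mean <= 0)
    stop("seed-channel signal is zero; normalization undefined")

  ok <- !per$excluded & is.finite(per$value)
  if (!any(ok)) stop("no valid microtubules in this FOV")
  fov_mean <- mean(per$value[ok])
  per$normalized <- 100 * per$value / seed_mean
  structure(list(per_mt = per, fov_mean = fov_mean, seed_mean = seed_mean,
                 normalized = 100 * fov_mean / seed_mean,
                 n_microtubules = sum(ok), n_seeds = length(seed_masks),
                 n_excluded = sum(!ok)),
            class = "fov_quantification")
}

#' @export
print.fov_quantification <- function(x, ...) {
  cat(sprintf(
    "FOV: %d microtubules (%d excluded), %d seeds\nmean antibody %.2f, mean seed %.2f, normalized intensity %.2f\n",
    x$n_microtubules, x$n_excluded, x$n_seeds, x$fov_mean, x$seed_mean,
    x$normalized))
  invisible(x)
}

#' Total antibody signal per seed
#'
#' Background-corrected total of the antibody channel divided by the number
#' of seeds in the field of view: the background per pixel is estimated from
#' a user-supplied signal-free region and multiplied by the total pixel
#' count before subtraction.
#'
#' @param fov an `fov_image`.
#' @param seed_count number of seeds observed (>= 1).
#' @param bg_region signal-free region given as `c(row_lo, row_hi, col_lo,
#'   col_hi)`; required — no default region is guessed.
#' @param channel channel name.
#' @return Background-corrected counts per seed.
#' @export
per_seed_total_signal <- function(fov, seed_count, bg_region,
                                  channel = "antibody") {
  stopifnot(inherits(fov, "fov_image"))
  if (seed_count < 1) stop("seed_count must be >= 1")
  if (missing(bg_region) || is.null(bg_region))
    stop("no signal-free region available: supply 'bg_region' = c(row_lo, row_hi, col_lo, col_hi)")
  img <- fov$channels[[channel]]
  if (is.null(img)) stop("channel '", channel, "' not present")
  bg <- img[bg_region[1]:bg_region[2], bg_region[3]:bg_region[4]]
  (sum(img) - mean(bg) * length(img)) / seed_count
}
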