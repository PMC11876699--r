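## FFT cross-correlation between two frames; returns the (dx, dy) shift of
## `b` relative to `a` (b approx a translated by +(dx, dy)), with subpixel
## refinement by quadratic interpolation of the correlation peak.
.pairwise_shift <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("flat (zero-variance) frame: shift undefined")
  ny <- nrow(a); nx <- ncol(a)
  ## mean-subtract and edge-taper (Hann window) to suppress wraparound
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
  w <- outer(wy, wx)
  aw <- (a - mean(a)) * w
  bw <- (b - mean(b)) * w
  cc <- Re(stats::fft(stats::fft(bw) * Conj(stats::fft(aw)), inverse = TRUE))
  p <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy <- wrap(p[1], ny); dx <- wrap(p[2], nx)
  ## quadratic subpixel refinement from the peak and its neighbours
  idx <- function(i, n) ((i - 1) %% n) + 1
  sub <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else {
      d <- (cm - cp) / (2 * den)
      max(min(d, 0.5), -0.5)
    }
  }
  ddy <- sub(cc[idx(p[1] - 1, ny), p[2]], cc[p[1], p[2]], cc[idx(p[1] + 1, ny), p[2]])
  ddx <- sub(cc[p[1], idx(p[2] - 1, nx)], cc[p[1], p[2]], cc[p[1], idx(p[2] + 1, nx)])
  c(dx = dx + ddx, dy = dy + ddy)
}

#' Estimate rigid per-frame drift by cross-correlation
#'
#' Measures the translation between successive frames from the peak of their
#' cross-correlation (computed by FFT on mean-subtracted, Hann-tapered
#' frames) with subpixel refinement by quadratic interpolation of the peak
#' and its neighbours, then accumulates the pairwise shifts relative to the
#' first frame.
#'
#' @param movie a 3-D array `[ny, nx, nframes]`, or a named list of such
#'   arrays; `channel` selects the channel to measure on.
#' @param channel channel name when `movie` is multichannel.
#' @return Object of class `drift_track`: data frame with columns `frame`,
#'   `dx`, `dy` (cumulative displacement, px; frame 1 is the reference at
#'   (0, 0)).
#' @export
estimate_drift <- function(movie, channel = NULL) {
  if (is.list(movie) && !is.array(movie)) {
    if (is.null(channel)) stop("multichannel movie: specify 'channel'")
    if (!channel %in% names(movie)) stop("channel '", channel, "' not present")
    movie <- movie[[channel]]
  }
  stopifnot(length(dim(movie)) == 3)
  nf <- dim(movie)[3]
  if (nf < 2) stop("need at least 2 frames to estimate drift")
  steps <- t(vapply(seq_len(nf - 1), function(k) {
    .pairwise_shift(movie[, , k], movie[, , k + 1])
  }, c(dx = 0, dy = 0)))
  track <- data.frame(frame = seq_len(nf),
                      dx = c(0, cumsum(steps[, "dx"])),
                      dy = c(0, cumsum(steps[, "dy"])))
  class(track) <- c("drift_track", "data.frame")
  track
}

#' Correct a movie for measured drift
#'
#' Translates every frame of every channel by the negated cumulative
#' displacement (bilinear interpolation for subpixel shifts); uncovered edges
#' are filled with the frame's median background estimate.
#'
#' @inheritParams estimate_drift
#' @param track a `drift_track` from [estimate_drift()] (or any data frame
#'   with cumulative `dx`, `dy` per frame).
#' @return Movie of the same structure as the input.
#' @export
correct_drift <- function(movie, track) {
  nf <- if (is.array(movie)) dim(movie)[3] else dim(movie[[1]])[3]
  if (nrow(track) != nf)
    stop("drift track length (", nrow(track), ") != frame count (", nf, ")")
  neg <- data.frame(dx = -track$dx, dy = -track$dy)
  apply_drift(movie, neg, fill = NULL)
}
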