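#' Extract tip trajectories from a kymograph
#'
#' Localizes, per frame and per side of the seed, the microtubule tip as the
#' farthest half-maximum crossing of the smoothed intensity profile beyond
#' the seed, linearly interpolated to subpixel. The half-maximum level is
#' half of the kymograph's robust plateau amplitude (the median of per-frame
#' maxima beyond the seed over frames with clear signal) above the per-frame
#' baseline estimated from the outermost pixels, which makes the crossing sit
#' exactly at the tip for an edge blurred by a symmetric PSF and makes the
#' localization invariant to constant intensity offsets. Frames with no
#' signal beyond the seed get the position of the seed edge and quality
#' `"none"`.
#'
#' @param kymo a `kymograph` (frames x pixels), e.g. from
#'   [render_kymograph()].
#' @param seed_extent integer column range `c(lo, hi)` of the seed; defaults
#'   to the kymograph's own.
#' @param channel channel to analyse (default `"tubulin"`).
#' @param smooth running-mean window (px, odd) applied along each profile.
#' @param edge_px pixels at each spatial edge used for the baseline.
#' @return Object of class `tip_trajectory`: list with elements `right` and
#'   `left`, each a data frame (`frame`, `time`, `position` um along the
#'   axis, `dist` um beyond the seed edge, `quality`), plus calibration
#'   fields.
#' @export
extract_tip_trajectory <- function(kymo, seed_extent = NULL,
                                   channel = "tubulin", smooth = 3,
                                   edge_px = 5) {
  stopifnot(inherits(kymo, "kymograph"))
  P <- kymo$channels[[channel]]
  if (is.null(P)) stop("channel '", channel, "' not present")
  npx <- ncol(P); nf <- nrow(P)
  if (is.null(seed_extent)) seed_extent <- kymo$seed_extent
  if (seed_extent[1] < 1 || seed_extent[2] > npx || seed_extent[1] > seed_extent[2])
    stop("seed extent [", seed_extent[1], ", ", seed_extent[2],
         "] outside the image (1..", npx, ")")
  ps <- kymo$pixel_size

  ## running-mean smoothing along the spatial axis
  if (smooth > 1) {
    kern <- rep(1 / smooth, smooth)
    Ps <- t(apply(P, 1, function(r) {
      f <- stats::filter(r, kern, sides = 2)
      f[is.na(f)] <- r[is.na(f)]
      as.numeric(f)
    }))
  } else Ps <- P

  edge_cols <- c(seq_len(min(edge_px, npx)), seq(npx - min(edge_px, npx) + 1, npx))
  baseline <- apply(Ps[, edge_cols, drop = FALSE], 1, stats::median)
  noise <- stats::mad(as.numeric(P[, edge_cols]) -
                        rep(baseline, times = length(edge_cols)))

  one_side <- function(side) {
    if (side == "right") {
      cols <- seq(seed_extent[2] + 1, npx)
      edge_col <- seed_extent[2]
    } else {
      cols <- rev(seq_len(seed_extent[1] - 1))   # ordered seed -> edge
      edge_col <- seed_extent[1]
    }
    S <- Ps[, cols, drop = FALSE] - baseline
    mx <- apply(S, 1, max)
    clear <- mx > 5 * noise
    amp <- if (any(clear)) stats::median(mx[clear]) else NA_real_
    pos_px <- rep(NA_real_, nf)        # subpixel offset from seed edge, >= 0
    quality <- rep("none", nf)
    if (is.finite(amp) && amp > 0) {
      level <- amp / 2
      for (f in seq_len(nf)) {
        above <- which(S[f, ] >= level)
        if (length(above) == 0) next
        j <- max(above)
        if (j < ncol(S)) {
          frac <- (S[f, j] - level) / (S[f, j] - S[f, j + 1])
          pos_px[f] <- j + max(min(frac, 1), 0)
          quality[f] <- if (mx[f] >= 0.75 * amp) "ok" else "low"
        } else {
          pos_px[f] <- j
          quality[f] <- "edge"          # tip at the image border
        }
      }
    }
    dist <- ifelse(is.na(pos_px), 0, pos_px * ps)
    dirn <- if (side == "right") 1 else -1
    position <- kymo$origin + (edge_col - 1) * ps + dirn * dist
    data.frame(frame = seq_len(nf), time = kymo$times,
               position = position, dist = dist, quality = quality)
  }

  structure(list(right = one_side("right"), left = one_side("left"),
                 pixel_size = ps, frame_interval = kymo$frame_interval,
                 seed_extent = seed_extent, origin = kymo$origin,
                 mt_id = kymo$mt_id),
            class = "tip_trajectory")
}

#' Segment growth events from a tip trajectory
#'
#' Detects growth events on one side of the seed: growth is registered once
#' the tip exceeds the seed edge by a threshold (default 3 px); a catastrophe
#' is registered where the tip regresses by more than the threshold within
#' one frame interval or falls back to the seed edge. The onset is then
#' refined backwards to the frame at which the tip left the seed edge, so
#' lifetimes are not biased by the detection threshold. Events still growing
#' at the last frame are flagged censored (the catastrophe frame is the last
#' frame before the collapse).
#'
#' @param traj a `tip_trajectory` from [extract_tip_trajectory()].
#' @param side `"right"` or `"left"`.
#' @param threshold_px detection/regression threshold in pixels.
#' @return Data frame of growth events: `side`, `onset_frame`, `onset_time`,
#'   `cat_frame`, `cat_time` (`NA` when censored), `censored`, `lifetime`
#'   (s, `NA` when censored), `n_frames`.
#' @export
segment_growth_events <- function(traj, side = c("right", "left"),
                                  threshold_px = 3) {
  side <- match.arg(side)
  tr <- traj[[side]]
  empty <- data.frame(side = character(0), onset_frame = integer(0),
                      onset_time = numeric(0), cat_frame = integer(0),
                      cat_time = numeric(0), censored = logical(0),
                      lifetime = numeric(0), n_frames = integer(0))
  if (nrow(tr) == 0) return(empty)
  ps <- traj$pixel_size
  thr <- threshold_px * ps
  eps <- 0.75 * ps
  d <- tr$dist
  nf <- length(d)
  ev <- list()
  state <- "idle"
  onset <- NA_integer_
  f <- 1
  while (f <= nf) {
    if (state == "idle") {
      if (d[f] > thr) {
        ## refine onset: walk back to the last frame at the seed edge
        o <- f
        while (o > 1 && d[o - 1] > eps) o <- o - 1
        onset <- max(o - 1L, 1L)
        state <- "growing"
      }
      f <- f + 1
    } else {
      collapsed <- (d[f] < d[f - 1] - thr) || (d[f] <= eps)
      if (collapsed) {
        ev[[length(ev) + 1]] <- data.frame(
          side = side, onset_frame = onset, onset_time = tr$time[onset],
          cat_frame = f - 1L, cat_time = tr$time[f - 1],
          censored = FALSE,
          lifetime = tr$time[f - 1] - tr$time[onset],
          n_frames = f - onset)
        state <- "idle"
        onset <- NA_integer_
      }
      f <- f + 1
    }
  }
  if (state == "growing") {
    ev[[length(ev) + 1]] <- data.frame(
      side = side, onset_frame = onset, onset_time = tr$time[onset],
      cat_frame = nf, cat_time = NA_real_, censored = TRUE,
      lifetime = NA_real_, n_frames = nf - onset + 1L)
  }
  if (length(ev) == 0) return(empty)
  do.call(rbind, ev)
}

#' Growth speed of one event by least squares
#'
#' Ordinary least-squares slope of tip position versus time over the full
#' event, converted to um/min. Frames with quality `"none"` are excluded.
#'
#' @param event one row of the data frame from [segment_growth_events()].
#' @param traj the `tip_trajectory` the event was segmented from.
#' @return List with `speed` (um/min), `residual_sd` (um), `n_frames`;
#'   `speed` is `NA` (with a warning) when fewer than 3 usable frames remain.
#' @export
estimate_growth_speed <- function(event, traj) {
  tr <- traj[[event$side]]
  rows <- seq(event$onset_frame, event$cat_frame)
  ## only frames with a full-amplitude plateau: while the extension is
  ## shorter than a few PSF widths the half-maximum crossing localizes
  ## short, which would steepen the slope
  use <- rows[tr$quality[rows] == "ok"]
  if (length(use) < 3) {
    warning("event dropped: fewer than 3 usable frames")
    return(list(speed = NA_real_, residual_sd = NA_real_, n_frames = length(use)))
  }
  t <- tr$time[use]; x <- tr$dist[use]
  fit <- stats::lm.fit(cbind(1, t), x)
  list(speed = unname(fit$coefficients[2]) * 60,
       residual_sd = stats::sd(fit$residuals),
       n_frames = length(use))
}

#' Lifetimes of uncensored growth events
#'
#' @param events data frame from [segment_growth_events()] (possibly several
#'   sides/microtubules bound together).
#' @return Numeric vector of uncensored lifetimes (s) with attribute
#'   `n_censored`.
#' @export
extract_lifetimes <- function(events) {
  lt <- events$lifetime[!events$censored]
  attr(lt, "n_censored") <- sum(events$censored)
  lt
}

#' Assign microtubule polarity from per-side growth speeds
#'
#' The side of the seed with the larger mean growth speed is labelled the
#' plus end (fast-growing), the other the minus end. Ties are broken toward
#' the side with more events, then lexicographically by side name (and the
#' assignment is flagged ambiguous). Seeds with events on a single side are
#' labelled `"unknown"` rather than guessed.
#'
#' @param speeds_by_side named list with numeric speed vectors for sides
#'   `"right"` and `"left"` (um/min).
#' @return List: `labels` (named character vector side -> label),
#'   `ambiguous` (logical).
#' @export
assign_polarity <- function(speeds_by_side) {
  sides <- c("right", "left")
  n <- vapply(sides, function(s) length(speeds_by_side[[s]]), integer(1))
  if (any(n == 0)) {
    lab <- stats::setNames(rep("unknown", 2), sides)
    return(list(labels = lab, ambiguous = FALSE))
  }
  m <- vapply(sides, function(s) mean(speeds_by_side[[s]]), numeric(1))
  ambiguous <- FALSE
  if (m[1] != m[2]) {
    plus <- sides[which.max(m)]
  } else if (n[1] != n[2]) {
    plus <- sides[which.max(n)]
    ambiguous <- TRUE
  } else {
    plus <- sort(sides)[1]
    ambiguous <- TRUE
  }
  minus <- setdiff(sides, plus)
  list(labels = stats::setNames(c("plus", "minus"), c(plus, minus))[sides],
       ambiguous = ambiguous)
}

#' Full kymograph analysis
#'
#' Convenience chain: tip extraction, event segmentation on both sides,
#' speed estimation per event, polarity assignment.
#'
#' @inheritParams extract_tip_trajectory
#' @param threshold_px catastrophe/onset detection threshold (px).
#' @return Data frame of events with `end` labels, fitted `speed` (um/min),
#'   `residual_sd`, `lifetime` and `censored`; events with fewer than 3
#'   usable frames are dropped (counted in attribute `n_dropped`).
#' @export
analyze_kymograph <- function(kymo, seed_extent = NULL, channel = "tubulin",
                              threshold_px = 3) {
  traj <- extract_tip_trajectory(kymo, seed_extent = seed_extent, channel = channel)
  evs <- rbind(segment_growth_events(traj, "right", threshold_px),
               segment_growth_events(traj, "left", threshold_px))
  if (nrow(evs) == 0) {
    out <- cbind(evs, speed = numeric(0), residual_sd = numeric(0), end = character(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  sp <- lapply(seq_len(nrow(evs)), function(i)
    suppressWarnings(estimate_growth_speed(evs[i, ], traj)))
  evs$speed <- vapply(sp, `[[`, numeric(1), "speed")
  evs$residual_sd <- vapply(sp, `[[`, numeric(1), "residual_sd")
  dropped <- is.na(evs$speed)
  pol <- assign_polarity(list(
    right = evs$speed[evs$side == "right" & !dropped],
    left = evs$speed[evs$side == "left" & !dropped]))
  evs$end <- unname(pol$labels[evs$side])
  out <- evs[!dropped, , drop = FALSE]
  attr(out, "n_dropped") <- sum(dropped)
  attr(out, "ambiguous_polarity") <- pol$ambiguous
  out
}
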