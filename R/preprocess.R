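#' Pre-processing configuration
#'
#' The three-stage trajectory conditioning chain: (1) median filter with an
#' 8-sample window against impulsive tracking noise, (2) cubic-spline
#' resampling to a uniform 50 Hz grid, (3) third-order low-pass Butterworth
#' at 10 Hz (zero-phase by default), which retains the voluntary-movement
#' band while suppressing tremor interference (> 7.5 Hz).
#'
#' @param median_window median filter window in samples (>= 1)
#' @param target_rate resampling rate in Hz
#' @param butter_order Butterworth filter order
#' @param butter_cutoff cutoff frequency in Hz, must be below
#'   `target_rate / 2`
#' @param zero_phase apply the filter forward-backward (non-causal, no lag;
#'   effective squared magnitude response); `FALSE` gives a single causal
#'   pass
#' @return object of class `preprocess_config`
#' @export
preprocess_config <- function(median_window = 8L, target_rate = 50,
                              butter_order = 3L, butter_cutoff = 10,
                              zero_phase = TRUE) {
  if (median_window < 1) stop("median_window must be >= 1")
  if (butter_cutoff <= 0 || butter_cutoff >= target_rate / 2) {
    stop("butter_cutoff must lie in (0, target_rate/2)")
  }
  structure(list(median_window = as.integer(median_window),
                 target_rate = target_rate,
                 butter_order = as.integer(butter_order),
                 butter_cutoff = butter_cutoff,
                 zero_phase = isTRUE(zero_phase)),
            class = "preprocess_config")
}

#' Sliding-window median filter
#'
#' Removes impulsive spikes and tracking outliers while preserving signal
#' edges. Window convention: for window `w` the output at sample `i` is the
#' median of samples `i - floor(w/2)` .. `i + w - 1 - floor(w/2)` (for the
#' default even window of 8: `i-4 .. i+3`, left-heavy center; the median of
#' an even count is the mean of the two middle order statistics). Edges use
#' nearest-value (replicate) padding, so output length equals input length.
#' Non-finite samples are ignored within each window (`NA` only where a
#' whole window is non-finite).
#'
#' @param x numeric series (length >= 1)
#' @param window window size in samples
#' @return filtered series, same length as `x`
#' @export
median_filter <- function(x, window = 8L) {
  if (!length(x)) stop("series must be non-empty")
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  if (window == 1L || length(x) == 1L) return(x)
  L <- length(x)
  lw <- window %/% 2L
  offs <- seq.int(-lw, window - 1L - lw)
  idx <- outer(seq_len(L), offs, `+`)
  idx[idx < 1L] <- 1L
  idx[idx > L] <- L
  m <- matrix(x[idx], nrow = L)
  if (anyNA(m) || any(!is.finite(m))) {
    m[!is.finite(m)] <- NA_real_
    return(apply(m, 1, stats::median, na.rm = TRUE))
  }
  row_medians(m)
}

# Vectorized row medians via a bubble sorting network of pmin/pmax passes:
# O(w^2) vectorized compare-exchanges instead of L median() calls.
row_medians <- function(m) {
  w <- ncol(m)
  for (i in seq_len(w - 1L)) {
    for (j in seq_len(w - i)) {
      a <- m[, j]
      b <- m[, j + 1L]
      m[, j] <- pmin(a, b)
      m[, j + 1L] <- pmax(a, b)
    }
  }
  if (w %% 2L == 1L) m[, (w + 1L) %/% 2L]
  else (m[, w %/% 2L] + m[, w %/% 2L + 1L]) / 2
}

#' Cubic-spline resampling to a uniform grid
#'
#' Fits an interpolating cubic spline (Forsythe-Malcolm-Moler end
#' conditions, exact on polynomials up to degree 3) through the finite
#' samples and evaluates it on a uniform grid spanning exactly the first to
#' the last timestamp at (as close as possible to) `target_rate`. Flagged /
#' non-finite samples are excluded from spline construction and re-created
#' by the interpolant.
#'
#' @param x numeric series
#' @param timestamps strictly increasing sample times in seconds
#' @param target_rate target sampling rate in Hz
#' @return list with `x` (resampled series) and `timestamps` (uniform grid)
#' @export
resample_cubic <- function(x, timestamps, target_rate = 50) {
  if (length(x) != length(timestamps)) {
    stop("series and timestamps must have equal length")
  }
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  ok <- is.finite(x) & is.finite(timestamps)
  if (sum(ok) < 4) stop("need at least 4 finite samples for cubic resampling")
  t0 <- timestamps[1]
  t1 <- timestamps[length(timestamps)]
  n_out <- max(2L, as.integer(round((t1 - t0) * target_rate)) + 1L)
  grid <- seq(t0, t1, length.out = n_out)
  sf <- stats::splinefun(timestamps[ok], x[ok], method = "fmm")
  list(x = sf(grid), timestamps = grid)
}

#' Low-pass Butterworth filter
#'
#' Digital Butterworth (bilinear transform, prewarped at the cutoff) applied
#' either as a single causal pass or forward-backward (zero-phase; squared
#' magnitude response, no lag). Edge transients are controlled by
#' odd-symmetric (antisymmetric) extension of the series plus removal of the
#' leading value before filtering, so a constant series passes through
#' unchanged (exact unity DC gain) even at the edges.
#'
#' @param x uniformly sampled series
#' @param rate sampling rate in Hz
#' @param order filter order
#' @param cutoff cutoff frequency in Hz, must be below the Nyquist rate
#' @param zero_phase forward-backward application
#' @return filtered series, same length as `x`
#' @export
butterworth_lowpass <- function(x, rate, order = 3L, cutoff = 10,
                                zero_phase = TRUE) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0) stop("cutoff must be positive")
  L <- length(x)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  p <- min(3L * (order + 1L), L - 1L)
  if (p < 1L) return(x)
  c0 <- x[1]
  front <- 2 * x[1] - x[seq.int(p + 1L, 2L)]
  back <- 2 * x[L] - x[seq.int(L - 1L, L - p)]
  xe <- c(front, x, back) - c0
  y <- as.numeric(signal::filter(bf, xe))
  if (zero_phase) {
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
  }
  y[seq.int(p + 1L, p + L)] + c0
}

#' Theoretical magnitude response of the digital Butterworth stage
#'
#' Closed-form gain of the implemented (bilinear, prewarped) digital filter
#' at frequency `f`: `1/sqrt(1 + (tan(pi f / rate) / tan(pi cutoff / rate))^(2 order))`,
#' squared when `zero_phase`. Used by the validation suite as an
#' implementation-independent oracle.
#'
#' @param f frequency in Hz
#' @param rate sampling rate in Hz
#' @inheritParams butterworth_lowpass
#' @return gain in \[0, 1\]
#' @export
butterworth_gain <- function(f, rate, order = 3L, cutoff = 10,
                             zero_phase = TRUE) {
  wr <- tan(pi * f / rate) / tan(pi * cutoff / rate)
  g <- 1 / sqrt(1 + wr^(2 * order))
  if (zero_phase) g^2 else g
}

#' Condition a trial's landmark trajectory
#'
#' Applies the full pre-processing chain (median filter, cubic-spline
#' resampling, Butterworth low-pass) independently to each of the three
#' coordinate components of each of the 33 landmarks. Trial timestamps are
#' replaced by the uniform grid; event timestamps are unchanged. Flagged
#' frames are interpolated over by the spline stage, so the conditioned
#' trajectory has no flagged frames.
#'
#' @param trial a `trial_record`
#' @param config a [preprocess_config()]
#' @return the trial with a conditioned trajectory (`$preprocessed` set to
#'   `TRUE`)
#' @export
preprocess_trajectory <- function(trial, config = preprocess_config()) {
  stopifnot(inherits(trial, "trial_record"))
  tr <- trial$trajectory
  ts <- tr$timestamps
  L <- length(ts)
  pos <- tr$positions
  flat <- matrix(pos, nrow = L)  # L x 99, column-major over (landmark, coord)

  # Stage 1: median filter every channel (vectorized across channels when
  # the window has no missing data).
  w <- config$median_window
  if (w > 1L && L > 1L) {
    lw <- w %/% 2L
    offs <- seq.int(-lw, w - 1L - lw)
    idx <- outer(seq_len(L), offs, `+`)
    idx[idx < 1L] <- 1L
    idx[idx > L] <- L
    if (all(is.finite(flat))) {
      med <- matrix(NA_real_, L, ncol(flat))
      for (ch in seq_len(ncol(flat))) {
        med[, ch] <- row_medians(matrix(flat[idx, ch], nrow = L))
      }
      flat <- med
    } else {
      flat <- apply(flat, 2, median_filter, window = w)
    }
  }

  # Stage 2 + 3: per channel, spline to the uniform grid then Butterworth.
  first <- resample_cubic(flat[, 1], ts, config$target_rate)
  grid <- first$timestamps
  rate <- if (length(grid) > 1) 1 / mean(diff(grid)) else config$target_rate
  out <- matrix(NA_real_, nrow = length(grid), ncol = ncol(flat))
  for (ch in seq_len(ncol(flat))) {
    rs <- if (ch == 1) first else resample_cubic(flat[, ch], ts, config$target_rate)
    out[, ch] <- butterworth_lowpass(rs$x, rate = rate,
                                     order = config$butter_order,
                                     cutoff = config$butter_cutoff,
                                     zero_phase = config$zero_phase)
  }
  new_pos <- array(out, dim = c(length(grid), n_pose_landmarks(), 3))
  trial$trajectory <- landmark_trajectory(grid, new_pos,
                                          nominal_fps = config$target_rate,
                                          landmark_names = tr$landmark_names)
  trial$preprocessed <- TRUE
  trial
}
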