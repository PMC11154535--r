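#' Cardiac features from the green channel
#'
#' Subtle blood-flow color changes modulate the green channel of the pixels
#' over the animal's body. A square region C of `gamma_px` pixels centered
#' on the centroid is averaged per frame into a trace H(t); bandpass
#' filtering isolates the cardiac band, peaks give inter-beat intervals
#' T(t), and the heart-rate proxy is h(t) = t_h / T with t_h a scaling
#' constant in seconds (the default passband 4.76-7.14 Hz corresponds to
#' 285-428 beats/min, a small rodent's range).
#'
#' @name cardiac-features
NULL

#' Mean green value over region C, per frame
#'
#' For each frame, averages the green channel over the `gamma_px`-sided
#' square centered at the centroid, clipped to image bounds. Frames with an
#' invalid centroid or mask area below `alpha_th` yield `NA` (the heartbeat
#' information is not extracted there).
#'
#' @param frames A frame source (see [as_frame_source()]).
#' @param centroids n x 2 matrix of `(Gx, Gy)` per frame (`NA` rows allowed).
#' @param gamma_px Side of region C in pixels (positive).
#' @param areas Mask pixel counts per frame.
#' @param alpha_th Minimum valid area (pixels^2).
#' @return Numeric series of length n with `NA` gaps.
#' @export
green_trace <- function(frames, centroids, gamma_px, areas, alpha_th) {
  if (!is_scalar_num(gamma_px) || gamma_px <= 0)
    stop("gamma_px must be a positive scalar")
  src <- as_frame_source(frames)
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == src$n, length(areas) == src$n)
  half <- gamma_px / 2
  out <- rep(NA_real_, src$n)
  for (i in seq_len(src$n)) {
    if (anyNA(centroids[i, ]) || areas[i] < alpha_th) next
    fr <- src$get(i)
    d <- dim(fr)
    cx <- centroids[i, 1]; cy <- centroids[i, 2]
    x0 <- max(0, round(cx - half)); x1 <- min(d[2] - 1, round(cx + half))
    y0 <- max(0, round(cy - half)); y1 <- min(d[1] - 1, round(cy + half))
    if (x1 < x0 || y1 < y0) next
    out[i] <- mean(fr[(y0:y1) + 1, (x0:x1) + 1, 2])
  }
  out
}

# mean green over region C for a single frame (used by the streaming pipeline)
green_mean_region_c <- function(frame, centroid, gamma_px) {
  d <- dim(frame)
  half <- gamma_px / 2
  x0 <- max(0, round(centroid[1] - half)); x1 <- min(d[2] - 1, round(centroid[1] + half))
  y0 <- max(0, round(centroid[2] - half)); y1 <- min(d[1] - 1, round(centroid[2] + half))
  if (x1 < x0 || y1 < y0) return(NA_real_)
  mean(frame[(y0:y1) + 1, (x0:x1) + 1, 2])
}

#' Bandpass filter a trace with a second-order Butterworth design
#'
#' Zero-phase (forward-backward) application by default, so peak times are
#' not delayed by the filter's group delay; a causal single-pass variant is
#' available for live use. `NA` gaps are bridged by linear interpolation
#' before filtering and re-masked to `NA` afterwards, which keeps filter
#' edge transients from fabricating beats inside gaps.
#'
#' @param x Numeric series (may contain `NA` gaps).
#' @param fl,fh Lower/upper cutoff in Hz, `fl < fh < fs / 2`.
#' @param fs Sampling rate in Hz.
#' @param zero_phase Forward-backward filtering. Default `TRUE`.
#' @return Filtered series, same length as `x`, `NA` where `x` was `NA`.
#' @export
bandpass <- function(x, fl, fh, fs, zero_phase = TRUE) {
  stopifnot(is_scalar_num(fl), is_scalar_num(fh), is_scalar_num(fs))
  if (!(fl > 0 && fl < fh && fh < fs / 2))
    stop("cutoffs must satisfy 0 < fl < fh < fs/2 (Nyquist)")
  if (sum(!is.na(x)) < 12L)
    stop("series too short for the filter warm-up (need >= 12 finite samples)")
  na <- is.na(x)
  xi <- x
  if (any(na)) {
    idx <- which(!na)
    xi <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  }
  bf <- signal::butter(2, c(fl, fh) / (fs / 2), type = "pass")
  y <- if (zero_phase) signal::filtfilt(bf, xi)
       else as.numeric(signal::filter(bf, xi))
  y[na] <- NA_real_
  y
}

#' Peak detection by local mountain climbing
#'
#' A sample is a peak when it exceeds every sample in a window of
#' `floor(fs / (2 * fh))` samples on each side — half a period of the upper
#' cutoff frequency, so the tightest rhythm the passband admits keeps every
#' beat while sub-period jitter peaks are suppressed — with ties broken to
#' the earliest index (the first sample of a plateau of equal maxima wins).
#' Candidates whose window touches the series boundary or an `NA` gap are
#' not reported, so no peak is ever emitted inside or adjacent to a masked
#' gap.
#'
#' @param filtered Filtered series (may contain `NA` gaps).
#' @param fs Sampling rate in Hz.
#' @param fh Upper cutoff in Hz (sets the minimum peak spacing).
#' @return Numeric vector of peak times in seconds (`(index - 1) / fs`),
#'   possibly empty.
#' @export
find_peaks_mountain_climbing <- function(filtered, fs, fh) {
  n <- length(filtered)
  if (n == 0L) stop("empty series")
  w <- max(1L, floor(fs / (2 * fh)))
  peaks <- integer(0)
  for (i in seq_len(n)) {
    if (i - w < 1L || i + w > n) next
    win <- filtered[(i - w):(i + w)]
    if (anyNA(win)) next
    xi <- filtered[i]
    left <- filtered[(i - w):(i - 1L)]
    right <- filtered[(i + 1L):(i + w)]
    if (all(xi > left) && all(xi >= right)) peaks <- c(peaks, i)
  }
  (peaks - 1) / fs
}

#' Heart-rate series from peak times
#'
#' Each consecutive peak pair gives an inter-beat interval T and an
#' instantaneous rate `t_h / T` (beats per `t_h`-second window; the raw
#' frequency is `1 / T` Hz). The rate becomes known at the second peak of
#' its pair and is held (zero-order hold) until the next peak, and after
#' the last peak to the end of the series; frames before the second peak
#' have no rate.
#'
#' @param peaks Sorted peak times in seconds.
#' @param t_h Scaling constant in seconds (default 0.7).
#' @param fs Frame rate in Hz.
#' @param n_frames Length of the output series.
#' @return Numeric series of length `n_frames`, `NA` where no rate is
#'   defined.
#' @export
heart_rate <- function(peaks, t_h = 0.7, fs, n_frames) {
  stopifnot(is_scalar_num(t_h), t_h > 0, is_scalar_num(fs), fs > 0)
  out <- rep(NA_real_, n_frames)
  if (length(peaks) < 2L) return(out)
  if (is.unsorted(peaks, strictly = TRUE)) stop("peaks must be strictly increasing")
  ft <- (seq_len(n_frames) - 1) / fs
  intervals <- diff(peaks)
  # rate from pair (t[i-1], t[i]) is in effect from t[i] (inclusive) onward
  idx <- findInterval(ft, peaks[-1])          # 0 before 2nd peak
  has <- idx >= 1L
  out[has] <- t_h / intervals[pmin(idx[has], length(intervals))]
  out
}

#' Full cardiac trace from a raw green series
#'
#' Runs [bandpass()], [find_peaks_mountain_climbing()], and [heart_rate()]
#' and bundles the results.
#'
#' @param raw Raw green-channel series H(t) (with `NA` gaps).
#' @param fs Frame rate in Hz.
#' @param fl,fh Passband cutoffs in Hz (defaults 4.76 and 7.14).
#' @param t_h Rate scaling constant in seconds (default 0.7).
#' @param zero_phase Passed to [bandpass()].
#' @return A `cardiac_trace`: list with `raw`, `filtered`, `peaks` (times,
#'   s), `intervals` (s), `rate` (per-frame series) and `params`.
#' @export
cardiac_trace <- function(raw, fs, fl = 4.76, fh = 7.14, t_h = 0.7,
                          zero_phase = TRUE) {
  if (sum(!is.na(raw)) < 12L) {
    # not enough signal to filter (e.g. the animal was never detected)
    return(structure(list(raw = raw, filtered = rep(NA_real_, length(raw)),
                          peaks = numeric(0), intervals = numeric(0),
                          rate = rep(NA_real_, length(raw)),
                          params = list(fl = fl, fh = fh, fs = fs, t_h = t_h)),
                     class = "cardiac_trace"))
  }
  filtered <- bandpass(raw, fl, fh, fs, zero_phase = zero_phase)
  peaks <- find_peaks_mountain_climbing(filtered, fs, fh)
  rate <- heart_rate(peaks, t_h = t_h, fs = fs, n_frames = length(raw))
  rate[is.na(raw)] <- NA_real_   # rate gated where the trace itself is invalid
  structure(list(raw = raw, filtered = filtered, peaks = peaks,
                 intervals = diff(peaks), rate = rate,
                 params = list(fl = fl, fh = fh, fs = fs, t_h = t_h)),
            class = "cardiac_trace")
}

#' @export
print.cardiac_trace <- function(x, ...) {
  cat(sprintf(
    "<cardiac_trace: %d samples @ %g Hz, %d peaks, median rate %s (t_h=%g s)>\n",
    length(x$raw), x$params$fs, length(x$peaks),
    if (all(is.na(x$rate))) "NA" else sprintf("%.2f", stats::median(x$rate, na.rm = TRUE)),
    x$params$t_h))
  invisible(x)
}

#' Export a cardiac trace as a per-frame data frame
#'
#' @param x A `cardiac_trace`.
#' @param ... Unused.
#' @return `data.frame` with columns `t`, `H_raw`, `H_filtered`, `is_peak`,
#'   `T`, `h`, `valid`.
#' @export
as.data.frame.cardiac_trace <- function(x, ...) {
  n <- length(x$raw)
  fs <- x$params$fs
  peak_idx <- round(x$peaks * fs) + 1
  is_peak <- seq_len(n) %in% peak_idx
  T_col <- rep(NA_real_, n)
  if (length(x$peaks) >= 2L)
    T_col[peak_idx[-1]] <- x$intervals
  data.frame(t = seq_len(n) - 1L, H_raw = x$raw, H_filtered = x$filtered,
             is_peak = is_peak, T = T_col, h = x$rate, valid = !is.na(x$raw))
}
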