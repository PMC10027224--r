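#' Frequency bands for the vigilance index
#'
#' Conventional band edges; the ratio numerator is theta + delta, the
#' denominator alpha + high beta + spindle. All edges configurable.
#'
#' @param delta,theta,alpha,spindle,beta_high `c(lo, hi)` in Hz.
#' @export
vigilance_bands <- function(delta = c(0.5, 4), theta = c(4, 8),
                            alpha = c(8, 12), spindle = c(12, 16),
                            beta_high = c(20, 30)) {
  structure(list(delta = delta, theta = theta, alpha = alpha,
                 spindle = spindle, beta_high = beta_high),
            class = "vigilance_bands")
}

#' Vigilance index per 30-s window
#'
#' Band-power ratio (theta + delta) / (alpha + beta_high + spindle) on
#' non-overlapping 30-s windows. Band powers are Welch estimates (4-s
#' Hanning sub-windows, 50% overlap) averaged across channels before the
#' ratio is taken, so the index is invariant to overall signal scaling.
#' High values indicate slow-wave sleep. Windows with zero denominator are
#' marked invalid.
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @param fs sampling rate (Hz).
#' @param bands a [vigilance_bands()].
#' @param window window length in seconds (default 30).
#' @return data.frame of class `vigilance_series`: `start_s`, `index`,
#'   `valid`.
#' @export
vigilance_index <- function(x, fs, bands = vigilance_bands(), window = 30) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  wlen <- round(window * fs)
  if (nrow(x) < wlen) stop("signal shorter than one window", call. = FALSE)
  nwin <- nrow(x) %/% wlen
  idx <- num <- den <- numeric(nwin)
  for (i in seq_len(nwin)) {
    rows <- ((i - 1) * wlen + 1):(i * wlen)
    p <- matrix(0, 5, ncol(x))
    for (ch in seq_len(ncol(x))) {
      spec <- welch_psd(x[rows, ch], fs)
      p[, ch] <- c(band_power(spec, bands$theta),
                   band_power(spec, bands$delta),
                   band_power(spec, bands$alpha),
                   band_power(spec, bands$beta_high),
                   band_power(spec, bands$spindle))
    }
    pm <- rowMeans(p)
    num[i] <- pm[1] + pm[2]
    den[i] <- pm[3] + pm[4] + pm[5]
  }
  out <- data.frame(start_s = (seq_len(nwin) - 1) * window,
                    index = ifelse(den > 0, num / den, NA_real_),
                    valid = den > 0)
  class(out) <- c("vigilance_series", "data.frame")
  attr(out, "window") <- window
  out
}

#' Classify slow-wave sleep from a vigilance series
#'
#' A 30-s window is SWS when its vigilance index exceeds the day's mean plus
#' one standard deviation; days are scored individually (midnight-to-midnight
#' bounds via `day_bounds`, or the whole series as one day). A 2-min segment
#' is SWS only if all four constituent 30-s windows are.
#'
#' @param vig a [vigilance_index()] result.
#' @param day_bounds optional numeric vector of day boundaries in seconds
#'   (e.g. `c(0, 86400, 172800)`); default treats the series as one day.
#' @param segment_s aggregation segment length (default 120).
#' @return list of class `sws_mask`: `window` (30-s flags), `segment`
#'   (2-min labels), `thresholds` (per day).
#' @export
sws_classify <- function(vig, day_bounds = NULL, segment_s = 120) {
  stopifnot(inherits(vig, "vigilance_series"))
  window <- attr(vig, "window")
  if (is.null(window)) window <- 30
  if (is.null(day_bounds))
    day_bounds <- c(min(vig$start_s), max(vig$start_s) + window)
  is_sws <- rep(NA, nrow(vig))
  thresholds <- numeric(length(day_bounds) - 1)
  for (d in seq_len(length(day_bounds) - 1)) {
    sel <- vig$start_s >= day_bounds[d] & vig$start_s < day_bounds[d + 1]
    vals <- vig$index[sel & vig$valid]
    if (length(vals) < 1)
      stop("day ", d, " contains no valid window", call. = FALSE)
    thr <- mean(vals) + sd(vals)
    if (is.na(thr)) thr <- Inf       # single-window day: nothing flagged
    thresholds[d] <- thr
    is_sws[sel] <- vig$valid[sel] & vig$index[sel] > thr
  }
  win <- data.frame(start_s = vig$start_s, is_sws = is_sws)
  per_seg <- as.integer(round(segment_s / window))
  nseg <- floor(nrow(win) / per_seg)
  seg <- data.frame(start_s = (seq_len(nseg) - 1) * segment_s,
                    is_sws = vapply(seq_len(nseg), function(i) {
                      rows <- ((i - 1) * per_seg + 1):(i * per_seg)
                      all(win$is_sws[rows] %in% TRUE)
                    }, logical(1)))
  structure(list(window = win, segment = seg, thresholds = thresholds),
            class = "sws_mask")
}
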