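#' Power extraction settings
#'
#' Defaults implement the broadband gamma-power definition: median Welch
#' power across the frequency bins inside 56-96 Hz (endpoints inclusive),
#' one estimate every 125 ms, log10-transformed. At 256 Hz a 125-ms window
#' is 32 samples, so each estimate is a single Hanning-tapered periodogram
#' with 8-Hz bin spacing (bins 56, 64, 72, 80, 88, 96 Hz inside the band).
#'
#' @param band `c(lo, hi)` in Hz, endpoints inclusive.
#' @param step window step in seconds.
#' @export
power_spec <- function(band = c(56, 96), step = 0.125) {
  stopifnot(band[1] > 0, band[2] > band[1], step > 0)
  structure(list(band = band, step = step), class = "power_spec")
}

#' Construct a power-series object
#'
#' @param values numeric matrix, windows x channels, log10 power (NA =
#'   dropped window).
#' @param step seconds per sample.
#' @param channels channel ids.
#' @param band frequency band (Hz) the power was taken from.
#' @param start_s recording time of the first window's start.
#' @export
power_series <- function(values, step = 0.125, channels = NULL,
                         band = c(56, 96), start_s = 0) {
  values <- as.matrix(values)
  if (is.null(channels)) channels <- colnames(values)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(ncol(values)))
  structure(list(values = values, step = step, fs = 1 / step,
                 channels = channels, band = band, start_s = start_s),
            class = "power_series")
}

#' Broadband gamma-power time series
#'
#' Converts a conditioned multichannel signal into per-channel log10
#' broadband power sampled every `spec$step` seconds: in each non-overlapping
#' window, a Hanning-tapered periodogram is computed and the median power over
#' the frequency bins inside the band (endpoints inclusive) is taken, then
#' log10. Windows overlapping excluded samples, on excluded channels, or
#' with zero power are dropped (NA).
#'
#' @param x numeric matrix (samples x channels) or vector; sampling rate
#'   `fs`.
#' @param fs sampling rate in Hz (the pipeline's common rate is 256).
#' @param spec a [power_spec()].
#' @param keep optional per-sample logical vector, TRUE = usable (e.g. from
#'   [build_exclusion_mask()]).
#' @param drop_channels channel ids (or indices) excluded entirely.
#' @param channels channel ids (defaults to column names).
#' @return a [power_series()].
#' @export
gamma_power_series <- function(x, fs = 256, spec = power_spec(),
                               keep = NULL, drop_channels = NULL,
                               channels = NULL) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (spec$band[2] >= fs / 2)
    stop("band must lie below the Nyquist frequency", call. = FALSE)
  wlen <- round(spec$step * fs)
  if (nrow(x) < wlen) stop("signal shorter than one window", call. = FALSE)
  nwin <- nrow(x) %/% wlen
  if (is.null(channels)) channels <- colnames(x)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(ncol(x)))
  w <- hann_window(wlen)
  freqs <- (0:(wlen %/% 2)) * fs / wlen
  bins <- which(freqs >= spec$band[1] & freqs <= spec$band[2])
  vals <- matrix(NA_real_, nwin, ncol(x))
  for (ch in seq_len(ncol(x))) {
    seg <- matrix(x[seq_len(wlen * nwin), ch], nrow = wlen)
    seg <- (seg - rep(colMeans(seg), each = wlen)) * w
    p <- Mod(mvfft(seg)[bins, , drop = FALSE])^2 * (2 / (fs * sum(w^2)))
    vals[, ch] <- apply(p, 2, median)
  }
  vals[vals <= 0] <- NA               # all-zero windows: log10 undefined
  vals <- log10(vals)
  if (!is.null(keep)) {
    # a window is dropped if it overlaps any excluded sample
    km <- matrix(keep[seq_len(wlen * nwin)], nrow = wlen)
    bad <- colSums(!km) > 0
    vals[bad, ] <- NA
  }
  if (!is.null(drop_channels)) {
    di <- if (is.numeric(drop_channels)) drop_channels
          else match(drop_channels, channels)
    vals[, di[!is.na(di)]] <- NA
  }
  power_series(vals, spec$step, channels, spec$band)
}

#' Time-shuffled surrogate of a power series
#'
#' Randomly permutes values within each 2-min segment, independently per
#' channel. The per-segment power distribution is preserved exactly while
#' temporal correlations are destroyed; independent permutations across
#' channels destroy spatial correlations as well.
#'
#' @param ps a [power_series()].
#' @param segment_s shuffling block length in seconds (default 120).
#' @param seed integer seed (shuffling is reproducible; the caller's RNG
#'   stream is left untouched).
#' @return a [power_series()] of identical shape.
#' @export
shuffle_surrogate <- function(ps, segment_s = 120, seed = 1) {
  stopifnot(inherits(ps, "power_series"))
  v <- ps$values
  seg_len <- round(segment_s * ps$fs)
  n <- nrow(v)
  starts <- seq(1L, n, by = seg_len)
  out <- with_seed(seed, {
    for (s in starts) {
      e <- min(s + seg_len - 1L, n)
      for (ch in seq_len(ncol(v)))
        v[s:e, ch] <- v[sample.int(e - s + 1L) + s - 1L, ch]
    }
    v
  })
  power_series(out, ps$step, ps$channels, ps$band, ps$start_s)
}
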