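#' Welch power spectral density estimate
#'
#' One-sided PSD by averaging Hanning-tapered periodograms of overlapping
#' sub-windows. Used internally for the vigilance band-power index; exposed
#' because band-power definitions are part of the package's contract.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param nperseg sub-window length in samples (default 4 s worth).
#' @param overlap fractional overlap between sub-windows (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power density, x-units^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = round(4 * fs), overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  u <- sum(w^2)
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg)[seq_len(nf)])^2
    acc <- acc + p
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  sc <- rep(2, nf)
  sc[1] <- 1
  if (nperseg %% 2 == 0) sc[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = psd * sc)
}

# Band power from a welch_psd result: integral of the PSD over [lo, hi).
# Half-open so adjacent conventional bands partition the axis.
band_power <- function(spec, band) {
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq >= band[1] & spec$freq < band[2]
  sum(spec$psd[sel]) * df
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}
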