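#' Zero-phase notch filter for power-line noise
#'
#' Removes the 50 Hz mains component and its first harmonic with a
#' second-order IIR notch (quality factor 30) applied forward and backward
#' (zero phase). Attenuation at the notch frequencies exceeds 20 dB while
#' the passband (e.g. 20 Hz, 76 Hz) is changed by less than 1 dB.
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @param fs sampling rate (Hz); must exceed twice the highest notch
#'   frequency.
#' @param freqs notch frequencies in Hz (default 50 and 100).
#' @param Q notch quality factor (center frequency / -3 dB width).
#' @return filtered signal, same shape as `x`.
#' @export
notch_filter <- function(x, fs, freqs = c(50, 100), Q = 30) {
  if (fs <= 2 * max(freqs))
    stop("sampling rate too low for requested notch frequencies",
         call. = FALSE)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  for (f0 in freqs) {
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) / (2 * Q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    b <- b / a[1]; a <- a / a[1]
    for (ch in seq_len(ncol(x)))
      x[, ch] <- signal::filtfilt(b, a, x[, ch])
  }
  if (vec) x[, 1] else x
}

#' Resample a recording to the common 256 Hz rate
#'
#' Zero-phase low-pass at 0.8 x the target Nyquist (102.4 Hz), then integer
#' decimation. Only the clinically occurring rates 256, 512 and 1024 Hz are
#' supported; 256 Hz input is returned unchanged.
#'
#' @param x numeric matrix (samples x channels) or vector at `fs_in`.
#' @param fs_in input sampling rate, one of 256, 512, 1024.
#' @return signal at 256 Hz with `length_out = length_in * 256 / fs_in`.
#' @export
resample_to_256 <- function(x, fs_in) {
  if (!fs_in %in% c(256, 512, 1024))
    stop("unsupported input rate: ", fs_in, call. = FALSE)
  if (fs_in == 256) return(x)
  q <- fs_in / 256
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  bf <- signal::butter(8, 0.8 * 128 / (fs_in / 2), type = "low")
  out <- matrix(NA_real_, ceiling(nrow(x) / q), ncol(x))
  for (ch in seq_len(ncol(x))) {
    y <- signal::filtfilt(bf, x[, ch])
    out[, ch] <- y[seq(1, nrow(x), by = q)]
  }
  colnames(out) <- colnames(x)
  if (vec) out[, 1] else out
}

#' Annotation set for exclusion logic
#'
#' @param seizures,subclinical lists of `c(start, end)` (s) or 2-column
#'   matrices.
#' @param ied_channels channel ids whose signals carry interictal
#'   epileptiform discharges (excluded entirely).
#' @param artifact_hours 1-based indices of 1-h segments flagged as
#'   artefactual (segment k spans `[(k-1)*3600, k*3600)` s).
#' @export
annotation_set <- function(seizures = list(), subclinical = list(),
                           ied_channels = character(),
                           artifact_hours = integer()) {
  structure(list(seizures = as_intervals(seizures, "seizures"),
                 subclinical = as_intervals(subclinical, "subclinical"),
                 ied_channels = as.character(ied_channels),
                 artifact_hours = as.integer(artifact_hours)),
            class = "annotation_set")
}

#' Exclusion mask from clinical annotations
#'
#' Seizures are excluded together with a 10-min preictal and 10-min
#' postictal margin; subclinical events with a 2-min margin on both sides;
#' flagged artifact hours are dropped wholesale and IED channels entirely.
#' Margins are clipped to the recording.
#'
#' @param ann an [annotation_set()].
#' @param duration recording duration (s).
#' @param fs sampling rate of the signal the mask applies to (Hz).
#' @return list of class `exclusion_mask`: `keep` (logical, one per sample),
#'   `drop_channels`, and `log` (one row per applied exclusion).
#' @export
build_exclusion_mask <- function(ann, duration, fs) {
  stopifnot(inherits(ann, "annotation_set"))
  n <- round(duration * fs)
  keep <- rep(TRUE, n)
  log <- data.frame(reason = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  add <- function(lo, hi, reason) {
    lo <- max(0, lo); hi <- min(duration, hi)
    if (hi <= lo) return()
    i0 <- floor(lo * fs) + 1L
    i1 <- min(n, ceiling(hi * fs))
    keep[i0:i1] <<- FALSE
    log[nrow(log) + 1L, ] <<- list(reason, lo, hi)
  }
  sz <- ann$seizures
  for (i in seq_len(nrow(sz))) add(sz[i, 1] - 600, sz[i, 2] + 600, "seizure")
  sub <- ann$subclinical
  for (i in seq_len(nrow(sub)))
    add(sub[i, 1] - 120, sub[i, 2] + 120, "subclinical")
  for (h in ann$artifact_hours) add((h - 1) * 3600, h * 3600, "artifact_hour")
  structure(list(keep = keep, drop_channels = ann$ied_channels, log = log),
            class = "exclusion_mask")
}
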