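#' Configuration for the synthetic iEEG generator
#'
#' The generator emulates the statistical properties the analysis pipeline
#' measures: a latent log-normal gamma-band envelope with tunable
#' autocorrelation timescale (`tau_env`; envelope autocorrelation
#' `exp(-t/tau_env)`, half-decay `tau_env * log(2)`) and distance-dependent
#' cross-channel correlation (Gaussian kernel of length `ell_space`), a 1/f
#' background, 50/100 Hz line components, slow-wave-sleep epochs with boosted
#' delta power and decorrelated envelopes, and clinical annotations.
#'
#' @param n_channels number of channels (default 64).
#' @param fs raw sampling rate in Hz (default 256).
#' @param duration recording length in seconds.
#' @param tau_env latent envelope timescale in seconds (default 4).
#' @param ell_space spatial mixing length in mm (default 30).
#' @param snr_env amplitude ratio of the envelope-modulated gamma component
#'   to the background within the gamma band (default 6).
#' @param sws_epochs,seizures,subclinical lists of `c(start, end)` seconds.
#' @param ied_channels channel ids labelled as IED carriers.
#' @param delta_boost amplitude factor applied to 0.5-4 Hz background power
#'   during SWS epochs (default 4, i.e. 16x delta power).
#' @param line_amp line-noise amplitude as a fraction of signal RMS (fixed
#'   design default 0.1).
#' @param sdlog standard deviation of log10 envelope (default 0.35).
#' @param seed integer seed; identical configurations give bit-identical
#'   datasets.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 64, fs = 256, duration = 1200,
                         tau_env = 4, ell_space = 30, snr_env = 6,
                         sws_epochs = list(), seizures = list(),
                         subclinical = list(), ied_channels = character(),
                         delta_boost = 4, line_amp = 0.1, sdlog = 0.35,
                         seed = 1) {
  stopifnot(fs > 0, duration > 0, tau_env > 0, ell_space > 0, snr_env >= 0,
            n_channels >= 1)
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              duration = duration, tau_env = tau_env,
              ell_space = ell_space, snr_env = snr_env,
              sws_epochs = as_intervals(sws_epochs, "sws_epochs"),
              seizures = as_intervals(seizures, "seizures"),
              subclinical = as_intervals(subclinical, "subclinical"),
              ied_channels = as.character(ied_channels),
              delta_boost = delta_boost, line_amp = line_amp,
              sdlog = sdlog, seed = as.integer(seed))
  for (nm in c("sws_epochs", "seizures", "subclinical"))
    if (nrow(cfg[[nm]]) > 0 && any(cfg[[nm]] > duration))
      stop(nm, ": interval outside [0, duration]", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' Generate electrode coordinates
#'
#' Layouts: `grid` (square grid, 9.5-mm pitch, 1-mm jitter, with the second
#' electrode placed 5 mm from the first so sub-7-mm distances exist),
#' `strip` (linear, same pitch), `random` (uniform in a 90-mm cube). For
#' `grid` with n >= 50 the pairwise distances span at least [5, 90] mm so
#' the 7-79 mm spatial-correlation window is well populated.
#'
#' @param n number of electrodes (>= 2).
#' @param layout one of `"grid"`, `"strip"`, `"random"`.
#' @param seed integer seed.
#' @param pitch inter-electrode spacing in mm (grid/strip).
#' @param jitter uniform coordinate jitter half-width in mm.
#' @return data.frame of class `electrode_set`: `id`, `x`, `y`, `z` (mm).
#' @export
gen_electrodes <- function(n, layout = c("grid", "strip", "random"),
                           seed = 1, pitch = 9.5, jitter = 1) {
  if (n < 2) stop("need at least 2 electrodes", call. = FALSE)
  layout <- match.arg(layout)
  coords <- with_seed(seed, {
    if (layout == "grid") {
      k <- ceiling(sqrt(n))
      g <- expand.grid(ix = 0:(k - 1), iy = 0:(k - 1))[seq_len(n), ]
      cbind(g$ix * pitch, g$iy * pitch, 0) +
        cbind(runif(n, -jitter, jitter), runif(n, -jitter, jitter), 0)
    } else if (layout == "strip") {
      cbind((0:(n - 1)) * pitch + runif(n, -jitter, jitter),
            runif(n, -jitter, jitter), 0)
    } else {
      matrix(runif(3 * n, 0, 90), ncol = 3)
    }
  })
  if (layout != "random")           # guarantee one sub-7-mm pair
    coords[2, ] <- coords[1, ] + c(5, 0, 0)
  out <- data.frame(id = sprintf("E%03d", seq_len(n)),
                    x = coords[, 1], y = coords[, 2], z = coords[, 3])
  class(out) <- c("electrode_set", "data.frame")
  out
}

#' Latent gamma-power envelopes with known spatio-temporal structure
#'
#' Per channel, a unit-variance AR(1) Gaussian process at the 8-Hz envelope
#' rate with autocorrelation `exp(-t/tau_env)`; channels are mixed through
#' the Cholesky factor of the Gaussian spatial kernel
#' `exp(-d^2 / (2 ell_space^2))` of electrode distance, so cross-channel
#' correlation decays with distance at length `ell_space`. The log-Gaussian
#' field is exponentiated (base 10, scale `sdlog`), making power log-normal.
#' Within SWS epochs the field is replaced by fresh white noise, destroying
#' both temporal and spatial correlation.
#'
#' @param cfg a [synth_config()].
#' @param electrodes an [gen_electrodes()] table with `cfg$n_channels` rows.
#' @return positive envelope matrix (time x channels) at 8 Hz, with
#'   attributes `fs_env` and `log10` (the latent Gaussian field).
#' @export
gen_latent_envelopes <- function(cfg, electrodes) {
  stopifnot(inherits(cfg, "synth_config"))
  if (nrow(electrodes) != cfg$n_channels)
    stop("electrode count does not match n_channels", call. = FALSE)
  fs_env <- 8
  nt <- round(cfg$duration * fs_env)
  nc <- cfg$n_channels
  phi <- exp(-1 / (fs_env * cfg$tau_env))
  burn <- ceiling(fs_env * cfg$tau_env * 6)
  d <- as.matrix(stats::dist(as.matrix(electrodes[, c("x", "y", "z")])))
  k <- exp(-d^2 / (2 * cfg$ell_space^2))
  ru <- chol(k + diag(1e-8, nc))
  x <- with_seed(cfg$seed, {
    e <- matrix(rnorm((nt + burn) * nc), nt + burn, nc)
    e <- apply(e, 2, function(col)
      as.numeric(filter(col, phi, method = "recursive"))) * sqrt(1 - phi^2)
    e <- e[(burn + 1):(burn + nt), , drop = FALSE] %*% ru
    t_env <- (seq_len(nt) - 0.5) / fs_env
    sws <- in_intervals(t_env, cfg$sws_epochs)
    if (any(sws)) e[sws, ] <- rnorm(sum(sws) * nc)
    e
  })
  env <- 10^(cfg$sdlog * x)
  attr(env, "fs_env") <- fs_env
  attr(env, "log10") <- cfg$sdlog * x
  env
}

# 1/f-amplitude background noise via spectral shaping, unit RMS.
# Returns the signal and the fraction of its power inside `band`.
pink_noise <- function(n, fs, corner = 0.5) {
  f <- seq(0, fs / 2, length.out = n %/% 2 + 1)
  amp <- 1 / sqrt(pmax(f, corner))
  amp[1] <- 0
  sh <- c(amp, rev(amp[2:(n - length(amp) + 1)]))
  z <- fft(rnorm(n))
  x <- Re(fft(z * sh, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

pink_band_fraction <- function(n, fs, band, corner = 0.5) {
  f <- seq(0, fs / 2, length.out = n %/% 2 + 1)
  a2 <- 1 / pmax(f, corner)
  a2[1] <- 0
  sum(a2[f >= band[1] & f <= band[2]]) / sum(a2)
}

#' Synthesize a multichannel iEEG-like recording
#'
#' Raw signal per channel = envelope-modulated 56-96 Hz band-limited noise
#' + 1/f background + 50/100 Hz line components (common across channels,
#' combined amplitude `line_amp` x signal RMS). During SWS epochs the 0.5-4
#' Hz background power is boosted by `delta_boost` (amplitude). The gamma
#' component is scaled so its RMS is `snr_env` times the background RMS
#' inside the gamma band.
#'
#' @param cfg a [synth_config()].
#' @param envelopes matrix from [gen_latent_envelopes()].
#' @param electrodes matching [gen_electrodes()] table.
#' @return numeric matrix (samples x channels) with attributes `fs` and
#'   `channels`.
#' @export
synth_ieeg <- function(cfg, envelopes, electrodes) {
  stopifnot(inherits(cfg, "synth_config"))
  if (ncol(envelopes) != nrow(electrodes))
    stop("envelope / electrode count mismatch", call. = FALSE)
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  nc <- cfg$n_channels
  fs_env <- attr(envelopes, "fs_env")
  if (is.null(fs_env)) fs_env <- 8
  t_raw <- (seq_len(n) - 0.5) / fs
  t_env <- (seq_len(nrow(envelopes)) - 0.5) / fs_env
  bp_gamma <- signal::butter(4, c(56, 96) / (fs / 2), type = "pass")
  bp_delta <- signal::butter(4, c(0.5, 4) / (fs / 2), type = "pass")
  gamma_frac <- pink_band_fraction(n, fs, c(56, 96))
  delta_frac <- pink_band_fraction(n, fs, c(0.5, 4))
  sws_raw <- in_intervals(t_raw, cfg$sws_epochs)
  out <- with_seed(cfg$seed + 1L, {
    sig <- matrix(0, n, nc)
    for (ch in seq_len(nc)) {
      bg <- pink_noise(n, fs)
      carrier <- signal::filtfilt(bp_gamma, rnorm(n))
      carrier <- carrier / sqrt(mean(carrier^2))
      env_up <- approx(t_env, envelopes[, ch], xout = t_raw, rule = 2)$y
      g <- carrier * env_up
      rms_g <- sqrt(mean(g^2))
      if (rms_g > 0)
        g <- g * (cfg$snr_env * sqrt(gamma_frac) / rms_g)
      x <- bg + g
      if (any(sws_raw)) {
        dwave <- signal::filtfilt(bp_delta, rnorm(n))
        dwave <- dwave / sqrt(mean(dwave^2)) *
          (cfg$delta_boost * sqrt(delta_frac))
        x[sws_raw] <- x[sws_raw] + dwave[sws_raw]
      }
      sig[, ch] <- x
    }
    rms_sig <- sqrt(mean(sig^2))
    line <- cfg$line_amp * rms_sig *
      (sin(2 * pi * 50 * t_raw) + sin(2 * pi * 100 * t_raw))
    sig + line
  })
  colnames(out) <- electrodes$id
  attr(out, "fs") <- fs
  attr(out, "channels") <- electrodes$id
  out
}

#' Write a synthetic dataset to disk
#'
#' Signals go to a Parquet array container (`signals.parquet`, one column
#' per channel), electrode coordinates and annotations to CSV, and the full
#' ground-truth configuration to a JSON sidecar. [read_dataset()] inverts
#' the layout.
#'
#' @param signal matrix from [synth_ieeg()].
#' @param electrodes matching electrode table.
#' @param cfg the generating [synth_config()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(signal, electrodes, cfg, dir) {
  if (!all(is.finite(signal))) stop("signal must be finite", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory", call. = FALSE)
  arrow::write_parquet(as.data.frame(signal),
                       file.path(dir, "signals.parquet"))
  write.csv(as.data.frame(electrodes), file.path(dir, "electrodes.csv"),
            row.names = FALSE)
  iv2df <- function(m, type) {
    if (nrow(m) == 0)
      return(data.frame(type = character(0), start_s = numeric(0),
                        end_s = numeric(0), channel = character(0)))
    data.frame(type = type, start_s = m[, 1], end_s = m[, 2], channel = "")
  }
  ann <- rbind(iv2df(cfg$seizures, "seizure"),
               iv2df(cfg$subclinical, "subclinical"))
  write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  gt <- unclass(cfg)
  gt$sws_epochs <- apply(cfg$sws_epochs, 1, identity, simplify = FALSE)
  gt$seizures <- apply(cfg$seizures, 1, identity, simplify = FALSE)
  gt$subclinical <- apply(cfg$subclinical, 1, identity, simplify = FALSE)
  gt$fs_signal <- attr(signal, "fs")
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `signal` (matrix, attr `fs`), `electrodes`,
#'   `annotations`, `config` (ground-truth list).
#' @export
read_dataset <- function(dir) {
  sig <- as.matrix(arrow::read_parquet(file.path(dir, "signals.parquet")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  attr(sig, "fs") <- gt$fs_signal
  attr(sig, "channels") <- colnames(sig)
  el <- read.csv(file.path(dir, "electrodes.csv"))
  class(el) <- c("electrode_set", "data.frame")
  list(signal = sig, electrodes = el,
       annotations = read.csv(file.path(dir, "annotations.csv")),
       config = gt)
}
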