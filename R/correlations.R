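#' Segment start indices for windowed correlation analysis
#'
#' TC uses consecutive 75%-overlapping 2-min segments (30-s step); SC uses
#' consecutive non-overlapping 2-min segments. Segments that would run past
#' the end of the series are dropped; segments containing dropped (NA)
#' samples are marked invalid.
#'
#' @param n_samples length of the power series.
#' @param fs sampling rate of the series (Hz; 8 for the 125-ms power step).
#' @param length_s segment length in seconds (default 120).
#' @param overlap fractional overlap, 0.75 for TC, 0 for SC.
#' @param valid optional logical vector (TRUE = sample usable) or matrix
#'   (samples x channels); a segment is valid only if all its samples are.
#' @return data.frame with `start`, `end` (sample indices), `start_s`, and
#'   `valid`.
#' @export
segment_indices <- function(n_samples, fs, length_s = 120, overlap = 0.75,
                            valid = NULL) {
  seg_len <- round(length_s * fs)
  if (n_samples < seg_len)
    return(data.frame(start = integer(0), end = integer(0),
                      start_s = numeric(0), valid = logical(0)))
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n_samples - seg_len + 1L, by = step)
  out <- data.frame(start = starts, end = starts + seg_len - 1L,
                    start_s = (starts - 1L) / fs)
  out$valid <- vapply(seq_len(nrow(out)), function(i) {
    if (is.null(valid)) return(TRUE)
    idx <- out$start[i]:out$end[i]
    if (is.matrix(valid)) all(valid[idx, ]) else all(valid[idx])
  }, logical(1))
  out
}

#' Autocorrelation curve of a power segment
#'
#' Mean-subtracted, biased-normalised (1/n) autocorrelation, the estimator
#' whose smooth long-lag behaviour the half-decay rule relies on.
#'
#' @param x numeric vector (one 2-min power segment, or a model activity
#'   trace).
#' @param fs samples per second (8 for the power series) or per step (1 for
#'   the model).
#' @param lag_max_s maximum lag in seconds (or steps when `fs = 1`).
#' @param baseline baseline window `c(lo, hi)` in the same units as lags, or
#'   the scalar 0 for a fixed zero baseline.
#' @return object of class `acf_curve`: list with `lags`, `values`,
#'   `baseline`.
#' @export
acf_curve <- function(x, fs = 8, lag_max_s = 60, baseline = c(40, 60)) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("segment contains dropped samples", call. = FALSE)
  if (var(x) == 0) stop("zero-variance segment", call. = FALSE)
  lag_max <- min(round(lag_max_s * fs), length(x) - 1L)
  a <- acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  structure(list(lags = (0:lag_max) / fs, values = a, baseline = baseline),
            class = "acf_curve")
}

#' Temporal correlation as autocorrelation half-decay time
#'
#' TC is the first lag at which the autocorrelation drops strictly below
#' halfway between its value at the first lag and a tail baseline (the
#' median autocorrelation over the baseline window, or 0 for the fixed-zero
#' variant). The floor is one lag: even white noise yields TC = 0.125 s at
#' the 8 Hz power rate. If no crossing occurs within the lag range the
#' maximum lag is returned with `capped = TRUE`.
#'
#' @param curve an [acf_curve()].
#' @return list of class `tc_value`: `value` (seconds, or steps for model
#'   traces), `floor` (TRUE when value equals one lag), `capped`.
#' @export
tc_half_decay <- function(curve) {
  stopifnot(inherits(curve, "acf_curve"))
  lags <- curve$lags
  a <- curve$values
  if (length(lags) < 2) stop("need at least two lags", call. = FALSE)
  bl <- curve$baseline
  if (length(bl) == 1 && bl == 0) {
    b <- 0
  } else {
    sel <- lags >= bl[1] & lags <= bl[2]
    if (!any(sel))
      stop("baseline window outside lag range", call. = FALSE)
    b <- median(a[sel])
  }
  a1 <- a[2]                       # value at the first (non-zero) lag
  thr <- b + (a1 - b) / 2
  below <- which(a[-1] < thr)      # search from the first lag on
  if (length(below) == 0) {
    value <- lags[length(lags)]
    capped <- TRUE
  } else {
    value <- lags[below[1] + 1L]
    capped <- FALSE
  }
  structure(list(value = value, floor = isTRUE(all.equal(value, lags[2])),
                 capped = capped, threshold = thr, baseline_value = b),
            class = "tc_value")
}

#' Per-segment TC of a power series
#'
#' Applies the half-decay rule to every valid 75%-overlapping 2-min segment
#' of every channel and aggregates across channels (mean) within segments.
#'
#' @param ps a [power_series()].
#' @param baseline baseline window in seconds, or 0.
#' @param overlap segment overlap (default 0.75).
#' @param lag_max_s maximum autocorrelation lag (default 60 s).
#' @return data.frame: `start_s`, `tc` (channel-mean seconds), `n_channels`.
#'   Per-channel values in attribute `"per_channel"`.
#' @export
tc_series <- function(ps, baseline = c(40, 60), overlap = 0.75,
                      lag_max_s = 60) {
  stopifnot(inherits(ps, "power_series"))
  v <- ps$values
  segs <- segment_indices(nrow(v), ps$fs, 120, overlap)
  per <- matrix(NA_real_, nrow(segs), ncol(v))
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start[i]:segs$end[i]
    for (ch in seq_len(ncol(v))) {
      seg <- v[idx, ch]
      if (anyNA(seg) || var(seg) == 0) next
      per[i, ch] <- tc_half_decay(
        acf_curve(seg, ps$fs, lag_max_s, baseline))$value
    }
  }
  out <- data.frame(start_s = segs$start_s,
                    tc = rowMeans(per, na.rm = TRUE),
                    n_channels = rowSums(!is.na(per)))
  out$tc[out$n_channels == 0] <- NA_real_
  attr(out, "per_channel") <- per
  out
}

#' Distance-binned pairwise cross-correlation profile
#'
#' Zero-lag Pearson correlation for all channel pairs in each valid
#' non-overlapping 2-min segment, pooled across segments and averaged in
#' 1-mm Euclidean-distance bins.
#'
#' @param ps a [power_series()].
#' @param electrodes electrode coordinate table with columns `x`, `y`, `z`
#'   matching the power-series channels.
#' @param bin bin width (mm; default 1).
#' @param segments optional precomputed [segment_indices()] table
#'   (non-overlapping by default).
#' @return data.frame of class `dist_profile`: `center` (bin center, mm),
#'   `mean_r`, `n_pairs` (distinct channel pairs), `n_values` (pooled
#'   pair-segment correlations). Attribute `"per_segment"` holds the
#'   segment-resolved profile list.
#' @export
cross_corr_by_distance <- function(ps, electrodes, bin = 1, segments = NULL) {
  stopifnot(inherits(ps, "power_series"))
  v <- ps$values
  if (ncol(v) < 2) stop("need at least two channels", call. = FALSE)
  coords <- as.matrix(electrodes[, c("x", "y", "z")])
  if (nrow(coords) != ncol(v))
    stop("electrode count does not match channel count", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  up <- upper.tri(d)
  pair_d <- d[up]
  if (is.null(segments))
    segments <- segment_indices(nrow(v), ps$fs, 120, 0, valid = !is.na(v))
  segments <- segments[segments$valid, , drop = FALSE]
  if (nrow(segments) == 0) {
    prof <- data.frame(center = numeric(0), mean_r = numeric(0),
                       n_pairs = integer(0), n_values = integer(0))
    class(prof) <- c("dist_profile", "data.frame")
    return(prof)
  }
  rs <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    idx <- segments$start[i]:segments$end[i]
    rs[[i]] <- suppressWarnings(cor(v[idx, ]))[up]
  }
  r_all <- unlist(rs)
  d_all <- rep(pair_d, length(rs))
  ok <- !is.na(r_all)
  bin_idx <- floor(d_all[ok] / bin)
  mean_r <- tapply(r_all[ok], bin_idx, mean)
  n_values <- tapply(r_all[ok], bin_idx, length)
  pair_bins <- floor(pair_d / bin)
  n_pairs <- table(factor(pair_bins, levels = names(mean_r)))
  prof <- data.frame(center = (as.numeric(names(mean_r)) + 0.5) * bin,
                     mean_r = as.numeric(mean_r),
                     n_pairs = as.integer(n_pairs),
                     n_values = as.integer(n_values))
  prof <- prof[order(prof$center), ]
  rownames(prof) <- NULL
  class(prof) <- c("dist_profile", "data.frame")
  attr(prof, "per_segment") <- rs
  attr(prof, "pair_dist") <- pair_d
  prof
}

#' Mean spatial correlation over a distance interval
#'
#' Unweighted mean of the populated distance-bin means whose centers fall
#' inside the interval (endpoints inclusive). The default 7-79 mm window is
#' the range typically populated by clinical electrode layouts; 9-50 mm and
#' 50-79 mm variants are available through `interval`.
#'
#' @param profile a `dist_profile` from [cross_corr_by_distance()].
#' @param interval `c(lo, hi)` in the profile's distance units.
#' @return numeric SC value (class `sc_value`, attributes `interval`,
#'   `n_bins`).
#' @export
sc_mean <- function(profile, interval = c(7, 79)) {
  stopifnot(inherits(profile, "dist_profile"))
  sel <- profile$center >= interval[1] & profile$center <= interval[2]
  if (!any(sel)) stop("no populated bins in interval", call. = FALSE)
  structure(mean(profile$mean_r[sel]), class = "sc_value",
            interval = interval, n_bins = sum(sel))
}

#' Per-segment SC of a power series
#'
#' SC per valid non-overlapping 2-min segment: pair correlations binned by
#' distance within the segment, bin means averaged over the interval.
#'
#' @inheritParams cross_corr_by_distance
#' @inheritParams sc_mean
#' @return data.frame: `start_s`, `sc`.
#' @export
sc_series <- function(ps, electrodes, interval = c(7, 79), bin = 1) {
  stopifnot(inherits(ps, "power_series"))
  v <- ps$values
  coords <- as.matrix(electrodes[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(coords))
  up <- upper.tri(d)
  pair_bin <- floor(d[up] / bin)
  centers <- (pair_bin + 0.5) * bin
  in_int <- centers >= interval[1] & centers <= interval[2]
  segs <- segment_indices(nrow(v), ps$fs, 120, 0, valid = !is.na(v))
  sc <- rep(NA_real_, nrow(segs))
  for (i in seq_len(nrow(segs))) {
    if (!segs$valid[i]) next
    idx <- segs$start[i]:segs$end[i]
    r <- suppressWarnings(cor(v[idx, ]))[up]
    ok <- in_int & !is.na(r)
    if (!any(ok)) next
    sc[i] <- mean(tapply(r[ok], pair_bin[ok], mean))
  }
  data.frame(start_s = segs$start_s, sc = sc)
}

#' Hurst exponent by detrended fluctuation analysis
#'
#' Cumulative-sum profile, 50%-overlapping windows at log-spaced scales,
#' per-window linear detrending, RMS fluctuation F(s), and the least-squares
#' slope of log F versus log s. H = 0.5 for uncorrelated signals and
#' approaches 1 for long-range correlated, self-affine signals.
#'
#' @param x numeric series.
#' @param scales `c(min, max)` window sizes in samples (default 100-1000).
#' @param n_scales number of log-spaced scales (default 10).
#' @return list of class `hurst_estimate`: `H`, `scales`, `fluctuation`.
#' @export
dfa_hurst <- function(x, scales = c(100, 1000), n_scales = 10) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 * scales[2])
    stop("series shorter than twice the maximum scale", call. = FALSE)
  ss <- unique(round(exp(seq(log(scales[1]), log(scales[2]),
                             length.out = n_scales))))
  if (length(ss) < 5) stop("fewer than 5 distinct scales", call. = FALSE)
  y <- cumsum(x - mean(x))
  fl <- vapply(ss, function(s) {
    starts <- seq(1L, n - s + 1L, by = max(1L, floor(s / 2)))
    tc <- seq_len(s) - (s + 1) / 2          # centered time axis
    stt <- sum(tc^2)
    rms <- vapply(starts, function(st) {
      w <- y[st:(st + s - 1L)]
      beta <- sum(tc * w) / stt
      res <- w - mean(w) - beta * tc
      sqrt(mean(res^2))
    }, numeric(1))
    mean(rms)
  }, numeric(1))
  h <- unname(coef(lm(log(fl) ~ log(ss)))[2])
  structure(list(H = h, scales = ss, fluctuation = fl),
            class = "hurst_estimate")
}
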