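#' Configuration of the excitable-lattice network model
#'
#' N probabilistic binary neurons on a square grid with periodic boundaries;
#' all-to-all connectivity with uniform random strengths shaped by a
#' Gaussian profile of torus distance (width `sigma`). A random 20% of
#' neurons is inhibitory (outgoing weights negated). The matrix is rescaled
#' so its largest absolute eigenvalue equals `lambda`; `lambda` always
#' refers to the unperturbed network (`f_exc = f_inh = 1`), the AED factors
#' are applied afterwards. One random neuron is forced active every
#' `drive_every` steps as background drive.
#'
#' @param n neuron count, a perfect square (default 1600).
#' @param sigma Gaussian profile width in grid units (default 4).
#' @param alpha_inh inhibitory fraction (default 0.2).
#' @param lambda target largest absolute eigenvalue (default 1).
#' @param f_exc,f_inh multiplicative factors on excitatory / inhibitory
#'   outgoing weights mimicking antiepileptic drug action (default 1).
#' @param max_t simulation length in steps (default 2000).
#' @param n_monitor number of randomly monitored neurons for SC (default
#'   40).
#' @param drive_every drive interval in steps (default 1: one random neuron
#'   activated every step).
#' @param seed integer seed.
#' @export
net_config <- function(n = 1600, sigma = 4, alpha_inh = 0.2, lambda = 1,
                       f_exc = 1, f_inh = 1, max_t = 2000, n_monitor = 40,
                       drive_every = 1, seed = 1) {
  k <- sqrt(n)
  if (k != round(k)) stop("n must be a perfect square", call. = FALSE)
  stopifnot(sigma > 0, alpha_inh >= 0, alpha_inh <= 1, lambda >= 0,
            f_exc > 0, f_inh > 0, max_t >= 1, n_monitor >= 0)
  structure(list(n = as.integer(n), k = as.integer(k), sigma = sigma,
                 alpha_inh = alpha_inh, lambda = lambda, f_exc = f_exc,
                 f_inh = f_inh, max_t = as.integer(max_t),
                 n_monitor = as.integer(n_monitor),
                 drive_every = as.integer(drive_every),
                 seed = as.integer(seed)),
            class = "net_config")
}

# Grid positions (0-based columns ix, iy) of neurons 1..n, row-major.
grid_positions <- function(n, k) {
  cbind(ix = (seq_len(n) - 1) %% k, iy = (seq_len(n) - 1) %/% k)
}

# Pairwise torus (periodic-boundary) Euclidean distance between two
# position sets on a k x k grid.
torus_dist <- function(p1, p2, k) {
  dx <- abs(outer(p1[, 1], p2[, 1], "-"))
  dy <- abs(outer(p1[, 2], p2[, 2], "-"))
  dx <- pmin(dx, k - dx)
  dy <- pmin(dy, k - dy)
  sqrt(dx^2 + dy^2)
}

#' Largest absolute eigenvalue by power iteration
#'
#' Estimates the spectral radius of a dense square matrix from the
#' geometric mean of the iterate norm growth, which is robust to complex
#' dominant pairs.
#'
#' @param w square numeric matrix.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @export
spectral_radius <- function(w, tol = 1e-10, max_iter = 5000) {
  n <- nrow(w)
  window <- 20L
  v <- sin(seq_len(n)) + 1.5        # deterministic generic direction
  v <- v / sqrt(sum(v^2))
  logn <- rep(NA_real_, window)
  est_prev <- -Inf
  for (i in seq_len(max_iter)) {
    v2 <- as.numeric(w %*% v)
    nrm <- sqrt(sum(v2 * v2))
    if (nrm == 0) return(0)
    v <- v2 / nrm
    logn[(i - 1L) %% window + 1L] <- log(nrm)
    if (i >= window) {
      est <- exp(mean(logn))
      if (abs(est - est_prev) <= tol * est && i >= 2L * window) return(est)
      est_prev <- est
    }
  }
  est_prev
}

#' Build the signed lattice connectivity matrix
#'
#' `w[i, j]` is the connection from neuron j to i: uniform(0, 1) base
#' strength times the Gaussian profile `exp(-r_ij^2 / (2 sigma^2))` of torus
#' distance; self-connections are zero. A seeded random fraction
#' `alpha_inh` of neurons has its outgoing weights (columns) multiplied by
#' -1. The whole matrix is rescaled by one constant so the largest absolute
#' eigenvalue equals `lambda`; `f_exc` / `f_inh` are applied to the
#' excitatory / inhibitory columns afterwards.
#'
#' @param cfg a [net_config()].
#' @return list of class `weight_matrix`: `w` (with AED factors applied),
#'   `lambda` (unperturbed), `inhibitory` (logical), `positions`, `k`,
#'   `cfg`.
#' @export
build_weights <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  n <- cfg$n; k <- cfg$k
  pos <- grid_positions(n, k)
  r <- torus_dist(pos, pos, k)
  prof <- exp(-r^2 / (2 * cfg$sigma^2))
  out <- with_seed(cfg$seed, {
    w <- matrix(runif(n * n), n, n) * prof
    inh <- rep(FALSE, n)
    inh[sample.int(n, round(cfg$alpha_inh * n))] <- TRUE
    list(w = w, inh = inh)
  })
  w <- out$w
  diag(w) <- 0
  w[, out$inh] <- -w[, out$inh]
  if (cfg$lambda > 0) {
    est <- spectral_radius(w)
    if (est == 0) stop("degenerate weight matrix", call. = FALSE)
    w <- w * (cfg$lambda / est)
  } else {
    w[] <- 0
  }
  if (cfg$f_exc != 1) w[, !out$inh] <- w[, !out$inh] * cfg$f_exc
  if (cfg$f_inh != 1) w[, out$inh] <- w[, out$inh] * cfg$f_inh
  structure(list(w = w, lambda = cfg$lambda, inhibitory = out$inh,
                 positions = pos, k = k, cfg = cfg),
            class = "weight_matrix")
}

#' Clamped firing probabilities (single-step transition kernel)
#'
#' `p_i = min(max(sum_j w[i,j] s_j, 0), 1)`: zero when the summed input is
#' non-positive, one when it reaches one, the raw sum in between.
#'
#' @param w weight matrix (or a [build_weights()] result).
#' @param s binary state vector.
#' @export
firing_probabilities <- function(w, s) {
  if (inherits(w, "weight_matrix")) w <- w$w
  pmin(pmax(as.numeric(w %*% s), 0), 1)
}

#' One synchronous update of the lattice (reference implementation)
#'
#' Draws all neuron states independently Bernoulli(p) from
#' [firing_probabilities()], then forces the drive neuron active. The
#' batched simulator ([simulate_net()]) implements the same transition.
#'
#' @param s current binary state vector.
#' @param w weight matrix or [build_weights()] result.
#' @param drive index of the neuron forced active (NA for none).
#' @export
net_step <- function(s, w, drive = NA) {
  p <- firing_probabilities(w, s)
  s_new <- as.integer(runif(length(p)) < p)
  if (!is.na(drive)) s_new[drive] <- 1L
  s_new
}

#' Simulate the lattice model
#'
#' Runs `runs` independent replicates of `max_t` synchronous steps from the
#' all-zero state, recording the population activity S(t) (fraction of
#' neurons firing) and the binary traces of `n_monitor` seeded-random
#' monitored neurons.
#'
#' @param wm a [build_weights()] result.
#' @param runs number of replicate simulations (batched in one call).
#' @param max_t,n_monitor,drive_every override the values in `wm$cfg`.
#' @param seed integer seed for monitor choice and all Bernoulli/drive
#'   draws.
#' @return list of class `activity_trace`: `S` (max_t x runs), `monitor`
#'   (max_t x n_monitor x runs binary array), `monitor_idx`,
#'   `monitor_pos`, `k`.
#' @export
simulate_net <- function(wm, runs = 1, max_t = NULL, n_monitor = NULL,
                         drive_every = NULL, seed = 1) {
  stopifnot(inherits(wm, "weight_matrix"))
  cfg <- wm$cfg
  if (is.null(max_t)) max_t <- cfg$max_t
  if (is.null(n_monitor)) n_monitor <- cfg$n_monitor
  if (is.null(drive_every)) drive_every <- cfg$drive_every
  n <- nrow(wm$w)
  res <- with_seed(seed, {
    idx <- if (n_monitor > 0) sample.int(n, n_monitor) else integer(0)
    sim <- simulate_lattice_cpp(wm$w, max_t, runs, idx, drive_every)
    list(idx = idx, sim = sim)
  })
  structure(list(S = res$sim$S, monitor = res$sim$monitor,
                 monitor_idx = res$idx,
                 monitor_pos = wm$positions[res$idx, , drop = FALSE],
                 k = wm$k),
            class = "activity_trace")
}

#' Temporal correlation of a model activity trace
#'
#' The data pipeline's half-decay rule applied to the autocorrelation of
#' S(t): lags in steps, baseline = median autocorrelation over lags
#' 400-600, floor one step, capped at the maximum lag.
#'
#' @param s activity trace S(t) (numeric vector).
#' @param lag_max maximum lag in steps (default 600).
#' @param baseline baseline lag window (default `c(400, 600)`).
#' @return a `tc_value` (value in steps).
#' @export
model_tc <- function(s, lag_max = 600, baseline = c(400, 600)) {
  tc_half_decay(acf_curve(s, fs = 1, lag_max_s = lag_max,
                          baseline = baseline))
}

#' Spatial correlation of monitored model neurons
#'
#' Zero-lag Pearson correlations of the monitored binary traces, pooled in
#' unit-width torus-distance bins and averaged over bin centers inside the
#' interval (default 1-10 grid units).
#'
#' @param mon binary trace matrix (steps x monitored neurons).
#' @param pos monitored-neuron grid positions (rows match columns of
#'   `mon`).
#' @param k grid side length.
#' @param interval distance interval in grid units.
#' @return numeric SC value.
#' @export
model_sc <- function(mon, pos, k, interval = c(1, 10)) {
  d <- torus_dist(pos, pos, k)
  up <- upper.tri(d)
  r <- suppressWarnings(cor(mon))[up]
  ok <- !is.na(r)
  if (!any(ok)) stop("all monitored traces constant", call. = FALSE)
  bin <- floor(d[up][ok])
  means <- tapply(r[ok], bin, mean)
  centers <- as.numeric(names(means)) + 0.5
  sel <- centers >= interval[1] & centers <= interval[2]
  if (!any(sel)) stop("no populated bins in interval", call. = FALSE)
  mean(means[sel])
}

# Per-run measurement of one batched simulation: TC, SC, Hurst and their
# time-shuffled surrogates. Returns a data.frame with one row per run.
measure_runs <- function(trace, hurst = TRUE, surrogate = TRUE,
                         seed = 1) {
  runs <- ncol(trace$S)
  out <- data.frame(run = seq_len(runs), tc = NA_real_, tc_capped = NA,
                    sc = NA_real_, hurst = NA_real_, tc_surr = NA_real_,
                    sc_surr = NA_real_)
  with_seed(seed, {
    for (r in seq_len(runs)) {
      s <- trace$S[, r]
      mon <- trace$monitor[, , r]
      tc <- tryCatch(model_tc(s), error = function(e) NULL)
      if (!is.null(tc)) {
        out$tc[r] <- tc$value
        out$tc_capped[r] <- tc$capped
      }
      out$sc[r] <- tryCatch(model_sc(mon, trace$monitor_pos, trace$k),
                            error = function(e) NA_real_)
      if (hurst)
        out$hurst[r] <- tryCatch(dfa_hurst(s)$H,
                                 error = function(e) NA_real_)
      if (surrogate) {
        s_sh <- s[sample.int(length(s))]
        out$tc_surr[r] <- tryCatch(model_tc(s_sh)$value,
                                   error = function(e) NA_real_)
        mon_sh <- apply(mon, 2, function(col) col[sample.int(length(col))])
        out$sc_surr[r] <- tryCatch(
          model_sc(mon_sh, trace$monitor_pos, trace$k),
          error = function(e) NA_real_)
      }
    }
  })
  out
}

#' Sweep the connectivity eigenvalue and measure TC, SC and Hurst per run
#'
#' For each lambda a seeded weight realization is built, `runs_per_lambda`
#' replicate simulations are run, and per-run TC (steps), SC, DFA Hurst
#' exponent and time-shuffled surrogate TC/SC are measured. The Spearman
#' correlation of TC and SC pooled over all runs quantifies their
#' co-variation across distances to criticality.
#'
#' @param lambdas eigenvalue grid (default `seq(0.7, 1, 0.05)`).
#' @param runs_per_lambda replicate simulations per lambda.
#' @param cfg template [net_config()] (lambda and seed are overridden).
#' @param seed master seed.
#' @param hurst,surrogate logical: measure DFA exponents / surrogates.
#' @return data.frame (one row per run) with columns `lambda`, `run`, `tc`,
#'   `tc_capped`, `sc`, `hurst`, `tc_surr`, `sc_surr`; attribute
#'   `"spearman"` holds the pooled TC-SC rank correlation and its surrogate
#'   counterpart.
#' @export
sweep_lambda <- function(lambdas = seq(0.7, 1, by = 0.05),
                         runs_per_lambda = 150, cfg = net_config(),
                         seed = 1, hurst = TRUE, surrogate = TRUE) {
  seeds <- with_seed(seed, matrix(sample.int(2^31 - 2, 3 * length(lambdas)),
                                  ncol = 3))
  res <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    cfg_i <- cfg
    cfg_i$lambda <- lambdas[i]
    cfg_i$seed <- seeds[i, 1]
    wm <- build_weights(cfg_i)
    trace <- simulate_net(wm, runs = runs_per_lambda, seed = seeds[i, 2])
    m <- measure_runs(trace, hurst = hurst, surrogate = surrogate,
                      seed = seeds[i, 3])
    m$lambda <- lambdas[i]
    res[[i]] <- m[, c("lambda", "run", "tc", "tc_capped", "sc", "hurst",
                      "tc_surr", "sc_surr")]
  }
  out <- do.call(rbind, res)
  rho <- cor(out$tc, out$sc, method = "spearman", use = "complete.obs")
  rho_surr <- if (surrogate)
    cor(out$tc_surr, out$sc_surr, method = "spearman",
        use = "complete.obs") else NA_real_
  attr(out, "spearman") <- c(data = rho, surrogate = rho_surr)
  out
}

#' Paired contrast of antiepileptic-drug factors in the model
#'
#' Simulates matched ensembles at two values of `f_exc` (same weight
#' realization and simulation seeds) and compares per-run TC and SC with
#' one-sided paired Wilcoxon tests (reduced excitability is expected to
#' lower both).
#'
#' @param cfg template [net_config()] (typically `lambda = 1`).
#' @param f_exc_values two excitability factors, reference first.
#' @param runs paired runs per condition (>= 30).
#' @param seed master seed.
#' @param f_inh_values optional: contrast `f_inh` instead (set
#'   `f_exc_values = NULL`).
#' @return list of class `aed_contrast`: `table` (long), `summary` (mean
#'   TC/SC per condition), `tests` (one-sided paired Wilcoxon p for TC and
#'   SC).
#' @export
aed_contrast <- function(cfg = net_config(lambda = 1),
                         f_exc_values = c(1, 0.95), runs = 200, seed = 1,
                         f_inh_values = NULL) {
  if (runs < 30) stop("need at least 30 paired runs", call. = FALSE)
  use_inh <- is.null(f_exc_values)
  vals <- if (use_inh) f_inh_values else f_exc_values
  stopifnot(length(vals) == 2)
  seeds <- with_seed(seed, sample.int(2^31 - 2, 3))
  res <- vector("list", 2)
  for (i in 1:2) {
    cfg_i <- cfg
    cfg_i$seed <- seeds[1]
    if (use_inh) cfg_i$f_inh <- vals[i] else cfg_i$f_exc <- vals[i]
    wm <- build_weights(cfg_i)
    trace <- simulate_net(wm, runs = runs, seed = seeds[2])
    m <- measure_runs(trace, hurst = FALSE, surrogate = FALSE,
                      seed = seeds[3])
    m$f <- vals[i]
    res[[i]] <- m
  }
  tab <- do.call(rbind, res)
  mean_na <- function(x) mean(x, na.rm = TRUE)
  summary <- data.frame(f = vals,
                        mean_tc = vapply(res, function(m) mean_na(m$tc),
                                         numeric(1)),
                        mean_sc = vapply(res, function(m) mean_na(m$sc),
                                         numeric(1)))
  tests <- list(
    tc = suppressWarnings(wilcox.test(res[[1]]$tc, res[[2]]$tc,
                                      paired = TRUE,
                                      alternative = "greater")),
    sc = suppressWarnings(wilcox.test(res[[1]]$sc, res[[2]]$sc,
                                      paired = TRUE,
                                      alternative = "greater")))
  structure(list(table = tab, summary = summary, tests = tests,
                 factor = if (use_inh) "f_inh" else "f_exc"),
            class = "aed_contrast")
}
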