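# Shared fixtures built in code.

# Small synthetic recording with matching electrodes; envelope-level access
# through attr(env, "log10").
make_recording <- function(n_channels = 8, duration = 480, tau_env = 2,
                           ell_space = 30, seed = 4, ...) {
  cfg <- synth_config(n_channels = n_channels, duration = duration,
                      tau_env = tau_env, ell_space = ell_space,
                      seed = seed, ...)
  el <- gen_electrodes(n_channels, "grid", seed = seed + 1)
  env <- gen_latent_envelopes(cfg, el)
  list(cfg = cfg, electrodes = el, env = env,
       signal = synth_ieeg(cfg, env, el))
}

# Envelope-level power series (the latent log10 field used directly as a
# PowerSeries): cheap substrate for estimator tests.
envelope_power_series <- function(cfg, electrodes) {
  env <- gen_latent_envelopes(cfg, electrodes)
  power_series(attr(env, "log10"))
}

# Exact expected population activity of a tiny lattice over a few steps,
# by full enumeration of the 2^N-state Markov chain (independent of the
# simulator): synchronous Bernoulli draws from clamped inputs, then a
# uniformly random neuron forced active.
enumerate_expected_activity <- function(w, steps) {
  n <- nrow(w)
  nstates <- 2^n
  state_bits <- t(vapply(0:(nstates - 1),
                         function(s) as.integer(intToBits(s)[1:n]),
                         integer(n)))
  trans <- matrix(0, nstates, nstates)
  for (s in seq_len(nstates)) {
    sv <- state_bits[s, ]
    p <- pmin(pmax(as.numeric(w %*% sv), 0), 1)
    for (s2 in seq_len(nstates)) {
      s2v <- state_bits[s2, ]
      pr <- prod(ifelse(s2v == 1, p, 1 - p))
      if (pr == 0) next
      for (d in seq_len(n)) {
        s3 <- bitwOr(s2 - 1L, bitwShiftL(1L, d - 1L)) + 1L
        trans[s, s3] <- trans[s, s3] + pr / n
      }
    }
  }
  activity <- rowSums(state_bits) / n
  pvec <- c(1, rep(0, nstates - 1))      # all-zero initial state
  vapply(seq_len(steps), function(t) {
    pvec <<- as.numeric(pvec %*% trans)
    sum(pvec * activity)
  }, numeric(1))
}

# Pink (1/f power) noise by spectral shaping: independent oracle input for
# DFA checks.
make_pink_noise <- function(n, seed) {
  set.seed(seed)
  f <- seq(0, 0.5, length.out = n %/% 2 + 1)
  amp <- 1 / sqrt(pmax(f, f[2]))
  amp[1] <- 0
  shape <- c(amp, rev(amp[2:(n - length(amp) + 1)]))
  x <- Re(fft(fft(rnorm(n)) * shape, inverse = TRUE) / n)
  x / sd(x)
}
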