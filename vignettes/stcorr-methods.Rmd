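---
title: "Measuring spatio-temporal correlations in intracranial EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatio-temporal correlations in intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcorr)
```

# Overview

How long does the activity of a cortical patch stay correlated with its own
past, and how far across the cortical sheet does it stay correlated with its
neighbours? `stcorr` turns multichannel intracranial EEG (iEEG/ECoG) into
two scalar summaries of these integration properties:

* **Temporal correlation (TC)** — the half-decay time of the
  autocorrelation function of broadband gamma-power, in seconds.
* **Spatial correlation (SC)** — the mean zero-lag pairwise correlation of
  the same power series, binned by inter-electrode distance and averaged
  over a distance window.

Both are computed against within-segment time-shuffled surrogates, split by
slow-wave sleep (SWS), related to a five-region functional hierarchy, and
compared with a probabilistic excitable-lattice model whose proximity to a
critical point is set by one parameter. Because clinical long-term
recordings cannot be redistributed, the package ships a synthetic generator
with *known* spatio-temporal ground truth; every stage of the pipeline is
validated against it.

# The measurement pipeline

## Signal conditioning

Recordings are notch-filtered at 50 and 100 Hz (zero-phase biquad, quality
factor 30) and brought to a common 256 Hz rate by zero-phase low-pass
filtering at 0.8 x the target Nyquist followed by integer decimation
(`notch_filter()`, `resample_to_256()`). The source material does not fix
filter orders or phase behaviour; zero-phase IIR filtering is the
conventional choice when later analyses are sensitive to timing, and the
responses are verified directly in the tests (>= 20 dB notch attenuation,
< 1 dB passband ripple).

Clinical annotations drive a per-sample exclusion mask
(`build_exclusion_mask()`): seizures are removed together with 10-min
pre-ictal and post-ictal margins, subclinical events with 2-min margins,
visually flagged artifact hours wholesale, and channels carrying interictal
epileptiform discharges entirely. Any 125-ms power window that overlaps an
excluded sample is dropped, and any 2-min analysis segment containing a
dropped sample is skipped downstream — exclusions can only shrink, never
bias, the usable data.

## Broadband gamma-power

Population firing near an electrode is indexed by power in the 56–96 Hz
band. `gamma_power_series()` computes, every 125 ms, a single 32-sample
Hanning-tapered periodogram and takes the *median* of the frequency bins
inside the band (8 Hz resolution: 56, 64, 72, 80, 88, 96 Hz; endpoints
inclusive), then log10. The 125-ms window admits no sub-averaging, so the
"Welch" estimate degenerates to one tapered periodogram per window; windows
are non-overlapping. Power is approximately log-normal, so the log10 series
is near-Gaussian — the tests check that its skewness stays inside
[-0.5, 0.5] on synthetic data.

## Temporal correlations

For each channel, autocorrelation functions are estimated on consecutive
75%-overlapping 2-min segments (`acf_curve()`): mean-subtracted, with
biased (1/n) normalisation, which trades a small downward bias for much
smoother long-lag behaviour — important because the **baseline** is the
median autocorrelation between 40 and 60 s. TC is the first lag at which
the autocorrelation falls *strictly below* halfway between its value at the
first lag (0.125 s) and the baseline (`tc_half_decay()`). Three numerical
conventions matter:

* the comparison is strict (`< threshold`), so exact ties postpone the
  crossing to the next lag;
* the floor is one lag (0.125 s): if the first-lag value is already below
  the threshold — as in shuffled surrogates — TC is 0.125 s, never less;
* if no crossing occurs within 60 s the value is capped there and flagged,
  a case the source material leaves unspecified.

Alternative baselines ([15, 30] s, or fixed 0) are configuration; across
segments spanning a genuine range of timescales the three variants give
rank correlations above 0.9, so conclusions do not hinge on the choice.

## Spatial correlations

On non-overlapping 2-min segments, zero-lag Pearson correlations of all
channel pairs are pooled across segments and averaged in 1-mm bins of
inter-electrode Euclidean distance (`cross_corr_by_distance()`; a pair
falls in bin [k, k+1) mm, reported at center k + 0.5). SC is the
unweighted mean of populated bin means with centers inside 7–79 mm
(`sc_mean()`), the range clinical grids populate well; [9, 50] and
[50, 79] mm variants are arguments, not code paths. "Cross-correlation"
here is a single coefficient per pair per segment — zero lag only — which
is why shuffled surrogates must give SC = 0, a property the tests assert to
within ±0.01. Pair correlations are pooled, then binned; the alternative
(bin within patient, then average) matters only when patients are combined,
which the package leaves to the caller.

## Surrogates

`shuffle_surrogate()` permutes the power series within each 2-min segment,
independently per channel, after power extraction. The per-segment power
*distribution* is exactly preserved (the tests compare sorted values) while
temporal — and, through per-channel independence, spatial — correlations
are destroyed. Surrogate TC equals the 0.125-s floor and surrogate SC
scatters around zero; any structure surviving the shuffle would indicate a
power-distribution artifact rather than genuine correlation.

## Slow-wave-sleep staging

The vigilance index on 30-s windows is the band-power ratio

$$\mathrm{index} = \frac{P_\theta + P_\delta}
{P_\alpha + P_{\beta_\mathrm{high}} + P_\mathrm{spindle}}$$

with Welch band powers (4-s Hanning sub-windows, 50% overlap) averaged
across channels before the ratio, making the index invariant to overall
scaling. The originating method does not print its band edges; the package
defaults to conventional definitions (delta 0.5–4, theta 4–8, alpha 8–12,
spindle 12–16, high beta 20–30 Hz), all configurable. A window is SWS when
its index exceeds the day's mean + 1 SD — days are scored individually,
midnight to midnight — and a 2-min segment is SWS only if all four of its
30-s windows are. The method detects SWS only; it is not a hypnogram.

## Hierarchy and statistics

Electrodes are assigned to the region (MT, LIP, LPFC, OFC, ACC — ordered
along the visual pathway) whose nearest atlas point lies within 9.5 mm
(`assign_regions()`); exact ties break by hierarchy order. Atlases are
consumed as point-cloud CSVs; surface reconstruction and template warping
are upstream of this package. Contrasts (SWS vs non-SWS, high vs low drug
load) balance group sizes by undersampling the majority
(`balance_undersample()`), use two-sided paired Wilcoxon signed-rank tests
with a seeded 10^4-resample percentile bootstrap CI on the median
difference (`paired_wilcoxon()`), combine per-patient Spearman TC–SC
correlations with Fisher's method (`covariation()`), and fit per-patient
least-squares slopes of TC against hierarchy rank (`hierarchy_slope()`,
mean over segments within region). Drug loads are summed dose/DDD
fractions per day (`aed_load()`).

# The lattice model

`net_config()` describes N = 1600 binary neurons on a 40 x 40 torus.
Connection strengths are uniform(0, 1) draws shaped by a Gaussian profile
of torus distance,

$$w_{ij} \propto u_{ij}\, e^{-r_{ij}^2 / 2\sigma^2}, \qquad \sigma = 4,$$

with zero diagonal; a random 20% of neurons is inhibitory (outgoing weights
negated). One global constant rescales the matrix so its largest absolute
eigenvalue is $\lambda$ — the single knob controlling distance to
criticality. Drug action multiplies excitatory or inhibitory columns by
$f_\mathrm{exc}$ / $f_\mathrm{inh}$ *after* scaling, so a reported
$\lambda$ always refers to the unperturbed network.

Dynamics are synchronous: neuron *i* fires at *t*+1 with probability equal
to its summed input clamped to [0, 1],

$$p_i(t+1) = \min\!\big(\max\!\big(\textstyle\sum_j w_{ij} s_j(t),\, 0\big),\, 1\big),$$

draws are independent Bernoulli, and one uniformly random neuron is forced
active each step as background drive (the run length is max_t = 2000
steps). For $\lambda < 1$ the population activity
$S(t) = N^{-1}\sum_i s_i(t)$ stays near the drive floor; for $\lambda > 1$
it saturates — both regimes are asserted in the tests, and a 4-neuron
version of the simulator is checked against exhaustive enumeration of its
2^4-state Markov chain.

Model TC applies the same half-decay rule to the autocorrelation of S(t)
(lags in steps, baseline = median over lags 400–600, mirroring the data
pipeline's tail median); model SC correlates 40 randomly monitored binary
traces, binned by torus distance, averaged over 1–10 grid units. DFA
Hurst exponents of S(t) use scales 100–1000 steps, 50%-overlapping
windows, linear detrending. `sweep_lambda()` ties it together: per-run TC,
SC, H and shuffled surrogates across
$\lambda \in \{0.7, 0.75, \ldots, 1.0\}$.

Two design points were genuinely open. First, the drive protocol: the
source material describes both "one random neuron per time step" (Methods)
and a phrasing that could be read as one activation per 2000 steps (figure
caption). The package follows the Methods reading — continuous weak drive
— and exposes `drive_every` so the sparse-drive variant is one argument
away. Second, whether each simulation redraws its weight matrix:
`sweep_lambda()` builds one seeded realization per lambda and runs the
replicate simulations on it, which keeps the sweep affordable and matches
the "adjust lambda by a constant factor" construction.

With these choices the model reproduces the data-like phenomenology at
desk scale (150 runs per lambda rather than 10^4): pooled Spearman
rho(TC, SC) ~ 0.8 across the sweep and ~0 for surrogates, ensemble-mean
TC maximal at lambda = 1, SC rising towards it, H near 0.5 at lambda = 0.7
and well above 0.8 at lambda = 1. Two honest caveats: S(t) at lambda = 0.7
retains short cascade correlations, so its mean DFA exponent sits slightly
above 0.5 (~0.55); and at lambda = 1 the 2000-step trace is strongly
nonstationary from the all-zero start, so DFA exponents exceed 1 (~1.4)
rather than sitting at 1 — the qualitative contrast between the regimes is
large and stable.

# The synthetic generator

`synth_config()` + `gen_electrodes()` + `gen_latent_envelopes()` +
`synth_ieeg()` emulate what the pipeline measures, not the biophysics:

* a latent per-channel log-Gaussian envelope at the 8-Hz power rate:
  AR(1) in time with autocorrelation $e^{-t/\tau_\mathrm{env}}$ (half-decay
  $\tau_\mathrm{env}\ln 2$), mixed across channels through the Cholesky
  factor of a Gaussian kernel of electrode distance (length
  `ell_space`), then exponentiated so power is log-normal;
* a 56–96 Hz noise carrier amplitude-modulated by that envelope, on a 1/f
  background with 50/100 Hz line components (10% of signal RMS, exercising
  the notch filter);
* SWS epochs: 0.5–4 Hz power boosted by `delta_boost` (default 4 in
  amplitude) *and* the envelope field replaced by white noise, so both the
  staging index and the correlation breakdown have ground truth;
* seizure/subclinical intervals and IED-channel labels written as
  annotations for the exclusion logic.

Electrode layouts use a 9.5-mm grid pitch with 1-mm jitter and one forced
5-mm pair, so 64-electrode grids span at least 5–90 mm and the 7–79 mm SC
window is densely populated.

Defaults were fixed once against the generator's own contract: `sdlog =
0.35` (spread of log10 power) and `snr_env = 6` (gamma-band amplitude SNR)
are the values at which the extracted power tracks the injected envelope at
Spearman rho > 0.8 per channel *while* log-power skewness stays inside
±0.5. Both requirements bind against the noise floor of the 32-sample
periodogram (~0.15 log10 units): weaker modulation is swamped by estimator
noise, stronger low-SNR modulation clips against the background floor and
skews the distribution.

What the generator does *not* emulate: realistic seizure or discharge
waveforms (annotations are intervals only), non-stationary drift over
hours, volume-conduction artifacts, reference-montage effects, or
region-specific spectra. Passing tests therefore demonstrate that the
estimators recover known correlation structure under realistic noise — not
that any clinical claim reproduces; the clinical-scale results require the
original recordings.

# Problem sizes and reproducibility

Everything is seeded: identical configurations give bit-identical
datasets, weights and simulations (the RNG stream is isolated, so library
calls do not disturb the caller's RNG). The shipped tests and the
acceptance script use desk-scale sizes chosen as the package's own
defaults: 150 runs per lambda (7 lambdas, N = 1600, max_t = 2000), 64 x
30-min synthetic recordings for the surrogate-SC null, 20 seeds per
generator grid point, 20 synthetic subjects for the SWS cohort, 200 paired
runs for the drug-factor contrast. Monotonicity and co-variation
conclusions are stable at these sizes; single-run quantities (one segment's
TC, one simulation's H) remain noisy by nature, which is why all headline
quantities are ensemble statistics.

# Worked example

```{r example, eval = FALSE}
el <- gen_electrodes(16, "grid", seed = 1)
cfg <- synth_config(n_channels = 16, duration = 600, tau_env = 2,
                    ell_space = 30, seed = 1)
sig <- synth_ieeg(cfg, gen_latent_envelopes(cfg, el), el)

ps <- gamma_power_series(sig)                 # 8 Hz log10 gamma-power
mean(tc_series(ps)$tc, na.rm = TRUE)          # ~ 0.125 + 2 log(2) seconds
sc_mean(cross_corr_by_distance(ps, el))       # distance-averaged SC

sur <- shuffle_surrogate(ps, seed = 2)
mean(tc_series(sur)$tc, na.rm = TRUE)         # ~ 0.125 s floor
sc_mean(cross_corr_by_distance(sur, el))      # ~ 0
```

# Known limitations

* The EDF container is replaced by a Parquet + CSV + JSON layout
  (`write_dataset()` / `read_dataset()`); signals round-trip losslessly,
  but interoperability with clinical EDF tooling is out of scope.
* The half-decay TC is grid-quantised to 0.125 s and capped at 60 s;
  segments with genuinely longer memory are censored at the cap.
* Model SC uses only 20 distinct torus distances at N = 1600, so
  single-run SC values are noisy; only ensemble statistics are
  interpretable.
* Fisher's method assumes independent per-unit p-values; overlapping
  segments within a unit violate independence for the *within*-unit p, so
  combined p-values should be read as descriptive, as in the original
  analysis.
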