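---
title: "Interhemispheric spike-field analysis with bicoher"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interhemispheric spike-field analysis with bicoher}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicoher)
```

## The scientific problem

When a primate plans a movement of one arm, posterior parietal cortex in
the *opposite* hemisphere carries most of the spiking signal, yet
low-frequency (beta, ~20-30 Hz) field potentials in *both* hemispheres
are modulated — including by the arm the local spikes ignore. One
candidate explanation is interhemispheric transfer: spikes in one
hemisphere's reach region contribute synaptic (dendritic) currents, and
hence local field potential (LFP), in the homotopic region of the other
hemisphere. A competing explanation is a common upstream drive to both
hemispheres. The two architectures predict the same zero-lag spike-field
coherence but opposite *signs* of the optimal spike-to-field lag: under
direct communication the field follows the spikes by an axonal conduction
delay (10-15 ms); under common input the field leads the spikes.

`bicoher` implements the full analysis chain needed to test these ideas
on trialized two-hemisphere recordings — multitaper spectral estimation,
trial-ensemble LFP-LFP and spike-LFP coherence, a lagged coherence scan,
wavelet spike-phase metrics (PLV, PPC), interspike-interval-shuffle
permutation nulls, per-frequency condition contrasts, and an algebraic
local/contralateral mixing model — together with a synthetic session
generator whose ground truth (coupling strengths, conduction delay,
architecture) is known, so every estimator can be validated end to end.

## Data model

A session holds trials; each trial has two LFP channels ("left",
"right") sampled at 1 kHz, per-unit spike trains, and three events
(target onset, go cue, movement onset) on one per-trial clock starting at
sample 0. LFP sample $i$ (0-based) covers $[i/f_s, (i+1)/f_s)$ seconds,
and every analysis window is half-open $[t_0, t_1)$ for both samples and
spikes, so adjacent windows tile without double counting.

Trials are labelled with one of ten conditions: five movement types
(saccade only, ipsimanual reach, contramanual reach, bimanual reaches to
a common target — "together" — or to diametrically opposed targets —
"apart") crossed with preferred/null direction. Because
"ipsimanual"/"contramanual" are hemisphere-relative terms, the stored
label uses the left hemisphere as the reference frame and
`relabel_for_hemisphere()` remaps at analysis time (swap
ipsi/contramanual; flip the bimanual-apart direction, whose label refers
to the contralateral arm). For bundles on disk the package uses a plain
directory format: a JSON manifest plus little-endian float64 blocks for
LFP, spikes and events (bit-exact round trips), with a `trials.csv`
export for quick inspection.

## The multitaper engine

Power spectra use discrete prolate spheroidal (Slepian) tapers computed
from the symmetric tridiagonal eigenproblem, with $K = \lfloor 2NW
\rfloor - 1$ tapers for time-half-bandwidth product $NW$. The per-trial
PSD is the taper-weighted average of eigenspectra,
$$S_{xx,n}(f) = \frac{1}{f_s K}\sum_{k=1}^{K} w_k |X_{n,k}(f)|^2,$$
averaged across trials. Weights are either Thomson's adaptive weights
(iterated to relative tolerance $10^{-6}$, at most 100 iterations, with
an eigenvalue-weight fallback and a warning on non-convergence) or fixed
eigenvalue weights. Two configurations recur: 400 ms (or 200 ms) windows
at $NW = 2.5$ giving 4 tapers and $\pm 6.25$ Hz ($\pm 12.5$ Hz)
resolution for LFP power and LFP-LFP coherence, and 800 ms windows at
$NW = 12$ giving 23 tapers and $\pm 15$ Hz resolution for spike-LFP
coherence. A band labelled 20-30 Hz analysed at $\pm 6.25$ Hz actually
carries information from 13.75-36.25 Hz; `effective_band()` computes
this, and all band-confinement claims in the package are stated against
the effective band.

Numerical conventions (chosen here, verified by internal oracles rather
than against any external magnitude): no zero padding ($n_{fft} = T$,
grid spacing $f_s/T$); one-sided spectra with the factor 2 on non-DC,
non-Nyquist bins so that $\sum S(f)\,\Delta f$ equals the signal
variance; per-window mean subtraction only; taper signs fixed so the
max-magnitude element is positive. Band power sums the PSD over grid
frequencies in the half-open band $[f_{lo}, f_{hi})$.

Baseline normalization divides by the mean band power over the 500 ms
before target onset and subtracts 1. The baseline is estimated with the
*same* window length as the timecourse being normalized (averaging the
sliding windows that fit inside the baseline epoch): comparing band
power across different window lengths would compare different spectral
smoothings and bias the ratio by several percent for narrowband rhythms.

## Coherence

Coherency is the ratio of the trial- and taper-averaged cross-spectrum to
the geometric mean of the averaged auto-spectra,
$C_{xy}(f) = S_{xy}(f) / \sqrt{S_{xx}(f) S_{yy}(f)}$; the package
reports its magnitude (0 = independent, 1 = perfectly coherent).
Coherence is intrinsically a cross-trial measurement, so a single trial
is an error, not a degenerate number. Both signals share one set of
eigenvalue taper weights, which keeps $|C| \le 1$ by Cauchy-Schwarz.
Spike-LFP coherence bins spikes at the LFP rate (1 ms bins, counts, so
multi-spike bins are preserved), subtracts each trial's mean rate to
remove the DC component, and runs the identical machinery.

Two estimator subtleties matter in practice and are enforced by the
package's higher-level wrappers:

* **Ensemble homogeneity.** `condition_coherence()` estimates coherence
  per (movement type, direction) ensemble and averages magnitudes rather
  than pooling directions. The finite-trial bias of $|C|$ depends on how
  per-trial power co-varies across the two channels; pooling trials with
  condition-dependent heteroscedasticity (e.g. gamma power high in both
  hemispheres on some trials, high in only one on others) modulates that
  bias and can fabricate "coherence differences" far outside any truly
  coupled band. Equal-sized homogeneous ensembles make the bias identical
  across conditions, so it cancels in contrasts.
* **Unequal trial counts.** For the same reason, conditions being
  contrasted should be estimated from equally many trials per ensemble;
  the bias scales like $\sqrt{\pi / (4NK)}$.

## The lagged coherence scan

`lagged_spike_lfp_coherence()` recomputes spike-LFP coherence with the
LFP window shifted by each lag on a 1 ms grid over ±50 ms and
band-averages the magnitude (default 24-38 Hz). Positive lag means the
LFP is delayed relative to the spikes. The scan's ability to localize a
delay comes entirely from the *bandwidth* of the coupling: a coupling
with power spread over bandwidth $2B$ yields a lag profile attenuated
roughly like $\mathrm{sinc}(2B\,\delta)$ at mismatch $\delta$, so a
6 Hz-wide rhythm is nearly shift-invariant over ±50 ms while a broadband
drive localizes sharply. This is why spike-LFP coherence uses the wide
$\pm 15$ Hz smoothing configuration.

A second, less obvious effect is phasor interference: if a zero-lag
narrowband channel (a shared rhythm) and a delayed broadband channel (a
spike-derived drive) are both present, their complex cross-spectral
contributions add with a relative phase $2\pi f d$, and the magnitude
maximum can be displaced well past the true delay. The package's
architecture scenarios (below) therefore isolate one mechanism at a
time, which is also what makes them interpretable as predictions.

## Phase metrics

The LFP phase at each spike time is read out with an L2-normalized
Morlet wavelet (7 cycles — a time-frequency compromise appropriate for
beta; the width is a package convention). Spikes closer than three
envelope SDs to a trace edge are dropped and counted. The phase
convention is fixed by a pure-cosine oracle: phase 0 at the oscillation
peak, decreasing to $-\pi/2$ at the falling zero-crossing a quarter
cycle later. Both phase statistics are rotation-invariant, so the
convention affects reported phases only.

The phase-locking value pools phases across trials,
$\mathrm{PLV} = |\tfrac1S \sum_s e^{j\theta_s}|$, with Rayleigh
significance $p = e^{-Z}$, $Z = S\,\mathrm{PLV}^2$ (with the standard
$(1 + (2Z - Z^2)/4S)$ correction below 50 spikes). PLV is positively
biased at low counts ($E[\mathrm{PLV}] \approx \sqrt{\pi}/2\,S^{-1/2}$
under uniformity — an explicit acceptance check). The pairwise phase
consistency uses per-trial mean resultants $m_n$ and is bias-corrected:
$$\mathrm{PPC} = \frac{|\sum_n m_n|^2 - \sum_n |m_n|^2}{N(N-1)},$$
with expectation 0 under no locking (it can be negative, exactly $-1$
for two antiphase trials) and limit $(I_1(\kappa)/I_0(\kappa))^2$ for
von Mises phases.

## Inference

The null for spike-field coherence permutes each trial's interspike
intervals (count, first-spike time and ISI multiset preserved exactly),
recomputes coherence — 188 permutations by default — and records
per-frequency 95th/99th percentile thresholds. Per-permutation RNG
streams are derived from one master seed by counter, so results are
independent of execution order. Shuffled thresholds do not depend on
movement condition (a tested invariance), which justifies pooling them
across movement types.

Spike-count controls mirror standard practice: units need at least 500
spikes in every movement condition (strict inequality at 499), and a
subsampling control draws exactly N spikes uniformly without replacement
while preserving trial structure. Condition contrasts run two-sided
t-tests per frequency across sites — paired by default, since conditions
are measured at the same sites, with a pooled option — and Bonferroni
correction over the tested grid (39 frequencies for the default 14-90 Hz
grid at 2 Hz spacing, a package choice).

## The mixing model

The mixing model asks whether per-condition beta-band LFP modulation is
explained by local spiking alone or needs a contralateral contribution:
$$\beta_c = \mathrm{gain}\,[w\,r_{\mathrm{local},c} +
(1-w)\,r_{\mathrm{contra},c}] + \mathrm{offset},$$
over the ten condition profiles, with $w \in [0,1]$ fitted by a
0.01-resolution grid search plus local refinement, and compared against
the pure-local boundary ($w = 1$) by an F-test on $(1, n-3)$ degrees of
freedom. The functional form (an affine mixture of baseline-normalized
population rates), the constraint and the fitting procedure are this
package's reconstruction of a two-source mixing analysis; its claims are
limited to self-consistency and parameter recovery on synthetic data,
where generating weights in $\{0.6, \dots, 1.0\}$ are recovered within
±0.05 at the default profile noise (SD 0.02 on normalized modulations).
Collinear local/contralateral rate vectors set an identifiability flag
and block model comparison.

## The synthetic session generator

No public recordings accompany the problem, so the generator *is* the
test bed, and its defaults define the study conditions:

* **Design.** 15 repetitions of each of the 10 interleaved conditions;
  2.7 s trials at 1 kHz; target onset 0.7 s, go cue 2.2 s, movement
  2.4 s. One unit per hemisphere by default.
* **Beta.** A 25 Hz ± 3 Hz Gaussian narrowband process per hemisphere,
  built as $a_c[\sqrt{c}\,s(t) + \sqrt{1-c}\,p_h(t)]$ from a shared
  component $s$ and private components $p_h$. Post-target amplitudes are
  ordered saccade 1.4 > ipsimanual 1.2 > contramanual 1.0 >
  bimanual-together 0.8 > bimanual-apart 0.6 (relative units); before
  target onset all conditions use the saccade-level amplitude, so
  baseline normalization has a condition-independent reference. Shared
  fractions are 0.5 (together), 0.25 (saccade/unimanual), 0.1 (apart),
  0.25 at baseline — producing the elevated/suppressed interhemispheric
  coherence pattern.
* **Gamma and rates.** 90 ± 20 Hz narrowband gamma and Poisson spike
  rates are contralaterally tuned: high (gamma amplitude 0.5, 45 Hz
  spikes) iff the hemisphere's contralateral arm moves in the preferred
  direction, low (0.15, 25 Hz) otherwise, 30 Hz at baseline. Values are
  typical parietal reach-region magnitudes.
* **Spiking.** Inhomogeneous Poisson by thinning with a 1 ms dead time
  (the base rate is dead-time compensated so mean counts match), with
  intensity $r_c\,e^{\kappa \cos \phi(t)}/I_0(\kappa)$, $\kappa = 0.8$,
  where $\phi$ is the own-hemisphere beta phase (from the analytic
  signal).
* **Architectures.** Under `direct`, each hemisphere's LFP also receives
  the opposite hemisphere's spike train, mean-centered, smoothed with a
  Gaussian kernel and delayed by the 12 ms conduction delay. The kernel
  SD is 10 ms: the von Mises rate modulation carries harmonics at 2-3x
  the beta frequency, and a sharper kernel would let the drive inject
  condition-dependent coherence into the gamma band, contradicting the
  design goal that condition differences are confined to the effective
  beta band. Under `common_input` there is no cross drive and spikes
  follow the local beta phase evaluated one conduction delay earlier
  (field leads spikes).
* **Scenario presets.** `architecture_scenario("direct")` (cross gain 4,
  shared fraction 0.05, 5 ms kernel) and
  `architecture_scenario("common_input")` (no drive, broadband 12 Hz
  half-bandwidth shared component, $\kappa = 1.5$) isolate each
  mechanism so the lag scan recovers the injected ±12 ms delay; in the
  default mixed configuration the narrowband coupling is nearly
  shift-invariant and phasor interference displaces the peak, so the
  dissociation is tested where it is identifiable.

All randomness flows from one master seed through per-trial derived
streams: identical configurations give bit-identical sessions.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: non-stationary beta bursts, 1/f broadband
background, volume conduction, electrode drift, multi-unit
contamination, reaction-time variability, or any within-trial evolution
of coupling. The generator's linear-mixture beta sharing makes the
common-signal coherence law exact by construction; real coherence levels
and their interpretation depend on physiology the generator does not
model.

## Problem sizes and numerical choices

The validation suite uses trial counts of 15 per condition (matching the
emulated design) for end-to-end checks, 200-500 trial ensembles for
closed-form coherence oracles, 1000 replicates for estimator-bias
checks, 188-permutation nulls over 50 independent runs for calibration,
and 10-20 seeded runs for pattern and lag-recovery checks; these sizes
were chosen so Monte-Carlo error sits well inside each stated tolerance.
Degenerate inputs error early and descriptively (empty ensembles,
single-trial coherence, zero baseline power, out-of-trace epochs, spikes
above Nyquist); all-zero segments return all-zero spectra; adaptive
weighting falls back to eigenvalue weights (with a counted warning) if
the iteration does not converge; paired contrasts with a zero-variance
difference report p = 1 when the difference is identically zero and
p = 0 when it is a nonzero constant.

## Known limitations

The mixing model's functional form is a reconstruction (see above). The
lag scan shifts the LFP window (not the spikes); its sign convention is
pinned by the simulator oracle. Site-level coherence spectra are
averaged with equal weight across sites. The package analyses trialized
sessions only; continuous recordings, spike sorting and directed
(Granger-style) measures are out of scope.
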