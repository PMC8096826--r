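# bicoher

Interhemispheric spike-field and field-field coherence analysis for
trialized two-hemisphere electrophysiology.

## The problem

During the planning of arm movements, spiking in the posterior parietal
reach region encodes mainly the contralateral arm, yet beta-band
(20-30 Hz) local field potentials in both hemispheres carry information
about *both* arms. Where does the ipsilateral-arm information in the
field come from? Two architectures compete:

* **Direct communication** — spikes from one hemisphere's reach region
  contribute dendritic currents (hence LFP) in the other, after an
  axonal conduction delay of 10-15 ms;
* **Common input** — an upstream source drives similar fields in both
  hemispheres, and the field drives the local spikes.

Both predict interhemispheric spike-field coherence; they differ in the
*sign* of the optimal spike-to-field lag. `bicoher` implements the full
analysis chain to make that dissociation, for researchers analysing
paired-hemisphere recordings or building simulation-validated pipelines:

* DPSS (Slepian) multitaper power spectra with Thomson adaptive weights:
  per-trial PSD `S(f) = (1/(f_s K)) sum_k w_k |X_k(f)|^2`, averaged over
  trials; band power, sliding-window timecourses, baseline
  normalization (`value / baseline - 1`);
* trial-ensemble coherency `C(f) = S_xy / sqrt(S_xx S_yy)` for LFP-LFP
  and spike-LFP pairs (spikes binned at 1 ms, mean rate removed), with a
  lagged coherence scan over ±50 ms;
* spike-phase metrics from Morlet wavelet phases: phase-locking value
  `PLV = |mean(exp(i theta_s))|` with Rayleigh test, and pairwise phase
  consistency `PPC = (|sum m_n|^2 - sum |m_n|^2) / (N(N-1))` from
  per-trial resultants `m_n`;
* interspike-interval-shuffle permutation nulls (188 permutations,
  95%/99% per-frequency thresholds), minimum-spike-count filters,
  subsampling controls, per-frequency condition contrasts with
  Bonferroni correction;
* an algebraic mixing model
  `beta_c = gain [w r_local + (1-w) r_contra] + offset` fitted over the
  ten task conditions with `w` constrained to [0, 1], compared against
  the pure-local boundary by F-test;
* a synthetic two-hemisphere session generator with known ground truth
  (condition-dependent beta amplitude and interhemispheric sharing,
  contralaterally tuned gamma and spiking, von Mises spike-phase
  coupling, a 12 ms conduction delay, and switchable
  direct/common-input architectures).

## Worked example

```r
library(bicoher)

s <- generate_session(sim_config(seed = 42))$session
s
#> <bicoher_session> 150 trials, 2 units, f_s = 1000 Hz
#>   bimanual_apart     30 trials
#>   bimanual_together  30 trials
#>   contramanual       30 trials
#>   ipsimanual         30 trials
#>   saccade            30 trials
#>   provenance: synthetic (seed 42, direct architecture)

# Interhemispheric beta coherence in the 500 ms before the go cue:
# elevated when both arms reach one target, suppressed when they reach
# opposite targets.
beta <- function(cs) mean(cs$magnitude[cs$freq >= 20 & cs$freq <= 30])
beta(condition_coherence(s, "bimanual_together"))   # 0.555
beta(condition_coherence(s, "bimanual_apart"))      # 0.202

# Lagged spike-LFP coherence of a left unit against the right-hemisphere
# field: the peak at a positive lag says the field follows the spikes.
trs <- select_trials(s, "bimanual_together")
lagged_spike_lfp_coherence(trs, "L1", epoch("go_cue", -0.8, 0),
                           s$f_s, "right")
#> <lag_scan> band 24-38 Hz, lags -50..50 ms; peak 0.163 at +17 ms

# Mixing model: how much of the beta modulation is local?
fit <- fit_mixing_weight(build_condition_profiles(s))
summary(fit)
#> Interhemispheric mixing model
#>   local-input weight w = 0.438  (gain -0.768, offset -0.402)
#>   RSS: free 0.6876 | pure local (w=1) 0.8421 | pure contralateral (w=0) 0.7814
#>   vs pure local drive: F(1,7) = 1.573, p = 0.25
```

The coherence numbers recover the generator's injected shared fractions
(0.5 vs 0.1 plus noise dilution); the +17 ms lag-scan peak reflects the
injected 12 ms conduction delay blurred by the narrowband shared rhythm
(the `architecture_scenario()` presets isolate the mechanisms and
recover the delay within a few ms); the negative mixing gain reflects
the generator's inverted beta-vs-rate ordering. See the vignette
(`vignettes/interhemispheric-coherence.Rmd`) for the model, conventions
and design decisions, and `run_pipeline()` (or
`inst/cli/bicoher.R run --config run.json`) for the one-shot pipeline
that writes CSV/JSON tables and a Markdown report.

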