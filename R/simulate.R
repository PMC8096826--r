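# Synthetic two-hemisphere session generator with known ground truth.
#
# Each hemisphere's LFP is a sum of (i) a narrowband beta process built
# from a shared component s(t) and a private component p_h(t), mixed as
# amp * (sqrt(c) s + sqrt(1 - c) p_h) where c is the condition's shared
# fraction, (ii) a contralaterally tuned gamma process, and (iii) white
# noise. Spikes are an inhomogeneous Poisson process whose intensity is
# modulated by the phase of the unit's own-hemisphere beta component
# through a von Mises gain. Under the direct-communication architecture
# each hemisphere's LFP additionally receives the opposite hemisphere's
# smoothed spike train after a conduction delay; under the common-input
# architecture spikes follow the local beta phase with a filter delay, so
# the field leads the spikes.

#' Simulator configuration
#'
#' Defaults emulate a delayed-reach session: ten interleaved conditions
#' (five movement types x preferred/null), 15 repetitions each, 1 kHz
#' sampling, a 25 Hz beta rhythm whose amplitude after target onset is
#' ordered saccade > ipsimanual > contramanual > bimanual-together >
#' bimanual-apart, interhemispheric beta sharing elevated for
#' bimanual-together and suppressed for bimanual-apart, contralaterally
#' tuned spiking and gamma, and a 12 ms interhemispheric conduction delay.
#' Before target onset every condition uses the saccade-level beta
#' amplitude and the baseline shared fraction, so baseline normalization
#' has a condition-independent reference.
#'
#' @param seed Master seed; all randomness flows from it.
#' @param n_trials_per_condition Repetitions of each of the 10 conditions.
#' @param trial_duration Trace length in seconds.
#' @param f_s Sampling rate (Hz).
#' @param beta_freq Beta center frequency (Hz).
#' @param beta_half_bw Half-bandwidth (Hz) of the narrowband beta
#'   processes (default 3: a 22-28 Hz rhythm).
#' @param beta_amp_by_condition Named relative beta amplitudes per
#'   movement type (post-target).
#' @param baseline_beta_amp Pre-target beta amplitude (all conditions).
#' @param shared_fraction_by_condition Named fraction (0-1) of beta-band
#'   variance common to the two hemispheres, per movement type.
#' @param baseline_shared_fraction Pre-target shared fraction.
#' @param conduction_delay Interhemispheric delay in seconds.
#' @param architecture `"direct"` (spikes from one hemisphere drive the
#'   other's field after the delay) or `"common_input"` (shared field
#'   drives spikes after a filter delay).
#' @param rate_driven,rate_undriven Post-target firing rate (Hz) for units
#'   whose contralateral arm does / does not move in the preferred
#'   direction.
#' @param rate_baseline Pre-target firing rate (Hz).
#' @param phase_coupling_kappa Von Mises concentration of spike-phase
#'   coupling (>= 0).
#' @param noise_sd White noise SD (relative voltage units).
#' @param gamma_freq Gamma center frequency (Hz).
#' @param gamma_amp_driven,gamma_amp_undriven Gamma amplitudes for
#'   driven/undriven hemispheres.
#' @param cross_gain Gain of the delayed spike-derived cross drive
#'   (direct architecture).
#' @param smooth_sd Gaussian smoothing SD (s) applied to the spike drive.
#' @param refractory Absolute dead time (s) of the spike sampler.
#' @param target_on,delay_period,move_latency Event layout: target onset
#'   time, target-to-go delay, go-to-movement latency (seconds).
#' @param n_units_per_hemisphere Units simulated per hemisphere.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_trials_per_condition = 15,
                       trial_duration = 2.7,
                       f_s = 1000,
                       beta_freq = 25,
                       beta_half_bw = 3,
                       beta_amp_by_condition = c(
                         saccade = 1.4, ipsimanual = 1.2,
                         contramanual = 1.0, bimanual_together = 0.8,
                         bimanual_apart = 0.6),
                       baseline_beta_amp = 1.4,
                       shared_fraction_by_condition = c(
                         saccade = 0.25, ipsimanual = 0.25,
                         contramanual = 0.25, bimanual_together = 0.5,
                         bimanual_apart = 0.1),
                       baseline_shared_fraction = 0.25,
                       conduction_delay = 0.012,
                       architecture = c("direct", "common_input"),
                       rate_driven = 45,
                       rate_undriven = 25,
                       rate_baseline = 30,
                       phase_coupling_kappa = 0.8,
                       noise_sd = 0.5,
                       gamma_freq = 90,
                       gamma_amp_driven = 0.5,
                       gamma_amp_undriven = 0.15,
                       cross_gain = 0.6,
                       smooth_sd = 0.010,
                       refractory = 0.001,
                       target_on = 0.7,
                       delay_period = 1.5,
                       move_latency = 0.2,
                       n_units_per_hemisphere = 1) {
  architecture <- match.arg(architecture)
  cfg <- as.list(environment())
  stopifnot(all(beta_amp_by_condition >= 0),
            all(shared_fraction_by_condition >= 0),
            all(shared_fraction_by_condition <= 1),
            rate_driven >= 0, rate_undriven >= 0,
            phase_coupling_kappa >= 0,
            abs(trial_duration * f_s - round(trial_duration * f_s)) < 1e-9)
  stopifnot(all(MOVEMENT_TYPES %in% names(beta_amp_by_condition)),
            all(MOVEMENT_TYPES %in% names(shared_fraction_by_condition)))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d, %d trials/condition, %g s @ %g Hz, %s architecture\n",
    x$seed, x$n_trials_per_condition, x$trial_duration, x$f_s,
    x$architecture))
  invisible(x)
}

# Unit-variance narrowband Gaussian process: white noise through a
# zero-phase Butterworth bandpass (order-2 filter run forward and
# backward = 4th-order magnitude response), center +/- half_bw.
narrowband_noise <- function(n, f0, half_bw, f_s) {
  bf <- signal::butter(2, c(f0 - half_bw, f0 + half_bw) / (f_s / 2),
                       type = "pass")
  x <- signal::filtfilt(bf, rnorm(n + 2000))
  x <- x[1001:(1000 + n)]            # discard filter edges
  x / stats::sd(x)
}

# Instantaneous phase via the analytic signal (FFT Hilbert transform).
analytic_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(X * h, inverse = TRUE) / n)
}

#' Generate one trial's two-hemisphere LFP pair
#'
#' Builds the shared and private beta components, applies the
#' condition-dependent amplitude envelope (baseline level before target
#' onset, condition level after), adds contralaterally tuned gamma and
#' white noise. The spike-derived cross drive of the direct architecture
#' is added later by [generate_session()], once spikes exist.
#'
#' @param cfg A [sim_config()].
#' @param movement_type,direction Condition label (left-hemisphere
#'   reference frame).
#' @return List with `left`, `right` (voltage traces), `shared` (the
#'   common beta process), `beta_left`, `beta_right` (beta components),
#'   `phase_left`, `phase_right` (instantaneous beta phases).
#' @export
generate_lfp_pair <- function(cfg, movement_type, direction) {
  n <- round(cfg$trial_duration * cfg$f_s)
  i_target <- round(cfg$target_on * cfg$f_s)
  pre <- seq_len(i_target)

  s <- narrowband_noise(n, cfg$beta_freq, cfg$beta_half_bw, cfg$f_s)
  pL <- narrowband_noise(n, cfg$beta_freq, cfg$beta_half_bw, cfg$f_s)
  pR <- narrowband_noise(n, cfg$beta_freq, cfg$beta_half_bw, cfg$f_s)

  amp <- rep(cfg$beta_amp_by_condition[[movement_type]], n)
  amp[pre] <- cfg$baseline_beta_amp
  cc <- rep(cfg$shared_fraction_by_condition[[movement_type]], n)
  cc[pre] <- cfg$baseline_shared_fraction

  beta_L <- amp * (sqrt(cc) * s + sqrt(1 - cc) * pL)
  beta_R <- amp * (sqrt(cc) * s + sqrt(1 - cc) * pR)

  arms <- arm_movements(movement_type, direction)
  gamma_amp <- function(arm) {
    if (arm == "preferred") cfg$gamma_amp_driven else cfg$gamma_amp_undriven
  }
  gam_env_L <- rep(gamma_amp(arms$right_arm), n)  # left hem <- right arm
  gam_env_R <- rep(gamma_amp(arms$left_arm), n)
  gam_env_L[pre] <- cfg$gamma_amp_undriven
  gam_env_R[pre] <- cfg$gamma_amp_undriven
  gam_L <- gam_env_L * narrowband_noise(n, cfg$gamma_freq, 20, cfg$f_s)
  gam_R <- gam_env_R * narrowband_noise(n, cfg$gamma_freq, 20, cfg$f_s)

  list(left = beta_L + gam_L + rnorm(n, sd = cfg$noise_sd),
       right = beta_R + gam_R + rnorm(n, sd = cfg$noise_sd),
       shared = s, beta_left = beta_L, beta_right = beta_R,
       phase_left = analytic_phase(beta_L),
       phase_right = analytic_phase(beta_R))
}

#' Generate one unit's spike train for a trial
#'
#' Inhomogeneous Poisson by thinning with a 1 ms (configurable) dead time.
#' The intensity is `r(t) * exp(kappa * cos(phi(t))) / I0(kappa)` where
#' `phi` is the unit's own-hemisphere beta phase: under the direct
#' architecture at zero lag, under common input evaluated
#' `conduction_delay` earlier (the field leads the spikes). The base rate
#' is dead-time compensated so that mean counts match `r * duration`.
#'
#' @param cfg A [sim_config()].
#' @param movement_type,direction Condition label.
#' @param hemisphere Unit's hemisphere.
#' @param phase Instantaneous beta phase of that hemisphere (radians, one
#'   per sample).
#' @return Sorted numeric vector of spike times (seconds).
#' @export
generate_spikes <- function(cfg, movement_type, direction, hemisphere,
                            phase) {
  n <- length(phase)
  i_target <- round(cfg$target_on * cfg$f_s)
  arms <- arm_movements(movement_type, direction)
  contra_arm <- if (hemisphere == "left") arms$right_arm else arms$left_arm
  r_cond <- if (contra_arm == "preferred") cfg$rate_driven else
    cfg$rate_undriven
  rate <- rep(r_cond, n)
  rate[seq_len(i_target)] <- cfg$rate_baseline
  # dead-time compensation
  rate <- rate / (1 - rate * cfg$refractory)

  kap <- cfg$phase_coupling_kappa
  lag_samp <- if (cfg$architecture == "common_input")
    round(cfg$conduction_delay * cfg$f_s) else 0L
  idx_phase <- function(i) {
    j <- i - lag_samp
    phase[pmax(j, 1L)]
  }
  gain_max <- exp(kap) / besselI(kap, 0)
  lam_max <- max(rate) * gain_max
  n_cand <- rpois(1, lam_max * n / cfg$f_s)
  if (n_cand == 0) return(numeric(0))
  tc <- sort(runif(n_cand, 0, n / cfg$f_s))
  ic <- pmin(floor(tc * cfg$f_s) + 1, n)
  lam <- rate[ic] * exp(kap * cos(idx_phase(ic))) / besselI(kap, 0)
  keep <- runif(n_cand) < lam / lam_max
  st <- tc[keep]
  if (cfg$refractory > 0 && length(st) > 1) {
    out <- st[1]; last <- st[1]
    for (t in st[-1]) {
      if (t - last >= cfg$refractory) { out <- c(out, t); last <- t }
    }
    st <- out
  }
  st
}

# Gaussian-smoothed, delayed, mean-centered spike drive at the LFP rate.
spike_drive <- function(spikes, n, f_s, delay, smooth_sd) {
  counts <- bin_spikes(spikes, n, f_s)
  counts <- counts - mean(counts)
  hw <- ceiling(4 * smooth_sd * f_s)
  u <- (-hw):hw
  kern <- exp(-(u / f_s)^2 / (2 * smooth_sd^2))
  kern <- kern / sum(kern)
  sm <- stats::convolve(counts, rev(kern), type = "open")
  sm <- sm[(hw + 1):(hw + n)]
  d <- round(delay * f_s)
  c(numeric(d), sm)[seq_len(n)]
}

#' Generate a complete synthetic session
#'
#' Produces `n_trials_per_condition x 10` trials in a seed-determined
#' interleaved order. Each trial draws its own RNG stream derived from the
#' master seed by counter, so identical configurations give bit-identical
#' sessions. Under the direct architecture each hemisphere's LFP receives
#' the opposite hemisphere's smoothed spike train delayed by the
#' conduction delay.
#'
#' @param cfg A [sim_config()].
#' @return List with `session` (a [session()]) and `ground_truth`
#'   (config echo plus the realized trial order and per-trial seeds:
#'   enough to regenerate every trial deterministically).
#' @export
generate_session <- function(cfg) {
  cl <- condition_labels()
  conds <- cl[rep(seq_len(nrow(cl)), cfg$n_trials_per_condition), ]
  set.seed(cfg$seed)
  ord <- sample.int(nrow(conds))
  conds <- conds[ord, ]

  units <- data.frame(
    unit_id = c(paste0("L", seq_len(cfg$n_units_per_hemisphere)),
                paste0("R", seq_len(cfg$n_units_per_hemisphere))),
    hemisphere = rep(c("left", "right"), each = cfg$n_units_per_hemisphere),
    stringsAsFactors = FALSE)

  n <- round(cfg$trial_duration * cfg$f_s)
  go_cue <- cfg$target_on + cfg$delay_period
  move_onset <- go_cue + cfg$move_latency
  trials <- vector("list", nrow(conds))
  trial_seeds <- integer(nrow(conds))

  for (i in seq_len(nrow(conds))) {
    mt <- conds$movement_type[i]; dir <- conds$direction[i]
    ts <- derive_seed(cfg$seed, i)
    trial_seeds[i] <- ts
    set.seed(ts)
    lf <- generate_lfp_pair(cfg, mt, dir)
    spikes <- list()
    for (j in seq_len(nrow(units))) {
      h <- units$hemisphere[j]
      ph <- if (h == "left") lf$phase_left else lf$phase_right
      spikes[[units$unit_id[j]]] <- generate_spikes(cfg, mt, dir, h, ph)
    }
    left <- lf$left; right <- lf$right
    if (cfg$architecture == "direct") {
      for (j in seq_len(nrow(units))) {
        drv <- spike_drive(spikes[[units$unit_id[j]]], n, cfg$f_s,
                           cfg$conduction_delay, cfg$smooth_sd)
        if (units$hemisphere[j] == "left")
          right <- right + cfg$cross_gain * drv
        else left <- left + cfg$cross_gain * drv
      }
    }
    trials[[i]] <- trial(i, mt, dir, left, right, spikes,
                         target_on = cfg$target_on, go_cue = go_cue,
                         move_onset = move_onset)
  }
  s <- session(trials, units, f_s = cfg$f_s,
               provenance = sprintf("synthetic (seed %d, %s architecture)",
                                    cfg$seed, cfg$architecture))
  gt <- list(config = unclass(cfg),
             trial_order = ord,
             trial_seeds = trial_seeds,
             conditions = conds)
  list(session = s, ground_truth = gt)
}

#' Architecture-dissociation scenario presets
#'
#' Configurations that isolate the two candidate mechanisms of
#' interhemispheric coordination so the lagged coherence scan can
#' dissociate them. In the `"direct"` scenario interhemispheric coupling
#' comes almost entirely from the spike-derived cross drive (strong cross
#' gain, near-zero shared fraction), so the scan peaks at a positive lag
#' equal to the conduction delay. In the `"common_input"` scenario there
#' is no cross drive; both fields share a broadband common drive
#' (half-bandwidth 12 Hz) and spikes follow the local field after the
#' same delay, so the extremum falls at negative lag.
#'
#' @param architecture `"direct"` or `"common_input"`.
#' @param seed Master seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
architecture_scenario <- function(architecture = c("direct",
                                                   "common_input"),
                                  seed = 1, ...) {
  architecture <- match.arg(architecture)
  flat <- function(v) stats::setNames(rep(v, 5), MOVEMENT_TYPES)
  if (architecture == "direct") {
    sim_config(seed = seed, architecture = "direct", cross_gain = 4,
               smooth_sd = 0.005,
               shared_fraction_by_condition = flat(0.05),
               baseline_shared_fraction = 0.05, ...)
  } else {
    sim_config(seed = seed, architecture = "common_input", cross_gain = 0,
               shared_fraction_by_condition = flat(0.6),
               baseline_shared_fraction = 0.6, beta_half_bw = 12,
               phase_coupling_kappa = 1.5, ...)
  }
}
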