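# Shared fixtures, built in code at test time.

# Small, fast session for structural tests.
small_config <- function(seed = 1, n_trials_per_condition = 2, ...) {
  sim_config(seed = seed,
             n_trials_per_condition = n_trials_per_condition, ...)
}

# A hand-built deterministic trial: pure 25 Hz cosine on both channels.
cosine_trial <- function(id = 1, f0 = 25, f_s = 1000, dur = 3,
                         spikes = list(), movement_type = "saccade",
                         direction = "preferred") {
  tt <- (0:(dur * f_s - 1)) / f_s
  x <- cos(2 * pi * f0 * tt)
  trial(id, movement_type, direction, x, x, spikes,
        target_on = 0.7, go_cue = 2.2, move_onset = 2.4)
}

# Independent white-noise spike/LFP fixture for null-calibration tests:
# homogeneous Poisson trains paired with unrelated noise segments.
independent_pairs <- function(n_trials, T_samples, f_s, rate = 40) {
  dur <- T_samples / f_s
  spk <- lapply(seq_len(n_trials), function(i)
    sort(runif(rpois(1, rate * dur), 0, dur)))
  lfp <- lapply(seq_len(n_trials), function(i) rnorm(T_samples))
  list(spikes = spk, lfp = lfp)
}

# Band-averaged interhemispheric lag profile pooled over the two
# unit/contra-channel pairs of a session.
pooled_lag_profile <- function(s, movement_type = "bimanual_together",
                               band = c(24, 38),
                               ep = epoch("go_cue", -0.8, 0)) {
  trs <- select_trials(s, movement_type)
  l1 <- lagged_spike_lfp_coherence(trs, "L1", ep, s$f_s, "right",
                                   band = band)
  l2 <- lagged_spike_lfp_coherence(trs, "R1", ep, s$f_s, "left",
                                   band = band)
  list(lags = l1$lags, value = (l1$value + l2$value) / 2)
}

beta_lfp_coherence <- function(s, movement_types,
                               ep = epoch("go_cue", -0.5, 0),
                               band = c(20, 30), nw = 2.5) {
  cs <- condition_coherence(s, movement_types, ep, nw)
  mean(cs$magnitude[cs$freq >= band[1] & cs$freq <= band[2]])
}

# Baseline-normalized beta band power per movement type over the delay
# epoch, pooling directions and both channels.
delay_beta_modulation <- function(s, band = c(20, 30),
                                  ep = epoch("target_on", 0.65, 1.15),
                                  base = epoch("target_on", -0.5, 0)) {
  T_e <- round((ep$end_offset - ep$start_offset) * s$f_s)
  T_b <- round((base$end_offset - base$start_offset) * s$f_s)
  tp_e <- make_tapers(T_e, 2.5)
  tp_b <- make_tapers(T_b, 2.5)
  out <- numeric(0)
  for (mt in c("saccade", "ipsimanual", "contramanual",
               "bimanual_together", "bimanual_apart")) {
    trs <- select_trials(s, mt)
    segs_e <- c(lapply(trs, function(tr) extract_epoch(tr, ep, s$f_s)$lfp$left),
                lapply(trs, function(tr) extract_epoch(tr, ep, s$f_s)$lfp$right))
    segs_b <- c(lapply(trs, function(tr) extract_epoch(tr, base, s$f_s)$lfp$left),
                lapply(trs, function(tr) extract_epoch(tr, base, s$f_s)$lfp$right))
    bp_e <- band_power(mt_spectrum(segs_e, tp_e, s$f_s, "eigenvalue"), band)
    bp_b <- band_power(mt_spectrum(segs_b, tp_b, s$f_s, "eigenvalue"), band)
    out[mt] <- bp_e / bp_b - 1
  }
  out
}

# Synthesize a condition profile from known mixing parameters.
synthetic_profile <- function(w, gain = 1, offset = 0, noise_sd = 0) {
  cl <- condition_labels()
  rate_of <- function(mt, dir, hemi) {
    arms <- bicoher:::arm_movements(mt, dir)
    contra <- if (hemi == "left") arms$right_arm else arms$left_arm
    if (contra == "preferred") 0.5 else -0.17   # normalized about baseline
  }
  local <- mapply(rate_of, cl$movement_type, cl$direction, "left")
  contra <- mapply(rate_of, cl$movement_type, cl$direction, "right")
  beta <- gain * (w * local + (1 - w) * contra) + offset +
    rnorm(nrow(cl), sd = noise_sd)
  data.frame(movement_type = cl$movement_type, direction = cl$direction,
             beta_mod = beta, local_rate = local, contra_rate = contra)
}
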