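# Trial-ensemble coherence. Coherence is a measurement across trials:
# auto- and cross-spectra are averaged over tapers (eigenvalue weights,
# shared between the two signals so |C| <= 1 by Cauchy-Schwarz) and over
# trials before the ratio is formed.

# Core: trial/taper-averaged cross-spectral matrix from precomputed tapered
# FFT lists (each element T x K complex). Returns two-sided spectra.
cross_spectra <- function(Xs, Ys, w_eig, f_s) {
  K <- length(w_eig)
  N <- length(Xs)
  T_ <- nrow(Xs[[1]])
  Sxx <- numeric(T_); Syy <- numeric(T_); Sxy <- complex(T_)
  for (n in seq_len(N)) {
    X <- Xs[[n]]; Y <- Ys[[n]]
    Sxx <- Sxx + drop((abs(X)^2) %*% w_eig)
    Syy <- Syy + drop((abs(Y)^2) %*% w_eig)
    Sxy <- Sxy + drop((X * Conj(Y)) %*% w_eig)
  }
  list(Sxx = Sxx / (f_s * K * N), Syy = Syy / (f_s * K * N),
       Sxy = Sxy / (f_s * K * N))
}

coherence_from_ffts <- function(Xs, Ys, tapers, f_s, n_spikes = NA) {
  w_eig <- tapers$eigenvalues * tapers$K / sum(tapers$eigenvalues)
  cs <- cross_spectra(Xs, Ys, w_eig, f_s)
  T_ <- tapers$T
  n_os <- floor(T_ / 2) + 1
  idx <- seq_len(n_os)
  denom <- sqrt(cs$Sxx[idx] * cs$Syy[idx])
  coh <- ifelse(denom > 0, cs$Sxy[idx] / denom, 0 + 0i)
  structure(list(freq = (idx - 1) * f_s / T_,
                 coherency = coh, magnitude = abs(coh),
                 n_trials = length(Xs), K = tapers$K, NW = tapers$NW,
                 f_s = f_s,
                 half_bandwidth = half_bandwidth(T_ / f_s, tapers$NW),
                 n_spikes = n_spikes),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf(
    "<coherence_spectrum> %d freqs, %d trials, K = %d (+/-%g Hz smoothing)\n",
    length(x$freq), x$n_trials, x$K, x$half_bandwidth))
  if (!is.na(x$n_spikes)) cat("  spike-LFP,", x$n_spikes, "spikes\n")
  invisible(x)
}

#' LFP-LFP coherence
#'
#' Complex coherency `C(f) = S_xy / sqrt(S_xx * S_yy)` from trial- and
#' taper-averaged multitaper spectra. Magnitude runs from 0 (independent)
#' to 1 (perfectly coherent) and is invariant to rescaling either signal.
#'
#' @param x_trials,y_trials Lists of equal-length numeric segments, one
#'   per trial (same trial count, `>= 2`: coherence is undefined on a
#'   single trial).
#' @param tapers A [make_tapers()] object with `T` equal to the segment
#'   length.
#' @param f_s Sampling rate in Hz.
#' @return A `"coherence_spectrum"` object: `freq`, complex `coherency`,
#'   `magnitude`, trial/taper counts and the smoothing half-bandwidth.
#' @export
lfp_lfp_coherence <- function(x_trials, y_trials, tapers, f_s) {
  if (length(x_trials) != length(y_trials))
    stop("x and y must have the same number of trials")
  if (length(x_trials) < 2)
    stop("coherence is a measurement across trials: need >= 2 trials")
  if (!all(vapply(c(x_trials, y_trials), length, 1L) == tapers$T))
    stop("all segments must have length tapers$T")
  Xs <- lapply(x_trials, mt_fft, tapers = tapers)
  Ys <- lapply(y_trials, mt_fft, tapers = tapers)
  coherence_from_ffts(Xs, Ys, tapers, f_s)
}

# Bin spike times (seconds, window-relative, in [0, T/f_s)) into counts at
# the LFP rate. Counts, not indicators: multi-spike bins are preserved.
bin_spikes <- function(spikes, T_samples, f_s) {
  if (!length(spikes)) return(numeric(T_samples))
  idx <- floor(spikes * f_s) + 1
  idx <- idx[idx >= 1 & idx <= T_samples]
  tabulate(idx, nbins = T_samples)
}

#' Spike-LFP coherence
#'
#' Spikes are binned at the LFP sampling rate (1 ms bins, counts), the
#' per-trial mean rate is subtracted to remove the DC component, and the
#' same multitaper cross-spectral machinery as [lfp_lfp_coherence()] is
#' applied. The conventional configuration is an 800 ms window at NW = 12
#' (23 tapers, +/-15 Hz smoothing): wide smoothing trades frequency detail
#' for low-variance coherence estimates from limited spikes.
#'
#' @param spike_trains List of numeric vectors: window-relative spike
#'   times in seconds, one vector per trial (aligned with `lfp_trials`).
#' @param lfp_trials List of numeric LFP segments of length `tapers$T`.
#' @inheritParams lfp_lfp_coherence
#' @return A `"coherence_spectrum"` with `n_spikes` recorded.
#' @export
spike_lfp_coherence <- function(spike_trains, lfp_trials, tapers, f_s) {
  if (length(spike_trains) != length(lfp_trials))
    stop("spike_trains and lfp_trials must align trial-for-trial")
  if (length(lfp_trials) < 2)
    stop("coherence is a measurement across trials: need >= 2 trials")
  n_spk <- sum(lengths(spike_trains))
  if (n_spk < 1) stop("no spikes in any trial")
  T_ <- tapers$T
  Xs <- lapply(spike_trains, function(st)
    mt_fft(bin_spikes(st, T_, f_s), tapers))
  Ys <- lapply(lfp_trials, mt_fft, tapers = tapers)
  coherence_from_ffts(Xs, Ys, tapers, f_s, n_spikes = n_spk)
}

#' Lagged spike-LFP coherence scan
#'
#' Recomputes spike-LFP coherence with the LFP window shifted by each lag
#' and band-averages the magnitude. Positive lag means the LFP is delayed
#' relative to the spikes (spikes lead); under direct interhemispheric
#' communication the scan peaks at a positive lag equal to the conduction
#' delay, while under common input (field driving spikes) the extremum
#' falls at negative lag. Spike Fourier transforms are computed once; only
#' the LFP window moves.
#'
#' @param trials List of full [trial()] objects (one condition).
#' @param unit_id Unit whose spikes are analysed.
#' @param ep The analysis [epoch()]; shifted LFP windows must stay within
#'   every trace (an out-of-trace shift is an error).
#' @param f_s Sampling rate in Hz.
#' @param lfp_channel `"left"` or `"right"`.
#' @param lags Lag grid in seconds (default 1 ms steps over +/-50 ms).
#' @param band Band (Hz) over which magnitude is averaged (default
#'   24-38 Hz).
#' @param nw Time-half-bandwidth product (default 12).
#' @return A `"lag_scan"` object: `lags` (s), `value` (band-averaged
#'   coherence magnitude), `band`, `n_spikes`.
#' @export
lagged_spike_lfp_coherence <- function(trials, unit_id, ep, f_s,
                                       lfp_channel,
                                       lags = seq(-0.05, 0.05, by = 0.001),
                                       band = c(24, 38), nw = 12) {
  if (any(abs(lags) > 0.05 + 1e-12))
    stop("lags must satisfy |lag| <= 50 ms")
  T_ <- round((ep$end_offset - ep$start_offset) * f_s)
  tapers <- make_tapers(T_, nw)
  base <- lapply(trials, extract_epoch, ep = ep, f_s = f_s)
  spk <- lapply(base, function(b) b$spikes[[unit_id]])
  if (sum(lengths(spk)) < 1) stop("no spikes in any trial")
  Xs <- lapply(spk, function(st) mt_fft(bin_spikes(st, T_, f_s), tapers))

  vals <- vapply(lags, function(lg) {
    sh <- epoch(ep$anchor, ep$start_offset + lg, ep$end_offset + lg)
    Ys <- lapply(trials, function(tr)
      mt_fft(extract_epoch(tr, sh, f_s)$lfp[[lfp_channel]], tapers))
    cs <- coherence_from_ffts(Xs, Ys, tapers, f_s)
    sel <- cs$freq >= band[1] & cs$freq <= band[2]
    mean(cs$magnitude[sel])
  }, numeric(1))

  structure(list(lags = lags, value = vals, band = band,
                 n_trials = length(trials), n_spikes = sum(lengths(spk)),
                 nw = nw, half_bandwidth = half_bandwidth(T_ / f_s, nw)),
            class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, ...) {
  i <- which.max(x$value)
  cat(sprintf(
    "<lag_scan> band %g-%g Hz, lags %g..%g ms; peak %.3f at %+g ms\n",
    x$band[1], x$band[2], 1000 * min(x$lags), 1000 * max(x$lags),
    x$value[i], 1000 * x$lags[i]))
  invisible(x)
}

#' Hemisphere opposite to a given one
#' @param h `"left"` or `"right"`.
#' @return The other hemisphere.
#' @export
opposite_hemisphere <- function(h) if (h == "left") "right" else "left"

#' Condition-level interhemispheric LFP coherence
#'
#' Computes left-right LFP coherence separately for each (movement type,
#' direction) trial ensemble and averages the magnitude spectra. Keeping
#' ensembles homogeneous matters: pooling directions would mix trials
#' whose per-trial power co-varies (or anti-varies) across the two
#' channels, which modulates the finite-trial coherence bias and can
#' masquerade as condition differences far outside the coupled band.
#' With equal ensemble sizes the bias is identical across conditions and
#' cancels in contrasts.
#'
#' @param s A [session()].
#' @param movement_types Movement types pooled into this condition (e.g.
#'   `c("ipsimanual", "contramanual")` for "unimanual").
#' @param ep Analysis [epoch()].
#' @param nw Time-half-bandwidth product (default 2.5).
#' @return A list with `freq`, `magnitude` (ensemble-averaged), and
#'   `n_ensembles`.
#' @export
condition_coherence <- function(s, movement_types,
                                ep = epoch("go_cue", -0.5, 0), nw = 2.5) {
  T_ <- round((ep$end_offset - ep$start_offset) * s$f_s)
  tp <- make_tapers(T_, nw)
  mags <- NULL; freq <- NULL; n_ens <- 0L
  for (mt in movement_types) {
    for (dir in DIRECTIONS) {
      trs <- select_trials(s, mt, dir)
      if (length(trs) < 2) next
      xs <- lapply(trs, function(tr) extract_epoch(tr, ep, s$f_s)$lfp$left)
      ys <- lapply(trs, function(tr) extract_epoch(tr, ep, s$f_s)$lfp$right)
      cs <- lfp_lfp_coherence(xs, ys, tp, s$f_s)
      freq <- cs$freq
      mags <- rbind(mags, cs$magnitude)
      n_ens <- n_ens + 1L
    }
  }
  if (is.null(mags)) stop("no ensemble with >= 2 trials")
  list(freq = freq, magnitude = colMeans(mags), n_ensembles = n_ens)
}
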