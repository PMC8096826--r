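# Wavelet phase extraction at spike times, PLV and PPC.
#
# Phase convention: phase 0 at the oscillation peak, decreasing with time
# within a cycle (-pi/2 at the falling zero-crossing after the peak). The
# convention is pinned by a pure-cosine test; PLV and PPC are invariant to
# any common rotation, so the choice only matters when reporting phases.

#' LFP phase at spike times
#'
#' Evaluates a Morlet wavelet coefficient (L2-normalized Gaussian envelope,
#' 7 cycles by default) at each spike's sample and returns its phase under
#' the package convention (0 at the local oscillation peak, decreasing).
#' Spikes closer than the wavelet half-support (3 envelope SDs) to either
#' trace edge are dropped and counted.
#'
#' @param lfp Numeric vector: the full trial LFP trace.
#' @param spikes Numeric vector of spike times in seconds on the trace
#'   clock.
#' @param frequency Analysis frequency in Hz (positive, below Nyquist).
#' @param f_s Sampling rate in Hz.
#' @param cycles Wavelet width in cycles (default 7).
#' @return List with `phases` (radians in (-pi, pi]) and `n_dropped`.
#' @export
phases_at_spikes <- function(lfp, spikes, frequency, f_s, cycles = 7) {
  if (frequency <= 0 || frequency >= f_s / 2)
    stop("frequency must be in (0, f_s/2)")
  sigma_t <- cycles / (2 * pi * frequency)
  hw <- ceiling(3 * sigma_t * f_s)
  u <- (-hw):hw
  # positive-exponent kernel picks the clockwise-rotating component, so
  # the phase decreases after the oscillation peak (package convention)
  kern <- exp(-(u / f_s)^2 / (2 * sigma_t^2)) *
    exp(2i * pi * frequency * u / f_s)
  kern <- kern / sqrt(sum(abs(kern)^2))
  n <- length(lfp)
  idx <- floor(spikes * f_s) + 1
  ok <- idx - hw >= 1 & idx + hw <= n
  n_dropped <- sum(!ok)
  idx <- idx[ok]
  phases <- vapply(idx, function(i) {
    Arg(sum(lfp[(i - hw):(i + hw)] * kern))
  }, numeric(1))
  list(phases = phases, n_dropped = n_dropped)
}

#' Collect spike phases across trials
#'
#' Applies [phases_at_spikes()] to every trial of a condition and keeps the
#' per-trial grouping required by [ppc()].
#'
#' @param trials List of [trial()] objects.
#' @param unit_id Unit whose spikes are analysed.
#' @param ep [epoch()] restricting which spikes enter (phases are still
#'   computed from the full trace, so epoch-interior spikes are rarely
#'   edge-dropped).
#' @param channel LFP channel, `"left"` or `"right"`.
#' @inheritParams phases_at_spikes
#' @return Object of class `"spike_phases"`: `phases` (list per trial),
#'   `frequency`, `n_spikes`, `n_dropped`.
#' @export
spike_phase_set <- function(trials, unit_id, ep, frequency, f_s,
                            channel = "left", cycles = 7) {
  phases <- vector("list", length(trials))
  n_dropped <- 0L
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    anchor_t <- tr$events[[ep$anchor]]
    t0 <- anchor_t + ep$start_offset
    t1 <- anchor_t + ep$end_offset
    st <- tr$spikes[[unit_id]]
    st <- st[st >= t0 & st < t1]
    r <- phases_at_spikes(tr$lfp[[channel]], st, frequency, f_s, cycles)
    phases[[i]] <- r$phases
    n_dropped <- n_dropped + r$n_dropped
  }
  structure(list(phases = phases, frequency = frequency,
                 n_spikes = sum(lengths(phases)), n_dropped = n_dropped),
            class = "spike_phases")
}

as_spike_phases <- function(phase_list, frequency = NA) {
  structure(list(phases = phase_list, frequency = frequency,
                 n_spikes = sum(lengths(phase_list)), n_dropped = 0L),
            class = "spike_phases")
}

#' Phase-locking value
#'
#' Magnitude of the mean resultant vector of spike phases pooled across
#' trials, with a Rayleigh test of circular uniformity. PLV is positively
#' biased at low spike counts: under uniform phases its expectation is
#' about `sqrt(pi)/2 * S^(-1/2)`.
#'
#' @param ph A `"spike_phases"` object (or list of per-trial phase
#'   vectors).
#' @return List with `plv` in `[0, 1]`, `p` (Rayleigh), and `n_spikes`.
#' @export
plv <- function(ph) {
  if (!inherits(ph, "spike_phases")) ph <- as_spike_phases(ph)
  theta <- unlist(ph$phases)
  S <- length(theta)
  if (S < 2) stop("PLV needs at least 2 spikes")
  R <- Mod(mean(exp(1i * theta)))
  Z <- S * R^2
  p <- exp(-Z)
  if (S < 50) p <- p * (1 + (2 * Z - Z^2) / (4 * S))
  list(plv = R, p = min(max(p, 0), 1), n_spikes = S)
}

#' Pairwise phase consistency
#'
#' Bias-corrected phase-consistency statistic from per-trial mean
#' resultant vectors `m_n`:
#' `PPC = (|sum m_n|^2 - sum |m_n|^2) / (N (N - 1))`.
#' Expectation 0 under no locking; can be negative; tends to the squared
#' population resultant as trials accumulate. Phases are never pooled
#' across trials.
#'
#' @param ph A `"spike_phases"` object (or list of per-trial phase
#'   vectors). Trials with no spikes are excluded; at least 2 spiking
#'   trials are required.
#' @return PPC in `[-1, 1]`.
#' @export
ppc <- function(ph) {
  if (!inherits(ph, "spike_phases")) ph <- as_spike_phases(ph)
  m <- vapply(ph$phases[lengths(ph$phases) > 0],
              function(th) mean(exp(1i * th)), complex(1))
  N <- length(m)
  if (N < 2) stop("PPC needs at least 2 trials with spikes")
  (Mod(sum(m))^2 - sum(Mod(m)^2)) / (N * (N - 1))
}
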