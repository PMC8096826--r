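# Statistical machinery: interspike-interval-shuffle permutation nulls for
# spike-field coherence, spike-count filters, and per-frequency condition
# contrasts with Bonferroni correction.

#' Shuffle the interspike intervals of one trial's train
#'
#' Keeps the first-spike time and the multiset of interspike intervals,
#' permuting the interval order uniformly at random. Spike count, first
#' spike and ISI multiset are preserved exactly; phase relationships with
#' the field are destroyed. Trains with 0 or 1 spike are returned
#' unchanged.
#'
#' @param spikes Sorted numeric vector of spike times (seconds).
#' @return Shuffled, sorted spike train of the same length.
#' @export
isi_shuffle <- function(spikes) {
  n <- length(spikes)
  if (n <= 1) return(spikes)
  isi <- diff(spikes)
  spikes[1] + cumsum(c(0, isi[sample.int(n - 1)]))
}

#' ISI-shuffle permutation null for spike-LFP coherence
#'
#' Recomputes spike-LFP coherence `n_perm` times with every trial's
#' interspike intervals independently shuffled, and records per-frequency
#' 95th and 99th percentile thresholds. LFP Fourier transforms are
#' computed once; only the spike transforms are redone per permutation.
#' Deterministic given `seed` (per-permutation streams are derived by
#' counter, so results do not depend on execution order).
#'
#' @inheritParams spike_lfp_coherence
#' @param n_perm Number of permutations (default 188; at least 20).
#' @param seed Master seed for the permutation streams.
#' @return Object of class `"null_distribution"`: `freq`, `null`
#'   (`n_perm x n_freq` coherence magnitudes), `q95`, `q99`, `n_perm`.
#' @export
permutation_null <- function(spike_trains, lfp_trials, tapers, f_s,
                             n_perm = 188, seed = 1) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  if (length(spike_trains) != length(lfp_trials))
    stop("spike_trains and lfp_trials must align trial-for-trial")
  if (sum(lengths(spike_trains)) < 1) stop("no spikes in any trial")
  T_ <- tapers$T
  K <- tapers$K
  N <- length(lfp_trials)
  n_os <- floor(T_ / 2) + 1
  # batch all trials' tapered transforms into one FFT call per permutation
  w_eig <- tapers$eigenvalues * K / sum(tapers$eigenvalues)
  wvec <- rep(w_eig, N)
  taper_block <- tapers$tapers[, rep(seq_len(K), N), drop = FALSE]
  expand <- function(M) M[, rep(seq_len(N), each = K), drop = FALSE]
  Ymat <- vapply(lfp_trials, function(y) y - mean(y), numeric(T_))
  Yf <- stats::mvfft(taper_block * expand(Ymat))
  Syy <- drop((abs(Yf)^2) %*% wvec)[seq_len(n_os)]
  YfC <- Conj(Yf)
  null <- matrix(NA_real_, n_perm, n_os)
  for (p in seq_len(n_perm)) {
    set.seed(derive_seed(seed, p))
    shuf <- lapply(spike_trains, isi_shuffle)
    Cm <- vapply(shuf, function(st) {
      b <- bin_spikes(st, T_, f_s)
      b - mean(b)
    }, numeric(T_))
    Xf <- stats::mvfft(taper_block * expand(Cm))
    Sxx <- drop((abs(Xf)^2) %*% wvec)[seq_len(n_os)]
    Sxy <- drop((Xf * YfC) %*% wvec)[seq_len(n_os)]
    denom <- sqrt(Sxx * Syy)
    null[p, ] <- ifelse(denom > 0, Mod(Sxy) / denom, 0)
  }
  structure(list(freq = (seq_len(n_os) - 1) * f_s / T_, null = null,
                 q95 = apply(null, 2, stats::quantile, 0.95),
                 q99 = apply(null, 2, stats::quantile, 0.99),
                 n_perm = n_perm, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d permutations, %d freqs; median q95 = %.3f\n",
    x$n_perm, length(x$freq), stats::median(x$q95)))
  invisible(x)
}

#' Filter units by minimum spike count per movement condition
#'
#' Retains a unit only if its spike count within the analysis epoch
#' reaches the threshold in every movement condition, protecting coherence
#' estimates against rate differences. The threshold is inclusive
#' (`>= threshold`); 499 spikes in any one condition excludes the unit.
#'
#' @param s A [session()].
#' @param ep Analysis [epoch()].
#' @param threshold Minimum spike count per movement condition (default
#'   500).
#' @return Character vector of retained unit ids.
#' @export
min_spike_filter <- function(s, ep, threshold = 500) {
  keep <- character(0)
  for (u in s$units$unit_id) {
    ok <- TRUE
    for (mt in MOVEMENT_TYPES) {
      trs <- select_trials(s, mt)
      cnt <- sum(vapply(trs, function(tr)
        length(extract_epoch(tr, ep, s$f_s)$spikes[[u]]), numeric(1)))
      if (cnt < threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, u)
  }
  keep
}

#' Subsample a condition's spikes to a fixed count
#'
#' Uniform sampling without replacement across the pooled spikes of all
#' trials, preserving trial structure and within-trial order. Used as a
#' control that equates spike counts across conditions.
#'
#' @param spike_trains List of per-trial spike-time vectors.
#' @param target Number of spikes to retain (at most the pooled total).
#' @return List of per-trial spike-time vectors with exactly `target`
#'   spikes in total.
#' @export
subsample_spikes <- function(spike_trains, target) {
  tot <- sum(lengths(spike_trains))
  if (target > tot)
    stop(sprintf("insufficient spikes: have %d, need %d", tot, target))
  if (target == tot) return(spike_trains)
  trial_of <- rep(seq_along(spike_trains), lengths(spike_trains))
  keep <- sort(sample.int(tot, target))
  pooled <- unlist(spike_trains)
  out <- vector("list", length(spike_trains))
  for (i in seq_along(out)) {
    out[[i]] <- pooled[keep[trial_of[keep] == i]]
  }
  out
}

#' Per-frequency condition contrast with Bonferroni correction
#'
#' Two-sided t-tests at each frequency across sites between two
#' conditions, paired by default (conditions are measured at the same
#' sites); `paired = FALSE` gives the pooled two-sample test. The
#' Bonferroni factor defaults to the number of tested frequencies.
#'
#' @param a,b Numeric matrices, sites x frequencies, for the two
#'   conditions (matching frequency grids required).
#' @param freq Optional frequency grid (Hz) for labelling.
#' @param paired Paired per-site tests (default) or pooled.
#' @param n_bonferroni Correction factor (default `ncol(a)`).
#' @param alpha Significance criterion (default 0.05).
#' @param label Free-text comparison label.
#' @return Object of class `"contrast_result"`: per-frequency `t`, `p`,
#'   `p_corrected`, logical `significant` (corrected) and
#'   `significant_uncorrected`.
#' @export
condition_contrast <- function(a, b, freq = NULL, paired = TRUE,
                               n_bonferroni = NULL, alpha = 0.05,
                               label = "") {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("condition arrays must match in shape")
  if (nrow(a) < 2) stop("need at least 2 sites")
  m <- ncol(a)
  if (is.null(n_bonferroni)) n_bonferroni <- m
  tt <- vapply(seq_len(m), function(j) {
    x <- a[, j]; y <- b[, j]
    if (paired) {
      d <- x - y
      if (stats::sd(d) == 0) {
        # degenerate: identical arrays are null, a constant offset is not
        if (mean(d) == 0) return(c(t = 0, p = 1))
        return(c(t = sign(mean(d)) * Inf, p = 0))
      }
      r <- stats::t.test(d)
    } else {
      if (stats::sd(c(x, y)) == 0) return(c(t = 0, p = 1))
      r <- stats::t.test(x, y, var.equal = TRUE)
    }
    c(t = unname(r$statistic), p = r$p.value)
  }, c(t = 0, p = 0))
  p_corr <- pmin(1, tt["p", ] * n_bonferroni)
  structure(list(freq = freq %||% seq_len(m), t = tt["t", ], p = tt["p", ],
                 p_corrected = p_corr,
                 significant = p_corr < alpha,
                 significant_uncorrected = tt["p", ] < alpha,
                 n_sites = nrow(a), paired = paired,
                 n_bonferroni = n_bonferroni, label = label),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result> %s: %d freqs, %d sites, %s t-tests, Bonferroni x%d\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$freq), x$n_sites, if (x$paired) "paired" else "pooled",
    x$n_bonferroni))
  sig <- which(x$significant)
  if (length(sig))
    cat("  significant (corrected) at:", paste(x$freq[sig], collapse = ", "),
        "Hz\n")
  else cat("  no corrected significant frequencies\n")
  invisible(x)
}

# Per-stream seed derivation: keeps every derived seed a valid 32-bit
# integer and independent of execution order.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + counter * 16807) %% 2147483647)
}
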