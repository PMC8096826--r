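# DPSS multitaper spectral engine.
#
# Conventions (documented in the methods vignette):
#  * n_fft = T (no zero padding); frequency grid spacing f_s/T.
#  * One-sided spectra; non-DC, non-Nyquist bins carry a factor 2 so that
#    sum(S * df) equals the signal variance (Parseval).
#  * Per-window mean subtraction only; no further detrending.
#  * Taper sign convention: the max-magnitude element of each taper is
#    positive, making results reproducible across LAPACK builds.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `K = floor(2 * NW) - 1` DPSS sequences of length `T`
#' by the symmetric tridiagonal eigenproblem, unit-energy normalized, with
#' in-band concentrations evaluated from the sinc-kernel quadratic form.
#' A time-half-bandwidth product of 2.5 yields 4 tapers; NW = 12 yields 23.
#'
#' @param T_samples Window length in samples (>= 8).
#' @param NW Time-half-bandwidth product (>= 1).
#' @return Object of class `"taper_set"`: list with `tapers`
#'   (`T_samples x K` matrix, columns unit energy, mutually orthonormal),
#'   `eigenvalues` (concentrations, descending), `NW`, `K`, `T`.
#' @export
make_tapers <- function(T_samples, NW) {
  if (T_samples < 8) stop("T_samples must be >= 8")
  if (NW < 1) stop("NW must be >= 1")
  K <- floor(2 * NW) - 1
  if (K < 1) stop("2*NW - 1 must be >= 1")
  if (K >= T_samples) stop("NW too large for window length (K >= T)")
  key <- sprintf("T%d_NW%.6g", T_samples, NW)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])

  W <- NW / T_samples
  t_idx <- 0:(T_samples - 1)
  diag_main <- ((T_samples - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * W)
  off <- t_idx[-1] * (T_samples - t_idx[-1]) / 2
  A <- diag(diag_main)
  A[cbind(1:(T_samples - 1), 2:T_samples)] <- off
  A[cbind(2:T_samples, 1:(T_samples - 1))] <- off
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(K), drop = FALSE]

  # unit energy + sign convention
  for (k in seq_len(K)) {
    v <- V[, k]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    V[, k] <- v
  }

  # concentrations lambda_k = v' S v with S the sinc kernel
  dm <- outer(t_idx, t_idx, "-")
  Skern <- sin(2 * pi * W * dm) / (pi * dm)
  diag(Skern) <- 2 * W
  lam <- vapply(seq_len(K), function(k) drop(crossprod(V[, k], Skern %*% V[, k])),
                numeric(1))
  ord <- order(lam, decreasing = TRUE)
  ts <- structure(list(tapers = V[, ord, drop = FALSE],
                       eigenvalues = lam[ord],
                       NW = NW, K = K, T = T_samples),
                  class = "taper_set")
  .taper_cache[[key]] <- ts
  ts
}

#' @export
print.taper_set <- function(x, ...) {
  cat(sprintf("<taper_set> T = %d samples, NW = %g, K = %d tapers\n",
              x$T, x$NW, x$K))
  cat("  concentrations:", format(round(x$eigenvalues, 6)), "\n")
  invisible(x)
}

#' Spectral half-bandwidth of a multitaper configuration
#'
#' The frequency resolution is +/- `NW / window_seconds` Hz: a 400 ms
#' window at NW = 2.5 smooths over +/- 6.25 Hz; 800 ms at NW = 12 over
#' +/- 15 Hz.
#'
#' @param window_seconds Analysis window length in seconds.
#' @param NW Time-half-bandwidth product.
#' @return Half-bandwidth in Hz.
#' @export
half_bandwidth <- function(window_seconds, NW) {
  if (window_seconds <= 0) stop("window_seconds must be > 0")
  NW / window_seconds
}

#' Effective frequency band after multitaper smoothing
#'
#' A nominal band `(f_lo, f_hi)` analysed with half-bandwidth `W` actually
#' carries information from `(f_lo - W, f_hi + W)` (lower edge floored at
#' zero): a 20-30 Hz band at 400 ms / NW 2.5 spans 13.75-36.25 Hz.
#'
#' @param band Numeric length-2, `(f_lo, f_hi)` with `f_lo < f_hi`.
#' @inheritParams half_bandwidth
#' @return Numeric length-2 effective band in Hz.
#' @export
effective_band <- function(band, window_seconds, NW) {
  if (band[1] >= band[2]) stop("band must satisfy f_lo < f_hi")
  W <- half_bandwidth(window_seconds, NW)
  c(max(0, band[1] - W), band[2] + W)
}

# Tapered Fourier coefficients of one segment: T x K complex matrix.
# Mean is removed per window.
mt_fft <- function(x, tapers) {
  stats::mvfft(tapers$tapers * (x - mean(x)))
}

# Thomson adaptive weights for one trial. eig_spec: n_freq x K two-sided
# eigenspectra (|X_k|^2 / fs); lambda: concentrations; sig2: series
# variance (two-sided integral of the true PSD). Returns list(S, wts)
# where wts is n_freq x K with rowMeans(wts) == 1 (Eq. 2 normalization).
adaptive_weights <- function(eig_spec, lambda, sig2, max_iter = 100,
                             tol = 1e-6) {
  K <- length(lambda)
  if (K < 2) return(list(S = eig_spec[, 1], wts = matrix(1, nrow(eig_spec), 1),
                         converged = TRUE))
  if (sig2 <= 0 || !any(eig_spec > 0))   # degenerate (e.g. all-zero) input
    return(list(S = rowMeans(eig_spec), wts = matrix(1, nrow(eig_spec), K),
                converged = TRUE))
  S <- rowMeans(eig_spec[, 1:2, drop = FALSE])
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # b_k(f) = S / (lambda_k S + (1 - lambda_k) sig2)
    denom <- outer(S, lambda) + matrix((1 - lambda) * sig2,
                                       nrow(eig_spec), K, byrow = TRUE)
    b2 <- (S / denom)^2
    num <- rowSums(sweep(b2, 2, lambda, "*") * eig_spec)
    den <- rowSums(sweep(b2, 2, lambda, "*"))
    S_new <- num / den
    if (max(abs(S_new - S) / pmax(S, .Machine$double.eps)) < tol) {
      S <- S_new; converged <- TRUE; break
    }
    S <- S_new
  }
  denom <- outer(S, lambda) + matrix((1 - lambda) * sig2,
                                     nrow(eig_spec), K, byrow = TRUE)
  b2 <- (S / denom)^2
  w <- sweep(b2, 2, lambda, "*")
  w <- w / rowMeans(w)                   # so that (1/K) sum_k w_k = 1
  list(S = S, wts = w, converged = converged)
}

#' Multitaper power spectral density
#'
#' Trial-averaged multitaper PSD: each segment is windowed with every
#' Slepian taper, Fourier transformed, and the eigenspectra are combined
#' with either Thomson's adaptive weights (iterated to relative tolerance
#' 1e-6, falling back to eigenvalue weights with a warning on
#' non-convergence) or fixed eigenvalue weights. Per-trial spectra are then
#' averaged across trials. Units are V^2/Hz; one-sided so that
#' `sum(S * df)` equals the signal variance.
#'
#' @param trials List of numeric vectors, all of length `tapers$T`.
#' @param tapers A [make_tapers()] object.
#' @param f_s Sampling rate in Hz.
#' @param weighting `"adaptive"` (default) or `"eigenvalue"`.
#' @return Object of class `"mt_spectrum"`: list with `freq` (Hz, 0 to
#'   Nyquist), `S` (V^2/Hz), `n_trials`, `df`, `weighting`, `NW`, `K`.
#' @export
mt_spectrum <- function(trials, tapers, f_s,
                        weighting = c("adaptive", "eigenvalue")) {
  weighting <- match.arg(weighting)
  if (length(trials) < 1) stop("need at least one trial")
  T_ <- tapers$T
  if (!all(vapply(trials, length, 1L) == T_))
    stop("all segments must have length tapers$T = ", T_)
  lam <- tapers$eigenvalues
  K <- tapers$K
  w_eig <- lam * K / sum(lam)
  n_os <- floor(T_ / 2) + 1
  acc <- numeric(T_)
  n_fallback <- 0L
  for (x in trials) {
    X <- mt_fft(x, tapers)
    eig_spec <- (abs(X)^2) / f_s                 # two-sided, n_freq x K
    if (weighting == "adaptive") {
      xm <- x - mean(x)
      aw <- adaptive_weights(eig_spec, lam, sig2 = mean(xm^2) / f_s)
      if (!aw$converged) n_fallback <- n_fallback + 1L
      S_n <- if (aw$converged) {
        rowSums(aw$wts * eig_spec) / K
      } else {
        drop(eig_spec %*% w_eig) / K
      }
    } else {
      S_n <- drop(eig_spec %*% w_eig) / K
    }
    acc <- acc + S_n
  }
  if (n_fallback > 0)
    warning(sprintf(
      "adaptive weights failed to converge in %d of %d trials; eigenvalue weights used there",
      n_fallback, length(trials)))
  S2 <- acc / length(trials)
  # fold to one-sided
  S <- S2[seq_len(n_os)]
  dbl <- 2:(n_os - if (T_ %% 2 == 0) 1 else 0)
  S[dbl] <- 2 * S[dbl]
  structure(list(freq = (seq_len(n_os) - 1) * f_s / T_, S = S,
                 df = f_s / T_, f_s = f_s, n_trials = length(trials),
                 weighting = weighting, NW = tapers$NW, K = K),
            class = "mt_spectrum")
}

#' @export
print.mt_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mt_spectrum> %d freqs (0-%g Hz, df = %g), %d trials, NW = %g, K = %d, %s weights\n",
    length(x$freq), max(x$freq), x$df, x$n_trials, x$NW, x$K, x$weighting))
  invisible(x)
}

#' Band-limited power
#'
#' Sums the PSD over grid frequencies in the half-open band
#' `[f_lo, f_hi)` times the grid spacing; the half-open convention makes
#' adjacent bands tile without double counting.
#'
#' @param spectrum A [mt_spectrum()] object.
#' @param band Numeric length-2 `(f_lo, f_hi)` in Hz.
#' @return Band power in V^2.
#' @export
band_power <- function(spectrum, band) {
  sel <- spectrum$freq >= band[1] & spectrum$freq < band[2]
  if (!any(sel)) stop(sprintf("no grid frequencies in band [%g, %g)",
                              band[1], band[2]))
  sum(spectrum$S[sel]) * spectrum$df
}

#' Sliding-window band-power timecourse
#'
#' Band power in windows `[center - half_width, center + half_width)`
#' stepped every `step` seconds relative to an anchor event, computed per
#' condition (movement type, optionally split by direction). Window centers
#' whose windows exceed any trial's trace are omitted and counted, never
#' silently NaN-filled.
#'
#' @param s A [session()].
#' @param band Numeric length-2 `(f_lo, f_hi)` in Hz.
#' @param half_width Window half-width in seconds (e.g. 0.2 for +/-200 ms
#'   windows every 100 ms).
#' @param step Step between window centers in seconds.
#' @param anchor Anchor event name.
#' @param centers Numeric vector of window-center offsets (seconds,
#'   relative to the anchor).
#' @param channel `"left"` or `"right"` LFP channel.
#' @param nw Time-half-bandwidth product (default 2.5).
#' @param by_direction Split conditions by direction (default `FALSE`:
#'   directions merged, as appropriate for untuned beta power).
#' @param weighting Taper weighting passed to [mt_spectrum()].
#' @return Object of class `"power_timecourse"`: data frame `values` with
#'   columns condition (and direction), center, power; plus band/window
#'   metadata and the count of omitted windows.
#' @export
power_timecourse <- function(s, band, half_width, step, anchor,
                             centers = NULL, channel = "left", nw = 2.5,
                             by_direction = FALSE,
                             weighting = "eigenvalue") {
  if (is.null(centers))
    stop("supply window-center offsets via `centers`")
  stopifnot(all(diff(centers) > 0))
  T_ <- round(2 * half_width * s$f_s)
  tp <- make_tapers(T_, nw)
  groups <- if (by_direction) {
    cl <- condition_labels()
    lapply(seq_len(nrow(cl)), function(i)
      list(mt = cl$movement_type[i], dir = cl$direction[i]))
  } else {
    lapply(MOVEMENT_TYPES, function(m) list(mt = m, dir = NULL))
  }
  rows <- list(); omitted <- 0L
  for (g in groups) {
    trs <- select_trials(s, g$mt, g$dir)
    if (!length(trs)) next
    for (ctr in centers) {
      segs <- list(); ok <- TRUE
      for (tr in trs) {
        res <- tryCatch(
          extract_epoch(tr, epoch(anchor, ctr - half_width,
                                  ctr + half_width), s$f_s),
          error = function(e) NULL)
        if (is.null(res)) { ok <- FALSE; break }
        segs[[length(segs) + 1]] <- res$lfp[[channel]]
      }
      if (!ok) { omitted <- omitted + 1L; next }
      sp <- mt_spectrum(segs, tp, s$f_s, weighting = weighting)
      rows[[length(rows) + 1]] <- data.frame(
        condition = g$mt,
        direction = if (is.null(g$dir)) NA_character_ else g$dir,
        center = ctr, power = band_power(sp, band),
        stringsAsFactors = FALSE)
    }
  }
  if (omitted > 0)
    message(omitted, " window(s) omitted: epoch exceeded trace extent")
  structure(list(values = do.call(rbind, rows), band = band,
                 half_width = half_width, step = step, anchor = anchor,
                 channel = channel, nw = nw,
                 normalization = "raw", n_omitted = omitted),
            class = "power_timecourse")
}

#' @export
print.power_timecourse <- function(x, ...) {
  cat(sprintf(
    "<power_timecourse> band %g-%g Hz, +/-%g s windows, anchor %s, %s\n",
    x$band[1], x$band[2], x$half_width, x$anchor, x$normalization))
  print(utils::head(x$values))
  invisible(x)
}

#' Normalize a power timecourse to baseline
#'
#' Divides each band-power value by the condition's mean band power over a
#' baseline epoch (by convention the 500 ms before target presentation)
#' and subtracts 1, giving modulation as a fraction of baseline. The
#' baseline is estimated with the same window length and band as the
#' timecourse itself (averaging the sliding windows that fit inside the
#' baseline epoch), so the estimator's spectral smoothing cancels in the
#' ratio.
#'
#' @param tc A [power_timecourse()].
#' @param s The [session()] the timecourse was computed from.
#' @param baseline A [epoch()] giving the baseline window (default 500 ms
#'   before target onset).
#' @return The timecourse with `power` replaced by fractional modulation
#'   and `normalization = "percent_of_baseline"`.
#' @export
normalize_to_baseline <- function(tc, s,
                                  baseline = epoch("target_on", -0.5, 0)) {
  hw <- tc$half_width
  T_w <- round(2 * hw * s$f_s)
  tpb <- make_tapers(T_w, tc$nw)
  ctrs <- seq(baseline$start_offset + hw, baseline$end_offset - hw,
              by = tc$step)
  if (!length(ctrs))
    stop("baseline epoch shorter than one analysis window")
  vals <- tc$values
  for (g in unique(paste(vals$condition, vals$direction))) {
    sel <- paste(vals$condition, vals$direction) == g
    mt0 <- vals$condition[sel][1]
    dir0 <- vals$direction[sel][1]
    trs <- select_trials(s, mt0, if (is.na(dir0)) NULL else dir0)
    segs <- list()
    for (ctr in ctrs) {
      ep_b <- epoch(baseline$anchor, ctr - hw, ctr + hw)
      segs <- c(segs, lapply(trs, function(tr)
        extract_epoch(tr, ep_b, s$f_s)$lfp[[tc$channel]]))
    }
    base <- band_power(mt_spectrum(segs, tpb, s$f_s,
                                   weighting = "eigenvalue"), tc$band)
    if (base <= 0) stop("baseline band power is zero for condition ", g)
    vals$power[sel] <- vals$power[sel] / base - 1
  }
  tc$values <- vals
  tc$normalization <- "percent_of_baseline"
  tc
}
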