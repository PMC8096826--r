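# Algebraic model of interhemispheric signal transfer: per-condition
# beta-band LFP modulation expressed as an affine function of a convex
# mixture of local and contralateral normalized population firing rates,
#
#   beta_c = gain * (w * r_local,c + (1 - w) * r_contra,c) + offset.
#
# The functional form (affine mixture of baseline-normalized rates), the
# [0, 1] constraint on w and the grid-search-plus-refinement fit are this
# package's reconstruction of a two-source mixing analysis; its claims are
# limited to self-consistency and recovery on synthetic data.

#' Per-condition beta-power and population-rate profiles
#'
#' For each of the ten conditions (site-relative frame: ipsi/contra
#' resolved per hemisphere, bimanual-apart direction referred to the
#' site's contralateral arm) computes baseline-normalized beta band power
#' of the local LFP, the baseline-normalized mean firing rate of the local
#' hemisphere's units, and that of the contralateral hemisphere's units,
#' averaged over the two hemispheres.
#'
#' @param s A [session()].
#' @param beta_band Band in Hz (default 20-30).
#' @param ep Analysis [epoch()] (default 0.65-1.15 s after target onset).
#' @param baseline Baseline [epoch()] (default the 500 ms before target
#'   onset).
#' @param nw Time-half-bandwidth product for the power estimate.
#' @return Object of class `"condition_profile"`: data frame with columns
#'   `movement_type`, `direction`, `beta_mod`, `local_rate`,
#'   `contra_rate` (all as fractional modulation about baseline, 0 =
#'   baseline).
#' @export
build_condition_profiles <- function(s, beta_band = c(20, 30),
                                     ep = epoch("target_on", 0.65, 1.15),
                                     baseline = epoch("target_on", -0.5, 0),
                                     nw = 2.5) {
  cl <- condition_labels()
  T_e <- round((ep$end_offset - ep$start_offset) * s$f_s)
  T_b <- round((baseline$end_offset - baseline$start_offset) * s$f_s)
  tp_e <- make_tapers(T_e, nw)
  tp_b <- make_tapers(T_b, nw)

  rate_of <- function(trs, unit_ids, epo) {
    dur <- epo$end_offset - epo$start_offset
    cnt <- 0; ntr <- 0
    for (tr in trs) {
      ex <- extract_epoch(tr, epo, s$f_s)
      cnt <- cnt + sum(lengths(ex$spikes[unit_ids]))
      ntr <- ntr + 1
    }
    cnt / (ntr * dur * length(unit_ids))
  }

  rows <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    mt <- cl$movement_type[i]; dir <- cl$direction[i]
    acc <- c(beta = 0, local = 0, contra = 0)
    for (h in c("left", "right")) {
      # stored label whose site-frame meaning at hemisphere h is (mt, dir)
      lab <- relabel_for_hemisphere(mt, dir, h)
      trs <- select_trials(s, lab$movement_type, lab$direction)
      if (!length(trs))
        stop(sprintf("missing condition: %s/%s", lab$movement_type, dir))
      segs_e <- lapply(trs, function(tr)
        extract_epoch(tr, ep, s$f_s)$lfp[[h]])
      segs_b <- lapply(trs, function(tr)
        extract_epoch(tr, baseline, s$f_s)$lfp[[h]])
      bp_e <- band_power(mt_spectrum(segs_e, tp_e, s$f_s, "eigenvalue"),
                         beta_band)
      bp_b <- band_power(mt_spectrum(segs_b, tp_b, s$f_s, "eigenvalue"),
                         beta_band)
      if (bp_b <= 0) stop("zero baseline beta power")
      u_loc <- s$units$unit_id[s$units$hemisphere == h]
      u_con <- s$units$unit_id[s$units$hemisphere ==
                                 opposite_hemisphere(h)]
      r_loc_e <- rate_of(trs, u_loc, ep)
      r_loc_b <- rate_of(trs, u_loc, baseline)
      r_con_e <- rate_of(trs, u_con, ep)
      r_con_b <- rate_of(trs, u_con, baseline)
      acc <- acc + c(beta = bp_e / bp_b - 1,
                     local = r_loc_e / r_loc_b - 1,
                     contra = r_con_e / r_con_b - 1)
    }
    acc <- acc / 2
    rows[[i]] <- data.frame(movement_type = mt, direction = dir,
                            beta_mod = acc[["beta"]],
                            local_rate = acc[["local"]],
                            contra_rate = acc[["contra"]],
                            stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("condition_profile",
                                            "data.frame"))
}

#' Fit the local/contralateral mixing weight
#'
#' Least-squares fit of
#' `beta_c = gain * (w * r_local,c + (1 - w) * r_contra,c) + offset`
#' over the ten condition profiles, with the local-input weight `w`
#' constrained to `[0, 1]` by a 0.01-resolution grid search followed by
#' local refinement. Also reports the residual sums of squares of the two
#' boundary models (`w = 1`, pure local drive; `w = 0`, pure
#' contralateral drive). If the local and contralateral rate vectors are
#' (near-)collinear the fit is flagged unidentifiable and `w` is
#' meaningless.
#'
#' @param profile A [build_condition_profiles()] result, or any data
#'   frame with columns `beta_mod`, `local_rate`, `contra_rate`.
#' @return Object of class `"mixing_fit"` with components `w`, `gain`,
#'   `offset`, `rss_free`, `rss_local`, `rss_contra`, `identifiable`,
#'   `fitted`, `data`, `n`.
#' @export
fit_mixing_weight <- function(profile) {
  y <- profile$beta_mod
  rl <- profile$local_rate
  rc <- profile$contra_rate
  n <- length(y)
  if (n < 4) stop("need at least 4 conditions to fit")

  rss_at <- function(w) {
    x <- w * rl + (1 - w) * rc
    f <- stats::lm.fit(cbind(1, x), y)
    sum(f$residuals^2)
  }
  grid <- seq(0, 1, by = 0.01)
  rss_grid <- vapply(grid, rss_at, numeric(1))
  w0 <- grid[which.min(rss_grid)]
  lo <- max(0, w0 - 0.01); hi <- min(1, w0 + 0.01)
  op <- stats::optimize(rss_at, c(lo, hi))
  w_hat <- op$minimum
  if (rss_at(w0) < op$objective) w_hat <- w0

  # identifiability: mixture direction must actually change with w
  dvec <- rl - rc
  identifiable <- stats::sd(dvec) > 1e-10 &&
    (stats::sd(rl) > 1e-12 || stats::sd(rc) > 1e-12)

  x <- w_hat * rl + (1 - w_hat) * rc
  f <- stats::lm.fit(cbind(1, x), y)
  fit <- structure(list(
    w = w_hat, gain = unname(f$coefficients[2]),
    offset = unname(f$coefficients[1]),
    rss_free = sum(f$residuals^2),
    rss_local = rss_at(1), rss_contra = rss_at(0),
    identifiable = identifiable,
    fitted = unname(drop(cbind(1, x) %*% f$coefficients)),
    data = profile, n = n), class = "mixing_fit")
  fit
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat("Interhemispheric mixing model\n")
  cat(sprintf("  local-input weight w = %.3f  (gain %.3f, offset %.3f)\n",
              x$w, x$gain, x$offset))
  cat(sprintf("  RSS: free %.4g | pure local (w=1) %.4g | pure contralateral (w=0) %.4g\n",
              x$rss_free, x$rss_local, x$rss_contra))
  if (!x$identifiable)
    cat("  WARNING: local and contralateral rates collinear; w not identifiable\n")
  invisible(x)
}

#' @export
summary.mixing_fit <- function(object, ...) {
  cmp <- if (object$identifiable) compare_models(object) else NULL
  structure(list(fit = object, comparison = cmp),
            class = "summary.mixing_fit")
}

#' @export
print.summary.mixing_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$comparison))
    cat(sprintf(
      "  vs pure local drive: F(1,%d) = %.3f, p = %.4g\n",
      x$comparison$df2, x$comparison$F, x$comparison$p))
  invisible(x)
}

#' @export
coef.mixing_fit <- function(object, ...) {
  c(w = object$w, gain = object$gain, offset = object$offset)
}

#' @export
predict.mixing_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  x <- object$w * d$local_rate + (1 - object$w) * d$contra_rate
  object$gain * x + object$offset
}

#' @export
residuals.mixing_fit <- function(object, ...) {
  object$data$beta_mod - object$fitted
}

#' @export
plot.mixing_fit <- function(x, ...) {
  obs <- x$data$beta_mod
  graphics::plot(x$fitted, obs,
                 xlab = "model beta modulation",
                 ylab = "observed beta modulation",
                 main = sprintf("mixing fit, w = %.2f", x$w), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare the free-weight model against pure local drive
#'
#' F-test for the one extra parameter:
#' `F = (RSS(w = 1) - RSS(free)) / (RSS(free) / (n - 3))` on
#' `(1, n - 3)` degrees of freedom.
#'
#' @param fit A [fit_mixing_weight()] result (must be identifiable).
#' @return List with `F`, `p`, `df1`, `df2`, `delta_rss`.
#' @export
compare_models <- function(fit) {
  if (!fit$identifiable)
    stop("fit is not identifiable; model comparison is meaningless")
  df2 <- fit$n - 3
  dr <- fit$rss_local - fit$rss_free
  F_ <- if (fit$rss_free <= 0) {
    if (dr <= 0) 0 else Inf
  } else (dr / 1) / (fit$rss_free / df2)
  p <- stats::pf(F_, 1, df2, lower.tail = FALSE)
  list(F = F_, p = p, df1 = 1, df2 = df2, delta_rss = dr)
}
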