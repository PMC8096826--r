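#' @importFrom stats fft mvfft quantile rnorm runif rexp rbinom t.test var sd
#'   median optimize pf coef predict residuals qnorm rpois
#' @importFrom utils head tail write.csv read.csv
NULL

# Recognised movement types and directions. "ipsimanual"/"contramanual" are
# stored relative to the LEFT hemisphere (the bundle's reference convention);
# analysis code remaps per hemisphere with relabel_for_hemisphere().
MOVEMENT_TYPES <- c("saccade", "ipsimanual", "contramanual",
                    "bimanual_together", "bimanual_apart")
DIRECTIONS <- c("preferred", "null")

#' The ten condition labels
#'
#' Five movement types crossed with two directions. For bimanual-apart
#' trials the direction refers to the contralateral (reference-hemisphere)
#' arm; the other arm moves to the diametrically opposed target.
#'
#' @return A data.frame with columns `movement_type` and `direction`
#'   (10 rows).
#' @export
condition_labels <- function() {
  expand.grid(movement_type = MOVEMENT_TYPES, direction = DIRECTIONS,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 1:2]
}

#' Construct a single trial
#'
#' @param trial_id Integer trial identifier.
#' @param movement_type One of `"saccade"`, `"ipsimanual"`, `"contramanual"`,
#'   `"bimanual_together"`, `"bimanual_apart"`.
#' @param direction `"preferred"` or `"null"`.
#' @param lfp_left,lfp_right Numeric vectors of equal length: voltage samples
#'   at the session sampling rate. Sample `i` (1-based) covers time
#'   `[(i-1)/f_s, i/f_s)` seconds.
#' @param spikes Named list of numeric vectors, one per unit, of spike times
#'   in seconds on the trial clock (ascending).
#' @param target_on,go_cue,move_onset Event times in seconds on the trial
#'   clock.
#' @return An object of class `"bicoher_trial"`.
#' @export
trial <- function(trial_id, movement_type, direction, lfp_left, lfp_right,
                  spikes = list(), target_on, go_cue, move_onset) {
  structure(list(
    trial_id = as.integer(trial_id),
    movement_type = movement_type,
    direction = direction,
    lfp = list(left = as.numeric(lfp_left), right = as.numeric(lfp_right)),
    spikes = spikes,
    events = list(target_on = target_on, go_cue = go_cue,
                  move_onset = move_onset)
  ), class = "bicoher_trial")
}

#' Construct a two-hemisphere session
#'
#' @param trials List of [trial()] objects.
#' @param units Data frame with columns `unit_id` (character) and
#'   `hemisphere` (`"left"` or `"right"`).
#' @param f_s Sampling rate in Hz (default 1000).
#' @param provenance Free-text provenance string.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `"bicoher_session"`.
#' @export
session <- function(trials, units, f_s = 1000, provenance = "",
                    validate = TRUE) {
  s <- structure(list(trials = trials, units = units, f_s = f_s,
                      provenance = provenance),
                 class = "bicoher_session")
  if (validate) validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks every trial: condition label validity, event ordering
#' (`target_on < go_cue`), events within the trace extent, equal-length LFP
#' channels, and ascending spike times. Errors name the offending trial and
#' field.
#'
#' @param s A [session()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_session <- function(s) {
  stopifnot(inherits(s, "bicoher_session"))
  if (!all(c("unit_id", "hemisphere") %in% names(s$units)))
    stop("units must have columns unit_id and hemisphere")
  if (!all(s$units$hemisphere %in% c("left", "right")))
    stop("unit hemisphere must be 'left' or 'right'")
  for (tr in s$trials) {
    id <- tr$trial_id
    if (!tr$movement_type %in% MOVEMENT_TYPES)
      stop(sprintf("trial %d: unknown movement_type '%s'", id,
                   tr$movement_type))
    if (!tr$direction %in% DIRECTIONS)
      stop(sprintf("trial %d: unknown direction '%s'", id, tr$direction))
    nl <- length(tr$lfp$left); nr <- length(tr$lfp$right)
    if (nl != nr)
      stop(sprintf("trial %d: LFP channels differ in length (%d vs %d)",
                   id, nl, nr))
    dur <- nl / s$f_s
    ev <- tr$events
    if (ev$target_on >= ev$go_cue)
      stop(sprintf("trial %d: go_cue (%g) must follow target_on (%g)",
                   id, ev$go_cue, ev$target_on))
    for (e in c("target_on", "go_cue", "move_onset")) {
      if (ev[[e]] < 0 || ev[[e]] > dur)
        stop(sprintf("trial %d: event %s (%g s) outside trace [0, %g)",
                     id, e, ev[[e]], dur))
    }
    for (u in names(tr$spikes)) {
      st <- tr$spikes[[u]]
      if (is.unsorted(st, strictly = FALSE))
        stop(sprintf("unsorted spikes, unit %s, trial %d", u, id))
      if (length(st) && (st[1] < 0 || st[length(st)] > dur))
        stop(sprintf("trial %d: unit %s spike outside trace", id, u))
    }
  }
  invisible(TRUE)
}

#' @export
print.bicoher_session <- function(x, ...) {
  cat(sprintf("<bicoher_session> %d trials, %d units, f_s = %g Hz\n",
              length(x$trials), nrow(x$units), x$f_s))
  tab <- table(vapply(x$trials, `[[`, "", "movement_type"))
  for (nm in names(tab)) cat(sprintf("  %-18s %d trials\n", nm, tab[[nm]]))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Define an analysis epoch
#'
#' An epoch is a half-open window `[start_offset, end_offset)` in seconds
#' relative to a named trial event.
#'
#' @param anchor Event name: `"target_on"`, `"go_cue"` or `"move_onset"`.
#' @param start_offset,end_offset Offsets in seconds, `start < end`.
#' @return An object of class `"bicoher_epoch"`.
#' @export
epoch <- function(anchor, start_offset, end_offset) {
  if (!anchor %in% c("target_on", "go_cue", "move_onset"))
    stop("unknown anchor event: ", anchor)
  if (!(start_offset < end_offset))
    stop("epoch start_offset must be < end_offset")
  structure(list(anchor = anchor, start_offset = start_offset,
                 end_offset = end_offset), class = "bicoher_epoch")
}

#' Extract an epoch from a trial
#'
#' Slices both LFP channels to the window and re-references retained spikes
#' to the window start. Windows are half-open `[start, end)` for both
#' samples and spikes; an epoch that exceeds the trace is an error, never a
#' silent truncation.
#'
#' @param tr A [trial()].
#' @param ep A [epoch()].
#' @param f_s Sampling rate in Hz.
#' @return List with `lfp` (left/right slices of
#'   `round((end-start)*f_s)` samples), `spikes` (window-relative times),
#'   `t0` (window start on the trial clock) and `duration`.
#' @export
extract_epoch <- function(tr, ep, f_s) {
  anchor_t <- tr$events[[ep$anchor]]
  t0 <- anchor_t + ep$start_offset
  t1 <- anchor_t + ep$end_offset
  i0 <- round(t0 * f_s)                 # 0-based index of first sample
  n <- round((t1 - t0) * f_s)
  nsamp <- length(tr$lfp$left)
  if (i0 < 0 || i0 + n > nsamp)
    stop(sprintf(
      "trial %d: epoch [%g, %g) s exceeds trace [0, %g) s",
      tr$trial_id, t0, t1, nsamp / f_s))
  idx <- (i0 + 1):(i0 + n)
  spk <- lapply(tr$spikes, function(st) st[st >= t0 & st < t1] - t0)
  list(lfp = list(left = tr$lfp$left[idx], right = tr$lfp$right[idx]),
       spikes = spk, t0 = t0, duration = t1 - t0)
}

#' Select trials by condition
#'
#' @param s A [session()].
#' @param movement_type Movement type to match.
#' @param direction Optional direction; if `NULL`, both directions match.
#' @return List of matching trials, order preserved.
#' @export
select_trials <- function(s, movement_type, direction = NULL) {
  keep <- vapply(s$trials, function(tr) {
    tr$movement_type %in% movement_type &&
      (is.null(direction) || tr$direction == direction)
  }, logical(1))
  s$trials[keep]
}

#' Remap a condition label to a hemisphere's frame
#'
#' Stored labels use the left hemisphere as the reference: "ipsimanual"
#' means the left arm moves. For a right-hemisphere unit or channel the
#' roles swap (ipsimanual and contramanual exchange), and for
#' bimanual-apart the direction flips because the label's direction refers
#' to the reference hemisphere's contralateral arm.
#'
#' @param movement_type,direction Stored label.
#' @param hemisphere `"left"` or `"right"`.
#' @return List with remapped `movement_type` and `direction`.
#' @export
relabel_for_hemisphere <- function(movement_type, direction, hemisphere) {
  if (hemisphere == "left")
    return(list(movement_type = movement_type, direction = direction))
  mt <- switch(movement_type,
               ipsimanual = "contramanual",
               contramanual = "ipsimanual",
               movement_type)
  dir <- direction
  if (movement_type == "bimanual_apart")
    dir <- if (direction == "preferred") "null" else "preferred"
  list(movement_type = mt, direction = dir)
}

# Which arm moves, and in which direction, for a stored label.
# Returns list(left_arm=, right_arm=) with values "preferred"/"null"/"none".
arm_movements <- function(movement_type, direction) {
  opp <- function(d) if (d == "preferred") "null" else "preferred"
  switch(movement_type,
    saccade = list(left_arm = "none", right_arm = "none"),
    ipsimanual = list(left_arm = direction, right_arm = "none"),
    contramanual = list(left_arm = "none", right_arm = direction),
    bimanual_together = list(left_arm = direction, right_arm = direction),
    bimanual_apart = list(left_arm = opp(direction), right_arm = direction),
    stop("unknown movement_type: ", movement_type))
}
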