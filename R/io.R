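#' Write a session bundle to disk
#'
#' The bundle is a directory holding `manifest.json` (format version,
#' sampling rate, unit table, per-trial metadata and array index),
#' `lfp.bin`, `spikes.bin` and `events.bin` (little-endian float64, giving
#' bit-exact round trips for voltage samples, spike and event times), and
#' a `trials.csv`
#' export (one row per trial with the condition label and event times) for
#' inspection. Invariants are validated before anything is written.
#'
#' @param s A [session()].
#' @param path Directory to create or overwrite.
#' @return Invisibly, `path`.
#' @seealso [read_session()]
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)

  lfp_con <- file(file.path(path, "lfp.bin"), "wb")
  spk_con <- file(file.path(path, "spikes.bin"), "wb")
  ev_con <- file(file.path(path, "events.bin"), "wb")
  on.exit({ close(lfp_con); close(spk_con); close(ev_con) }, add = TRUE)

  unit_ids <- as.character(s$units$unit_id)
  trial_meta <- vector("list", length(s$trials))
  spk_offset <- 0L
  for (i in seq_along(s$trials)) {
    tr <- s$trials[[i]]
    n <- length(tr$lfp$left)
    writeBin(tr$lfp$left, lfp_con, size = 8, endian = "little")
    writeBin(tr$lfp$right, lfp_con, size = 8, endian = "little")
    counts <- integer(length(unit_ids))
    for (j in seq_along(unit_ids)) {
      st <- tr$spikes[[unit_ids[j]]]
      if (is.null(st)) st <- numeric(0)
      writeBin(as.numeric(st), spk_con, size = 8, endian = "little")
      counts[j] <- length(st)
    }
    writeBin(c(tr$events$target_on, tr$events$go_cue,
               tr$events$move_onset), ev_con, size = 8, endian = "little")
    trial_meta[[i]] <- list(
      trial_id = tr$trial_id,
      movement_type = tr$movement_type,
      direction = tr$direction,
      n_samples = n,
      target_on = tr$events$target_on,
      go_cue = tr$events$go_cue,
      move_onset = tr$events$move_onset,
      spike_counts = counts)
    spk_offset <- spk_offset + sum(counts)
  }

  manifest <- list(
    format_version = "1.0",
    f_s = s$f_s,
    provenance = s$provenance,
    condition_codes = apply(condition_labels(), 1, paste, collapse = "/"),
    units = lapply(seq_len(nrow(s$units)), function(j)
      list(unit_id = unit_ids[j], hemisphere = s$units$hemisphere[j])),
    trials = trial_meta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  df <- do.call(rbind, lapply(trial_meta, function(m)
    data.frame(trial_id = m$trial_id, movement_type = m$movement_type,
               direction = m$direction, target_on = m$target_on,
               go_cue = m$go_cue, move_onset = m$move_onset,
               n_samples = m$n_samples)))
  utils::write.csv(df, file.path(path, "trials.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Parses the manifest, reads the binary LFP and spike arrays, rebuilds the
#' [session()] and validates every invariant (unknown condition codes,
#' unsorted spike trains and missing channels raise descriptive errors).
#'
#' @param path Bundle directory written by [write_session()].
#' @return A [session()].
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in bundle: ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  f_s <- manifest$f_s
  units <- data.frame(
    unit_id = vapply(manifest$units, `[[`, "", "unit_id"),
    hemisphere = vapply(manifest$units, `[[`, "", "hemisphere"),
    stringsAsFactors = FALSE)
  unit_ids <- units$unit_id

  lfp_con <- file(file.path(path, "lfp.bin"), "rb")
  spk_con <- file(file.path(path, "spikes.bin"), "rb")
  ev_con <- file(file.path(path, "events.bin"), "rb")
  on.exit({ close(lfp_con); close(spk_con); close(ev_con) }, add = TRUE)

  trials <- vector("list", length(manifest$trials))
  for (i in seq_along(manifest$trials)) {
    m <- manifest$trials[[i]]
    n <- m$n_samples
    left <- readBin(lfp_con, "double", n = n, size = 8, endian = "little")
    right <- readBin(lfp_con, "double", n = n, size = 8, endian = "little")
    if (length(left) != n || length(right) != n)
      stop(sprintf("trial %d: truncated LFP data (missing channel?)",
                   m$trial_id))
    counts <- unlist(m$spike_counts)
    spikes <- stats::setNames(vector("list", length(unit_ids)), unit_ids)
    for (j in seq_along(unit_ids)) {
      st <- readBin(spk_con, "double", n = counts[j], size = 8,
                    endian = "little")
      if (is.unsorted(st))
        stop(sprintf("unsorted spikes, unit %s, trial %d",
                     unit_ids[j], m$trial_id))
      spikes[[j]] <- st
    }
    if (!m$movement_type %in% MOVEMENT_TYPES)
      stop(sprintf("trial %d: unknown condition code '%s'", m$trial_id,
                   m$movement_type))
    ev <- readBin(ev_con, "double", n = 3, size = 8, endian = "little")
    trials[[i]] <- trial(m$trial_id, m$movement_type, m$direction,
                         left, right, spikes, ev[1], ev[2], ev[3])
  }
  session(trials, units, f_s = f_s, provenance = manifest$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
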