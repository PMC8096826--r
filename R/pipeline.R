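# End-to-end orchestration: simulate -> power -> coherence -> lag scan ->
# phase locking -> permutation null -> condition contrast -> mixing model,
# with a config echo, a run log and a Markdown report.

#' Pipeline run configuration
#'
#' Collects every number any stage uses, so the config echo is complete
#' (no hidden defaults). Epochs: baseline -0.5-0 s re target onset, delay
#' 0.65-1.15 s re target onset, pre-go -0.5-0 s (LFP-LFP) and -0.8-0 s
#' (spike-LFP) re go cue. Bands: beta 20-30 Hz, gamma 70-120 Hz, lag-scan
#' band 24-38 Hz. Multitaper: NW 2.5 for LFP power/coherence, NW 12 for
#' spike-LFP. 188 permutations.
#'
#' @param sim A [sim_config()] describing the synthetic session (or
#'   `NULL` with `session_path` pointing at an existing bundle).
#' @param session_path Optional existing bundle directory.
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param n_sites Number of independently simulated site-pairs used by the
#'   contrast stage (each is one simulated session with a derived seed).
#' @param n_perm Permutations for the spike-field null.
#' @param baseline_epoch,delay_epoch,prego_lfp_epoch,prego_spike_epoch
#'   Analysis epochs.
#' @param beta_band,gamma_band,lag_band Analysis bands (Hz).
#' @param nw_lfp,nw_spike Time-half-bandwidth products.
#' @param plv_freqs Frequencies (Hz) for the phase-locking stage.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(),
                       session_path = NULL,
                       out_dir = tempfile("bicoher_run_"),
                       seed = 1,
                       n_sites = 6,
                       n_perm = 188,
                       baseline_epoch = epoch("target_on", -0.5, 0),
                       delay_epoch = epoch("target_on", 0.65, 1.15),
                       prego_lfp_epoch = epoch("go_cue", -0.5, 0),
                       prego_spike_epoch = epoch("go_cue", -0.8, 0),
                       beta_band = c(20, 30),
                       gamma_band = c(70, 120),
                       lag_band = c(24, 38),
                       nw_lfp = 2.5,
                       nw_spike = 12,
                       plv_freqs = seq(10, 60, by = 5)) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from JSON
#'
#' The JSON mirrors [run_config()] field-for-field (epochs as
#' `{anchor, start, end}` objects, the simulator block under `sim`).
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path JSON file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(j), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- list()
  for (nm in names(j)) {
    v <- j[[nm]]
    if (nm %in% c("baseline_epoch", "delay_epoch", "prego_lfp_epoch",
                  "prego_spike_epoch")) {
      args[[nm]] <- epoch(v$anchor, v$start, v$end)
    } else if (nm == "sim") {
      sim_known <- names(formals(sim_config))
      sbad <- setdiff(names(v), sim_known)
      if (length(sbad))
        stop("unknown sim config keys: ", paste(sbad, collapse = ", "))
      args[[nm]] <- do.call(sim_config, v)
    } else args[[nm]] <- v
  }
  do.call(run_config, args)
}

write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage against a synthetic (or loaded) session and writes
#' CSV tables, JSON fits, `run.log` and a Markdown report. Identical
#' config and seed give bit-identical CSV/JSON outputs. A stage failure
#' halts the run with the stage name; outputs written so far are kept
#' alongside a `FAILED` marker file.
#'
#' @param cfg A [run_config()].
#' @return Object of class `"run_report"`: stage output paths, config
#'   echo, wall-clock seconds per stage and accumulated warnings.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  warns <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    message(msg)
  }
  outputs <- list()
  timings <- numeric(0)
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        writeLines(sprintf("FAILED at stage %s: %s", name,
                           conditionMessage(e)),
                   file.path(cfg$out_dir, "FAILED"))
        stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  # config echo
  echo <- rapply(cfg, function(x)
    if (inherits(x, "bicoher_epoch")) unclass(x) else x, how = "replace")
  jsonlite::write_json(echo, file.path(cfg$out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  note("effective beta band (NW %g, 400 ms windows): %s Hz", cfg$nw_lfp,
       paste(effective_band(cfg$beta_band, 0.4, cfg$nw_lfp),
             collapse = "-"))
  note("effective gamma band (NW %g, 200 ms windows): %s Hz", cfg$nw_lfp,
       paste(effective_band(cfg$gamma_band, 0.2, cfg$nw_lfp),
             collapse = "-"))
  note("effective lag band (NW %g, 800 ms windows): %s Hz", cfg$nw_spike,
       paste(effective_band(cfg$lag_band, 0.8, cfg$nw_spike),
             collapse = "-"))

  # --- simulate -------------------------------------------------------
  sess <- stage("simulate", function() {
    if (!is.null(cfg$session_path)) return(read_session(cfg$session_path))
    sim <- cfg$sim
    sim$seed <- derive_seed(cfg$seed, 1)
    gen <- generate_session(sim)
    bpath <- file.path(cfg$out_dir, "session")
    write_session(gen$session, bpath)
    jsonlite::write_json(gen$ground_truth,
                         file.path(cfg$out_dir, "session.truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    outputs$session <<- bpath
    gen$session
  })
  f_s <- sess$f_s

  # --- power ----------------------------------------------------------
  stage("power", function() {
    centers <- seq(cfg$baseline_epoch$start_offset + 0.2,
                   cfg$delay_epoch$end_offset, by = 0.1)
    tc <- power_timecourse(sess, cfg$beta_band, 0.2, 0.1, "target_on",
                           centers = centers, channel = "left",
                           nw = cfg$nw_lfp)
    tc <- normalize_to_baseline(tc, sess, cfg$baseline_epoch)
    outputs$power <<- write_stage_csv(
      tc$values, file.path(cfg$out_dir, "power.csv"))
  })

  # --- coherence (LFP-LFP, per condition, plus contrast sites) --------
  coh_res <- stage("coherence", function() {
    site_sessions <- c(list(sess), lapply(seq_len(cfg$n_sites - 1),
      function(i) {
        sim <- cfg$sim
        sim$seed <- derive_seed(cfg$seed, 100 + i)
        generate_session(sim)$session
      }))
    cond_sets <- list(
      saccade = "saccade",
      unimanual = c("ipsimanual", "contramanual"),
      bimanual_together = "bimanual_together",
      bimanual_apart = "bimanual_apart")
    per_site <- list(); freq <- NULL
    rows <- list()
    for (si in seq_along(site_sessions)) {
      ss <- site_sessions[[si]]
      for (cn in names(cond_sets)) {
        cs <- condition_coherence(ss, cond_sets[[cn]],
                                  cfg$prego_lfp_epoch, cfg$nw_lfp)
        freq <- cs$freq
        per_site[[cn]] <- rbind(per_site[[cn]], cs$magnitude)
        if (si == 1)
          rows[[cn]] <- data.frame(frequency = cs$freq, condition = cn,
                                   coherence = cs$magnitude,
                                   n_ensembles = cs$n_ensembles)
      }
    }
    outputs$coherence <<- write_stage_csv(
      do.call(rbind, rows), file.path(cfg$out_dir, "coherence.csv"))
    list(per_site = per_site, freq = freq)
  })

  # --- contrast -------------------------------------------------------
  stage("contrast", function() {
    freq <- coh_res$freq
    grid_sel <- freq >= 14 & freq <= 90      # 39-frequency analysis grid
    cons <- list(
      c("bimanual_together", "unimanual"),
      c("bimanual_apart", "unimanual"),
      c("bimanual_together", "bimanual_apart"))
    rows <- list()
    for (cp in cons) {
      ct <- condition_contrast(coh_res$per_site[[cp[1]]][, grid_sel],
                               coh_res$per_site[[cp[2]]][, grid_sel],
                               freq = freq[grid_sel],
                               label = paste(cp, collapse = " vs "))
      rows[[length(rows) + 1]] <- data.frame(
        comparison = paste(cp, collapse = "_vs_"), frequency = ct$freq,
        t = ct$t, p = ct$p, p_corrected = ct$p_corrected,
        significant = ct$significant)
    }
    outputs$contrast <<- write_stage_csv(
      do.call(rbind, rows), file.path(cfg$out_dir, "contrast.csv"))
  })

  # --- lag scan -------------------------------------------------------
  stage("lagscan", function() {
    trs <- select_trials(sess, "bimanual_together")
    u <- sess$units$unit_id[sess$units$hemisphere == "left"][1]
    ls <- lagged_spike_lfp_coherence(trs, u, cfg$prego_spike_epoch, f_s,
                                     lfp_channel = "right",
                                     band = cfg$lag_band,
                                     nw = cfg$nw_spike)
    outputs$lagscan <<- write_stage_csv(
      data.frame(lag_s = ls$lags, coherence = ls$value,
                 n_spikes = ls$n_spikes),
      file.path(cfg$out_dir, "lagscan.csv"))
  })

  # --- phase locking --------------------------------------------------
  stage("phaselock", function() {
    u <- sess$units$unit_id[sess$units$hemisphere == "left"][1]
    rows <- list()
    for (mt in c("bimanual_together", "bimanual_apart")) {
      trs <- select_trials(sess, mt)
      for (f0 in cfg$plv_freqs) {
        ph <- spike_phase_set(trs, u, cfg$prego_spike_epoch, f0, f_s,
                              channel = "right")
        pl <- plv(ph)
        rows[[length(rows) + 1]] <- data.frame(
          condition = mt, frequency = f0, plv = pl$plv,
          rayleigh_p = pl$p, ppc = ppc(ph), n_spikes = pl$n_spikes)
      }
    }
    outputs$phaselock <<- write_stage_csv(
      do.call(rbind, rows), file.path(cfg$out_dir, "phaselock.csv"))
  })

  # --- permutation null -----------------------------------------------
  stage("permtest", function() {
    u <- sess$units$unit_id[sess$units$hemisphere == "left"][1]
    trs <- select_trials(sess, "bimanual_together")
    T_ <- round((cfg$prego_spike_epoch$end_offset -
                   cfg$prego_spike_epoch$start_offset) * f_s)
    tp <- make_tapers(T_, cfg$nw_spike)
    ex <- lapply(trs, extract_epoch, ep = cfg$prego_spike_epoch, f_s = f_s)
    spk <- lapply(ex, function(e) e$spikes[[u]])
    lfp <- lapply(ex, function(e) e$lfp$right)
    nd <- permutation_null(spk, lfp, tp, f_s, n_perm = cfg$n_perm,
                           seed = derive_seed(cfg$seed, 2))
    obs <- spike_lfp_coherence(spk, lfp, tp, f_s)
    outputs$permtest <<- write_stage_csv(
      data.frame(frequency = nd$freq, observed = obs$magnitude,
                 q95 = nd$q95, q99 = nd$q99, n_perm = nd$n_perm),
      file.path(cfg$out_dir, "null.csv"))
  })

  # --- mixing model ---------------------------------------------------
  stage("mixmodel", function() {
    prof <- build_condition_profiles(sess, cfg$beta_band, cfg$delay_epoch,
                                     cfg$baseline_epoch, nw = cfg$nw_lfp)
    fit <- fit_mixing_weight(prof)
    cmp <- if (fit$identifiable) compare_models(fit) else NULL
    jsonlite::write_json(
      list(w = fit$w, gain = fit$gain, offset = fit$offset,
           rss_free = fit$rss_free, rss_local = fit$rss_local,
           rss_contra = fit$rss_contra, identifiable = fit$identifiable,
           comparison = cmp, profile = as.data.frame(fit$data)),
      file.path(cfg$out_dir, "mixfit.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    outputs$mixmodel <<- file.path(cfg$out_dir, "mixfit.json")
  })

  # --- report ---------------------------------------------------------
  rp <- file.path(cfg$out_dir, "report.md")
  lines <- c("# bicoher pipeline report", "",
             sprintf("Seed: %d", cfg$seed), "",
             "## Stage outputs", "",
             vapply(names(outputs), function(nm)
               sprintf("- %s: `%s`", nm, basename(outputs[[nm]])), ""),
             "", "## Warnings", "",
             if (length(warns)) paste("-", warns) else "- none")
  writeLines(lines, rp)
  outputs$report <- rp
  note("run complete: %d stage outputs, %d warnings", length(outputs),
       length(warns))

  structure(list(outputs = outputs, config = cfg, timings = timings,
                 warnings = warns, log = log_path),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", length(x$outputs), "outputs in",
      x$config$out_dir, "\n")
  for (nm in names(x$timings))
    cat(sprintf("  %-10s %6.2f s\n", nm, x$timings[[nm]]))
  if (length(x$warnings)) cat(" ", length(x$warnings), "warning(s)\n")
  invisible(x)
}
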