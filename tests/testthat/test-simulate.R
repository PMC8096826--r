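test_that("identical seeds give bit-identical sessions", {
  g1 <- generate_session(small_config(seed = 51))
  g2 <- generate_session(small_config(seed = 51))
  expect_identical(g1$session, g2$session)
  expect_identical(g1$ground_truth$trial_seeds, g2$ground_truth$trial_seeds)
  g3 <- generate_session(small_config(seed = 52))
  expect_false(identical(g1$session$trials[[1]]$lfp$left,
                         g3$session$trials[[1]]$lfp$left))
})

test_that("the session layout matches the configured design", {
  cfg <- small_config(seed = 53, n_trials_per_condition = 3)
  s <- generate_session(cfg)$session
  expect_length(s$trials, 30)
  cl <- condition_labels()
  for (i in seq_len(nrow(cl)))
    expect_length(select_trials(s, cl$movement_type[i], cl$direction[i]), 3)
  expect_setequal(s$units$unit_id, c("L1", "R1"))
  validate_session(s)
})

test_that("fully shared beta components are identical, unshared uncorrelated", {
  flat <- function(v) stats::setNames(rep(v, 5),
    c("saccade", "ipsimanual", "contramanual", "bimanual_together",
      "bimanual_apart"))
  cfg1 <- sim_config(seed = 54, noise_sd = 0, gamma_amp_driven = 0,
                     gamma_amp_undriven = 0,
                     shared_fraction_by_condition = flat(1),
                     baseline_shared_fraction = 1)
  set.seed(54)
  lf <- generate_lfp_pair(cfg1, "saccade", "preferred")
  expect_identical(lf$left, lf$right)

  cfg0 <- sim_config(seed = 55, noise_sd = 0,
                     shared_fraction_by_condition = flat(0),
                     baseline_shared_fraction = 0)
  set.seed(55)
  rs <- replicate(60, {
    lf <- generate_lfp_pair(cfg0, "saccade", "preferred")
    idx <- 1001:2000
    stats::cor(lf$beta_left[idx], lf$beta_right[idx])
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("injected beta amplitude ordering is recovered from band power", {
  s <- generate_session(sim_config(seed = 56,
                                   n_trials_per_condition = 5))$session
  mod <- delay_beta_modulation(s)
  ord <- names(sort(mod, decreasing = TRUE))
  expect_equal(ord, c("saccade", "ipsimanual", "contramanual",
                      "bimanual_together", "bimanual_apart"))
})

test_that("spike generation respects rates, refractoriness and coupling", {
  cfg <- sim_config(seed = 57)
  n <- round(cfg$trial_duration * cfg$f_s)

  # zero rate -> empty train
  cfg0 <- sim_config(seed = 57, rate_driven = 0, rate_undriven = 0,
                     rate_baseline = 0)
  set.seed(1)
  expect_length(generate_spikes(cfg0, "saccade", "preferred", "left",
                                rep(0, n)), 0)

  # mean count within 3 SE of rate x duration (post-target portion)
  set.seed(2)
  counts <- replicate(100, {
    ph <- runif(n, -pi, pi)
    st <- generate_spikes(cfg, "contramanual", "preferred", "left", ph)
    sum(st >= cfg$target_on)
  })
  expected <- cfg$rate_driven * (cfg$trial_duration - cfg$target_on)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)

  # refractoriness: no ISI below the dead time
  set.seed(3)
  st <- generate_spikes(cfg, "contramanual", "preferred", "left",
                        runif(n, -pi, pi))
  expect_true(all(diff(st) >= cfg$refractory - 1e-12))

  # strong coupling concentrates spikes at beta phase zero
  cfgk <- sim_config(seed = 57, phase_coupling_kappa = 50)
  set.seed(4)
  lf <- generate_lfp_pair(cfgk, "contramanual", "preferred")
  st <- generate_spikes(cfgk, "contramanual", "preferred", "left",
                        lf$phase_left)
  ph_at <- lf$phase_left[pmin(floor(st * cfgk$f_s) + 1, n)]
  R <- Mod(mean(exp(1i * ph_at)))
  circ_sd <- sqrt(-2 * log(R))
  expect_lt(circ_sd, 0.3)
})

test_that("homogeneous trains have exponential ISIs when uncoupled", {
  cfg <- sim_config(seed = 58, phase_coupling_kappa = 0, refractory = 0)
  n <- round(cfg$trial_duration * cfg$f_s)
  set.seed(5)
  pvals <- replicate(60, {
    st <- generate_spikes(cfg, "contramanual", "preferred", "left",
                          rep(0, n))
    isi <- diff(st[st >= cfg$target_on])
    suppressWarnings(stats::ks.test(isi, "pexp",
                                    rate = 1 / mean(isi))$p.value)
  })
  expect_gt(mean(pvals > 0.01), 0.9)
})

test_that("gamma power is high only when the contralateral arm moves preferred", {
  cfg <- sim_config(seed = 59)
  tp <- make_tapers(500, 2.5)
  gpow <- function(mt, dir, chan) {
    set.seed(60)
    segs <- replicate(15, {
      lf <- generate_lfp_pair(cfg, mt, dir)
      lf[[chan]][1501:2000]                    # post-target window
    }, simplify = FALSE)
    band_power(mt_spectrum(segs, tp, cfg$f_s, "eigenvalue"), c(70, 110))
  }
  hi <- gpow("contramanual", "preferred", "left")    # right arm preferred
  lo1 <- gpow("contramanual", "null", "left")
  lo2 <- gpow("ipsimanual", "preferred", "left")     # left arm: ipsi
  hi2 <- gpow("ipsimanual", "preferred", "right")    # but contra to right hem
  expect_gt(hi, 2 * lo1)
  expect_gt(hi, 2 * lo2)
  expect_gt(hi2, 2 * lo2)
})

test_that("architecture scenarios dissociate by the sign of the lag extremum", {
  s_dir <- generate_session(architecture_scenario("direct", seed = 61,
    n_trials_per_condition = 8))$session
  p_dir <- pooled_lag_profile(s_dir)
  lag_dir <- 1000 * p_dir$lags[which.max(p_dir$value)]
  expect_gt(lag_dir, 0)

  s_com <- generate_session(architecture_scenario("common_input", seed = 61,
    n_trials_per_condition = 8))$session
  p_com <- pooled_lag_profile(s_com)
  lag_com <- 1000 * p_com$lags[which.max(p_com$value)]
  expect_lt(lag_com, 0)
})
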