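test_that("self-coherence is one and trivial preconditions are enforced", {
  set.seed(1)
  tp <- make_tapers(500, 2.5)
  xs <- replicate(8, rnorm(500), simplify = FALSE)
  cs <- lfp_lfp_coherence(xs, xs, tp, 1000)
  expect_true(all(abs(cs$magnitude - 1) < 1e-9))
  expect_true(all(cs$magnitude <= 1 + 1e-9))
  expect_error(lfp_lfp_coherence(xs[1], xs[1], tp, 1000),
               "across trials")
})

test_that("coherence is scale invariant and conjugates under swap", {
  set.seed(2)
  tp <- make_tapers(500, 2.5)
  xs <- list(); ys <- list()
  for (i in 1:20) {
    sh <- bicoher:::narrowband_noise(500, 25, 3, 1000)
    xs[[i]] <- sh + rnorm(500, sd = 0.7)
    ys[[i]] <- sh + rnorm(500, sd = 0.7)
  }
  c1 <- lfp_lfp_coherence(xs, ys, tp, 1000)
  c2 <- lfp_lfp_coherence(lapply(xs, `*`, 17), ys, tp, 1000)
  expect_equal(c1$magnitude, c2$magnitude, tolerance = 1e-10)
  c3 <- lfp_lfp_coherence(ys, xs, tp, 1000)
  expect_equal(c3$coherency, Conj(c1$coherency), tolerance = 1e-10)
})

test_that("common-signal coherence law holds across shared fractions", {
  # x = sqrt(c) s + sqrt(1-c) p: within the shared band |C| ~ c
  tp <- make_tapers(500, 2.5)
  set.seed(3)
  for (c_ in c(0.2, 0.5, 0.8)) {
    xs <- list(); ys <- list()
    for (i in 1:200) {
      sh <- bicoher:::narrowband_noise(500, 25, 3, 1000)
      xs[[i]] <- sqrt(c_) * sh +
        sqrt(1 - c_) * bicoher:::narrowband_noise(500, 25, 3, 1000)
      ys[[i]] <- sqrt(c_) * sh +
        sqrt(1 - c_) * bicoher:::narrowband_noise(500, 25, 3, 1000)
    }
    cs <- lfp_lfp_coherence(xs, ys, tp, 1000)
    expect_lt(abs(cs$magnitude[cs$freq == 26] - c_), 0.06)
  }
})

test_that("independent signals give only small-sample bias coherence", {
  set.seed(4)
  tp <- make_tapers(500, 2.5)
  xs <- replicate(50, rnorm(500), simplify = FALSE)
  ys <- replicate(50, rnorm(500), simplify = FALSE)
  cs <- lfp_lfp_coherence(xs, ys, tp, 1000)
  # E|C| under independence ~ sqrt(pi / (4 N K)) ~ 0.063 for N=50, K=4
  expect_lt(mean(cs$magnitude), 2 * sqrt(pi / (4 * 50 * tp$K)))
})

test_that("deterministically phase-locked spikes give strong coherence", {
  tp <- make_tapers(800, 12)
  f_s <- 1000
  tt <- (0:799) / f_s
  lfp <- cos(2 * pi * 25 * tt)
  spk <- seq(0, 0.799, by = 1 / 25)      # one spike per beta peak
  cs <- spike_lfp_coherence(replicate(10, spk, simplify = FALSE),
                            replicate(10, lfp, simplify = FALSE),
                            tp, f_s)
  expect_gt(max(cs$magnitude[cs$freq >= 20 & cs$freq <= 30]), 0.8)
  expect_equal(cs$half_bandwidth, 15)
  expect_equal(cs$n_spikes, 200)
  expect_error(
    spike_lfp_coherence(replicate(10, numeric(0), simplify = FALSE),
                        replicate(10, lfp, simplify = FALSE), tp, f_s),
    "no spikes")
})

test_that("a pure time shift preserves magnitude and rotates phase", {
  set.seed(6)
  tp <- make_tapers(500, 2.5)
  n_pad <- 600
  xs <- list(); ys0 <- list(); ysd <- list()
  shift <- 10                             # 10 ms
  for (i in 1:150) {
    z <- bicoher:::narrowband_noise(n_pad, 25, 3, 1000)
    xs[[i]] <- z[1:500] + rnorm(500, sd = 0.3)
    ys0[[i]] <- z[1:500] + rnorm(500, sd = 0.3)
    ysd[[i]] <- z[(1 + shift):(500 + shift)] + rnorm(500, sd = 0.3)
  }
  c0 <- lfp_lfp_coherence(xs, ys0, tp, 1000)
  cd <- lfp_lfp_coherence(xs, ysd, tp, 1000)
  sel <- c0$freq >= 22 & c0$freq <= 28
  expect_lt(max(abs(cd$magnitude[sel] - c0$magnitude[sel]) /
                  c0$magnitude[sel]), 0.06)
  # phase rotates by 2 pi f Delta for the shifted copy
  dphi <- Arg(cd$coherency[c0$freq == 26] / c0$coherency[c0$freq == 26])
  expect_lt(abs(abs(dphi) - 2 * pi * 26 * 0.010), 0.25)
})

test_that("lag zero reproduces the unlagged band-averaged coherence", {
  s <- generate_session(small_config(seed = 8,
                                     n_trials_per_condition = 5))$session
  ep <- epoch("go_cue", -0.8, 0)
  trs <- select_trials(s, "bimanual_together")
  ls <- lagged_spike_lfp_coherence(trs, "L1", ep, s$f_s, "right",
                                   lags = c(-0.005, 0, 0.005))
  ex <- lapply(trs, extract_epoch, ep = ep, f_s = s$f_s)
  cs <- spike_lfp_coherence(lapply(ex, function(e) e$spikes$L1),
                            lapply(ex, function(e) e$lfp$right),
                            make_tapers(800, 12), s$f_s)
  sel <- cs$freq >= 24 & cs$freq <= 38
  expect_equal(ls$value[2], mean(cs$magnitude[sel]), tolerance = 1e-10)
  expect_true(all(ls$value >= 0 & ls$value <= 1))
  expect_error(
    lagged_spike_lfp_coherence(trs, "L1", ep, s$f_s, "right",
                               lags = c(-0.2, 0)), "50 ms")
})
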