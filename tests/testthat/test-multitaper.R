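test_that("taper counts, orthonormality and bandwidth arithmetic", {
  tp <- make_tapers(400, 2.5)
  expect_equal(tp$K, 4)
  expect_equal(make_tapers(800, 12)$K, 23)
  expect_equal(make_tapers(400, 1)$K, 1)
  G <- crossprod(tp$tapers)
  expect_lt(max(abs(G - diag(tp$K))), 1e-10)
  expect_true(all(diff(tp$eigenvalues) <= 0))
  expect_error(make_tapers(8, 5), "K >= T")

  expect_equal(half_bandwidth(0.400, 2.5), 6.25)
  expect_equal(half_bandwidth(0.200, 2.5), 12.5)
  expect_equal(half_bandwidth(0.800, 12), 15)

  expect_equal(effective_band(c(20, 30), 0.4, 2.5), c(13.75, 36.25))
  expect_equal(effective_band(c(5, 10), 0.4, 2.5), c(0, 16.25))
})

test_that("PSD integrates to signal variance (Parseval)", {
  tp <- make_tapers(400, 2.5)
  expect_true(all(mt_spectrum(list(rep(0, 400)), tp, 1000)$S == 0))

  set.seed(101)
  trials <- replicate(200, rnorm(400), simplify = FALSE)
  for (w in c("eigenvalue", "adaptive")) {
    sp <- mt_spectrum(trials, tp, 1000, weighting = w)
    expect_true(all(sp$S >= 0))
    expect_lt(abs(sum(sp$S) * sp$df - 1), 0.05)
  }
})

test_that("a sinusoid's variance is recovered in its band, with low leakage", {
  tp <- make_tapers(400, 2.5)
  set.seed(5)
  trials <- lapply(1:8, function(i)
    2 * cos(2 * pi * 25 * (0:399) / 1000 + runif(1) * 2 * pi))
  sp <- mt_spectrum(trials, tp, 1000, weighting = "eigenvalue")
  bp <- band_power(sp, c(25 - 6.25, 25 + 6.25))
  expect_lt(abs(bp - 2) / 2, 0.02)              # A^2/2 = 2 V^2
  out <- band_power(sp, c(70, 120))
  expect_lt(out / (sum(sp$S) * sp$df), 0.01)    # leakage outside support
})

test_that("adaptive and eigenvalue weights agree for high-SNR white noise", {
  set.seed(9)
  trials <- replicate(100, rnorm(400), simplify = FALSE)
  tp <- make_tapers(400, 2.5)
  se <- mt_spectrum(trials, tp, 1000, "eigenvalue")
  sa <- mt_spectrum(trials, tp, 1000, "adaptive")
  expect_lt(stats::median(abs(sa$S - se$S) / se$S), 0.03)
})

test_that("band power is additive over adjacent bands", {
  set.seed(13)
  sp <- mt_spectrum(replicate(20, rnorm(500), simplify = FALSE),
                    make_tapers(500, 2.5), 1000)
  expect_equal(band_power(sp, c(10, 20)) + band_power(sp, c(20, 30)),
               band_power(sp, c(10, 30)))
  expect_error(band_power(sp, c(20.3, 20.9)), "no grid frequencies")
  # rectangle: flat unit spectrum over (20, 30) sums to 10 V^2
  flat <- sp; flat$S <- rep(1, length(sp$S))
  expect_equal(band_power(flat, c(20, 30)), 10, tolerance = 1e-12)
})

test_that("power timecourse is flat for stationary rhythms and tracks steps", {
  set.seed(21)
  f_s <- 1000; n <- 3000
  mk_tr <- function(i, step = FALSE) {
    x <- bicoher:::narrowband_noise(n, 25, 3, f_s)
    if (step) x[1501:n] <- 2 * x[1501:n]     # x2 amplitude => x4 power
    trial(i, "saccade", "preferred", x, x, list(),
          target_on = 1.5, go_cue = 2.5, move_onset = 2.8)
  }
  u <- data.frame(unit_id = "L1", hemisphere = "left")
  centers <- seq(-1.0, 1.0, by = 0.1)

  s_flat <- session(lapply(1:100, mk_tr), u, f_s)
  tc <- power_timecourse(s_flat, c(20, 30), 0.2, 0.1, "target_on",
                         centers = centers)
  v <- tc$values$power
  expect_lt(stats::sd(v) / mean(v), 0.15)
  expect_equal(diff(tc$values$center), rep(0.1, length(centers) - 1))

  s_step <- session(lapply(1:100, mk_tr, step = TRUE), u, f_s)
  tc2 <- power_timecourse(s_step, c(20, 30), 0.2, 0.1, "target_on",
                          centers = centers)
  vv <- tc2$values
  before <- mean(vv$power[vv$center <= -0.3])
  after <- mean(vv$power[vv$center >= 0.3])
  expect_lt(abs(after / before - 4) / 4, 0.10)
})

test_that("baseline normalization maps baseline power to zero and scales", {
  set.seed(33)
  f_s <- 1000; n <- 3000
  mk_tr <- function(i, post_amp) {
    x <- bicoher:::narrowband_noise(n, 25, 3, f_s)
    x[1501:n] <- post_amp * x[1501:n]
    trial(i, "saccade", "preferred", x, x, list(),
          target_on = 1.5, go_cue = 2.5, move_onset = 2.8)
  }
  u <- data.frame(unit_id = "L1", hemisphere = "left")
  # post-target amplitude x0.75 => power x0.5625 => normalized -0.4375
  s <- session(lapply(1:120, mk_tr, post_amp = 0.75), u, f_s)
  tc <- power_timecourse(s, c(20, 30), 0.2, 0.1, "target_on",
                         centers = seq(0.4, 1.0, 0.1))
  tcn <- normalize_to_baseline(tc, s, epoch("target_on", -0.5, 0))
  expect_equal(tcn$normalization, "percent_of_baseline")
  expect_lt(abs(mean(tcn$values$power) - (-0.4375)), 0.05)

  # unchanged amplitude => normalized ~ 0
  s0 <- session(lapply(1:120, mk_tr, post_amp = 1), u, f_s)
  tc0 <- power_timecourse(s0, c(20, 30), 0.2, 0.1, "target_on",
                          centers = seq(0.4, 1.0, 0.1))
  tcn0 <- normalize_to_baseline(tc0, s0, epoch("target_on", -0.5, 0))
  expect_lt(abs(mean(tcn0$values$power)), 0.1)
})
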