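test_that("ISI shuffling preserves count, first spike and ISI multiset", {
  set.seed(41)
  # brute-force enumeration: ISIs {0.10, 0.20} give exactly two orders
  outs <- unique(t(replicate(100, isi_shuffle(c(0.10, 0.20, 0.40)))))
  expect_equal(nrow(outs), 2)
  expect_true(all(apply(outs, 1, function(o)
    isTRUE(all.equal(o, c(0.10, 0.20, 0.40))) ||
      isTRUE(all.equal(o, c(0.10, 0.30, 0.40))))))

  expect_identical(isi_shuffle(0.25), 0.25)
  expect_identical(isi_shuffle(numeric(0)), numeric(0))

  train <- sort(runif(100, 0, 2))
  for (i in 1:200) {
    sh <- isi_shuffle(train)
    expect_length(sh, 100)
    expect_equal(sh[1], train[1])
    expect_equal(sort(diff(sh)), sort(diff(train)), tolerance = 1e-12)
    expect_false(is.unsorted(sh))
  }
})

test_that("permutation null is deterministic, ordered and detects coupling", {
  tp <- make_tapers(800, 12)
  f_s <- 1000
  tt <- (0:799) / f_s
  set.seed(42)
  lfp <- lapply(1:10, function(i)
    bicoher:::narrowband_noise(800, 25, 3, f_s) + rnorm(800, sd = 0.5))
  # spikes thinned from the LFP beta phase: genuinely coupled
  spk <- lapply(lfp, function(x) {
    ph <- bicoher:::analytic_phase(
      signal::filtfilt(signal::butter(2, c(22, 28) / 500, "pass"), x))
    cand <- sort(runif(120, 0, 0.8))
    cand[runif(120) < exp(1.5 * cos(ph[floor(cand * f_s) + 1])) / exp(1.5)]
  })
  nd <- permutation_null(spk, lfp, tp, f_s, n_perm = 40, seed = 5)
  nd2 <- permutation_null(spk, lfp, tp, f_s, n_perm = 40, seed = 5)
  expect_identical(nd$null, nd2$null)
  expect_equal(nd$n_perm, 40)
  expect_true(all(nd$q99 >= nd$q95))

  obs <- spike_lfp_coherence(spk, lfp, tp, f_s)
  sel <- obs$freq >= 20 & obs$freq <= 30
  expect_gt(max(obs$magnitude[sel] - nd$q99[sel]), 0)
})

test_that("doubling the permutation count moves the threshold little", {
  set.seed(43)
  pairs <- independent_pairs(12, 800, 1000)
  tp <- make_tapers(800, 12)
  n1 <- permutation_null(pairs$spikes, pairs$lfp, tp, 1000,
                         n_perm = 188, seed = 7)
  n2 <- permutation_null(pairs$spikes, pairs$lfp, tp, 1000,
                         n_perm = 376, seed = 7)
  sel <- n1$freq >= 5 & n1$freq <= 100
  expect_lt(stats::median(abs(n2$q95[sel] - n1$q95[sel]) / n1$q95[sel]),
            0.05)
})

test_that("null thresholds agree across movement conditions", {
  # shuffled coherence should not depend on condition structure
  set.seed(44)
  tp <- make_tapers(800, 12)
  qs <- sapply(1:2, function(cond) {
    pairs <- independent_pairs(12, 800, 1000, rate = c(25, 45)[cond])
    nd <- permutation_null(pairs$spikes, pairs$lfp, tp, 1000,
                           n_perm = 100, seed = 8 + cond)
    stats::median(nd$q95[nd$freq >= 10 & nd$freq <= 60])
  })
  expect_lt(abs(qs[1] - qs[2]) / mean(qs), 0.25)
})

test_that("the minimum spike-count filter applies per movement condition", {
  # craft a session where U1 passes everywhere and U2 misses one condition
  f_s <- 1000
  cl <- condition_labels()
  mk <- function(i, mt, dir, n1, n2) {
    trial(i, mt, dir, rep(0, 3000), rep(0, 3000),
          spikes = list(U1 = seq(1.4, 2.2 - 1e-9, length.out = n1),
                        U2 = seq(1.4, 2.2 - 1e-9, length.out = n2)),
          target_on = 0.7, go_cue = 2.2, move_onset = 2.4)
  }
  counts1 <- c(saccade = 600, ipsimanual = 550, contramanual = 700,
               bimanual_together = 510, bimanual_apart = 502)
  counts2 <- counts1; counts2["bimanual_apart"] <- 499
  trials <- lapply(seq_len(nrow(cl)), function(i) {
    mt <- cl$movement_type[i]
    # put all of a movement type's spikes in its preferred-direction trial
    n1 <- if (cl$direction[i] == "preferred") counts1[[mt]] else 0
    n2 <- if (cl$direction[i] == "preferred") counts2[[mt]] else 0
    mk(i, mt, cl$direction[i], n1, n2)
  })
  s <- session(trials, data.frame(unit_id = c("U1", "U2"),
                                  hemisphere = c("left", "right")), f_s)
  kept <- min_spike_filter(s, epoch("go_cue", -0.8, 0), threshold = 500)
  expect_equal(kept, "U1")
})

test_that("spike subsampling keeps trial structure and counts", {
  set.seed(46)
  trains <- lapply(1:10, function(i) sort(runif(80, 0, 0.8)))
  sub <- subsample_spikes(trains, 500)
  expect_equal(sum(lengths(sub)), 500)
  for (i in 1:10) {
    expect_true(all(sub[[i]] %in% trains[[i]]))
    expect_false(is.unsorted(sub[[i]]))
  }
  expect_identical(subsample_spikes(trains, 800), trains)
  expect_error(subsample_spikes(trains, 900), "insufficient")
})

test_that("subsampled coherence tracks the full-count estimate", {
  s <- generate_session(small_config(seed = 47,
                                     n_trials_per_condition = 6))$session
  ep <- epoch("go_cue", -0.8, 0)
  trs <- select_trials(s, "bimanual_together")
  ex <- lapply(trs, extract_epoch, ep = ep, f_s = s$f_s)
  spk <- lapply(ex, function(e) e$spikes$L1)
  lfp <- lapply(ex, function(e) e$lfp$right)
  tp <- make_tapers(800, 12)
  full <- spike_lfp_coherence(spk, lfp, tp, s$f_s)
  sel <- full$freq >= 20 & full$freq <= 30
  set.seed(48)
  subs <- replicate(10, {
    cs <- spike_lfp_coherence(subsample_spikes(spk, 250), lfp, tp, s$f_s)
    mean(cs$magnitude[sel])
  })
  expect_lt(abs(mean(subs) - mean(full$magnitude[sel])) /
              mean(full$magnitude[sel]), 0.15)
})

test_that("condition contrasts apply Bonferroni over the frequency grid", {
  set.seed(49)
  a <- matrix(rnorm(10 * 39), 10, 39)
  ct0 <- condition_contrast(a, a)
  expect_true(all(ct0$p == 1))
  expect_false(any(ct0$significant))

  b <- a; b[, 12] <- b[, 12] + 3      # strong effect at one frequency
  ct <- condition_contrast(a, b, n_bonferroni = 39)
  expect_equal(ct$p_corrected, pmin(1, ct$p * 39))
  expect_true(ct$significant[12])
  expect_true(all(which(ct$significant) == 12))
  # corrected flags are a subset of uncorrected flags
  expect_true(all(ct$significant <= ct$significant_uncorrected))
  # pooled variant runs and is less powerful here
  ctp <- condition_contrast(a, b, paired = FALSE)
  expect_true(ctp$p[12] < 0.05)
})
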