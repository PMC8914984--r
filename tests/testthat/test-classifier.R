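test_that("sub-band extraction separates band-membership tones", {
  seg40 <- make_segment(make_tone(40))
  seg200 <- make_segment(make_tone(200))
  r <- function(seg, low, high)
    rms(edge_trim(extract_subband(seg, low, high)$samples)) /
      rms(edge_trim(seg$samples))
  expect_gte(r(seg40, 25, 79), 0.9)
  expect_lte(r(seg40, 80, 350), 0.1)
  expect_gte(r(seg200, 80, 350), 0.9)
  expect_lte(r(seg200, 25, 79), 0.1)
})

test_that("the two sub-bands jointly conserve a two-tone mixture", {
  seg <- make_segment(make_tone(40) + make_tone(200))
  lf <- extract_subband(seg, 25, 79)
  hf <- extract_subband(seg, 80, 350)
  p_in <- rms(edge_trim(seg$samples))^2
  p_out <- rms(edge_trim(lf$samples))^2 + rms(edge_trim(hf$samples))^2
  expect_equal(p_out / p_in, 1, tolerance = 0.05)
})

test_that("ima matches the brute-force DFT magnitude-mean oracle", {
  expect_equal(ima(rep(0, 16)), 0)
  expect_equal(ima(c(1, 0, 0, 0)), 1)  # impulse: flat unit spectrum
  set.seed(31)
  for (n in c(4, 8, 17, 33, 64)) {
    x <- rnorm(n)
    expect_equal(ima(x), mean(Mod(dft_oracle(x))), tolerance = 1e-9)
  }
})

test_that("fatigue index signs follow tone band membership", {
  fi40 <- fatigue_index(make_segment(make_tone(40)))
  fi200 <- fatigue_index(make_segment(make_tone(200)))
  expect_gt(fi40$fatigue_index, 0)
  expect_lt(fi200$fatigue_index, 0)
  expect_equal(fi40$fatigue_index, fi40$ima_lfss - fi40$ima_hfss)
  expect_true(fi40$ima_lfss >= 0 && fi40$ima_hfss >= 0)
})

test_that("equal-tone mixture index matches the analytic gain oracle", {
  # on-bin tones: each contributes (amplitude x net filter gain) to the
  # IMA of a sub-signal, so the index is predictable from the designed
  # transfer-function magnitudes at the two tone frequencies
  seg <- make_segment(make_tone(40) + make_tone(200))
  fi <- fatigue_index(seg)
  g <- function(low, high, f)
    butter_gain_oracle(4, low, high, f, fs_default)
  predicted <- (g(25, 79, 40) + g(25, 79, 200)) -
               (g(80, 350, 40) + g(80, 350, 200))
  expect_equal(fi$fatigue_index, predicted, tolerance = 0.05)
  expect_equal(sign(fi$fatigue_index), sign(predicted))
})

test_that("adding low-band power never decreases the fatigue index", {
  base <- make_tone(200, amp = 1)
  idx <- vapply(seq(0, 1.5, by = 0.25), function(a)
    fatigue_index(make_segment(base + make_tone(40, amp = a)))$fatigue_index,
    numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("the decision rule is >= 0, with printed session indices", {
  # printed per-session index pairs: first segment -0.682 -> non-fatigue,
  # last segment 0.063 -> fatigue
  expect_equal(fatigue_decision(c(-0.682, 0.063)),
               c("non-fatigue", "fatigue"))
  expect_equal(fatigue_decision(0), "fatigue")      # boundary inclusive
  expect_equal(fatigue_decision(-1e-12), "non-fatigue")
})

test_that("the IEMG gate is strict and suppresses step 2", {
  seg <- make_segment(make_tone(40))  # low-band: index would be positive
  cls <- classify_segment(seg, iemg_initial = iemg(seg))
  expect_false(cls$gate_passed)       # equality does not pass
  expect_equal(cls$label, "non-fatigue")
  expect_null(cls$subband)
  cls2 <- classify_segment(seg, iemg_initial = iemg(seg) * 0.99)
  expect_true(cls2$gate_passed)
  expect_equal(cls2$label, "fatigue")
  # step-2-only mode labels by index sign even when the gate fails
  cls3 <- classify_segment(seg, iemg_initial = iemg(seg) * 2,
                           gate = FALSE)
  expect_false(cls3$gate_passed)
  expect_equal(cls3$label, "fatigue")
})

test_that("a constant-amplitude high-band tone never reads as fatigue", {
  rec <- emg_record(make_tone(200, dur = 12), fs_default)
  rep <- detect_fatigue(rec)
  expect_true(all(rep$segments$label == "non-fatigue"))
  expect_true(is.na(rep$onset_time))
})

test_that("labels are invariant under positive amplitude scaling", {
  sim <- simulate_semg(duration_s = 24, crossover_s = 12, amp_growth = 0.35,
                       seed = 13)
  rep1 <- detect_fatigue(sim$record)
  for (a in c(0.01, 250)) {
    reca <- emg_record(a * sim$record$samples, sim$record$fs)
    repa <- detect_fatigue(reca)
    expect_equal(repa$segments$label, rep1$segments$label)
    expect_equal(repa$onset_time, rep1$onset_time)
  }
})

test_that("the report structure is internally consistent", {
  sim <- simulate_semg(duration_s = 24, crossover_s = 12, amp_growth = 0.35,
                       seed = 3)
  rep <- detect_fatigue(sim$record)
  seg <- rep$segments
  expect_equal(seg$segment_index, seq_len(nrow(seg)))
  expect_equal(seg$t_start_s, (seq_len(nrow(seg)) - 1) * 1.5)
  expect_equal(rep$iemg_initial, seg$iemg[1])
  expect_equal(seg$label[1], "non-fatigue")  # baseline segment
  # label contract: fatigue iff gate passed and index >= 0
  expect_equal(seg$label == "fatigue",
               seg$gate_passed & !is.na(seg$fatigue_index) &
                 seg$fatigue_index >= 0)
  # onset is the first fatigue-labeled segment's start time
  expect_equal(rep$onset_time, seg$t_start_s[seg$label == "fatigue"][1])
  # gate-failed segments carry no sub-band analysis
  expect_true(all(is.na(seg$fatigue_index[!seg$gate_passed])))
  df <- as.data.frame(rep)
  expect_identical(df, seg)
})

test_that("detect_fatigue needs at least two windows", {
  expect_error(detect_fatigue(emg_record(rnorm(3.2 * 2000), 2000)),
               "too short|at least two")
})
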