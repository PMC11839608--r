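test_that("synthetic EEG puts the dominant amplitude in the signature band", {
  tr <- synthesize_eeg("STRESS_ANXIETY", snr = Inf, seed = 2)
  f <- band_powers(tr)
  expect_gt(f$beta_power, f$alpha_power)
  expect_gt(f$beta_power, f$theta_power)
  tr2 <- synthesize_eeg("RELAX_LOW_ENGAGEMENT", snr = Inf, seed = 2)
  f2 <- band_powers(tr2)
  expect_gt(f2$alpha_power, f2$beta_power)
  expect_gt(f2$alpha_power, f2$theta_power)
  expect_identical(synthesize_eeg("FOCUS", seed = 5),
                   synthesize_eeg("FOCUS", seed = 5))
  expect_error(synthesize_eeg("FOCUS", fs = 100), class = "apeo_domain_error")
  expect_error(synthesize_eeg("FOCUS", snr = -1),
               class = "apeo_invalid_argument")
})

test_that("bandpass filter meets its attenuation and passband contract", {
  # 0.2 Hz tone: essentially removed by the 1-50 Hz band
  lo <- tone_trace(0.2)
  expect_lt(signal_power(bandpass_filter(lo)) / signal_power(lo), 0.01)
  # 10 Hz tone: passband, most power retained
  mid <- tone_trace(10)
  expect_gt(signal_power(bandpass_filter(mid)) / signal_power(mid), 0.79)
  # >= 20 dB at twice the upper edge
  hi <- tone_trace(100, fs = 512)
  expect_lt(signal_power(bandpass_filter(hi)) / signal_power(hi), 0.01)
  expect_error(bandpass_filter(tone_trace(10), 50, 1),
               class = "apeo_domain_error")
})

test_that("band powers agree with a direct periodogram oracle on tones", {
  tr <- tone_trace(10)
  f <- band_powers(tr)
  oracle <- tone_band_power(tr$samples[, 1], 256, 8, 13)
  expect_equal(f$alpha_power, oracle, tolerance = 0.02)
  expect_gt(f$alpha_power / f$beta_power, 10)
  tr20 <- tone_trace(20)
  f20 <- band_powers(tr20)
  expect_gt(f20$beta_power, 10 * f20$theta_power)
  expect_lt(f20$theta_power, 1e-6)
})

test_that("band powers scale quadratically and are channel-permutation invariant", {
  x1 <- tone_trace(10, amplitude = 1)
  x2 <- tone_trace(10, amplitude = 2)
  expect_equal(band_powers(x2)$alpha_power / band_powers(x1)$alpha_power, 4,
               tolerance = 0.01)
  set.seed(8)
  m <- matrix(rnorm(512 * 3), ncol = 3)
  tr <- apeo:::new_eeg_trace(m, 128)
  trp <- apeo:::new_eeg_trace(m[, c(3, 1, 2)], 128)
  expect_equal(band_powers(tr), band_powers(trp), ignore_attr = TRUE)
})

test_that("zero traces yield zero powers with an undefined theta/alpha ratio", {
  z <- apeo:::new_eeg_trace(matrix(0, 1024, 2), 256)
  f <- band_powers(z)
  expect_equal(f$theta_power, 0)
  expect_equal(f$alpha_power, 0)
  expect_true(is.na(f$ta_ratio))
  expect_true(attr(f, "ta_undefined"))
  expect_error(band_powers(z, bands = list()),
               class = "apeo_invalid_argument")
})

test_that("rule engine follows the table rows and precedence", {
  base <- tibble::tibble(theta_power = 1, alpha_power = 1, beta_power = 1,
                         ta_ratio = 1)
  feat <- function(th = 1, al = 1, be = 1) {
    tibble::tibble(theta_power = th, alpha_power = al, beta_power = be,
                   ta_ratio = th / al)
  }
  expect_equal(classify_emotion(feat(be = 2), base), "STRESS_ANXIETY")
  expect_equal(classify_emotion(feat(th = 0.4), base), "OVERLOAD_FATIGUE")
  expect_equal(classify_emotion(feat(th = 2), base), "FOCUS")
  expect_equal(classify_emotion(feat(al = 2, th = 1.4), base),
               "RELAX_LOW_ENGAGEMENT")
  expect_equal(classify_emotion(feat(th = 0.5, al = 0.5, be = 0.5), base),
               "LACK_OF_INTEREST")
  # fatigue rule takes precedence over a simultaneous beta elevation
  expect_equal(classify_emotion(feat(th = 0.4, be = 2), base),
               "OVERLOAD_FATIGUE")
  expect_warning(out <- classify_emotion(feat(), base), "NONE")
  expect_equal(out, "NONE")
  expect_error(classify_emotion(feat(), feat(th = 0)),
               class = "apeo_domain_error")
})

test_that("state-to-adjustment map matches the rule table bijectively", {
  expect_equal(recommend_adjustment("STRESS_ANXIETY")$adjustment, "RELAXATION")
  expect_equal(recommend_adjustment("OVERLOAD_FATIGUE")$adjustment,
               "LOWER_INTENSITY_REST")
  expect_equal(recommend_adjustment("LACK_OF_INTEREST")$adjustment,
               "HIGH_ENERGY")
  adj <- vapply(emotion_states(),
                function(s) recommend_adjustment(s)$adjustment, character(1))
  expect_equal(length(unique(adj)), 5L)
  none <- recommend_adjustment("NONE")
  expect_true(is.na(none$adjustment))
})

test_that("noiseless end-to-end confusion matrix is exactly diagonal", {
  states <- emotion_states()
  confusion <- matrix(0, 5, 5, dimnames = list(states, states))
  for (seed in 1:20) {
    base <- band_powers(bandpass_filter(
      synthesize_eeg("REST", snr = Inf, seed = 1000 + seed)))
    for (st in states) {
      tr <- bandpass_filter(synthesize_eeg(st, snr = Inf, seed = seed))
      got <- classify_emotion(band_powers(tr), base)
      confusion[st, got] <- confusion[st, got] + 1
    }
  }
  expect_equal(unname(diag(confusion)), rep(20, 5))
  expect_equal(sum(confusion) - sum(diag(confusion)), 0)
})

test_that("EEG traces and the rule table round-trip through disk", {
  tr <- synthesize_eeg("FOCUS", duration = 2, fs = 128, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_eeg_csv(tr, tmp)
  back <- read_eeg_csv(tmp)
  expect_equal(back$fs, 128)
  expect_equal(unname(back$samples), unname(tr$samples), tolerance = 1e-12)
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_rule_table(tmp2)
  rt <- jsonlite::read_json(tmp2, simplifyVector = TRUE)
  expect_equal(nrow(rt), 5)
  expect_equal(rt$adjustment, adjustment_rules()$adjustment)
})
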