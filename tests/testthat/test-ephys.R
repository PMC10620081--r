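# Envelope-analysis pipeline: filters, Hilbert envelope, epoch metrics,
# depth profiles, interpolated maps.

test_that("bandpass behaves like a first-order Butterworth band", {
  fs <- 30000
  t <- (0:(fs - 1)) / fs
  mid <- (fs / 4):(3 * fs / 4)
  expect_lt(max(abs(bandpass(rep(1, fs), fs, 500, 5000)[mid])), 0.02)
  tone <- sin(2 * pi * 2000 * t)
  out <- bandpass(tone, fs, 500, 5000)
  expect_gt(max(out[mid]), 0.9)  # < 10% attenuation at 2 kHz
  # zero-phase filtering leaves the tone exactly in phase: the output is
  # a pure gain times the input away from the edges
  g <- sum(out[mid] * tone[mid]) / sum(tone[mid]^2)
  expect_lt(max(abs(out[mid] - g * tone[mid])), 0.01)
  expect_error(bandpass(tone, fs, 5000, 500), "invalid band")
})

test_that("envelope recovers constant and beating amplitudes", {
  fs <- 30000
  t <- (0:(2 * fs - 1)) / fs
  env1 <- envelope(sin(2 * pi * 2000 * t), fs)
  mid <- (fs / 2):(3 * fs / 2)
  expect_true(all(abs(env1[mid] - 1) < 0.02))
  # two equal tones at 2000/2005 Hz: envelope |2 cos(pi * 5 * t)|
  sig <- sin(2 * pi * 2000 * t) + sin(2 * pi * 2005 * t)
  env2 <- envelope(sig, fs)
  expect_gt(max(env2[mid]), 1.95)
  expect_lt(min(env2[mid]), 0.1)
  closed <- abs(2 * cos(pi * 5 * t[mid]))
  expect_lt(mean(abs(env2[mid] - closed)), 0.05)
  expect_equal(envelope(numeric(10), fs), numeric(10))
  expect_error(envelope(numeric(0), fs), "empty")
})

test_that("modulation metrics recover the two-tone closed forms", {
  fs <- 30000
  mk <- function(A1, A2, dur = 5)
    synth_recording(0, A1, A2, 2005, 2000, fs, dur, noise_sd = 0)$data[1, ]
  m11 <- modulation_metrics(mk(1, 1), fs, n_epochs = 5)
  expect_equal(m11$modulation_amplitude, 1, tolerance = 0.01)
  expect_equal(m11$absolute_amplitude, 2, tolerance = 0.01)
  expect_equal(m11$modulation_ratio, 1, tolerance = 0.02)
  m31 <- modulation_metrics(mk(3, 1), fs, n_epochs = 5)
  expect_equal(m31$modulation_amplitude, 1, tolerance = 0.01)
  expect_equal(m31$absolute_amplitude, 4, tolerance = 0.01)
  expect_equal(m31$modulation_ratio, 0.5, tolerance = 0.02)
  m0 <- modulation_metrics(mk(1, 0), fs, n_epochs = 5)
  expect_lt(m0$modulation_amplitude, 0.01)
  expect_lt(m0$modulation_ratio, 0.02)
  expect_error(modulation_metrics(mk(1, 1, dur = 2), fs, n_epochs = 5),
               "too short")
})

test_that("modulation ratio follows 2 min / (A1 + A2) across amplitude ratios", {
  fs <- 30000
  for (r in c(0.1, 0.3, 0.6, 0.9)) {
    tr <- synth_recording(0, 1, r, 2005, 2000, fs, 4, noise_sd = 0)$data[1, ]
    m <- modulation_metrics(tr, fs, n_epochs = 4)
    expect_equal(m$modulation_ratio, 2 * r / (1 + r), tolerance = 0.02)
    # the literal half-difference reading caps at 0.5
    mh <- modulation_metrics(tr, fs, n_epochs = 4,
                             ratio_mode = "half_difference")
    expect_equal(mh$modulation_ratio, r / (1 + r), tolerance = 0.02)
  }
})

test_that("the pipeline is linear in the recording scale", {
  fs <- 30000
  tr <- synth_recording(0, 1, 0.5, 2005, 2000, fs, 3, noise_sd = 0)$data[1, ]
  m1 <- modulation_metrics(tr, fs, n_epochs = 3)
  m2 <- modulation_metrics(5 * tr, fs, n_epochs = 3)
  expect_equal(m2$modulation_amplitude, 5 * m1$modulation_amplitude,
               tolerance = 1e-6)
  expect_equal(m2$absolute_amplitude, 5 * m1$absolute_amplitude,
               tolerance = 1e-6)
  expect_equal(m2$modulation_ratio, m1$modulation_ratio, tolerance = 1e-6)
})

test_that("contact normalization scales each metric to a unit maximum", {
  df <- data.frame(modulation_amplitude = c(1, 2, 4),
                   absolute_amplitude = c(2, 2, 2))
  out <- normalize_across_contacts(df)
  expect_equal(out$normalized_modulation_amplitude, c(0.25, 0.5, 1))
  expect_equal(out$normalized_absolute_amplitude, c(1, 1, 1))
  expect_equal(order(out$normalized_modulation_amplitude),
               order(df$modulation_amplitude))
  expect_error(normalize_across_contacts(
    data.frame(modulation_amplitude = c(0, 0), absolute_amplitude = 1:2)),
    "all-zero")
})

test_that("depth profiles are finite differences in V/m", {
  pr <- depth_profile(c(0, 1, 3), c(0, 2, 4))
  expect_equal(pr$field_Vm, c(0.5, 1.0))
  expect_equal(pr$mid_depth_mm, c(1, 3))
  ramp <- depth_profile(seq(0, 10, by = 2), seq(0, 25, by = 5))
  expect_true(all(abs(ramp$field_Vm - 0.4) < 1e-12))
  expect_error(depth_profile(c(1, 2), c(3, 3)), "increasing")
  expect_error(depth_profile(1, 1), "2 contacts")
})

test_that("a Gaussian-bump amplitude profile is recovered as its derivative", {
  depths <- seq(5, 55, by = 2.5)
  A2 <- 0.8 * exp(-((depths - 30) / 12)^2)
  rec <- synth_recording(depths, rep(3, length(depths)), A2,
                         2005, 2000, fs = 30000, duration = 3, noise_sd = 0)
  met <- analyze_recording(rec, band = "ti", n_epochs = 3)
  # A1 >> A2 everywhere, so modulation amplitude = min = A2 per contact
  pr <- depth_profile(met$contacts$modulation_amplitude, depths)
  dmid <- pr$mid_depth_mm
  analytic <- abs(-2 * (dmid - 30) / 12^2 * 0.8 * exp(-((dmid - 30) / 12)^2))
  big <- analytic > 0.25 * max(analytic)
  expect_lt(max(abs(pr$field_Vm[big] - analytic[big]) / analytic[big]), 0.05)
})

test_that("interpolated maps smooth contacts and hit the stated grid", {
  const <- interpolate_map(matrix(2, 5, 3), 1:5, c(0, 10, 20))
  expect_identical(dim(const), c(100L, 151L))
  expect_true(all(abs(const - 2) < 1e-12))
  expect_equal(tistim:::moving_average3(c(0, 3, 0)), c(1.5, 1, 1.5))
  expect_error(interpolate_map(matrix(1, 1, 3), 1, c(0, 10, 20)), "2 contacts")
  expect_error(interpolate_map(matrix(1, 3, 1), 1:3, 0), "2 electrodes")
})

test_that("full recording analysis matches per-contact closed-form ratios", {
  depths <- c(12, 50)
  rec <- synth_recording(depths, A1_profile = c(1, 1),
                         A2_profile = c(0.07, 1), 2005, 2000,
                         fs = 30000, duration = 3, noise_sd = 0)
  met <- analyze_recording(rec, band = "ti", n_epochs = 3)
  expect_equal(met$contacts$modulation_ratio[2], 1, tolerance = 0.02)
  expect_equal(met$contacts$modulation_ratio[1], 2 * 0.07 / 1.07,
               tolerance = 0.02)
  expect_equal(max(met$contacts$normalized_modulation_amplitude), 1)
  # deterministic end to end
  met2 <- analyze_recording(rec, band = "ti", n_epochs = 3)
  expect_identical(met$contacts, met2$contacts)
})

test_that("tACS-band input shows no envelope modulation", {
  fs <- 30000
  t <- (0:(3 * fs - 1)) / fs
  rec <- list(data = matrix(sin(2 * pi * 5 * t), 1), fs = fs,
              contact_depths = c(0, 10), f1 = 5, f2 = 5)
  rec$data <- rbind(rec$data, 0.5 * rec$data[1, ])
  class(rec) <- "ti_recording"
  met <- analyze_recording(rec, band = "tacs", n_epochs = 3)
  expect_lt(met$contacts$modulation_ratio[1], 0.1)
  expect_lt(met$contacts$modulation_amplitude[1],
            0.05 * met$contacts$absolute_amplitude[1])
})
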