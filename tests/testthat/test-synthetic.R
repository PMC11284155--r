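test_that("configuration invariants are enforced", {
  expect_error(simulation_config(effect_size = 0.5), "effect_size")
  expect_error(simulation_config(seizure_onsets = c(100, 90), duration = 200,
                                 min_seizure_gap = 5), "increasing")
  expect_error(simulation_config(seizure_onsets = c(100, 150), duration = 200,
                                 min_seizure_gap = 600), "min_seizure_gap")
  expect_error(simulation_config(seizure_onsets = 500, duration = 200),
               "within")
  expect_error(simulation_config(effect_band = "mu"), "effect_band")
})

test_that("generation is deterministic and the null patient has no injected effect", {
  cfg <- simulation_config(n_channels = 2, duration = 30, seed = 42)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$signal, r2$signal)

  # effect_size = 1 must produce exactly the background process
  cfg0 <- simulation_config(n_channels = 1, duration = 60,
                            seizure_onsets = 50, min_seizure_gap = 10,
                            preictal_duration = 20, effect_size = 1, seed = 7)
  cfg4 <- simulation_config(n_channels = 1, duration = 60,
                            seizure_onsets = 50, min_seizure_gap = 10,
                            preictal_duration = 20, effect_size = 4, seed = 7)
  r0 <- generate_recording(cfg0)
  r4 <- generate_recording(cfg4)
  pre <- (0:(60 * 256 - 1)) / 256 >= 30 & (0:(60 * 256 - 1)) / 256 < 50
  expect_equal(r0$signal[1, !pre], r4$signal[1, !pre], tolerance = 1e-10)
  expect_gt(mean(r4$signal[1, pre]^2), mean(r0$signal[1, pre]^2))
})

test_that("injected band-power shift is visible in the generated signal", {
  cfg <- simulation_config(
    n_channels = 1, fs = 256, duration = 1800, seizure_onsets = 1500,
    min_seizure_gap = 600, preictal_duration = 600, effect_band = "alpha",
    effect_size = 4, seed = 3
  )
  rec <- generate_recording(cfg)
  t <- (0:(1800 * 256 - 1)) / 256
  band_power_of <- function(idx) {
    w <- welch_psd(rec$signal[1, idx], 256)
    sum(trap_weights(w$freq, 8, 13) * w$psd)
  }
  # last preictal minute vs an interictal minute
  p_pre <- band_power_of(t >= 1440 & t < 1500)
  p_int <- band_power_of(t >= 300 & t < 360)
  expect_gt(p_pre, p_int)
  # ramp: final quarter of the preictal window carries >= 0.75 * effect_size
  p_q4 <- band_power_of(t >= 1350 & t < 1500)
  expect_gt(p_q4, 0.5 * cfg$effect_size * p_int)
})

test_that("null calibration: band powers reject at the nominal rate", {
  cfg <- simulation_config(
    n_channels = 1, fs = 256, duration = 1200, seizure_onsets = 1100,
    min_seizure_gap = 600, preictal_duration = 300, effect_size = 1, seed = 9
  )
  rec <- generate_recording(cfg)
  ws <- make_windows(rec)
  fm <- extract_features(ws)
  lab <- label_windows(fm$keys$time, 1100, sop = 300 / 60 - 5, sph = 5)
  a <- fm$values[lab == 1 & !is.na(lab), "ch01.rsp_alpha"]
  b <- fm$values[lab == 0 & !is.na(lab), "ch01.rsp_alpha"]
  expect_gt(stats::t.test(a, b)$p.value, 0.01)
})

test_that("segmentation yields the expected clip counts and clean classes", {
  cfg <- simulation_config(n_channels = 1, fs = 64, duration = 7200,
                           seizure_onsets = 5000, min_seizure_gap = 600,
                           preictal_duration = 3600, effect_size = 2, seed = 5)
  rec <- generate_recording(cfg)
  ds <- segment_recording(rec, segment_duration = 600,
                          preictal_duration = 3600, shuffle_seed = 2)
  labs <- vapply(ds$segments, `[[`, "", "label")
  # a 1-hour preictal span in 10-minute clips -> exactly 6 preictal files
  expect_identical(sum(labs == "preictal"), 6L)
  pre_gid <- vapply(ds$segments[labs == "preictal"], `[[`, 0, "group_id")
  expect_true(all(pre_gid == 1))
  # interictal clips tile [0, 1400) and (5120, 7200]: 2 clips before the
  # preictal span plus 3 after the blackout; clips straddling the preictal
  # boundary or the blackout are excluded from both classes
  expect_identical(sum(labs == "interictal"), 5L)
  int_gid <- vapply(ds$segments[labs == "interictal"], `[[`, 0, "group_id")
  expect_identical(sort(unique(int_gid)), c(1, 2))

  # no seizures -> no preictal clips
  rec0 <- generate_recording(simulation_config(n_channels = 1, fs = 64,
                                               duration = 1800, seed = 1))
  ds0 <- segment_recording(rec0, 600, 600)
  expect_identical(sum(vapply(ds0$segments, `[[`, "", "label") == "preictal"),
                   0L)

  expect_error(segment_recording(rec, 700, 3600), "divide")
  expect_error(
    segment_recording(generate_recording(
      simulation_config(n_channels = 1, fs = 64, duration = 30, seed = 1)),
      60, 60),
    "shorter")
})

test_that("recording fixtures round-trip through CSV + JSON", {
  cfg <- simulation_config(n_channels = 2, duration = 10,
                           seizure_onsets = 8, min_seizure_gap = 5,
                           preictal_duration = 4, seed = 21)
  rec <- generate_recording(cfg)
  path <- file.path(tempdir(), "rec_fixture")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$signal, rec$signal, tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$seizure_onsets, rec$seizure_onsets)

  ds <- segment_recording(rec, 2, 4, shuffle_seed = 3, ictal_blackout = 1)
  dir <- file.path(tempdir(), "seg_fixture")
  write_segments(ds, dir)
  back2 <- read_segments(dir)
  expect_equal(length(back2$segments), length(ds$segments))
  expect_equal(back2$segments[[1]]$data, ds$segments[[1]]$data,
               tolerance = 1e-12)
  expect_identical(vapply(back2$segments, `[[`, "", "label"),
                   vapply(ds$segments, `[[`, "", "label"))
})
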