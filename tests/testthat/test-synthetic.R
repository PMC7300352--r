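# Estimator-consistency checks use noise-reduced parameter sets (bursts and
# reversals change the net separation rate by construction, and heavy
# localization noise inflates transverse SDs); the default parameter set is
# exercised for its qualitative contracts further down.

test_that("a noise-free constant-speed pair is recovered exactly", {
  pars <- synth_track_params(cohesion_mean_min = 0, speed_um_min = 0.03,
                             burst_rate_per_min = 0, reversal_prob = 0,
                             axial_jitter_sd_um = 0, transverse_sd_um = 0,
                             loc_noise_sd_um = 0, drift_sd_um = 0,
                             intensity_cv = 0, duration_min = 40)
  out <- generate_track_pair(pars, seed = 1)
  res <- analyze_tracks(out$spots)
  expect_length(res$pairs, 1)
  tr <- suppressWarnings(res$pairs[[1]]$trend)
  expect_equal(tr$slope * 60, 0.03, tolerance = 1e-9)
  expect_equal(tr$r_squared, 1)
})

test_that("generation is deterministic and bookkeeping is per-pair", {
  pars <- synth_track_params(duration_min = 10)
  a <- generate_dataset(5, pars, seed = 3)
  b <- generate_dataset(5, pars, seed = 3)
  expect_identical(a$spots, b$spots)
  expect_identical(lapply(a$truth, `[[`, "sep_true"),
                   lapply(b$truth, `[[`, "sep_true"))
  expect_setequal(unique(a$spots$track), 1:10)
  expect_error(generate_dataset(0, pars), "n_pairs")
  c <- generate_dataset(5, pars, seed = 4)
  expect_false(identical(a$spots$x, c$spots$x))
  # byte-identical files for the same seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_spot_csv(a$spots, f1); write_spot_csv(b$spots, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a drift-only control shows no relative motion through the pipeline", {
  pars <- synth_track_params(speed_um_min = 0, cohesion_mean_min = 1e6,
                             burst_rate_per_min = 0, reversal_prob = 0,
                             axial_jitter_sd_um = 0, transverse_sd_um = 0,
                             loc_noise_sd_um = 1e-4, drift_sd_um = 0.2,
                             duration_min = 40)
  out <- generate_track_pair(pars, seed = 8)
  res <- suppressWarnings(analyze_tracks(out$spots))
  expect_length(res$pairs, 1)
  expect_lt(var(res$pairs[[1]]$series$x), 1e-6)
})

test_that("speed, cohesion duration and transverse SD are recovered at n = 200", {
  pars <- synth_track_params(speed_um_min = 0.03, cohesion_mean_min = 8,
                             burst_rate_per_min = 0, reversal_prob = 0,
                             transverse_sd_um = 0.06, loc_noise_sd_um = 0.02,
                             duration_min = 50)
  ds <- generate_dataset(200, pars, seed = 12)
  res <- suppressWarnings(analyze_tracks(ds$spots))
  expect_length(res$pairs, 200)
  est <- lapply(res$pairs, function(p)
    estimate_separation_speed(p$series$time_s, abs(p$series$x)))
  speeds <- vapply(est, `[[`, 0, "speed_um_min")
  expect_equal(mean(speeds), 0.03, tolerance = 0.10)
  # cohesion duration: onset of separation vs ground truth mean
  onsets <- vapply(est, `[[`, 0, "onset_s")
  truth_coh <- mean(vapply(ds$truth, `[[`, 0, "cohesion_frames")) * 10
  expect_equal(mean(onsets), truth_coh, tolerance = 0.15)
  # transverse SD: per-origin SD is sd(y-difference)/sqrt(2)
  ysd <- vapply(res$pairs, function(p) sd(p$series$y), 0) / sqrt(2)
  expect_equal(mean(ysd), 0.06, tolerance = 0.15)
})

test_that("default tracks show directed x motion and restricted y motion", {
  ds <- generate_dataset(40, synth_track_params(), seed = 5)
  res <- analyze_tracks(ds$spots)
  expect_gte(length(res$pairs), 35)  # nearly all pairs qualify
  # pooled mean x lag displacement grows ~linearly with lag
  lt <- linear_trend(res$lag_x$lag_s, res$lag_x$mean_disp)
  expect_gt(lt$r_squared, 0.95)
  expect_gt(lt$slope, 0)
  # y lag displacement plateaus below the pooled transverse spread
  p <- synth_track_params()
  y_cap <- sqrt(2) * sqrt(p$transverse_sd_um^2 + p$loc_noise_sd_um^2)
  expect_lt(max(res$lag_y$mean_disp), 2 * y_cap)
  expect_lt(mean(tail(res$lag_y$mean_disp, 3)) / mean(tail(res$lag_x$mean_disp, 3)),
            0.5)
})

test_that("merged-cohesion mode exercises the intensity pairing rule", {
  pars <- synth_track_params(merged_cohesion = TRUE, cohesion_mean_min = 5,
                             duration_min = 40)
  # several pairs so the per-movie median is dominated by single foci
  ds <- generate_dataset(6, pars, seed = 21)
  prs <- suppressWarnings(pair_origins(ds$spots))
  expect_gte(length(prs), 5)
  # at the split frame both rules may fire (the daughters start overlapped);
  # every pair must start at its ground-truth split frame either way
  starts <- vapply(prs, function(p) as.numeric(p$start_frame), 0)
  splits <- vapply(ds$truth, function(t) as.numeric(t$cohesion_frames), 0)
  expect_true(all(abs(sort(starts) - sort(splits)) <= 1))
})
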