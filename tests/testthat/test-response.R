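test_that("baseline normalization is exact, idempotent and guarded", {
  w <- flow_waveform(0:3, c(2, 2, 2, 4), baseline_window = c(0, 2.5))
  n1 <- normalize_to_baseline(w)
  expect_equal(n1$values, c(1, 1, 1, 2))
  expect_equal(normalize_to_baseline(n1)$values, n1$values)  # idempotent
  const <- flow_waveform(0:9, rep(3.7, 10), baseline_window = c(0, 4))
  expect_true(all(normalize_to_baseline(const)$values == 1))
  zero <- flow_waveform(0:9, rep(0, 10), baseline_window = c(0, 4))
  expect_error(normalize_to_baseline(zero), "baseline mean")
  one_sample <- flow_waveform(0:9, 1:10, baseline_window = c(0, 0.5))
  expect_error(normalize_to_baseline(one_sample), ">= 2")
})

test_that("presentation averaging is a pointwise mean with SE bookkeeping", {
  w1 <- flow_waveform(0:1, c(1, 2)); w2 <- flow_waveform(0:1, c(1, 0))
  avg <- average_presentations(list(w1, w2))
  expect_equal(avg$values, c(1, 1))
  expect_equal(avg$n_averaged, 2L)
  ident <- average_presentations(rep(list(w1), 10))
  expect_equal(ident$values, w1$values)
  expect_equal(ident$n_averaged, 10L)
  expect_error(average_presentations(list(w1, flow_waveform(c(0, 2), c(1, 1)))),
               "grids differ")
  # SD of the mean of n i.i.d.-noise waveforms shrinks as 1/sqrt(n)
  set.seed(6)
  sd_of_mean <- vapply(c(1, 4, 16), function(n) {
    reps <- replicate(400, {
      ws <- lapply(seq_len(n), function(i)
        flow_waveform(0:9, 1 + rnorm(10, 0, 0.1)))
      average_presentations(ws)$values[1]
    })
    sd(reps)
  }, 0)
  expect_equal(sd_of_mean[1] / sd_of_mean[2], 2, tolerance = 0.25)
  expect_equal(sd_of_mean[2] / sd_of_mean[3], 2, tolerance = 0.25)
})

test_that("per-class extraction isolates the responding class", {
  p <- make_protocol(n_repeats_per_frame = 16)
  resp <- hrf_design(0.25, 0.1)  # strong response for a small fixture
  sc <- make_scene(n_small = 20, n_medium = 4, n_large = 3, dim_px = c(48, 64),
                   responses = list(large = resp), seed = 17)
  tr <- simulate_trial_angiograms(p, sc, seed = 5)
  base <- Reduce(`+`, lapply(tr$angiograms[1:9], `[[`, "values")) / 9
  masks <- segment_vessels(angiogram_frame(base, scale = 4))
  wfs <- extract_class_response(tr$angiograms, masks, p)
  expect_length(wfs$large$values, 65L)
  expect_gt(max(wfs$large$values) - 1, 0.15)
  expect_lt(max(abs(wfs$small$values - 1)), 0.1)
  expect_lt(max(abs(wfs$medium$values - 1)), 0.1)
  # baseline mean is exactly 1 after normalization
  for (w in wfs) {
    inb <- w$times < baseline_window(p)[2]
    expect_equal(mean(w$values[inb]), 1, tolerance = 1e-12)
  }
  # global gain on all frames leaves the relative waveform unchanged
  frames2 <- lapply(tr$angiograms, function(f) {
    f$values <- f$values * 11; f
  })
  wfs2 <- extract_class_response(frames2, masks, p)
  expect_equal(wfs2$large$values, wfs$large$values)
})

test_that("waveform recovery error shrinks with presentation averaging", {
  p <- make_protocol(n_repeats_per_frame = 8)
  resp <- hrf_design(0.2, 0.08)
  sc <- make_scene(n_small = 12, n_medium = 2, n_large = 2, dim_px = c(40, 48),
                   responses = list(small = resp), seed = 23)
  truth <- 1 + ifelse(frame_times(p) >= 5,
                      hrf_eval(resp, pmax(frame_times(p) - 5, 0)), 0)
  rmse_for <- function(n_pres, seed0) {
    wfs <- lapply(seq_len(n_pres), function(i) {
      tr <- simulate_trial_angiograms(p, sc, seed = seed0 + i)
      base <- Reduce(`+`, lapply(tr$angiograms[1:9], `[[`, "values")) / 9
      masks <- segment_vessels(angiogram_frame(base, scale = 4))
      extract_class_response(tr$angiograms, masks, p)$small
    })
    avg <- average_presentations(wfs)
    sqrt(mean((avg$values - truth)^2))
  }
  expect_lt(rmse_for(8, 100), rmse_for(1, 200))
})

test_that("resampling is linear interpolation with span protection", {
  w <- flow_waveform(0:10, 2 * (0:10) + 1)
  same <- resample_to_grid(w, w$times)
  expect_equal(same$values, w$values)
  mid <- resample_to_grid(w, c(0.5, 3.25, 9.75))
  expect_equal(mid$values, 2 * c(0.5, 3.25, 9.75) + 1)  # exact on a ramp
  expect_error(resample_to_grid(w, c(-1, 5)), "outside")
  # 132-sample DCS grid onto the 65 frame centers
  p <- make_protocol()
  dcs <- simulate_dcs_waveform(p, hrf_design(0.03, 0.02), noise_sd = 0)
  on_frames <- resample_to_grid(dcs, frame_times(p))
  expect_length(on_frames$values, 65L)
  expect_equal(on_frames$modality, "DCS")
})
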