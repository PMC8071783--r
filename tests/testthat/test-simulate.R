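test_that("static scene with zero noise gives identical repeats", {
  sc <- tiny_scene(detector_noise_sd = 0)
  s <- simulate_bscan_series(sc, flow_levels = 0, repeats = 4, seed = 1)
  expect_equal(s$data[, , 1], s$data[, , 2])
  expect_equal(s$data[, , 1], s$data[, , 4])
  expect_true(all(compute_angiogram(s)$values == 0))
})

test_that("same seed gives bit-identical stacks, different seeds differ", {
  sc <- tiny_scene()
  s1 <- simulate_bscan_series(sc, repeats = 6, seed = 11)
  s2 <- simulate_bscan_series(sc, repeats = 6, seed = 11)
  s3 <- simulate_bscan_series(sc, repeats = 6, seed = 12)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, s3$data))
})

test_that("angiogram contrast is monotone in flow, inside the vessel only", {
  sc <- make_scene(n_small = 0, n_medium = 0, n_large = 1, dim_px = c(24, 24),
                   seed = 5)
  vessel <- (scene_truth_mask(sc) == 3)
  mean_in <- function(flow, seed) {
    s <- simulate_bscan_series(sc, flow_levels = flow, repeats = 1000,
                               seed = seed)
    a <- compute_angiogram(s)$values
    c(inside = mean(a[vessel]), outside = mean(a[!vessel]))
  }
  m1 <- mean_in(1, 21); m2 <- mean_in(2, 22)
  expect_gt(m2[["inside"]], m1[["inside"]] * 1.5)   # ~doubles with flow
  # parenchyma contrast is set by detector noise alone
  expect_equal(m2[["outside"]], m1[["outside"]], tolerance = 0.05)
  # documented mapping: E[angiogram] = (2/sqrt(pi)) * sqrt(sf^2 + sd^2)
  sf <- sc$flow_contrast_scale * 1 * 1   # large-vessel decorrelation = 1
  expected <- 2 / sqrt(pi) * sqrt(sf^2 + sc$detector_noise_sd^2)
  expect_equal(m1[["inside"]], expected, tolerance = 0.05)
})

test_that("simulate_trial returns protocol-shaped output with exact truth", {
  p <- make_protocol(n_repeats_per_frame = 4)
  resp <- hrf_design(0.05, 0.02)
  sc <- tiny_scene(responses = list(large = resp))
  tr <- simulate_trial(p, sc, seed = 2)
  expect_length(tr$series, 65L)
  expect_equal(dim(tr$series[[1]]$data)[3], 4L)
  # ground-truth flow attains its max at the argmax of the designed curve
  tg <- seq(0, 25, by = 1e-3)
  t_star <- tg[which.max(hrf_eval(resp, tg))] + p$stim_onset
  iv <- which(vapply(sc$vessels, `[[`, "", "class_truth") == "large")[1]
  fl <- tr$flows[, iv]
  expect_equal(tr$times[which.max(fl)], t_star, tolerance = 0.46)
  expect_equal(max(fl), 1 + 0.05, tolerance = 1e-3)
  # classes without a response stay at baseline
  is <- which(vapply(sc$vessels, `[[`, "", "class_truth") == "small")[1]
  expect_true(all(tr$flows[, is] == 1))
})

test_that("null response gives flat flow and flat extracted waveforms", {
  p <- make_protocol(n_repeats_per_frame = 8)
  sc <- tiny_scene()
  tr <- simulate_trial_angiograms(p, sc, seed = 4)
  expect_true(all(tr$flows == 1))
  base <- Reduce(`+`, lapply(tr$angiograms[1:9], `[[`, "values")) / 9
  masks <- segment_vessels(angiogram_frame(base, scale = sc$scale))
  wfs <- extract_class_response(tr$angiograms, masks, p)
  for (w in wfs) expect_lt(max(abs(w$values - 1)), 0.25)
})

test_that("DCS waveform matches its construction", {
  p <- make_protocol()
  expect_equal(length(simulate_dcs_waveform(p)$values), 132L)
  flat <- simulate_dcs_waveform(p, response = NULL, noise_sd = 0)
  expect_true(all(flat$values == 1))
  resp <- hrf_design(0.0337, 0.0304)
  clean <- simulate_dcs_waveform(p, resp, noise_sd = 0)
  expect_equal(max(clean$values), 1.0337, tolerance = 1e-4)
  expect_equal(min(clean$values), 1 - 0.0304, tolerance = 1e-4)
  s1 <- simulate_dcs_waveform(p, resp, noise_sd = 0.01, seed = 3)
  s2 <- simulate_dcs_waveform(p, resp, noise_sd = 0.01, seed = 3)
  expect_identical(s1$values, s2$values)
})

test_that("toy g2 model inverts by least squares", {
  g <- simulate_g2(2.5, beta = 0.5, tau_grid = c(0, 10^seq(-6, -2, length.out = 64)))
  expect_equal(g$g2[1], 1 + 0.5)                    # tau = 0 limit
  expect_equal(tail(g$g2, 1), 1, tolerance = 1e-3)  # decorrelation limit
  expect_equal(extract_flow_index(g), 2.5, tolerance = 1e-5)
  for (fi in c(0.3, 1, 7)) {
    expect_equal(extract_flow_index(simulate_g2(fi)), fi, tolerance = 1e-4)
  }
  flat <- data.frame(tau = g$tau, g2 = 1 + 0.5 * exp(2 * 1e4 * 0.1 * g$tau))
  expect_error(extract_flow_index(flat), "non-decaying")
})

test_that("flow levels validate", {
  sc <- tiny_scene()
  expect_error(simulate_bscan_series(sc, flow_levels = -1), ">= 0")
  expect_error(simulate_bscan_series(sc, flow_levels = c(capillary = 1)),
               "unknown vessel class")
  expect_error(simulate_bscan_series(sc, repeats = 1), ">= 2")
})
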