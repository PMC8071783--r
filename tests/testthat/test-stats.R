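test_that("pearson_r has the correlation identities", {
  p <- make_protocol()
  w1 <- simulate_dcs_waveform(p, hrf_design(0.03, 0.02), noise_sd = 0)
  expect_equal(pearson_r(w1, w1), 1)
  neg <- w1; neg$values <- 2 - w1$values       # reflect about baseline
  expect_equal(pearson_r(w1, neg), -1)
  aff <- w1; aff$values <- 3 * w1$values + 0.5 # positive affine rescale
  expect_equal(pearson_r(w1, aff), 1)
  expect_error(pearson_r(w1, flow_waveform(0:9, rep(1, 10))), "common time grid")
  flat <- w1; flat$values <- rep(1, length(w1$values))
  expect_error(pearson_r(w1, flat), "zero variance")
})

test_that("noise calibration realizes the target population correlation", {
  # brute-force verification of rho = 1/sqrt(1 + sigma^2/var(signal))
  p <- make_protocol()
  sig <- resample_to_grid(simulate_dcs_waveform(p, hrf_design(0.04, 0.03),
                                                noise_sd = 0),
                          frame_times(p))
  rho <- 0.68
  sigma <- calibrate_noise_for_r(sig, rho)
  expect_equal(sigma, sqrt(var(sig$values) * (1 / rho^2 - 1)))
  set.seed(31)
  rs <- replicate(1500, {
    noisy <- sig$values + rnorm(65, 0, sigma)
    cor(sig$values, noisy)
  })
  mc_se <- sd(rs) / sqrt(length(rs))
  # sample r is slightly biased low at n = 65; allow bias + 3 SE
  expect_lt(abs(mean(rs) - rho), 0.01 + 3 * mc_se)
})

test_that("interpolation-aware calibration corrects the variance shrink", {
  p <- make_protocol()
  dcs_t <- dcs_times(p)
  fr_t <- frame_times(p)
  sig <- resample_to_grid(simulate_dcs_waveform(p, hrf_design(0.04, 0.03),
                                                noise_sd = 0), fr_t)
  rho <- 0.68
  sigma <- calibrate_noise_for_r(sig, rho, noise_times = dcs_t,
                                 target_times = fr_t)
  expect_gt(sigma, calibrate_noise_for_r(sig, rho))  # inflated
  set.seed(77)
  rs <- replicate(1500, {
    noisy_fine <- stats::approx(dcs_t, rnorm(132, 0, sigma), xout = fr_t)$y
    cor(sig$values, sig$values + noisy_fine)
  })
  expect_lt(abs(mean(rs) - rho), 0.015 + 3 * sd(rs) / sqrt(length(rs)))
})

test_that("group aggregation matches hand arithmetic on a 3-animal fixture", {
  df <- data.frame(animal = rep(1:3, 2),
                   condition = rep(c("1", "3"), each = 3),
                   value = c(2, 4, 6, 3, 6, 9))
  g <- group_aggregate(df, reference = "1")
  expect_equal(g$mean, c(4, 6))
  expect_equal(g$sd, c(2, 3))
  expect_equal(g$n_animals, c(3L, 3L))
  # paired t-test against hand computation: diffs 1, 2, 3
  tt <- t.test(c(3, 6, 9), c(2, 4, 6), paired = TRUE)
  expect_equal(g$t_statistic[2], unname(tt$statistic))
  expect_equal(g$p_value[2], tt$p.value)
  # identical values across animals -> degenerate comparison is flagged
  same <- data.frame(animal = rep(1:3, 2), condition = rep(c("1", "3"), each = 3),
                     value = rep(5, 6))
  g2 <- group_aggregate(same)
  expect_true(g2$degenerate[2])
  expect_equal(g2$sd, c(0, 0))
})

test_that("t-test type-I error under the simulated null is nominal", {
  set.seed(19)
  n_sim <- 1000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    df <- data.frame(animal = rep(1:11, 2),
                     condition = rep(c("1", "3"), each = 11),
                     value = rnorm(22))
    g <- group_aggregate(df, paired = FALSE)
    rej[i] <- g$p_value[2] < 0.05
  }
  # binomial 3-sigma band around alpha = 0.05
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})
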