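test_that("trial normalization produces exact unit columns", {
  ep <- crp_epochs(cbind(c(3, 4), c(0, 2)), fs = 1, t1 = 0, t2 = 2)
  Vn <- normalize_trials(ep)
  expect_equal(Vn[, 1], c(0.6, 0.8))
  expect_equal(Vn[, 2], c(0, 1))
  # already-normalized input is unchanged; independent norm oracle
  set.seed(2)
  v <- rnorm(100); v <- v / sqrt(sum(v * v))
  Vn2 <- normalize_trials(matrix(v))
  expect_equal(Vn2[, 1], v, tolerance = 1e-12)
  expect_equal(sqrt(sum(Vn2[, 1]^2)), 1, tolerance = 1e-12)
  expect_error(normalize_trials(matrix(c(1, 0, 0, 0), 2, 2)), "zero norm")
})

test_that("cross-projection matrix follows the semi-normalized convention", {
  # identical trials [3,4] at 1 Hz: projection equals the trial norm
  ep <- crp_epochs(cbind(c(3, 4), c(3, 4)), fs = 1, t1 = 0, t2 = 2)
  pr <- cross_projection_matrix(ep, mode = "semi")
  expect_equal(pr$P[1, 2], 5)
  expect_equal(pr$P[2, 1], 5)
  expect_equal(pr$S, c(5, 5))

  # orthogonal trials project to zero in every mode
  ep0 <- crp_epochs(cbind(c(1, 0), c(0, 2)), fs = 4, t1 = 0, t2 = 0.5)
  for (m in c("semi", "full", "none")) {
    expect_equal(cross_projection_matrix(ep0, mode = m)$S, c(0, 0))
  }

  # K = 15 trials give K^2 - K = 210 off-diagonal projections
  ep15 <- snr3_session(seed = 5, K = 15)
  expect_length(cross_projection_matrix(ep15)$S, 210)

  # 1/fs scaling: semi-mode projections scale with the sample rate
  ep_fast <- crp_epochs(cbind(c(3, 4), c(3, 4)), fs = 10, t1 = 0, t2 = 0.2)
  expect_equal(cross_projection_matrix(ep_fast)$P[1, 2], 0.5)
})

test_that("the incremental profile equals brute-force recomputation per t2", {
  ep <- snr3_session(seed = 9, fs = 256, window = c(0, 1))
  for (m in c("semi", "full", "none")) {
    grid <- c(0.1, 0.25, 0.5, 0.9)
    prof <- projection_profile(ep, t2_grid = grid, mode = m)
    brute <- vapply(grid, function(t2) {
      cross_projection_matrix(ep, mode = m, t2 = t2)$S_mean
    }, numeric(1))
    expect_equal(prof$profile$s_mean, brute, tolerance = 1e-10)
  }
})

test_that("noiseless profiles plateau after the feature and match closed forms", {
  fs <- 1000
  ep <- make_session(synth_spec("square", amplitude = 100,
                                feature_duration = 0.1, fs = fs, K = 5,
                                window = c(0, 0.5)))
  prof <- response_duration(projection_profile(ep))
  s <- prof$profile$s_mean
  n_d <- round(0.1 * fs)
  i_d <- which(prof$n_grid == n_d)
  # strictly increasing up to the feature end, then exactly flat
  expect_true(all(diff(s[1:i_d]) > 0))
  expect_true(all(abs(s[i_d:length(s)] - s[i_d]) < 1e-10))
  # closed form at the peak: A * sqrt(n_d) / fs
  expect_equal(prof$peak_value, 100 * sqrt(n_d) / fs, tolerance = 1e-10)
  expect_equal(prof$tau_R, n_d / fs, tolerance = 1e-12)

  # constant offset: monotone growth, value A * sqrt(n) / fs at each window
  epc <- crp_epochs(matrix(7, 200, 4), fs = fs, t1 = 0, t2 = 0.2)
  profc <- projection_profile(epc)
  expect_true(all(diff(profc$profile$s_mean) > 0))
  expect_equal(profc$profile$s_mean, 7 * sqrt(profc$n_grid) / fs,
               tolerance = 1e-10)
})

test_that("splitting a noiseless feature in two preserves the peak value", {
  fs <- 1000
  one <- make_session(synth_spec("square", feature_duration = 0.1, fs = fs,
                                 K = 4, window = c(0, 0.5)))
  two <- make_session(synth_spec("double_square", feature_duration = 0.1,
                                 fs = fs, K = 4, window = c(0, 0.5)))
  p1 <- response_duration(projection_profile(one))
  p2 <- response_duration(projection_profile(two))
  expect_equal(p2$peak_value, p1$peak_value, tolerance = 1e-10)
  expect_gt(p2$tau_R, p1$tau_R)  # the split feature ends later
})

test_that("profiles are invariant to voltage mirroring and time reversal", {
  ep <- snr3_session(seed = 14, fs = 512, window = c(0, 0.5))
  prof <- response_duration(projection_profile(ep))
  neg <- ep; neg$data <- -neg$data
  prof_neg <- response_duration(projection_profile(neg))
  expect_equal(prof_neg$profile$s_mean, prof$profile$s_mean,
               tolerance = 1e-10)
  expect_equal(prof_neg$tau_R, prof$tau_R)

  # time reversal of noiseless identical trials: same peak and duration
  for (shp in c("ramp_up", "sine")) {
    fwd <- make_session(synth_spec(shp, feature_duration = 0.1, fs = 1000,
                                   K = 4, window = c(0, 0.4)))
    rev <- fwd; rev$data <- fwd$data[nrow(fwd$data):1, , drop = FALSE]
    pf <- suppressWarnings(response_duration(projection_profile(fwd)))
    pr <- suppressWarnings(response_duration(projection_profile(rev)))
    expect_equal(pr$peak_value, pf$peak_value, tolerance = 1e-10)
  }
})

test_that("semi-mode projections are scale-equivariant", {
  ep <- snr3_session(seed = 20, fs = 256, window = c(0, 0.5))
  c_ <- 3.7
  scaled <- ep; scaled$data <- c_ * scaled$data
  pr1 <- cross_projection_matrix(ep)
  pr2 <- cross_projection_matrix(scaled)
  expect_equal(pr2$P, c_ * pr1$P, tolerance = 1e-10)
  expect_equal(pr2$S_mean, c_ * pr1$S_mean, tolerance = 1e-10)
})

test_that("full normalization cannot resolve sustained structure", {
  # identical noiseless trials: fully-normalized profile is constant at 1
  ep <- make_session(synth_spec("square", feature_duration = 0.1, fs = 1000,
                                K = 4, window = c(0, 0.3)))
  prof <- projection_profile(ep, mode = "full")
  expect_true(all(abs(prof$profile$s_mean - 1) < 1e-12))
})

test_that("response duration picks the earliest peak with contiguous bounds", {
  # monotone increasing profile: boundary peak, flagged
  epc <- crp_epochs(matrix(2, 100, 3), fs = 100, t1 = 0, t2 = 1)
  expect_warning(prof <- response_duration(projection_profile(epc)),
                 "final grid point")
  expect_true(prof$boundary_peak)
  expect_equal(prof$tau_R, max(prof$profile$t2))

  # ties resolve to the earliest maximizer, bounds bracket tau_R
  ep <- make_session(synth_spec("square", feature_duration = 0.1, fs = 1000,
                                K = 4, window = c(0, 0.5)))
  prof <- response_duration(projection_profile(ep))
  expect_false(prof$boundary_peak)
  expect_equal(prof$tau_R, 0.1)
  expect_true(prof$tau_R_bounds[1] <= prof$tau_R)
  expect_true(prof$tau_R_bounds[2] >= prof$tau_R)
  s <- prof$profile$s_mean
  in_run <- prof$profile$t2 >= prof$tau_R_bounds[1] &
    prof$profile$t2 <= prof$tau_R_bounds[2]
  expect_true(all(s[in_run] >= 0.98 * prof$peak_value))
})

test_that("tau_R is robust to 2x grid decimation", {
  ep <- snr3_session(seed = 31, fs = 1024, window = c(0, 0.5))
  full <- response_duration(projection_profile(ep))
  every2 <- ep$t1 + seq(10, nrow(ep$data), by = 2) / ep$fs
  dec <- response_duration(projection_profile(ep, t2_grid = every2))
  expect_lt(abs(dec$tau_R - full$tau_R), 3 / ep$fs)
})

test_that("sub-minimum grid points are skipped with a warning", {
  ep <- snr3_session(seed = 8, fs = 256, window = c(0, 0.5))
  expect_warning(
    prof <- projection_profile(ep, t2_grid = c(0.005, 0.1, 0.2)),
    "skipped")
  expect_equal(nrow(prof$profile), 2L)
})
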