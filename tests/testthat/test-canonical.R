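test_that("kernel PCA recovers exact low-rank structure", {
  # identical trials: C is the common trial, unit-normalized
  v <- c(1, -2, 3, 0.5)
  V <- cbind(v, v, v)
  shape <- kernel_pca_first_component(V)
  expect_equal(shape$C, v / sqrt(sum(v^2)), tolerance = 1e-12)

  # rank-1 V = u w': C = +/- u, sign resolved by the mean-trace anchor
  set.seed(4)
  u <- rnorm(30); u <- u / sqrt(sum(u^2))
  w <- c(2, -1, 3, 0.5, 1)
  V1 <- u %o% w
  shape1 <- kernel_pca_first_component(V1)
  expected <- if (sum(u * rowMeans(V1)) >= 0) u else -u
  expect_equal(shape1$C, expected, tolerance = 1e-10)
})

test_that("the kernel trick matches the direct timepoint-eigendecomposition", {
  set.seed(77)
  for (i in 1:25) {
    T_ <- sample(4:64, 1); K <- sample(2:12, 1)
    V <- matrix(rnorm(T_ * K), T_, K)
    C <- kernel_pca_first_component(V)$C
    direct <- eigen(tcrossprod(V), symmetric = TRUE)$vectors[, 1]
    expect_equal(abs(sum(C * direct)), 1, tolerance = 1e-8)
    expect_equal(sqrt(sum(C^2)), 1, tolerance = 1e-10)
  }
})

test_that("shape extraction is deterministic and degenerate-safe", {
  V <- random_matrix(30, 5, seed = 12)
  s1 <- kernel_pca_first_component(V)
  s2 <- kernel_pca_first_component(V)
  expect_identical(s1$C, s2$C)
  expect_error(kernel_pca_first_component(matrix(0, 10, 3)), "Degenerate")
  expect_error(kernel_pca_first_component(matrix(c(1, NA), 2, 2)^0 * NA),
               "Non-finite")
  # eigenvalues descend and are non-negative
  expect_true(all(diff(s1$eigenvalues) <= 0))
  expect_true(all(s1$eigenvalues >= 0))
})

test_that("mean-trace shape agrees with kernel PCA for identical trials and fails on cancellation", {
  v <- c(0.5, 2, -1)
  V <- cbind(v, v, v, v)
  pca <- canonical_shape(V, method = "kernel_pca")
  mt <- canonical_shape(V, method = "mean_trace")
  expect_equal(mt$C, pca$C, tolerance = 1e-10)
  expect_equal(mt$method, "mean_trace")

  # {+v, -v}: the mean cancels but the principal direction survives
  V2 <- cbind(v, -v)
  expect_error(mean_trace_shape(V2), "identically zero")
  pca2 <- kernel_pca_first_component(V2)
  expect_equal(abs(sum(pca2$C * v / sqrt(sum(v^2)))), 1, tolerance = 1e-10)
})

test_that("mean-trace extraction underperforms kernel PCA on outlier sessions", {
  # sessions with one corrupted trial: the principal direction resists the
  # outlier while the mean absorbs it, giving lower average explained
  # variance and (by the same token) higher alpha' with lower SNR
  set.seed(55)
  ev_gap <- snr_gap <- aprime_gap <- numeric(10)
  for (r in 1:10) {
    ep <- snr3_session(seed = 100 + r, fs = 512, window = c(0, 0.5))
    ep$data[, 1] <- 40 * brown_noise(nrow(ep$data))  # one artifact trial
    prof <- suppressWarnings(response_duration(projection_profile(ep)))
    n_R <- prof$n_R
    Vt <- ep$data[seq_len(n_R), ]
    p_pca <- parameterize_trials(Vt, canonical_shape(Vt, "kernel_pca"))
    p_mt <- parameterize_trials(Vt, canonical_shape(Vt, "mean_trace"))
    good <- 2:ncol(Vt)
    ev_gap[r] <- mean(p_pca$explained_variance[good]) -
      mean(p_mt$explained_variance[good])
    snr_gap[r] <- mean(p_pca$snr[good]) - mean(p_mt$snr[good])
    aprime_gap[r] <- mean(p_mt$alpha_prime[good]) -
      mean(p_pca$alpha_prime[good])
  }
  expect_gt(mean(ev_gap), 0)
  expect_gt(mean(snr_gap), 0)
  expect_gt(mean(aprime_gap), 0)
})

test_that("extracting on an over-long window degrades explained variance", {
  # canonical shape estimated over [t1, 3 s] then truncated to the response
  # window explains less of the in-window variance than one extracted on the
  # response window directly; the 2.9 s of post-response noise corrupts the
  # long extraction. The effect needs the noise to carry comparable energy
  # to the response, so this uses a weak response (SNR 0.3).
  gaps <- numeric(8)
  n_R <- round(0.1 * 512)
  for (r in 1:8) {
    ep <- snr3_session(seed = 200 + r, snr = 0.3, fs = 512, window = c(0, 3))
    Vt <- ep$data[seq_len(n_R), ]
    direct <- canonical_shape(Vt)
    long <- canonical_shape(ep$data)
    long_trunc <- long
    long_trunc$C <- long$C[seq_len(n_R)]
    long_trunc$C <- long_trunc$C / sqrt(sum(long_trunc$C^2))
    ev_direct <- mean(parameterize_trials(Vt, direct)$explained_variance)
    ev_long <- mean(parameterize_trials(Vt, long_trunc)$explained_variance)
    gaps[r] <- ev_direct - ev_long
  }
  expect_true(all(gaps > 0))
})
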