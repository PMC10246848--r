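unit_vec <- function(n, seed) {
  set.seed(seed); v <- rnorm(n); v / sqrt(sum(v^2))
}

test_that("parameterization reproduces exact Pythagorean decompositions", {
  C <- unit_vec(50, 1)
  shape <- structure(list(C = C, method = "kernel_pca"), class = "crp_shape")

  # exact multiple of C
  p <- parameterize_trials(matrix(5 * C), shape)
  expect_equal(p$alpha, 5)
  expect_equal(p$noise, 0)
  expect_equal(p$explained_variance, 1)
  expect_equal(p$snr, Inf)

  # orthogonal trial
  r <- rnorm(50); r <- r - sum(r * C) * C
  p0 <- parameterize_trials(matrix(r), shape)
  expect_equal(p0$alpha, 0, tolerance = 1e-12)
  expect_equal(p0$explained_variance, 0, tolerance = 1e-12)

  # 3C + r with |r| = 4: alpha 3, noise 4, snr 0.75, EV 9/25
  r4 <- 4 * r / sqrt(sum(r^2))
  p34 <- parameterize_trials(matrix(3 * C + r4), shape)
  expect_equal(p34$alpha, 3, tolerance = 1e-12)
  expect_equal(p34$noise, 4, tolerance = 1e-12)
  expect_equal(p34$snr, 0.75, tolerance = 1e-12)
  expect_equal(p34$explained_variance, 9 / 25, tolerance = 1e-12)
  expect_equal(p34$alpha_prime, 3 / sqrt(50), tolerance = 1e-12)
})

test_that("reconstruction, orthogonality and the EV identity hold on random data", {
  for (seed in 1:5) {
    V <- random_matrix(60, 7, seed = seed)
    shape <- kernel_pca_first_component(V)
    p <- parameterize_trials(V, shape)
    eps <- residual_matrix(p)
    recon <- shape$C %o% p$alpha + eps
    expect_equal(recon, V, tolerance = 1e-10)
    expect_true(all(abs(crossprod(shape$C, eps)) < 1e-10))
    expect_true(all(p$explained_variance >= -1e-12 &
                    p$explained_variance <= 1 + 1e-12))
    expect_equal(p$explained_variance, p$snr^2 / (1 + p$snr^2),
                 tolerance = 1e-12)
  }
})

test_that("alpha' recovers injected per-trial amplitudes exactly without noise", {
  set.seed(6)
  spec <- synth_spec("sine", feature_duration = 0.12, fs = 500,
                     window = c(0, 0.3))
  sig <- make_signal(spec)
  a_k <- c(0.5, 1, 2, 3.5, 5, 8)
  V <- vapply(a_k, function(a) a * sig, numeric(length(sig)))
  shape <- kernel_pca_first_component(V)
  p <- parameterize_trials(V, shape)
  expect_equal(cor(p$alpha_prime, a_k)^2, 1, tolerance = 1e-10)
  expect_true(all(p$explained_variance > 1 - 1e-12))
})

test_that("all-zero trials are flagged instead of propagating NaN", {
  C <- unit_vec(20, 2)
  shape <- structure(list(C = C, method = "kernel_pca"), class = "crp_shape")
  V <- cbind(2 * C, 0 * C)
  p <- parameterize_trials(V, shape)
  expect_true(p$zero_trial[2])
  expect_equal(p$explained_variance[2], 0)
  expect_false(any(is.na(p$explained_variance)))
})

test_that("parameterization significance behaves at its edge cases", {
  C <- unit_vec(30, 3)
  shape <- structure(list(C = C, method = "kernel_pca"), class = "crp_shape")
  # matched +/- pairs: t exactly 0, p exactly 1
  a <- c(1.5, -1.5, 0.7, -0.7)
  V <- C %o% a
  sig <- parameterization_significance(parameterize_trials(V, shape))
  expect_equal(sig$t_value, 0)
  expect_equal(sig$p_value, 1)

  # identical alphas: degenerate, p reported as exactly 0
  Vd <- C %o% rep(2, 5)
  sigd <- parameterization_significance(parameterize_trials(Vd, shape))
  expect_true(sigd$degenerate)
  expect_identical(sigd$p_value, 0)

  # strong response: overwhelming significance
  ep <- snr3_session(seed = 17)
  res <- run_crp(ep)
  expect_lt(res$parameterization$p_value, 1e-4)
})

test_that("the alpha t-test wrapper is calibrated on Gaussian nulls", {
  set.seed(91)
  C <- unit_vec(25, 4)
  shape <- structure(list(C = C, method = "kernel_pca"), class = "crp_shape")
  ps <- vapply(1:400, function(i) {
    V <- matrix(rnorm(25 * 10), 25, 10)
    parameterization_significance(parameterize_trials(V, shape))$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("residual re-parameterization exposes perturbation structure", {
  ep <- snr3_session(seed = 23, fs = 512, window = c(0, 0.5))
  base <- run_crp(ep)
  C <- base$shape$C
  T_R <- length(C)

  # new trials that are pure multiples of the original shape leave nothing
  new_same <- crp_epochs(C %o% seq(2, 20, length.out = 8), fs = 512,
                         t1 = 0, t2 = T_R / 512)
  rp <- reparameterize_residuals(new_same, base$shape)
  expect_lt(max(abs(rp$residual_epochs$data)), 1e-10)

  # planted orthogonal structure D is recovered by a second extraction pass
  set.seed(8)
  D <- rnorm(T_R); D <- D - sum(D * C) * C; D <- D / sqrt(sum(D^2))
  a <- runif(8, 2, 4); b <- runif(8, 3, 6)
  new_mix <- crp_epochs(C %o% a + D %o% b, fs = 512, t1 = 0,
                        t2 = T_R / 512)
  rp2 <- reparameterize_residuals(new_mix, base$shape)
  shape2 <- kernel_pca_first_component(rp2$residual_epochs$data)
  expect_equal(abs(sum(shape2$C * D)), 1, tolerance = 1e-8)

  # window mismatch errors
  short <- crp_epochs(matrix(rnorm(10 * 4), 10, 4), fs = 512, t1 = 0,
                      t2 = 10 / 512)
  expect_error(reparameterize_residuals(short, base$shape), "shorter")
})
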