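#' Parameterize single trials against the canonical shape
#'
#' Expresses each trial as `V_k(t) = alpha_k * C(t) + eps_k(t)`. Because `C`
#' has unit norm, the projection weight is `alpha_k = sum_t C(t) V_k(t)` and
#' the residual `eps_k = V_k - alpha_k C` is exactly orthogonal to `C` by
#' construction. Per trial this yields:
#'
#' * `alpha`: projection weight (uV times a sample-count scale);
#' * `alpha_prime`: `alpha / sqrt(T_R)`, in intuitive microvolt units,
#'   comparable to a root-mean-squared response amplitude over the
#'   significant interval;
#' * `noise`: residual magnitude `sqrt(eps' eps)`;
#' * `snr`: `alpha / noise` (dimensionless; `+Inf` when `noise` is 0 and
#'   `alpha > 0`);
#' * `explained_variance`: `1 - eps' eps / V_k' V_k`, equal to
#'   `snr^2 / (1 + snr^2)`.
#'
#' @param V_trunc Numeric `T_R x K` matrix (or [crp_epochs]) over
#'   `[t1, tau_R)`. A longer epoch matrix is truncated to `length(C)`.
#' @param shape A `crp_shape` from [canonical_shape()].
#' @return A tibble of class `crp_params` with columns `trial`, `alpha`,
#'   `alpha_prime`, `noise`, `snr`, `explained_variance`, `zero_trial`
#'   (flag for all-zero trials, whose explained variance is reported as 0).
#'   The residual matrix is attached as attribute `residuals`, and the shape
#'   as attribute `shape`.
#' @export
parameterize_trials <- function(V_trunc, shape) {
  stopifnot(inherits(shape, "crp_shape"))
  ep <- NULL
  if (inherits(V_trunc, "crp_epochs")) {
    ep <- V_trunc
    V_trunc <- V_trunc$data
  }
  V <- epoch_data(V_trunc)
  T_R <- length(shape$C)
  if (nrow(V) > T_R) V <- V[seq_len(T_R), , drop = FALSE]
  if (nrow(V) != T_R) {
    abort(sprintf("Trial matrix has %d samples but the shape has %d.",
                  nrow(V), T_R))
  }
  C <- shape$C
  alpha <- as.vector(crossprod(C, V))
  eps <- V - C %o% alpha
  ss_eps <- colSums(eps^2)
  ss_v <- colSums(V^2)
  zero_trial <- ss_v == 0
  noise <- sqrt(ss_eps)
  snr <- ifelse(noise > 0, alpha / noise,
                ifelse(alpha > 0, Inf, ifelse(alpha < 0, -Inf, NaN)))
  ev <- ifelse(zero_trial, 0, 1 - ss_eps / ss_v)
  out <- tibble::tibble(
    trial = seq_len(ncol(V)),
    alpha = alpha,
    alpha_prime = alpha / sqrt(T_R),
    noise = noise,
    snr = snr,
    explained_variance = ev,
    zero_trial = zero_trial)
  attr(out, "residuals") <- eps
  attr(out, "shape") <- shape
  attr(out, "fs") <- if (!is.null(ep)) ep$fs else NULL
  attr(out, "t1") <- if (!is.null(ep)) ep$t1 else NULL
  class(out) <- c("crp_params", class(out))
  out
}

#' Residual matrix of a trial parameterization
#'
#' @param params A `crp_params` tibble from [parameterize_trials()].
#' @return The `T_R x K` residual matrix `eps` in microvolts.
#' @export
residual_matrix <- function(params) {
  stopifnot(inherits(params, "crp_params"))
  attr(params, "residuals")
}

#' Parameterization significance
#'
#' One-sample two-sided t-test of the per-trial projection weights
#' `alpha_k` against zero (`K - 1` degrees of freedom). For spurious
#' structure the weights scatter around zero; a reproducible response pulls
#' them away from it.
#'
#' @param params A `crp_params` tibble (K >= 3 trials).
#' @return A list with `t_value`, `p_value`, `df`, `n_values`, `mean`
#'   (mean alpha), `method = "parameterization"` and `degenerate` (`TRUE`
#'   when the alphas have zero variance, in which case `p_value` is reported
#'   as exactly 0).
#' @export
parameterization_significance <- function(params) {
  stopifnot(inherits(params, "crp_params"))
  a <- params$alpha
  if (length(a) < 3L) abort("Parameterization significance needs K >= 3 trials.")
  ttest_vs_zero(a, method = "parameterization")
}

# Shared one-sample t-test against zero with the degenerate zero-variance
# convention (identical nonzero values are unambiguously significant).
# Near-constant samples (spread at floating-point noise level relative to
# the mean) are treated the same way rather than erroring.
ttest_vs_zero <- function(x, method) {
  n <- length(x)
  if (sd(x) == 0 || sd(x) / sqrt(n) < 10 * .Machine$double.eps * abs(mean(x))) {
    return(list(t_value = if (mean(x) == 0) 0 else Inf * sign(mean(x)),
                p_value = if (mean(x) == 0) 1 else 0,
                df = n - 1L, n_values = n, mean = mean(x),
                method = method, degenerate = TRUE))
  }
  tt <- t.test(x, mu = 0, alternative = "two.sided")
  list(t_value = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n_values = n, mean = mean(x),
       method = method, degenerate = FALSE)
}

#' Re-parameterize new trials against a previously extracted shape
#'
#' For perturbation designs (drug, sleep state, therapeutic stimulation, ...)
#' a new session's trials are parameterized against the *original* canonical
#' shape; the residual matrix then feeds a fresh extraction pass, where any
#' significant structure reveals the response component introduced by the
#' perturbation.
#'
#' @param new_epochs A [crp_epochs] object covering at least the original
#'   shape's window `[t1, tau_R)`; longer epochs are truncated.
#' @param original_shape The `crp_shape` extracted from the baseline
#'   session.
#' @return A list with `params` (a `crp_params` tibble against the original
#'   shape) and `residual_epochs` (a [crp_epochs] of the residuals, ready
#'   for a fresh [run_crp()] pass).
#' @export
reparameterize_residuals <- function(new_epochs, original_shape) {
  stopifnot(inherits(new_epochs, "crp_epochs"),
            inherits(original_shape, "crp_shape"))
  T_R <- length(original_shape$C)
  if (nrow(new_epochs$data) < T_R) {
    abort("New epochs are shorter than the original shape window and cannot be truncated to match.")
  }
  trunc <- truncate_epochs(new_epochs, T_R)
  params <- parameterize_trials(trunc, original_shape)
  res_ep <- crp_epochs(residual_matrix(params), fs = trunc$fs,
                       t1 = trunc$t1, t2 = trunc$t2,
                       stim_times = trunc$stim_times,
                       channel = trunc$channel, stim_site = trunc$stim_site)
  list(params = params, residual_epochs = res_ep)
}

#' Write the per-trial parameter table as delimited text
#'
#' @param params A `crp_params` tibble.
#' @param path File path.
#' @param artifact_flags Optional logical vector marking rejected/artifact
#'   trials; defaults to all `FALSE`.
#' @export
write_params <- function(params, path, artifact_flags = NULL) {
  stopifnot(inherits(params, "crp_params"))
  flags <- artifact_flags %||% rep(FALSE, nrow(params))
  df <- data.frame(
    trial = params$trial,
    alpha = sprintf("%.10g", params$alpha),
    alpha_prime_uV = sprintf("%.10g", params$alpha_prime),
    noise = sprintf("%.10g", params$noise),
    snr = sprintf("%.10g", params$snr),
    explained_variance = sprintf("%.10g", params$explained_variance),
    artifact_flag = flags)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
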