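#' Balanced half-selection of cross-projection pairs
#'
#' The full cross-projection set counts every unordered trial pair twice
#' (once per normalization direction), which inflates a test against zero.
#' Inference therefore uses exactly one orientation per unordered pair,
#' chosen so each trial serves as the normalized member as close to half the
#' time as possible. The orientation is a deterministic circular tournament:
#' pair `(k, l)` is taken with `k` normalized iff
#' `((l - k) mod K) <= floor((K - 1) / 2)`; for even `K` the leftover
#' diametral pairs are split alternately. No randomness is involved.
#'
#' @param K Number of trials (>= 2).
#' @return A tibble of class `crp_selection` with columns `norm_trial` and
#'   `raw_trial`, one row per unordered pair (`(K^2 - K) / 2` rows), and
#'   attribute `K`.
#' @export
#' @examples
#' balanced_half_selection(4)
balanced_half_selection <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 2L || K != round(K)) {
    abort("`K` must be a single integer >= 2.")
  }
  K <- as.integer(K)
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  k <- pairs[, "row"]; l <- pairs[, "col"]
  half <- (K - 1L) %/% 2L
  d <- (l - k) %% K
  forward <- d <= half            # k is the normalized trial
  if (K %% 2L == 0L) {
    diam <- d == K %/% 2L         # diametral pairs, split alternately
    forward[diam] <- (k[diam] %% 2L) == 1L
  }
  out <- tibble::tibble(
    norm_trial = ifelse(forward, k, l),
    raw_trial = ifelse(forward, l, k))
  attr(out, "K") <- K
  class(out) <- c("crp_selection", class(out))
  out
}

# Values of P picked out by a selection.
selected_projections <- function(projections, selection) {
  stopifnot(inherits(projections, "crp_projections"),
            inherits(selection, "crp_selection"))
  if (attr(selection, "K") != projections$K) {
    abort("Selection and projection set disagree on the number of trials.")
  }
  projections$P[cbind(selection$norm_trial, selection$raw_trial)]
}

#' Extraction significance
#'
#' Tests whether a reproducible response structure exists at all: a
#' one-sample two-sided t-test of the balanced half-selection of
#' cross-projection values (computed at the response duration, or at a
#' stated window end) against zero.
#'
#' @param projections A `crp_projections` object, typically computed at
#'   `tau_R`.
#' @param selection Optional `crp_selection`; defaults to
#'   [balanced_half_selection()] for the matching `K`.
#' @return A list with `t_value`, `p_value`, `df`, `n_values`
#'   (`(K^2 - K) / 2`), `mean` (mean selected projection, uV.s for the
#'   semi-normalized mode), `method = "extraction"` and `degenerate`.
#' @export
extraction_significance <- function(projections, selection = NULL) {
  stopifnot(inherits(projections, "crp_projections"))
  selection <- selection %||% balanced_half_selection(projections$K)
  vals <- selected_projections(projections, selection)
  ttest_vs_zero(vals, method = "extraction")
}

#' Null-model calibration of extraction significance
#'
#' Runs the full pipeline (profile over the window-end grid, response
#' duration, extraction significance) on many surrogate sessions of pure
#' noise, and summarizes the resulting p-value distribution. For a
#' calibrated statistic the p-values are uniform on (0, 1).
#'
#' The extraction test can be scored at two window ends. `at = "full"`
#' (default) tests the projections over the full surrogate window; there
#' the half-selection t-test is calibrated and null p-values are uniform.
#' `at = "tau_R"` tests at the per-set response duration; because `tau_R`
#' maximizes the very mean being tested, this inherits a winner's-curse
#' bias and is anti-conservative on pure noise — it is provided for
#' studying that bias, not for calibration claims. Both p-value vectors are
#' returned; the summary statistics refer to the `at` choice.
#'
#' @param n_sets Number of surrogate sessions (>= 100).
#' @param K Trials per session (default 10).
#' @param n_samples Timepoints per trial (default 2048).
#' @param fs Sample rate in Hz (default 2048).
#' @param noise `"brown"` (random-walk surrogates) or `"white"`.
#' @param seed Integer seed; the p-value list is reproducible given it.
#' @param mode Projection normalization mode, default `"semi"`.
#' @param at Window end at which the extraction test is scored; see above.
#' @param min_samples Minimum profile window, see [projection_profile()].
#' @return An object of class `crp_calibration`: list with `p_values` (at
#'   the `at` window), `p_values_tau_R`, `p_values_full`, `tau_R` (per-set
#'   durations), `ks_statistic`, `ks_p_value` (vs uniform(0,1)),
#'   `frac_below_05`, and the generating settings.
#' @export
null_calibration <- function(n_sets, K = 10, n_samples = 2048, fs = 2048,
                             noise = c("brown", "white"), seed = NULL,
                             mode = "semi", at = c("full", "tau_R"),
                             min_samples = 10L) {
  noise <- match.arg(noise)
  at <- match.arg(at)
  if (n_sets < 100) abort("Use at least 100 surrogate sets for calibration.")
  if (!is.null(seed)) set.seed(seed)
  gen <- if (noise == "brown") brown_noise else white_noise
  sel <- balanced_half_selection(K)
  res <- vapply(seq_len(n_sets), function(i) {
    V <- vapply(seq_len(K), function(j) gen(n_samples), numeric(n_samples))
    ep <- crp_epochs(V, fs = fs, t1 = 0, t2 = n_samples / fs)
    prof <- suppressWarnings(
      response_duration(projection_profile(ep, mode = mode,
                                           min_samples = min_samples)))
    pr_tau <- cross_projection_matrix(ep, mode = mode, t2 = prof$tau_R)
    pr_full <- cross_projection_matrix(ep, mode = mode)
    c(tau_R = prof$tau_R,
      p_tau = extraction_significance(pr_tau, sel)$p_value,
      p_full = extraction_significance(pr_full, sel)$p_value)
  }, numeric(3))
  p_values <- if (at == "full") res["p_full", ] else res["p_tau", ]
  ks <- suppressWarnings(ks.test(p_values, "punif"))
  structure(
    list(p_values = unname(p_values),
         p_values_tau_R = unname(res["p_tau", ]),
         p_values_full = unname(res["p_full", ]),
         tau_R = unname(res["tau_R", ]),
         ks_statistic = unname(ks$statistic),
         ks_p_value = ks$p.value,
         frac_below_05 = mean(p_values < 0.05),
         n_sets = n_sets, K = K, n_samples = n_samples, fs = fs,
         noise = noise, mode = mode, at = at, seed = seed),
    class = "crp_calibration")
}

#' @export
print.crp_calibration <- function(x, ...) {
  cat(sprintf(
    "<crp_calibration> %d %s-noise sessions (K=%d, T=%d), scored at %s window\n  KS vs uniform: D=%.4f, p=%.3g; fraction p<0.05: %.4f\n",
    x$n_sets, x$noise, x$K, x$n_samples, x$at, x$ks_statistic, x$ks_p_value,
    x$frac_below_05))
  invisible(x)
}

#' @method tidy crp_calibration
#' @export
tidy.crp_calibration <- function(x, ...) {
  tibble::tibble(set = seq_along(x$p_values), p_value = x$p_values)
}

#' @method glance crp_calibration
#' @export
glance.crp_calibration <- function(x, ...) {
  tibble::tibble(n_sets = x$n_sets, noise = x$noise, K = x$K, at = x$at,
                 ks_statistic = x$ks_statistic, ks_p_value = x$ks_p_value,
                 frac_below_05 = x$frac_below_05)
}
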