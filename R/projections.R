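#' Unit-normalize each trial
#'
#' Returns the matrix of unit-L2-norm trial columns used on the "normalized"
#' side of the semi-normalized cross-projection.
#'
#' @param epochs A [crp_epochs] object or a numeric timepoints-by-trials
#'   matrix.
#' @return Numeric matrix of the same shape with every column of L2 norm 1.
#' @export
normalize_trials <- function(epochs) {
  V <- epoch_data(epochs)
  nrm <- sqrt(colSums(V^2))
  if (any(nrm == 0)) {
    abort(sprintf("Trial(s) %s have zero norm and cannot be normalized.",
                  paste(which(nrm == 0), collapse = ", ")))
  }
  sweep(V, 2L, nrm, `/`)
}

epoch_data <- function(x) {
  if (inherits(x, "crp_epochs")) x$data else {
    m <- as.matrix(x); storage.mode(m) <- "double"; m
  }
}

#' Single-trial cross-projection matrix
#'
#' Projects every trial into every other. With the default semi-normalized
#' mode, entry `P[k, l]` is the inner product of unit-normalized trial `k`
#' with raw trial `l`, scaled by `1/fs` so it carries units of uV.s. The
#' matrix is asymmetric: `P[k, l] != P[l, k]` in general. The off-diagonal
#' values (self-projections omitted, `K^2 - K` of them) form the set `S`
#' whose mean summarizes the stimulation-response interaction.
#'
#' @param epochs A [crp_epochs] object (a plain matrix is accepted if
#'   `fs` is supplied).
#' @param mode Normalization: `"semi"` (one trial normalized, `1/fs`
#'   scaling, uV.s — the recommended balance of amplitude and sustained
#'   structure), `"full"` (both trials normalized, dimensionless, no `1/fs`),
#'   or `"none"` (neither normalized, `1/fs` scaling).
#' @param t2 Optional window end (seconds from stimulus) at which to
#'   truncate before projecting; defaults to the full epoch.
#' @param fs Sample rate, only needed when `epochs` is a bare matrix.
#' @return An object of class `crp_projections`: list with `P` (K x K
#'   matrix), `S` (off-diagonal values), `S_mean`, `mode`, `window_end`,
#'   `fs`, `K`.
#' @export
#' @examples
#' ep <- crp_epochs(cbind(c(3, 4), c(3, 4)), fs = 1, t1 = 0, t2 = 2)
#' cross_projection_matrix(ep)$P
cross_projection_matrix <- function(epochs, mode = c("semi", "full", "none"),
                                    t2 = NULL, fs = NULL) {
  mode <- match.arg(mode)
  if (!inherits(epochs, "crp_epochs")) {
    if (is.null(fs)) abort("Supply `fs` when `epochs` is a bare matrix.")
    epochs <- crp_epochs(epochs, fs = fs, t1 = 0,
                         t2 = nrow(as.matrix(epochs)) / fs)
  }
  if (!is.null(t2)) {
    n_keep <- round((t2 - epochs$t1) * epochs$fs)
    if (n_keep < 1L || n_keep > nrow(epochs$data)) {
      abort("`t2` must lie inside the epoch window.")
    }
    epochs <- truncate_epochs(epochs, n_keep)
  }
  V <- epochs$data
  K <- ncol(V)
  if (K < 2L) abort("Projection analysis needs at least 2 trials.")
  P <- switch(mode,
    semi = crossprod(normalize_trials(V), V) / epochs$fs,
    full = crossprod(normalize_trials(V)),
    none = crossprod(V) / epochs$fs)
  dimnames(P) <- NULL
  off <- row(P) != col(P)
  structure(
    list(P = P, S = P[off], S_mean = mean(P[off]), mode = mode,
         window_end = epochs$t2, fs = epochs$fs, K = K),
    class = "crp_projections")
}

#' @export
print.crp_projections <- function(x, ...) {
  cat(sprintf(
    "<crp_projections> K=%d trials, mode=%s, window end %g s\n  |S|=%d, S_mean=%.4g %s\n",
    x$K, x$mode, x$window_end, length(x$S), x$S_mean,
    if (x$mode == "full") "(dimensionless)" else "uV.s"))
  invisible(x)
}

# Vectorized cumulative profile core. Returns the mean off-diagonal
# cross-projection for every prefix length 1..T, one value per sample.
# Cost O(T K^2) via per-pair cumulative inner products.
profile_core <- function(V, fs, mode) {
  T_ <- nrow(V); K <- ncol(V)
  ks <- rep(seq_len(K), times = K)   # normalized-side trial of each pair
  ls <- rep(seq_len(K), each = K)    # raw-side trial
  W <- V[, ks, drop = FALSE] * V[, ls, drop = FALSE]
  cumW <- apply(W, 2L, cumsum)
  if (T_ == 1L) cumW <- matrix(cumW, nrow = 1L)
  diag_cols <- which(ks == ls)
  norms2 <- cumW[, diag_cols, drop = FALSE]  # cumulative |V_k|^2, col k
  off <- which(ks != ls)
  num <- cumW[, off, drop = FALSE]
  s_bar <- switch(mode,
    semi = rowSums(num / sqrt(norms2[, ks[off], drop = FALSE])) /
      (length(off) * fs),
    full = rowSums(num / (sqrt(norms2[, ks[off], drop = FALSE]) *
                          sqrt(norms2[, ls[off], drop = FALSE]))) /
      length(off),
    none = rowSums(num) / (length(off) * fs))
  s_bar
}

#' Time-resolved cross-projection profile
#'
#' Recomputes the mean cross-projection `S_mean` with the window end `t2`
#' swept over a grid, yielding the temporal profile whose peak marks the
#' response duration. The computation is incremental (cumulative inner
#' products, total cost `O(T K^2)`), not a fresh projection per grid point.
#'
#' @inheritParams cross_projection_matrix
#' @param t2_grid Candidate window ends in seconds, sorted ascending.
#'   `NULL` (default) evaluates every sample from 10 samples after `t1` to
#'   the full epoch end; grid points shorter than `min_samples` are skipped
#'   with a warning.
#' @param min_samples Minimum number of samples in a window (default 10),
#'   guarding against degenerate near-single-sample normalizations.
#' @return An object of class `crp_profile`: list with `profile` (tibble of
#'   `t2` and `s_mean`), `mode`, `fs`, `t1`. [response_duration()] completes
#'   it with `tau_R` and its bounds.
#' @seealso [response_duration()], [autoplot.crp_profile()]
#' @export
projection_profile <- function(epochs, t2_grid = NULL,
                               mode = c("semi", "full", "none"),
                               min_samples = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(epochs, "crp_epochs"))
  V <- epochs$data
  if (ncol(V) < 2L) abort("Projection analysis needs at least 2 trials.")
  T_ <- nrow(V)
  if (T_ < min_samples) abort("Epoch shorter than `min_samples`.")
  if (is.null(t2_grid)) {
    n_grid <- seq.int(min_samples, T_)
  } else {
    if (is.unsorted(t2_grid, strictly = TRUE)) {
      abort("`t2_grid` must be strictly ascending.")
    }
    n_grid <- round((t2_grid - epochs$t1) * epochs$fs)
    bad <- n_grid < min_samples | n_grid > T_
    if (any(n_grid > T_)) abort("`t2_grid` extends past the epoch window.")
    if (any(bad)) {
      warn(sprintf("%d grid point(s) below the %d-sample minimum window were skipped.",
                   sum(bad), min_samples))
      n_grid <- n_grid[!bad]
    }
    if (length(n_grid) == 0L) abort("No usable grid points remain.")
  }
  s_all <- profile_core(V, epochs$fs, mode)
  structure(
    list(profile = tibble::tibble(t2 = epochs$t1 + n_grid / epochs$fs,
                                  s_mean = s_all[n_grid]),
         n_grid = n_grid, mode = mode, fs = epochs$fs, t1 = epochs$t1,
         tau_R = NULL),
    class = "crp_profile")
}

#' Response duration from the profile peak
#'
#' The response duration `tau_R` is the earliest window end at which the
#' cross-projection profile attains its maximum: past it, additional samples
#' no longer add reliably shared structure. Uncertainty bounds delimit the
#' contiguous run of grid points around the peak where the profile exceeds
#' 98% of its peak value. A peak on the final grid point is flagged
#' (`boundary_peak`) since the true duration may exceed the analysis window.
#'
#' @param profile A `crp_profile` from [projection_profile()].
#' @param bound_frac Fraction of the peak defining the uncertainty run
#'   (default 0.98).
#' @return The profile object completed with `tau_R`, `tau_R_bounds`,
#'   `peak_value`, `n_R` (samples in `[t1, tau_R)`) and `boundary_peak`.
#' @export
response_duration <- function(profile, bound_frac = 0.98) {
  stopifnot(inherits(profile, "crp_profile"))
  s <- profile$profile$s_mean
  if (all(is.na(s))) abort("Profile is entirely NA.")
  i_peak <- which.max(s)  # earliest maximizer on ties
  peak <- s[i_peak]
  ok <- s >= bound_frac * peak
  if (peak < 0) ok <- s >= peak / bound_frac  # keep the rule contiguous-safe
  run <- ok
  # contiguous run containing the peak
  lo <- i_peak
  while (lo > 1L && run[lo - 1L]) lo <- lo - 1L
  hi <- i_peak
  while (hi < length(run) && run[hi + 1L]) hi <- hi + 1L
  t2s <- profile$profile$t2
  profile$tau_R <- t2s[i_peak]
  profile$tau_R_bounds <- c(t2s[lo], t2s[hi])
  profile$peak_value <- peak
  profile$n_R <- profile$n_grid[i_peak]
  profile$boundary_peak <- i_peak == length(s)
  if (profile$boundary_peak) {
    warn("Profile peak lies on the final grid point; the response may outlast the analysis window.")
  }
  profile
}

#' @export
print.crp_profile <- function(x, ...) {
  cat(sprintf("<crp_profile> mode=%s, %d grid points over [%g, %g] s\n",
              x$mode, nrow(x$profile), min(x$profile$t2), max(x$profile$t2)))
  if (!is.null(x$tau_R)) {
    cat(sprintf("  tau_R = %g s (98%% bounds %g..%g s), peak S_mean = %.4g%s\n",
                x$tau_R, x$tau_R_bounds[1], x$tau_R_bounds[2], x$peak_value,
                if (isTRUE(x$boundary_peak)) " [boundary peak]" else ""))
  }
  invisible(x)
}

#' @describeIn projection_profile Tibble of the profile (`t2`, `s_mean`).
#' @param x A `crp_profile` object.
#' @param ... Unused.
#' @method tidy crp_profile
#' @export
tidy.crp_profile <- function(x, ...) x$profile

#' @method glance crp_profile
#' @export
glance.crp_profile <- function(x, ...) {
  tibble::tibble(
    tau_R = x$tau_R %||% NA_real_,
    tau_R_low = if (is.null(x$tau_R)) NA_real_ else x$tau_R_bounds[1],
    tau_R_high = if (is.null(x$tau_R)) NA_real_ else x$tau_R_bounds[2],
    peak_s_mean = x$peak_value %||% NA_real_,
    boundary_peak = x$boundary_peak %||% NA,
    mode = x$mode)
}
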