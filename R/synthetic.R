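#' Specification for a synthetic stimulation session
#'
#' Collects the parameters of a synthetic evoked-response session: a fixed
#' analytic feature shape, its amplitude and placement, a noise model, the
#' signal-to-noise mixing ratio, trial count, sample rate and epoch window.
#' Defaults reproduce the standard validation condition: a 100 ms, 100 uV
#' square wave at the start of a 1 s window sampled at 2048 Hz, 10 trials,
#' brown noise mixed at a 3-to-1 signal-to-noise ratio.
#'
#' @param shape One of `"square"`, `"double_square"` (two half-duration
#'   squares separated by a half-duration gap), `"ramp_up"`, `"ramp_down"`,
#'   `"triangle"`, `"sine"` (one full cycle), `"inv_sine"`, `"abs_sine"`,
#'   or `"custom"` (supply `custom` as a full-length sample vector).
#' @param amplitude Peak amplitude in microvolts (used directly for
#'   noiseless sessions; with noise, the template is variance-normalized
#'   before mixing, so only its shape matters).
#' @param feature_start Feature onset, seconds from window start.
#' @param feature_duration Feature duration in seconds.
#' @param noise `"none"`, `"brown"` or `"white"`.
#' @param snr Signal-to-noise mixing ratio (scalar, or one value per trial
#'   for variable-ratio designs): the variance-1 signal template is
#'   multiplied by `snr` and added to a variance-1 noise realization.
#' @param K Number of trials.
#' @param fs Sample rate, Hz.
#' @param window Epoch window `c(t1, t2)` in seconds from the stimulus.
#' @param custom Numeric vector for `shape = "custom"`, length
#'   `round(diff(window) * fs)`.
#' @return A list of class `crp_synth_spec`.
#' @seealso [make_signal()], [make_session()]
#' @export
synth_spec <- function(shape = "square", amplitude = 100,
                       feature_start = NULL, feature_duration = 0.1,
                       noise = "none", snr = 3, K = 10, fs = 2048,
                       window = c(0, 1), custom = NULL) {
  shapes <- c("square", "double_square", "ramp_up", "ramp_down", "triangle",
              "sine", "inv_sine", "abs_sine", "custom")
  if (!shape %in% shapes) {
    abort(sprintf("Unknown shape '%s'. Choose one of: %s.",
                  shape, paste(shapes, collapse = ", ")))
  }
  noise <- match.arg(noise, c("none", "brown", "white"))
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be c(t1, t2) with t1 < t2.")
  }
  feature_start <- feature_start %||% window[1]
  span <- if (shape == "double_square") 1.5 * feature_duration else feature_duration
  if (feature_start < window[1] ||
      feature_start + span > window[2] + 1e-12) {
    abort("The feature does not fit inside the window.")
  }
  if (noise != "none" && any(snr <= 0)) abort("`snr` must be positive when noise is present.")
  if (!length(snr) %in% c(1L, K)) abort("`snr` must be length 1 or one value per trial.")
  structure(
    list(shape = shape, amplitude = amplitude, feature_start = feature_start,
         feature_duration = feature_duration, noise = noise, snr = snr,
         K = as.integer(K), fs = fs, window = window, custom = custom),
    class = "crp_synth_spec")
}

#' One noiseless trial of a synthetic feature
#'
#' Samples the spec's piecewise-analytic waveform on the epoch grid; the
#' signal is zero outside the feature interval.
#'
#' @param spec A [synth_spec()].
#' @return Numeric vector of length `round(diff(window) * fs)`, microvolts.
#' @export
#' @examples
#' v <- make_signal(synth_spec("square", fs = 1000, window = c(0, 0.5)))
#' sum(v == 100)  # 100 ms of 100 uV
make_signal <- function(spec) {
  stopifnot(inherits(spec, "crp_synth_spec"))
  n <- round(diff(spec$window) * spec$fs)
  if (spec$shape == "custom") {
    if (is.null(spec$custom) || length(spec$custom) != n) {
      abort(sprintf("`custom` must be a vector of length %d.", n))
    }
    return(as.numeric(spec$custom))
  }
  # place the feature on the sample grid by index arithmetic, so boundaries
  # are exact regardless of floating-point representation of the times
  s0 <- round((spec$feature_start - spec$window[1]) * spec$fs)
  n_d <- round(spec$feature_duration * spec$fs)
  A <- spec$amplitude
  v <- numeric(n)
  if (spec$shape == "double_square") {
    # two squares of duration d/2 separated by a d/2 gap
    n_h <- round(n_d / 2)
    v[s0 + seq_len(n_h)] <- A
    v[s0 + 2L * n_h + seq_len(n_h)] <- A
    return(v)
  }
  u <- (seq_len(n_d) - 1L) / n_d  # feature phase in [0, 1)
  v[s0 + seq_len(n_d)] <- switch(spec$shape,
    square = rep(A, n_d),
    ramp_up = A * u,
    ramp_down = A * (1 - u),
    triangle = A * (1 - abs(2 * u - 1)),
    sine = A * sin(2 * pi * u),
    inv_sine = -A * sin(2 * pi * u),
    abs_sine = A * abs(sin(2 * pi * u)))
  v
}

#' Brown-noise surrogate timecourse
#'
#' A random-walk surrogate: the cumulative sum of i.i.d. uniform(-0.5, 0.5)
#' deviates, with the running (expanding cumulative) mean subtracted at each
#' sample, then z-scored to sample variance 1. This is the null noise model
#' whose spectrum falls off as 1/f^2, mimicking the strong low-frequency
#' content of field-potential recordings.
#'
#' @param n Number of samples (>= 2).
#' @param seed Optional integer seed for a reproducible trace.
#' @return Numeric vector of length `n`, mean 0, sample variance 1.
#' @export
brown_noise <- function(n, seed = NULL) {
  if (n < 2) abort("`n` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  b <- cumsum(runif(n, -0.5, 0.5))
  b <- b - cumsum(b) / seq_len(n)
  (b - mean(b)) / sd(b)
}

#' @rdname brown_noise
#' @export
white_noise <- function(n, seed = NULL) {
  if (n < 2) abort("`n` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  w <- rnorm(n)
  (w - mean(w)) / sd(w)
}

#' Generate a synthetic stimulation session
#'
#' Builds a `K`-trial epoch matrix from a [synth_spec()]. Without noise,
#' every trial is the raw signal at the stated amplitude. With noise, the
#' signal template is normalized to variance 1, multiplied by the (possibly
#' per-trial) signal-to-noise ratio, and added to an independent variance-1
#' noise realization per trial, so the ratio is on the amplitude scale of
#' the two variance-matched components.
#'
#' @param spec A [synth_spec()].
#' @param seed Optional integer seed; the same spec and seed give a
#'   bit-identical session.
#' @return A [crp_epochs] object (`t1`, `t2` from the spec window).
#' @export
#' @examples
#' ep <- make_session(synth_spec(noise = "brown", snr = 3, K = 10,
#'                               fs = 512, window = c(0, 0.5)), seed = 7)
#' dim(ep)
make_session <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "crp_synth_spec"))
  if (!is.null(seed)) set.seed(seed)
  sig <- make_signal(spec)
  n <- length(sig)
  if (spec$noise == "none") {
    V <- matrix(sig, nrow = n, ncol = spec$K)
  } else {
    if (sd(sig) == 0) abort("Signal template is constant; cannot variance-normalize for mixing.")
    s1 <- sig / sd(sig)
    snr <- rep(spec$snr, length.out = spec$K)
    if (length(spec$snr) == spec$K) snr <- spec$snr
    gen <- if (spec$noise == "brown") brown_noise else white_noise
    V <- vapply(seq_len(spec$K),
                function(k) snr[k] * s1 + gen(n),
                numeric(n))
  }
  crp_epochs(V, fs = spec$fs, t1 = spec$window[1], t2 = spec$window[2])
}
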