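#' Trial epoch matrix
#'
#' The basic container for stimulation-evoked trial data: a numeric matrix of
#' voltages (microvolts) with `T` rows (timepoints) and `K` columns (trials),
#' together with the sample rate and the epoch window. Row `i` holds the
#' voltage at time `t1 + (i - 1) / fs` seconds from the stimulus; the window
#' is half-open, `[t1, t2)`, so that `T = round((t2 - t1) * fs)` is identical
#' for all trials.
#'
#' @param data Numeric matrix, timepoints by trials, in microvolts. A vector
#'   is treated as a single-trial matrix.
#' @param fs Sample rate in Hz.
#' @param t1,t2 Epoch window start and end, in seconds from the stimulus.
#'   Defaults are 15 ms (clear of the stimulation artifact) to 1 s, the
#'   interval over which most evoked responses have returned to baseline.
#' @param stim_times Optional numeric vector of the `K` stimulation onset
#'   times (seconds) the epochs were cut around.
#' @param channel,stim_site Optional labels for the recording channel and the
#'   stimulated site.
#'
#' @return An object of class `crp_epochs`.
#' @seealso [extract_epochs()], [read_epochs()], [projection_profile()]
#' @export
#' @examples
#' v <- make_signal(synth_spec(fs = 500, window = c(0, 0.4)))
#' ep <- crp_epochs(cbind(v, v, v), fs = 500, t1 = 0, t2 = 0.4)
#' ep
crp_epochs <- function(data, fs, t1 = 0.015, t2 = 1,
                       stim_times = NULL, channel = NULL, stim_site = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive sample rate in Hz.")
  }
  if (t1 >= t2) abort("`t1` must be strictly less than `t2`.")
  if (!all(is.finite(data))) {
    bad <- which(!apply(is.finite(data), 2L, all))
    abort(sprintf("Non-finite samples in trial(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  T_expect <- round((t2 - t1) * fs)
  if (nrow(data) != T_expect) {
    abort(sprintf(
      "Epoch matrix has %d rows but the window [%g, %g) at %g Hz implies %d.",
      nrow(data), t1, t2, fs, T_expect))
  }
  if (!is.null(stim_times) && length(stim_times) != ncol(data)) {
    abort("`stim_times` must have one entry per trial.")
  }
  dimnames(data) <- NULL
  structure(
    list(data = data, fs = fs, t1 = t1, t2 = t2,
         stim_times = stim_times, channel = channel, stim_site = stim_site),
    class = "crp_epochs")
}

#' @export
print.crp_epochs <- function(x, ...) {
  cat(sprintf("<crp_epochs> %d timepoints x %d trials @ %g Hz, window [%g, %g) s\n",
              nrow(x$data), ncol(x$data), x$fs, x$t1, x$t2))
  if (!is.null(x$channel)) cat("  channel:", x$channel, "\n")
  if (!is.null(x$stim_site)) cat("  stim site:", x$stim_site, "\n")
  invisible(x)
}

#' @export
dim.crp_epochs <- function(x) dim(x$data)

#' Times from stimulus for each sample of an epoch matrix
#'
#' @param epochs A [crp_epochs] object.
#' @return Numeric vector of length `T`, seconds from the stimulus.
#' @export
epoch_times <- function(epochs) {
  stopifnot(inherits(epochs, "crp_epochs"))
  epochs$t1 + (seq_len(nrow(epochs$data)) - 1L) / epochs$fs
}

#' @describeIn crp_epochs Long-format view: one row per (time, trial) sample.
#' @param x A `crp_epochs` object.
#' @param ... Unused.
#' @method tidy crp_epochs
#' @export
tidy.crp_epochs <- function(x, ...) {
  tibble::tibble(
    time = rep(epoch_times(x), times = ncol(x$data)),
    trial = rep(seq_len(ncol(x$data)), each = nrow(x$data)),
    voltage = as.vector(x$data))
}

# Truncate an epoch matrix to its first n_keep samples (window end moves in).
truncate_epochs <- function(epochs, n_keep) {
  stopifnot(inherits(epochs, "crp_epochs"), n_keep >= 1L,
            n_keep <= nrow(epochs$data))
  crp_epochs(epochs$data[seq_len(n_keep), , drop = FALSE], fs = epochs$fs,
             t1 = epochs$t1, t2 = epochs$t1 + n_keep / epochs$fs,
             stim_times = epochs$stim_times, channel = epochs$channel,
             stim_site = epochs$stim_site)
}

#' Cut stimulation-locked epochs out of a continuous recording
#'
#' Slices a single-channel continuous voltage series into a trial matrix,
#' taking for each stimulation time `tau_k` the samples in the half-open
#' window `[tau_k + t1, tau_k + t2)`. Sample `i` of the recording is taken to
#' occur at time `(i - 1) / fs`, and window edges are aligned to the nearest
#' sample, so every trial yields exactly `round((t2 - t1) * fs)` samples.
#'
#' @param continuous Numeric vector, the continuous recording in microvolts.
#' @param fs Sample rate in Hz.
#' @param stim_times Numeric vector of stimulation onset times in seconds.
#' @param t1,t2 Epoch window relative to each stimulus, seconds; see
#'   [crp_epochs()] for the defaults.
#' @inheritParams crp_epochs
#' @return A [crp_epochs] object with one column per stimulation.
#' @export
#' @examples
#' rec <- sin(2 * pi * 3 * (0:999) / 100)
#' ep <- extract_epochs(rec, fs = 100, stim_times = c(1, 4, 7), t1 = 0, t2 = 1)
#' dim(ep)
extract_epochs <- function(continuous, fs, stim_times, t1 = 0.015, t2 = 1,
                           channel = NULL, stim_site = NULL) {
  continuous <- as.numeric(continuous)
  if (length(stim_times) == 0L) abort("`stim_times` is empty.")
  if (t1 >= t2) abort("`t1` must be strictly less than `t2`.")
  n_take <- round((t2 - t1) * fs)
  if (n_take < 1L) abort("Window shorter than one sample.")
  cols <- lapply(seq_along(stim_times), function(k) {
    start <- round((stim_times[k] + t1) * fs) + 1L
    stop_ <- start + n_take - 1L
    if (start < 1L || stop_ > length(continuous)) {
      abort(sprintf(
        "Epoch window for trial %d (stim at %g s) exceeds the recording (samples %d..%d of %d).",
        k, stim_times[k], start, stop_, length(continuous)))
    }
    continuous[start:stop_]
  })
  crp_epochs(do.call(cbind, cols), fs = fs, t1 = t1, t2 = t2,
             stim_times = as.numeric(stim_times),
             channel = channel, stim_site = stim_site)
}

#' Check per-trial baseline fidelity
#'
#' Cross-projection analysis is very sensitive to baselining: a constant
#' voltage offset masquerades as sustained reproducible structure. This
#' estimates a per-trial offset as the median voltage over a window far from
#' the stimulus-locked response (by default the final 20% of the epoch) and
#' flags trials whose offset exceeds a tolerance.
#'
#' @param epochs A [crp_epochs] object.
#' @param window Length-2 numeric, seconds from stimulus, within the epoch
#'   window (or a pre-stimulus interval if the epochs contain one). `NULL`
#'   uses the last 20% of the epoch.
#' @param tolerance Absolute offset (microvolts) beyond which a trial is
#'   flagged; default 5.
#' @return A tibble of class `crp_baseline` with columns `trial`,
#'   `offset` (microvolts) and `flag`, plus attributes `window` and
#'   `tolerance`.
#' @seealso [subtract_offset()]
#' @export
check_baseline <- function(epochs, window = NULL, tolerance = 5) {
  stopifnot(inherits(epochs, "crp_epochs"))
  tt <- epoch_times(epochs)
  if (is.null(window)) {
    window <- c(epochs$t1 + 0.8 * (epochs$t2 - epochs$t1), epochs$t2)
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be an increasing interval of two times.")
  }
  idx <- which(tt >= window[1] & tt < window[2])
  if (length(idx) == 0L) abort("Baseline window contains no samples.")
  offsets <- apply(epochs$data[idx, , drop = FALSE], 2L, median)
  out <- tibble::tibble(
    trial = seq_len(ncol(epochs$data)),
    offset = unname(offsets),
    flag = abs(offsets) > tolerance)
  attr(out, "window") <- window
  attr(out, "tolerance") <- tolerance
  class(out) <- c("crp_baseline", class(out))
  out
}

#' Subtract estimated baseline offsets from each trial
#'
#' @param epochs A [crp_epochs] object.
#' @param report A `crp_baseline` report from [check_baseline()] computed on
#'   the same epochs; `NULL` computes one with defaults.
#' @return A corrected [crp_epochs] object.
#' @export
subtract_offset <- function(epochs, report = NULL) {
  stopifnot(inherits(epochs, "crp_epochs"))
  if (is.null(report)) report <- check_baseline(epochs)
  if (nrow(report) != ncol(epochs$data)) {
    abort("Baseline report does not match the number of trials.")
  }
  corrected <- sweep(epochs$data, 2L, report$offset, `-`)
  ep <- epochs
  ep$data <- corrected
  ep
}

#' Read and write epoch matrices as delimited text
#'
#' The on-disk format is tab-delimited text, rows = timepoints, columns =
#' trials, preceded by a single header comment `# fs=<Hz> t1=<s> t2=<s>`.
#' Values are written with full double precision so a round trip is
#' bit-identical.
#'
#' @param path File path.
#' @return `read_epochs()` returns a [crp_epochs] object; `write_epochs()`
#'   invisibly returns `path`.
#' @export
read_epochs <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#", first)) {
    abort("Epoch file must start with a '# fs=<Hz> t1=<s> t2=<s>' header.")
  }
  get_field <- function(name) {
    m <- regmatches(first, regexec(paste0(name, "=([-0-9.eE+]+)"), first))[[1]]
    if (length(m) < 2L) abort(sprintf("Header is missing '%s='.", name))
    as.numeric(m[2])
  }
  mat <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  crp_epochs(mat, fs = get_field("fs"), t1 = get_field("t1"),
             t2 = get_field("t2"))
}

#' @rdname read_epochs
#' @param epochs A [crp_epochs] object.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "crp_epochs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g t1=%.17g t2=%.17g",
                     epochs$fs, epochs$t1, epochs$t2), con)
  utils::write.table(
    matrix(sprintf("%.17g", epochs$data), nrow = nrow(epochs$data)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a stimulation-events file
#'
#' Two-column delimited text: onset time in seconds, then a label.
#'
#' @param path File path.
#' @return A tibble with columns `onset` (seconds) and `label`.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("onset", "label"),
                          colClasses = c("numeric", "character"))
  tibble::as_tibble(ev)
}
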