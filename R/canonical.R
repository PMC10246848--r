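#' Canonical response shape
#'
#' Extracts the canonical, unit-norm response shape `C(t)` from the trial
#' matrix truncated to the response duration. The default method is linear
#' kernel PCA: because the number of timepoints `T_R` far exceeds the number
#' of trials `K`, the eigendecomposition of the `T_R x T_R` timepoint
#' covariance `V V'` is exchanged for that of the small `K x K` Gram matrix
#' `V' V`, whose leading eigenvector `f1` (eigenvalue `xi1^2`) is mapped back
#' to the timepoint domain as `C = V f1 / xi1` — the leading principal
#' direction of the trials, more robust to outlier trials than the plain
#' average. The alternative is the unit-normalized mean trace.
#'
#' The sign of a principal direction is arbitrary; it is anchored so the
#' projection of `C` onto the mean trace is non-negative, falling back to a
#' non-negative value at the largest-magnitude sample when that projection
#' is numerically zero. Repeated calls on identical input are bit-identical.
#'
#' @param V_trunc Numeric `T_R x K` matrix (or [crp_epochs]) already
#'   truncated to the response window `[t1, tau_R)`.
#' @param method `"kernel_pca"` (default) or `"mean_trace"`.
#' @param fs,t1 Optional sample rate and window start, used only to carry a
#'   time axis on the result (taken from `V_trunc` when it is a
#'   [crp_epochs]).
#' @return An object of class `crp_shape`: list with `C` (unit-norm numeric
#'   vector of length `T_R`), `eigenvalues` (all `K` Gram eigenvalues,
#'   descending; diagnostic only), `method`, `sign_anchor`, and optionally
#'   `time`.
#' @seealso [parameterize_trials()]
#' @export
canonical_shape <- function(V_trunc, method = c("kernel_pca", "mean_trace"),
                            fs = NULL, t1 = NULL) {
  method <- match.arg(method)
  if (inherits(V_trunc, "crp_epochs")) {
    fs <- V_trunc$fs; t1 <- V_trunc$t1
    V_trunc <- V_trunc$data
  }
  V <- epoch_data(V_trunc)
  shape <- switch(method,
                  kernel_pca = kernel_pca_first_component(V),
                  mean_trace = mean_trace_shape(V))
  if (!is.null(fs) && !is.null(t1)) {
    shape$time <- t1 + (seq_along(shape$C) - 1L) / fs
  }
  shape
}

#' @rdname canonical_shape
#' @export
kernel_pca_first_component <- function(V_trunc) {
  V <- epoch_data(V_trunc)
  if (!all(is.finite(V))) abort("Non-finite values in the trial matrix.")
  if (ncol(V) < 2L || nrow(V) < 2L) {
    abort("Kernel PCA needs at least 2 trials and 2 timepoints.")
  }
  G <- crossprod(V)
  G <- (G + t(G)) / 2  # guard against floating-point asymmetry
  eig <- eigen(G, symmetric = TRUE)
  xi2 <- eig$values
  tol <- max(nrow(V), ncol(V)) * .Machine$double.eps * max(abs(xi2), 0)
  if (xi2[1] <= tol) abort("Degenerate trial matrix: leading eigenvalue is numerically zero.")
  f1 <- eig$vectors[, 1L]
  C <- as.vector(V %*% f1) / sqrt(xi2[1])
  C <- C / sqrt(sum(C^2))  # defensive renormalization
  anchor_sign(C, rowMeans(V), "kernel_pca", eigenvalues = pmax(xi2, 0))
}

#' @rdname canonical_shape
#' @export
mean_trace_shape <- function(V_trunc) {
  V <- epoch_data(V_trunc)
  if (!all(is.finite(V))) abort("Non-finite values in the trial matrix.")
  m <- rowMeans(V)
  nrm <- sqrt(sum(m^2))
  if (nrm == 0) abort("Mean trace is identically zero; no mean-trace shape exists.")
  anchor_sign(m / nrm, m, "mean_trace")
}

anchor_sign <- function(C, mean_trace, method, eigenvalues = NULL) {
  proj <- sum(C * mean_trace)
  tol <- 1e-12 * sqrt(sum(mean_trace^2))
  if (abs(proj) > tol) {
    anchor <- "non-negative projection onto the mean trace"
    if (proj < 0) C <- -C
  } else {
    anchor <- "non-negative value at the largest-magnitude sample"
    if (C[which.max(abs(C))] < 0) C <- -C
  }
  structure(
    list(C = C, eigenvalues = eigenvalues, method = method,
         sign_anchor = anchor),
    class = "crp_shape")
}

#' @export
print.crp_shape <- function(x, ...) {
  cat(sprintf("<crp_shape> %s, %d samples, |C|=%.12g\n  sign anchor: %s\n",
              x$method, length(x$C), sqrt(sum(x$C^2)), x$sign_anchor))
  invisible(x)
}

#' @describeIn canonical_shape Tibble of the shape (`time` if known,
#'   `sample`, `C`).
#' @param x A `crp_shape` object.
#' @param ... Unused.
#' @method tidy crp_shape
#' @export
tidy.crp_shape <- function(x, ...) {
  out <- tibble::tibble(sample = seq_along(x$C), C = x$C)
  if (!is.null(x$time)) out <- tibble::add_column(out, time = x$time,
                                                  .before = 1L)
  out
}

#' Write a canonical shape as two-column delimited text
#'
#' Columns are time in seconds from the stimulus (sample index when no time
#' axis is attached) and the shape value.
#'
#' @param shape A `crp_shape`.
#' @param path File path.
#' @export
write_shape <- function(shape, path) {
  stopifnot(inherits(shape, "crp_shape"))
  tt <- shape$time %||% seq_along(shape$C)
  utils::write.table(
    data.frame(time = sprintf("%.10g", tt), C = sprintf("%.10g", shape$C)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
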