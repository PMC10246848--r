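#' Run the full canonical-response-parameterization pipeline
#'
#' Orchestrates one session end to end: optional baseline check/correction,
#' time-resolved cross-projection profile, response duration `tau_R`,
#' optional iterative artifact-trial rejection, truncation of the trial
#' matrix to `[t1, tau_R)`, canonical-shape extraction, single-trial
#' parameterization, and extraction and parameterization significance.
#' Fully deterministic given the input epochs and settings.
#'
#' @param epochs A [crp_epochs] object.
#' @param mode Projection normalization, `"semi"` (default), `"full"` or
#'   `"none"`.
#' @param t2_grid Optional window-end grid for the profile; default every
#'   sample (see [projection_profile()]).
#' @param canonical Shape extraction method: `"kernel_pca"` (default) or
#'   `"mean_trace"`.
#' @param baseline_correct If `TRUE`, estimate and subtract per-trial
#'   baseline offsets before analysis.
#' @param baseline_window,baseline_tolerance Passed to [check_baseline()].
#' @param reject_artifacts If `TRUE`, iteratively reject anomalous trials
#'   via [reject_and_rerun()] before the final pass.
#' @param artifact_p Anomaly threshold when rejecting; default `1e-6`.
#' @param min_samples Minimum profile window in samples (default 10).
#' @return An object of class `crp_result`: list with `tau_R`,
#'   `tau_R_bounds`, `s_mean_at_tau` (uV.s in semi mode), `extraction` and
#'   `parameterization` significance lists, `shape` (`crp_shape`), `params`
#'   (`crp_params` tibble), `profile` (`crp_profile`), `kept`/`rejected`
#'   trial indices, `baseline` report (if computed), `config`, and
#'   `warnings` (boundary peak, degenerate statistics).
#' @seealso [autoplot.crp_result()], [tidy.crp_result()],
#'   [write_crp_json()]
#' @export
#' @examples
#' ep <- make_session(synth_spec(noise = "brown", snr = 3, K = 10,
#'                               fs = 512, window = c(0, 0.5)), seed = 1)
#' res <- run_crp(ep)
#' res
run_crp <- function(epochs, mode = c("semi", "full", "none"),
                    t2_grid = NULL, canonical = c("kernel_pca", "mean_trace"),
                    baseline_correct = FALSE, baseline_window = NULL,
                    baseline_tolerance = 5, reject_artifacts = FALSE,
                    artifact_p = 1e-6, min_samples = 10L) {
  mode <- match.arg(mode)
  canonical <- match.arg(canonical)
  stopifnot(inherits(epochs, "crp_epochs"))
  K0 <- ncol(epochs$data)
  baseline <- NULL
  if (baseline_correct) {
    baseline <- check_baseline(epochs, window = baseline_window,
                               tolerance = baseline_tolerance)
    epochs <- subtract_offset(epochs, baseline)
  }
  kept <- seq_len(K0)
  rejected <- integer(0)
  if (reject_artifacts && K0 >= 4L) {
    rr <- reject_and_rerun(epochs, threshold_p = artifact_p, mode = mode,
                           canonical = canonical, min_samples = min_samples)
    res <- rr$result
    res$kept <- rr$kept
    res$rejected <- rr$rejected
    res$baseline <- baseline
    res$config$reject_artifacts <- TRUE
    res$config$artifact_p <- artifact_p
    res$config$baseline_correct <- baseline_correct
    return(res)
  }
  warnings_out <- character(0)
  prof <- withCallingHandlers(
    response_duration(projection_profile(epochs, t2_grid = t2_grid,
                                         mode = mode,
                                         min_samples = min_samples)),
    warning = function(w) {
      warnings_out <<- c(warnings_out, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  V_trunc <- truncate_epochs(epochs, prof$n_R)
  shape <- canonical_shape(V_trunc, method = canonical)
  params <- parameterize_trials(V_trunc, shape)
  proj_tau <- cross_projection_matrix(epochs, mode = mode, t2 = prof$tau_R)
  extraction <- extraction_significance(proj_tau)
  parameterization <- if (ncol(epochs$data) >= 3L) {
    parameterization_significance(params)
  } else NULL
  if (isTRUE(extraction$degenerate)) {
    warnings_out <- c(warnings_out, "Extraction t-test degenerate (zero variance).")
  }
  structure(
    list(tau_R = prof$tau_R,
         tau_R_bounds = prof$tau_R_bounds,
         s_mean_at_tau = proj_tau$S_mean,
         extraction = extraction,
         parameterization = parameterization,
         shape = shape,
         params = params,
         profile = prof,
         projections = proj_tau,
         kept = kept,
         rejected = rejected,
         baseline = baseline,
         config = list(t1 = epochs$t1, t2 = epochs$t2, fs = epochs$fs,
                       mode = mode, canonical = canonical,
                       baseline_correct = baseline_correct,
                       reject_artifacts = FALSE, artifact_p = artifact_p,
                       min_samples = min_samples),
         warnings = warnings_out),
    class = "crp_result")
}

#' @export
print.crp_result <- function(x, ...) {
  cat("<crp_result>\n")
  cat(sprintf("  trials: %d kept%s\n", length(x$kept),
              if (length(x$rejected)) sprintf(", %d rejected (%s)",
                                              length(x$rejected),
                                              paste(x$rejected, collapse = ", "))
              else ""))
  cat(sprintf("  response duration tau_R: %g s (98%% bounds %g..%g)\n",
              x$tau_R, x$tau_R_bounds[1], x$tau_R_bounds[2]))
  cat(sprintf("  S_mean at tau_R: %.4g uV.s\n", x$s_mean_at_tau))
  cat(sprintf("  extraction:       t=%.3g, p=%.3g (n=%d)\n",
              x$extraction$t_value, x$extraction$p_value,
              x$extraction$n_values))
  if (!is.null(x$parameterization)) {
    cat(sprintf("  parameterization: t=%.3g, p=%.3g (n=%d)\n",
                x$parameterization$t_value, x$parameterization$p_value,
                x$parameterization$n_values))
  }
  cat(sprintf("  mean alpha'=%.4g uV, mean SNR=%.3g, mean expl. var=%.3g\n",
              mean(x$params$alpha_prime), mean(x$params$snr),
              mean(x$params$explained_variance)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @describeIn run_crp Per-trial parameter table of a result.
#' @param x A `crp_result`.
#' @param ... Unused.
#' @method tidy crp_result
#' @export
tidy.crp_result <- function(x, ...) {
  out <- tibble::as_tibble(x$params)
  out$trial <- x$kept[out$trial]
  out
}

#' @describeIn run_crp One-row session-level summary.
#' @method glance crp_result
#' @export
glance.crp_result <- function(x, ...) {
  tibble::tibble(
    n_trials = length(x$kept),
    n_rejected = length(x$rejected),
    tau_R = x$tau_R,
    tau_R_low = x$tau_R_bounds[1],
    tau_R_high = x$tau_R_bounds[2],
    s_mean_at_tau = x$s_mean_at_tau,
    extraction_t = x$extraction$t_value,
    extraction_p = x$extraction$p_value,
    parameterization_t = x$parameterization$t_value %||% NA_real_,
    parameterization_p = x$parameterization$p_value %||% NA_real_,
    mean_alpha_prime = mean(x$params$alpha_prime),
    mean_snr = mean(x$params$snr),
    mean_explained_variance = mean(x$params$explained_variance),
    boundary_peak = isTRUE(x$profile$boundary_peak))
}

# Fixed-format number for deterministic JSON: 10 significant digits.
fmt10 <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) || is.logical(x) || is.integer(x)) return(x)
  as.numeric(sprintf("%.10g", x))
}

#' Serialize a CRP result to a machine-readable JSON summary
#'
#' Field order and number formatting (10 significant digits) are fixed so
#' that re-running an identical analysis produces a byte-identical file.
#'
#' @param result A `crp_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crp_json <- function(result, path) {
  stopifnot(inherits(result, "crp_result"))
  sig <- function(s) if (is.null(s)) NULL else list(
    t_value = fmt10(s$t_value), p_value = fmt10(s$p_value),
    n_values = s$n_values, mean = fmt10(s$mean),
    degenerate = s$degenerate)
  obj <- list(
    tau_R = fmt10(result$tau_R),
    tau_R_bounds = fmt10(result$tau_R_bounds),
    s_mean_at_tau = fmt10(result$s_mean_at_tau),
    extraction = sig(result$extraction),
    parameterization = sig(result$parameterization),
    canonical_method = result$shape$method,
    n_shape_samples = length(result$shape$C),
    kept = as.integer(result$kept),
    rejected = as.integer(result$rejected),
    trials = lapply(seq_len(nrow(result$params)), function(i) list(
      trial = as.integer(result$kept[result$params$trial[i]]),
      alpha = fmt10(result$params$alpha[i]),
      alpha_prime_uV = fmt10(result$params$alpha_prime[i]),
      noise = fmt10(result$params$noise[i]),
      snr = fmt10(result$params$snr[i]),
      explained_variance = fmt10(result$params$explained_variance[i]))),
    config = result$config,
    warnings = as.list(result$warnings))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Write the profile as two-column delimited text
#'
#' Columns: window end `t2` in seconds, mean cross-projection in uV.s.
#'
#' @param profile A `crp_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "crp_profile"))
  utils::write.table(
    data.frame(t2_seconds = sprintf("%.10g", profile$profile$t2),
               s_mean_uVs = sprintf("%.10g", profile$profile$s_mean)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
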