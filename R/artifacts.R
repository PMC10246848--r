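#' Detect anomalous (artifactual) trials from projection sub-distributions
#'
#' Each trial `k` is involved in `2(K - 1)` cross-projections (projections
#' of normalized trial `k` into the others, and of the normalized others
#' into raw trial `k`). Comparing this sub-distribution against the
#' projections not involving `k` with an unpaired two-sample t-test
#' identifies outliers: a trial whose involving projections sit far *below*
#' the rest shares little structure with the other trials and is flagged as
#' artifactual. The trial with the highest mean involving projection is
#' reported as the most representative of the response shape.
#'
#' @param projections A `crp_projections` with `K >= 4` trials (computed at
#'   `tau_R` or over the full naive window; the full window is the pipeline
#'   default, since artifacts outside the response window still corrupt
#'   extraction).
#' @param threshold_p Flagging threshold on the t-test p-value; default
#'   `1e-6`.
#' @param others Comparison group: `"noninvolving"` (default) compares
#'   against all projections between the other trials; `"half"` compares
#'   against the balanced half-selection values not involving `k`.
#' @return A tibble of class `crp_anomaly` with one row per trial:
#'   `trial`, `involving_mean`, `others_mean`, `t_value`, `p_value`,
#'   `direction` (`"below"`/`"above"`), `flag` (artifactual: significant
#'   *and* below). Attributes: `most_representative` (trial index),
#'   `threshold_p`, `others`.
#' @export
detect_anomalous_trials <- function(projections, threshold_p = 1e-6,
                                    others = c("noninvolving", "half")) {
  stopifnot(inherits(projections, "crp_projections"))
  others <- match.arg(others)
  P <- projections$P
  K <- projections$K
  if (K < 4L) abort("Anomaly detection needs at least 4 trials.")
  off <- row(P) != col(P)
  sel <- if (others == "half") balanced_half_selection(K)
  rows <- lapply(seq_len(K), function(k) {
    involving <- c(P[k, -k], P[-k, k])
    other_vals <- if (others == "noninvolving") {
      Pk <- P[-k, -k, drop = FALSE]
      Pk[row(Pk) != col(Pk)]
    } else {
      keep <- sel$norm_trial != k & sel$raw_trial != k
      P[cbind(sel$norm_trial[keep], sel$raw_trial[keep])]
    }
    tt <- tryCatch(
      t.test(involving, other_vals, var.equal = TRUE),
      error = function(e) {
        # essentially-constant groups: equal means are unremarkable,
        # separated means are unambiguously anomalous
        d <- mean(involving) - mean(other_vals)
        list(statistic = c(t = if (d == 0) 0 else Inf * sign(d)),
             p.value = if (d == 0) 1 else 0)
      })
    tibble::tibble(
      trial = k,
      involving_mean = mean(involving),
      others_mean = mean(other_vals),
      t_value = unname(tt$statistic),
      p_value = tt$p.value,
      direction = if (mean(involving) < mean(other_vals)) "below" else "above")
  })
  out <- dplyr::bind_rows(rows)
  out$flag <- out$p_value < threshold_p & out$direction == "below"
  attr(out, "most_representative") <- out$trial[which.max(out$involving_mean)]
  attr(out, "threshold_p") <- threshold_p
  attr(out, "others") <- others
  class(out) <- c("crp_anomaly", class(out))
  out
}

#' Iteratively reject artifactual trials and re-run the pipeline
#'
#' Drops the single worst flagged trial (smallest anomaly p-value among
#' below-mean flags), recomputes the full pipeline on the remaining trials,
#' and repeats until no trial is flagged, `max_iterations` is reached, or a
#' further rejection would leave fewer than 4 trials (in which case it stops
#' with a warning and returns the last valid state).
#'
#' @param epochs A [crp_epochs] object.
#' @param threshold_p Anomaly flagging threshold, default `1e-6`.
#' @param max_iterations Cap on rejections; default `Inf`.
#' @param detect_window `"full"` (default) detects anomalies on projections
#'   over the full naive window; `"tau_R"` detects at the current response
#'   duration.
#' @param others Passed to [detect_anomalous_trials()].
#' @inheritParams run_crp
#' @return A list with `kept` (trial indices retained), `rejected` (indices
#'   in rejection order), `result` (the final [run_crp()] result on the kept
#'   trials), and `history` (tibble of `iteration`, `rejected_trial`,
#'   `tau_R`, `s_mean_at_tau` before each rejection and after the last).
#' @export
reject_and_rerun <- function(epochs, threshold_p = 1e-6, max_iterations = Inf,
                             detect_window = c("full", "tau_R"),
                             others = c("noninvolving", "half"),
                             mode = "semi", canonical = "kernel_pca",
                             min_samples = 10L) {
  stopifnot(inherits(epochs, "crp_epochs"))
  detect_window <- match.arg(detect_window)
  others <- match.arg(others)
  kept <- seq_len(ncol(epochs$data))
  rejected <- integer(0)
  history <- list()
  iter <- 0L
  repeat {
    current <- epochs
    current$data <- epochs$data[, kept, drop = FALSE]
    if (!is.null(current$stim_times)) current$stim_times <- epochs$stim_times[kept]
    res <- run_crp(current, mode = mode, canonical = canonical,
                   min_samples = min_samples)
    history[[length(history) + 1L]] <- tibble::tibble(
      iteration = iter, n_trials = length(kept),
      tau_R = res$tau_R, s_mean_at_tau = res$s_mean_at_tau)
    proj <- if (detect_window == "full") {
      cross_projection_matrix(current, mode = mode)
    } else {
      cross_projection_matrix(current, mode = mode, t2 = res$tau_R)
    }
    report <- detect_anomalous_trials(proj, threshold_p = threshold_p,
                                      others = others)
    flagged <- report[report$flag, , drop = FALSE]
    if (nrow(flagged) == 0L || iter >= max_iterations) {
      return(list(kept = kept, rejected = rejected, result = res,
                  history = dplyr::bind_rows(history),
                  final_anomaly = report))
    }
    if (length(kept) - 1L < 4L) {
      warn("Further rejection would leave fewer than 4 trials; stopping with the last valid state.")
      return(list(kept = kept, rejected = rejected, result = res,
                  history = dplyr::bind_rows(history),
                  final_anomaly = report))
    }
    worst_local <- flagged$trial[which.min(flagged$p_value)]
    rejected <- c(rejected, kept[worst_local])
    kept <- kept[-worst_local]
    iter <- iter + 1L
  }
}

#' Write an anomaly report as delimited text
#'
#' @param report A `crp_anomaly` tibble.
#' @param path File path.
#' @export
write_anomaly <- function(report, path) {
  stopifnot(inherits(report, "crp_anomaly"))
  df <- data.frame(
    trial = report$trial,
    involving_mean = sprintf("%.10g", report$involving_mean),
    others_mean = sprintf("%.10g", report$others_mean),
    t = sprintf("%.10g", report$t_value),
    p = sprintf("%.10g", report$p_value),
    flag = report$flag)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
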