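#' Rank-based rescaling onto the reported-time distribution
#'
#' The iterative fit optimizes the order of samples, not the absolute day
#' unit, so raw estimates can drift off the calendar scale. This step maps
#' them back: the sample ranked r among the estimates receives the r-th
#' order statistic of the continuized reported times. The output is a
#' monotone transform of the estimates (Spearman correlation exactly 1) and
#' its multiset of values equals the reported-continuous multiset exactly.
#' Ties among estimates (samples the likelihood cannot distinguish) are
#' broken by `tiebreak` when given — the loop passes the continuized
#' reported times, the only remaining timing information — and by input
#' order otherwise; both deterministic.
#'
#' @param estimates Raw timing estimates (days).
#' @param reported_continuous Continuized reported timings (days), same
#'   length.
#' @param tiebreak Optional secondary key ordering exactly-tied estimates.
#' @return Rescaled estimates, in input order.
#' @export
#' @examples
#' rescale_to_reported(c(30, 10, 20), c(5.1, 7.0, 9.2))
rescale_to_reported <- function(estimates, reported_continuous,
                                tiebreak = NULL) {
  stopifnot(length(estimates) == length(reported_continuous))
  if (is.null(tiebreak)) {
    r <- rank(estimates, ties.method = "first")
  } else {
    r <- integer(length(estimates))
    r[order(estimates, tiebreak)] <- seq_along(estimates)
  }
  sort(reported_continuous)[r]
}

#' Fit timing estimates by iterative profile refinement
#'
#' The core loop. Reported days are first continuized
#' ([continuize_times()]); then each iteration (i) builds windowed Gaussian
#' temporal profiles per gene from the current timings at the scheduled
#' window size ([build_windows()], [window_schedule()]) and (ii) re-estimates
#' every sample's timing as the argmax of its aggregated pseudo-density
#' curve ([gene_density()], [combine_curves()]). Convergence is declared
#' once the Euclidean distance between successive timing vectors falls below
#' `config$converge` *and* the window schedule has reached its minimum (so
#' early coarse iterations cannot stop the fit prematurely). Final estimates
#' are rescaled onto the reported-time distribution
#' ([rescale_to_reported()]); asynchrony scores and outlier flags come from
#' the final iteration's curves.
#'
#' @param panel An `expression_panel` (preprocessed; see
#'   [preprocess_cohort()]).
#' @param raw_days Integer vector of reported days, aligned with the panel.
#' @param config An [endotime_config()]; `config$rng_seed` drives the jitter.
#' @return An `endotime_fit`: list with `records` (a `timing_records` data
#'   frame: sample id, reported day, continuized reported time, `eLH`
#'   estimate, asynchrony, per-gene argmax times, outlier flag), `profiles`
#'   (final `gene_profiles` with the qPCR calibration reference attached),
#'   `raw_estimates` (final pre-rescale timings, on the model's own axis),
#'   `trace` (per-iteration window size and displacement), `converged`, and
#'   `outlier_cutoff`.
#' @export
run_endotime <- function(panel, raw_days, config = endotime_config()) {
  stopifnot(inherits(panel, "expression_panel"))
  n <- nrow(panel$expr)
  stopifnot(length(raw_days) == n)
  if (n < config$window_min)
    stop(sprintf("cohort of %d samples is below the minimum window size %d",
                 n, config$window_min))
  if (config$window_start > n / 2)
    warning(sprintf(paste0(
      "initial window size %d exceeds half the cohort (n = %d); profiles ",
      "will be coarse - consider window_start near n/3"),
      config$window_start, n))
  rlh <- continuize_times(raw_days, seed = config$rng_seed)
  t_cur <- rlh
  trace <- list()
  converged <- FALSE
  profiles <- NULL
  res <- NULL
  for (k in seq_len(config$max_iterations) - 1L) {
    w <- window_schedule(k, config)
    profiles <- build_windows(panel, t_cur, min(w, n), config,
                              tiebreak = rlh)
    res <- estimate_panel(panel, profiles, min(w, n))
    disp <- sqrt(sum((res$estimates - t_cur)^2))
    trace[[k + 1L]] <- data.frame(iteration = k, w = min(w, n),
                                  displacement = disp)
    t_cur <- res$estimates
    if (disp < config$converge && w <= config$window_min) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("no convergence within %d iterations; returning last state",
                    config$max_iterations))
  eLH <- rescale_to_reported(t_cur, rlh, tiebreak = rlh)
  asyn <- res$asynchrony
  out <- if (n >= 10L && length(profiles) >= 2L) {
    flag_outliers(asyn, config)
  } else list(outlier = rep(NA, n), cutoff = NA_real_)
  records <- data.frame(
    sample_id = rownames(panel$expr),
    reported_day = as.integer(raw_days),
    rLH_continuous = rlh,
    eLH = eLH,
    asynchrony = if (length(profiles) >= 2L) asyn else NA_real_,
    stringsAsFactors = FALSE
  )
  am <- res$gene_argmax
  colnames(am) <- paste0("argmax_", colnames(am))
  records <- cbind(records, as.data.frame(am), row.names = NULL)
  records$outlier <- out$outlier
  class(records) <- c("timing_records", "data.frame")
  attr(profiles, "calibration") <- calibration_ref(panel)
  structure(list(records = records,
                 profiles = profiles,
                 raw_estimates = t_cur,
                 trace = do.call(rbind, trace),
                 converged = converged,
                 outlier_cutoff = out$cutoff),
            class = "endotime_fit")
}

#' Train on a raw cohort table
#'
#' Convenience front door: [preprocess_cohort()] then [run_endotime()].
#'
#' @param cohort A `cohort_table`.
#' @param config An [endotime_config()].
#' @return An `endotime_fit`; see [run_endotime()].
#' @export
endotime_train <- function(cohort, config = endotime_config()) {
  panel <- preprocess_cohort(cohort, config)
  run_endotime(panel, cohort$reported_day, config)
}

#' @export
print.endotime_fit <- function(x, ...) {
  n_it <- nrow(x$trace)
  cat(sprintf("<endotime_fit> %d samples, %d iterations (%sconverged)\n",
              nrow(x$records), n_it, if (x$converged) "" else "NOT "))
  cat(sprintf("  final displacement: %.4g days | outlier cutoff: %.4g\n",
              x$trace$displacement[n_it], x$outlier_cutoff))
  cat(sprintf("  eLH range: %.2f..%.2f days | %d outlier(s)\n",
              min(x$records$eLH), max(x$records$eLH),
              sum(x$records$outlier, na.rm = TRUE)))
  invisible(x)
}
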