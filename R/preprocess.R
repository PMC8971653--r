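#' Invert and unit-scale delta-CT values
#'
#' qPCR delta-CT values fall as expression rises, so every value is first
#' sign-inverted to correlate positively with expression, then each gene is
#' min-max scaled to `[0, 1]` across the cohort: the least-expressed sample
#' maps to 0 and the most-expressed to 1.
#'
#' @param cohort A `cohort_table` from [read_cohort()] / [as_cohort_table()].
#' @param config An [endotime_config()].
#' @return An `expression_panel`: a list with `expr` (samples x genes matrix
#'   in `[0, 1]`), `batch` (per-sample labels) and `directions` (per-gene
#'   direction flags).
#' @export
invert_and_scale <- function(cohort, config = endotime_config()) {
  genes <- names(config$panel_genes)
  x <- -as.matrix(cohort[, genes, drop = FALSE])
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  degenerate <- genes[span == 0]
  if (length(degenerate))
    stop("gene(s) constant across all samples: ",
         paste(degenerate, collapse = ", "))
  x <- sweep(sweep(x, 2, rng[1, ], "-"), 2, span, "/")
  rownames(x) <- cohort$sample_id
  structure(list(expr = x,
                 batch = cohort$batch,
                 directions = config$panel_genes),
            class = "expression_panel")
}

#' Additive batch correction
#'
#' Shifts each gene within each batch by a constant so that every batch's
#' mean expression equals the cohort grand mean, gene by gene. This is a
#' deliberately modest correction: only location is adjusted, variances and
#' within-batch ordering are untouched. Applying it twice is a no-op.
#'
#' @param panel An `expression_panel`.
#' @return The panel with batch-mean-equalized `expr`.
#' @export
batch_correct <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  b <- factor(panel$batch)
  if (nlevels(b) <= 1L) return(panel)
  grand <- colMeans(panel$expr)
  for (lev in levels(b)) {
    idx <- which(b == lev)
    shift <- grand - colMeans(panel$expr[idx, , drop = FALSE])
    panel$expr[idx, ] <- sweep(panel$expr[idx, , drop = FALSE], 2, shift, "+")
  }
  panel
}

#' Preprocess a cohort into an expression panel
#'
#' Convenience wrapper: [invert_and_scale()] followed by [batch_correct()].
#'
#' @inheritParams invert_and_scale
#' @return An `expression_panel`.
#' @export
preprocess_cohort <- function(cohort, config = endotime_config()) {
  batch_correct(invert_and_scale(cohort, config))
}

#' Continuize integer reported days
#'
#' Reported timings are whole days, too coarse for continuous modelling.
#' Two steps turn them into a continuous vector: (1) add independent jitter
#' drawn uniformly from (-0.5, 0.5) to each reported day; (2) sort the
#' jittered values, regress them on their rank (1..n) by ordinary least
#' squares, and replace each value by its fitted value. The result spaces
#' samples evenly along the time course while keeping each close to its
#' reported day, and never reorders samples whose reported days differ.
#'
#' @param days Integer vector of reported days.
#' @param seed Optional integer seed for the jitter; the caller's RNG stream
#'   is restored afterwards. `NULL` uses the ambient RNG state.
#' @return Numeric vector of continuized timings, in input order.
#' @export
continuize_times <- function(days, seed = NULL) {
  n <- length(days)
  jittered <- with_local_seed(seed, days + stats::runif(n, -0.5, 0.5))
  if (n < 2L) {
    warning("fewer than 2 samples: returning jittered value(s) unsmoothed")
    return(jittered)
  }
  ord <- order(jittered)            # stable: jitter ties fall back to input order
  rank_ <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, rank_), jittered[ord])
  smoothed <- numeric(n)
  smoothed[ord] <- fit$fitted.values
  smoothed
}
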