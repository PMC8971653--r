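#' Per-gene timing likelihood curve
#'
#' Evaluates, at every window time point of one gene's profile, the Gaussian
#' likelihood that the sample's expression value was drawn from that
#' window's distribution, then scales the curve to unit maximum so that
#' every gene votes with equal weight in the aggregation regardless of its
#' variance. The curve's argmax is the gene's individual timing estimate
#' for the sample; exact ties resolve to the earliest time point.
#'
#' @param sample_expr Scalar expression value of one gene in one sample.
#' @param profile One element of a `gene_profiles` object (vectors `tau`,
#'   `mu`, `sigma`).
#' @return A `density_curve`: list with `tau`, `density` (unit maximum) and
#'   `argmax_tau`.
#' @export
gene_density <- function(sample_expr, profile) {
  if (length(profile$tau) < 2L)
    stop("a profile needs at least 2 windows for estimation")
  d <- stats::dnorm(sample_expr, mean = profile$mu, sd = profile$sigma)
  d <- d / max(d)
  structure(list(tau = profile$tau, density = d,
                 argmax_tau = profile$tau[which.max(d)]),
            class = "density_curve")
}

#' Aggregate per-gene curves into one pseudo-density
#'
#' The unit-scaled per-gene curves are averaged and then consolidated over
#' windows of `w` consecutive grid points, mirroring the window size used to
#' build the profiles. Consolidation windows slide with `stride` (default 1,
#' overlapping, like the profile windows themselves; set `stride = w` for
#' disjoint bins): each bin's value is the mean of the scaled densities over
#' its member grid points and all genes, its time the median grid time of
#' its members. The argmax bin's time is the sample's new estimate, ties
#' resolving to the earliest bin. Sliding consolidation keeps the estimate
#' scale effectively continuous; disjoint bins quantize estimates to a few
#' values and let the iteration degenerate.
#'
#' @param curves List of `density_curve` objects sharing one `tau` grid.
#' @param w Bin size in grid points (the current window size); capped at
#'   half the grid length so the consolidated curve always retains a
#'   localizable maximum.
#' @param stride Step between successive bin start positions (grid points).
#' @return A `combined_curve`: list with `bin_taus`, `density`, `argmax_tau`.
#' @export
combine_curves <- function(curves, w, stride = 1L) {
  taus <- curves[[1]]$tau
  for (cv in curves)
    if (!identical(cv$tau, taus))
      stop("per-gene curves evaluated on different time grids")
  avg <- rowMeans(vapply(curves, function(cv) cv$density,
                         numeric(length(taus))))
  J <- length(taus)
  w <- max(1L, min(w, ceiling(J / 2)))
  starts <- seq.int(1L, J - w + 1L, by = stride)
  if (starts[length(starts)] != J - w + 1L)
    starts <- c(starts, J - w + 1L)
  dens <- vapply(starts, function(s) mean(avg[s:(s + w - 1L)]), numeric(1))
  bin_taus <- vapply(starts, function(s) stats::median(taus[s:(s + w - 1L)]),
                     numeric(1))
  structure(list(bin_taus = bin_taus, density = dens,
                 argmax_tau = bin_taus[which.max(dens)]),
            class = "combined_curve")
}

#' Asynchrony score
#'
#' The sample standard deviation (n - 1 denominator) of the per-gene
#' maximum-likelihood times of one sample, in days. Zero means every marker
#' gene agrees on the timing; large values flag samples whose genes vote for
#' conflicting times and whose aggregate estimate is therefore unreliable.
#'
#' @param gene_maxima Numeric vector of per-gene `argmax_tau` values (days).
#' @return Non-negative scalar, in days.
#' @export
asynchrony_score <- function(gene_maxima) {
  if (length(gene_maxima) < 2L)
    stop("asynchrony needs at least 2 per-gene maxima")
  stats::sd(gene_maxima)
}

#' Flag outliers by a segmented fit of ranked asynchrony scores
#'
#' When asynchrony scores are sorted, reliable cohorts show a shallow ramp
#' followed by a sharp rise for the few discordant samples. A continuous
#' two-segment linear model of score against rank is fitted for every
#' candidate breakpoint; the best breakpoint's score becomes the outlier
#' cutoff. To avoid declaring a kink in kink-free data, the two-segment fit
#' must beat the single-line fit by an F-ratio of at least
#' `config$outlier_f_gate`, otherwise no sample is flagged and the cutoff
#' is `Inf`.
#'
#' @param scores Numeric asynchrony scores, one per sample (n >= 10).
#' @param config An [endotime_config()].
#' @return List with `outlier` (logical vector, input order) and `cutoff`
#'   (days; `Inf` when no breakpoint passes the gate).
#' @export
flag_outliers <- function(scores, config = endotime_config()) {
  n <- length(scores)
  if (n < 10L) stop("outlier detection needs at least 10 samples")
  y <- sort(scores)
  x <- seq_len(n)
  sse_line <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  no_flag <- list(outlier = rep(FALSE, n), cutoff = Inf)
  if (sse_line <= 1e-12) return(no_flag)  # already a perfect single line
  cand <- 3:(n - 3)
  sse <- vapply(cand, function(c_) {
    sum(stats::lm.fit(cbind(1, x, pmax(x - c_, 0)), y)$residuals^2)
  }, numeric(1))
  best <- which.min(sse)
  sse_seg <- sse[best]
  f_ratio <- if (sse_seg == 0) Inf else
    ((sse_line - sse_seg) / 2) / (sse_seg / (n - 4))
  if (!is.finite(f_ratio) && sse_seg > 0) return(no_flag)
  if (f_ratio < config$outlier_f_gate) return(no_flag)
  cutoff <- y[cand[best]]
  list(outlier = scores > cutoff, cutoff = cutoff)
}

# One estimation pass of every sample against a set of profiles.
# Vectorized over samples: per gene a (windows x samples) likelihood matrix.
# Returns per-sample combined-curve estimates, the per-gene argmax matrix
# and the asynchrony scores.
estimate_panel <- function(panel, profiles, w) {
  x <- panel$expr
  genes <- names(profiles)
  missing_genes <- setdiff(genes, colnames(x))
  if (length(missing_genes))
    stop("panel lacks profile gene(s): ", paste(missing_genes, collapse = ", "))
  taus <- profiles[[1]]$tau
  J <- length(taus)
  if (J < 2L) stop("profiles need at least 2 windows")
  n <- nrow(x)
  acc <- matrix(0, J, n)
  argmax <- matrix(NA_real_, n, length(genes),
                   dimnames = list(rownames(x), genes))
  for (g in genes) {
    p <- profiles[[g]]
    z <- (matrix(x[, g], J, n, byrow = TRUE) - p$mu) / p$sigma
    d <- exp(-0.5 * z * z) / p$sigma          # Gaussian kernel; scaled below
    d <- sweep(d, 2, apply(d, 2, max), "/")
    argmax[, g] <- taus[apply(d, 2, which.max)]  # which.max: earliest tie
    acc <- acc + d
  }
  acc <- acc / length(genes)
  # sliding consolidation: mean of w consecutive grid points, stride 1;
  # capped at half the grid — a wider moving average cannot localize a
  # maximum and would collapse every estimate into a single bin
  wb <- max(1L, min(w, ceiling(J / 2)))
  cs <- rbind(0, apply(acc, 2, cumsum))
  idx <- seq_len(J - wb + 1L)
  binned <- (cs[idx + wb, , drop = FALSE] - cs[idx, , drop = FALSE]) / wb
  # median tau of each bin: taus are sorted, so index the middle element(s)
  lo <- idx + (wb - 1L) %/% 2L
  hi <- idx + wb %/% 2L
  bin_taus <- (taus[lo] + taus[hi]) / 2
  est <- bin_taus[apply(binned, 2, which.max)]
  asyn <- apply(argmax, 1, stats::sd)
  list(estimates = est, gene_argmax = argmax, asynchrony = asyn,
       bin_taus = bin_taus)
}
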