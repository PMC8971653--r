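#' Window size schedule
#'
#' The first iteration uses large windows so that unreliable reported timings
#' average out; successive iterations shrink the window to sharpen the
#' temporal profiles, down to a floor that keeps every likelihood curve
#' smooth with a single clear maximum. With the defaults the sizes run
#' 80, 70, 60, 50, 40, 30, 20, 20, ...
#'
#' @param iteration Zero-based iteration index.
#' @param config An [endotime_config()].
#' @return Integer window size for that iteration.
#' @export
#' @examples
#' sapply(0:8, window_schedule)
window_schedule <- function(iteration, config = endotime_config()) {
  stopifnot(iteration >= 0)
  max(config$window_start - config$window_step * as.integer(iteration),
      config$window_min)
}

#' Tricube distance weights within a temporal window
#'
#' Samples near the window's time point should influence its Gaussian
#' summary more than samples near the edge. Weights follow the tricube
#' kernel over temporal distance from `tau`, with the half-width inflated
#' slightly so the outermost member still carries a small positive weight;
#' weights are normalized to sum to one. A window whose members all share
#' one time gets uniform weights.
#'
#' @param member_times Times (days) of the window members.
#' @param tau Window time point (days).
#' @param edge_eps Relative half-width inflation keeping edge weights
#'   positive.
#' @return Numeric weights summing to 1.
#' @export
weight_kernel <- function(member_times, tau, edge_eps = 0.05) {
  d <- abs(member_times - tau)
  h <- max(d)
  if (h == 0) return(rep(1 / length(d), length(d)))
  u <- d / (h * (1 + edge_eps))
  w <- (1 - u^3)^3
  w / sum(w)
}

#' Build windowed Gaussian temporal profiles
#'
#' Samples are sorted by their current timings and grouped into overlapping
#' windows of `w` consecutive samples (stride 1 by default). Each window is
#' summarized, per gene, by a Gaussian: its time point `tau` is the median of
#' the members' timings, and its mean `mu` and standard deviation `sigma`
#' are tricube-weighted by each member's temporal distance from `tau`
#' ([weight_kernel()]), with `sigma` floored at `config$sigma_floor`.
#'
#' @param panel An `expression_panel`.
#' @param times Current per-sample timing vector (days), aligned with the
#'   panel rows.
#' @param w Window size in samples; clamped to the cohort size with a
#'   warning when larger.
#' @param config An [endotime_config()].
#' @param tiebreak Optional secondary sort key for samples whose `times`
#'   tie exactly (typically the continuized reported times, so tied samples
#'   keep a temporally meaningful order); `NULL` falls back to input order.
#' @return A `gene_profiles` object: per gene, vectors `tau`, `mu`, `sigma`
#'   ordered by `tau`, sharing one window layout across genes (kept in
#'   attributes `member_indices` and `taus`).
#' @export
build_windows <- function(panel, times, w, config = endotime_config(),
                          tiebreak = NULL) {
  x <- panel$expr
  n <- nrow(x)
  if (n < 2L) stop("at least 2 samples are required to build windows")
  stopifnot(length(times) == n)
  if (w > n) {
    warning(sprintf("window size %d exceeds cohort size %d; clamping", w, n))
    w <- n
  }
  if (w < 2L) stop("window size must be >= 2")
  ord <- if (is.null(tiebreak)) order(times)  # stable; ties keep input order
         else order(times, tiebreak)
  t_sorted <- times[ord]
  starts <- seq.int(1L, n - w + 1L, by = config$window_stride)
  if (starts[length(starts)] != n - w + 1L)
    starts <- c(starts, n - w + 1L) # ensure the final samples are covered
  n_win <- length(starts)
  genes <- colnames(x)
  taus <- numeric(n_win)
  mu <- matrix(0, n_win, length(genes), dimnames = list(NULL, genes))
  sg <- mu
  members <- vector("list", n_win)
  x_sorted <- x[ord, , drop = FALSE]
  for (j in seq_len(n_win)) {
    idx <- starts[j]:(starts[j] + w - 1L)
    tw <- t_sorted[idx]
    tau <- stats::median(tw)
    wt <- weight_kernel(tw, tau)
    xm <- x_sorted[idx, , drop = FALSE]
    m <- drop(crossprod(wt, xm))
    s <- sqrt(drop(crossprod(wt, sweep(xm, 2, m, "-")^2)))
    taus[j] <- tau
    mu[j, ] <- m
    sg[j, ] <- pmax(s, config$sigma_floor)
    members[[j]] <- ord[idx]
  }
  profiles <- lapply(genes, function(g)
    list(tau = taus, mu = as.vector(mu[, g]), sigma = as.vector(sg[, g])))
  names(profiles) <- genes
  structure(profiles, class = "gene_profiles",
            taus = taus, member_indices = members, w = w)
}

#' @export
print.gene_profiles <- function(x, ...) {
  cat(sprintf("<gene_profiles> %d gene(s), %d window(s), tau %.2f..%.2f days\n",
              length(x), length(x[[1]]$tau),
              min(x[[1]]$tau), max(x[[1]]$tau)))
  invisible(x)
}
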