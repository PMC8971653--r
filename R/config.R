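#' Default marker-gene panel
#'
#' The six-gene timing panel used throughout the package: five genes whose
#' expression rises monotonically across the luteal phase and one that falls.
#' The value is a named character vector mapping gene symbol to direction
#' (`"increasing"` or `"decreasing"`); supply your own vector of the same
#' shape to [endotime_config()] to stage other tissues or panels.
#'
#' @return Named character vector of gene directions.
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  c(IL2RB   = "increasing",
    IGFBP1  = "increasing",
    CXCL14  = "increasing",
    DPP4    = "increasing",
    GPX3    = "increasing",
    SLC15A2 = "decreasing")
}

#' Run configuration
#'
#' Bundles every tunable parameter of the timing pipeline. Defaults reproduce
#' the published training regime: windows of 80 samples shrinking by 10 per
#' iteration to a floor of 20, and convergence once the Euclidean distance
#' between successive timing vectors falls below 2 days.
#'
#' @param panel_genes Named character vector mapping gene symbol to direction
#'   (`"increasing"`/`"decreasing"`); order fixes the column order used
#'   throughout. Default [default_panel()].
#' @param window_start Window (bin) size for the first iteration, in samples.
#' @param window_step Decrease in window size per iteration, in samples.
#' @param window_min Minimum window size, in samples.
#' @param window_stride Stride between successive window start positions, in
#'   samples. The default 1 gives overlapping sliding windows; set equal to
#'   the window size for disjoint bins.
#' @param converge Convergence threshold: Euclidean distance (days) between
#'   the full timing vectors of successive iterations.
#' @param max_iterations Hard cap on iterations; exceeded runs return their
#'   best state flagged as non-converged.
#' @param day_range Integer vector `c(min, max)` of admissible reported days
#'   after the positive ovulation test (LH+).
#' @param sigma_floor Lower bound for any window's weighted SD, on the
#'   unit-scaled expression scale; prevents degenerate likelihood spikes.
#' @param outlier_f_gate Minimum F-ratio by which a two-segment fit of ranked
#'   asynchrony scores must beat a single line before any sample is flagged.
#' @param rng_seed Integer seed driving every stochastic step (the reported-day
#'   jitter); `NULL` leaves the caller's RNG state untouched.
#'
#' @return An object of class `endotime_config` (a validated list).
#' @export
#' @examples
#' cfg <- endotime_config(rng_seed = 1)
#' cfg$window_start
endotime_config <- function(panel_genes = default_panel(),
                            window_start = 80L,
                            window_step = 10L,
                            window_min = 20L,
                            window_stride = 1L,
                            converge = 2,
                            max_iterations = 100L,
                            day_range = c(4L, 12L),
                            sigma_floor = 0.01,
                            outlier_f_gate = 4,
                            rng_seed = NULL) {
  stopifnot(is.character(panel_genes), !is.null(names(panel_genes)))
  if (!all(panel_genes %in% c("increasing", "decreasing")))
    stop("panel gene directions must be 'increasing' or 'decreasing'")
  if (anyDuplicated(names(panel_genes)))
    stop("duplicated gene names in panel")
  window_start <- as.integer(window_start)
  window_step <- as.integer(window_step)
  window_min <- as.integer(window_min)
  if (!(window_start >= window_min && window_min > 0L))
    stop("window schedule requires start >= minimum > 0")
  if (window_step <= 0L) stop("window_step must be positive")
  if (window_stride < 1L) stop("window_stride must be >= 1")
  if (converge <= 0) stop("converge threshold must be positive")
  if (length(day_range) != 2L || day_range[1] >= day_range[2])
    stop("day_range must be c(min, max) with min < max")
  if (sigma_floor <= 0) stop("sigma_floor must be positive")
  structure(list(
    panel_genes = panel_genes,
    window_start = window_start,
    window_step = window_step,
    window_min = window_min,
    window_stride = as.integer(window_stride),
    converge = converge,
    max_iterations = as.integer(max_iterations),
    day_range = as.integer(day_range),
    sigma_floor = sigma_floor,
    outlier_f_gate = outlier_f_gate,
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "endotime_config")
}

#' @export
print.endotime_config <- function(x, ...) {
  cat("<endotime_config>\n")
  cat("  panel:", paste0(names(x$panel_genes),
                         ifelse(x$panel_genes == "decreasing", " (-)", " (+)"),
                         collapse = ", "), "\n")
  cat(sprintf("  windows: %d -> %d by %d (stride %d)\n",
              x$window_start, x$window_min, x$window_step, x$window_stride))
  cat(sprintf("  converge: %.3g days | max iterations: %d\n",
              x$converge, x$max_iterations))
  cat(sprintf("  day range: %d..%d | sigma floor: %.3g\n",
              x$day_range[1], x$day_range[2], x$sigma_floor))
  invisible(x)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
# seed == NULL runs expr under the ambient RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
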