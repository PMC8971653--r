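#' Default simulation specification
#'
#' A six-gene synthetic panel mirroring the marker panel's qualitative
#' behaviour: five genes rising monotonically across days 4-12 and one
#' falling, as a mixture of linear trends and logistic (sigmoid) switches
#' with midpoints staggered across days 5-11. The default noise regime is
#' the one the whole package is exercised under: reported days deviate from
#' the true tissue age by rounded Normal(0, 2 days) noise, expression
#' carries Normal(0, 0.05) noise on the unit scale, and batches add small
#' gene-specific offsets.
#'
#' @param n_samples Cohort size (default 250).
#' @param day_range Days spanned, `c(min, max)` (default 4-12).
#' @param timing_noise_sd SD (days) of the reported-day noise (default 2).
#' @param expr_noise_sd SD of per-observation expression noise on the
#'   latent unit scale (default 0.05).
#' @param n_batches Number of qPCR batches (default 3).
#' @param batch_offset_sd SD of the per-batch, per-gene additive offsets
#'   (default 0.05).
#' @param rng_seed Integer seed for [simulate_cohort()].
#' @return A `sim_spec` list; its `gene_models` data frame has one row per
#'   gene: `gene`, `shape` (`"linear"`/`"logistic"`), `direction`,
#'   `midpoint` (days), `steepness` (per day), `baseline`, `amplitude`.
#' @export
default_sim_spec <- function(n_samples = 250L,
                             day_range = c(4L, 12L),
                             timing_noise_sd = 2,
                             expr_noise_sd = 0.05,
                             n_batches = 3L,
                             batch_offset_sd = 0.05,
                             rng_seed = 1L) {
  gene_models <- data.frame(
    gene      = c("IL2RB", "IGFBP1", "CXCL14", "DPP4", "GPX3", "SLC15A2"),
    shape     = c("logistic", "logistic", "linear", "logistic", "linear",
                  "logistic"),
    direction = c("increasing", "increasing", "increasing", "increasing",
                  "increasing", "decreasing"),
    midpoint  = c(7, 9.5, 8, 11, 8, 5.5),
    steepness = c(1.2, 1.0, 0.125, 0.8, 0.125, 1.5),
    baseline  = c(0.15, 0.10, 0.10, 0.15, 0.20, 0.15),
    amplitude = c(0.70, 0.75, 0.75, 0.70, 0.65, 0.70),
    stringsAsFactors = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 day_range = as.integer(day_range),
                 gene_models = gene_models,
                 timing_noise_sd = timing_noise_sd,
                 expr_noise_sd = expr_noise_sd,
                 n_batches = as.integer(n_batches),
                 batch_offset_sd = batch_offset_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_spec")
}

# Noise-free latent expression of one gene model at times t.
# Linear genes ramp at `steepness` per day through (midpoint, baseline +
# amplitude/2); logistic genes switch over ~4/steepness days around the
# midpoint. Decreasing genes mirror the shape.
gene_model_value <- function(model, t) {
  v <- switch(model$shape,
    linear = model$baseline + model$amplitude *
      (0.5 + model$steepness * (t - model$midpoint)),
    logistic = model$baseline + model$amplitude /
      (1 + exp(-model$steepness * (t - model$midpoint))),
    stop("unknown gene model shape: ", model$shape))
  if (model$direction == "decreasing")
    v <- 2 * model$baseline + model$amplitude - v
  v
}

#' Simulate a cohort with known ground truth
#'
#' True tissue ages are drawn uniformly over the day range. Reported days
#' add Normal(0, `timing_noise_sd`) noise, round to whole days and clip to
#' the range (the clinic only schedules biopsies inside it). Expression is
#' the gene model evaluated at the *true* time plus Normal(0,
#' `expr_noise_sd`) noise plus the sample's batch offset, then sign-inverted
#' onto the delta-CT scale. With both noise SDs at zero, expression is an
#' exact function of true time and the reported day is the rounded truth.
#'
#' @param spec A `sim_spec` from [default_sim_spec()].
#' @return A `sim_cohort`: list with `cohort` (a `cohort_table` ready for
#'   [endotime_train()]), `true_times` (days), `latent` (noise-free
#'   samples x genes latent expression), and `spec`.
#' @export
simulate_cohort <- function(spec = default_sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"),
            spec$timing_noise_sd >= 0, spec$expr_noise_sd >= 0)
  with_local_seed(spec$rng_seed, {
    n <- spec$n_samples
    dr <- spec$day_range
    true_times <- stats::runif(n, dr[1], dr[2])
    reported <- as.integer(pmin(pmax(
      round(true_times + stats::rnorm(n, 0, spec$timing_noise_sd)),
      dr[1]), dr[2]))
    batch <- paste0("B", 1 + (seq_len(n) - 1L) %% spec$n_batches)
    genes <- spec$gene_models$gene
    offsets <- matrix(stats::rnorm(spec$n_batches * length(genes),
                                   0, spec$batch_offset_sd),
                      spec$n_batches, length(genes),
                      dimnames = list(paste0("B", seq_len(spec$n_batches)),
                                      genes))
    latent <- sapply(seq_along(genes), function(j)
      gene_model_value(spec$gene_models[j, ], true_times))
    colnames(latent) <- genes
    expr <- latent +
      matrix(stats::rnorm(n * length(genes), 0, spec$expr_noise_sd),
             n, length(genes)) +
      offsets[batch, , drop = FALSE]
    delta_ct <- -expr                     # back onto the delta-CT scale
    df <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                     batch = batch, reported_day = reported,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(delta_ct))
    cfg <- endotime_config(
      panel_genes = stats::setNames(spec$gene_models$direction, genes),
      day_range = dr)
    structure(list(cohort = as_cohort_table(df, cfg),
                   true_times = true_times,
                   latent = latent,
                   spec = spec),
              class = "sim_cohort")
  })
}

#' Paired RNA-seq TPM matrix for a simulated cohort
#'
#' Produces TPM values carrying the same latent temporal signal as the
#' cohort's qPCR values but on a different scale and with independent
#' noise: `TPM = 2^(a * latent + b + Normal(0, tau)) - 1`, floored at zero,
#' with per-gene affine constants `a`, `b`. With `tau = 0`, `a = 1`,
#' `b = 0`, `log2(TPM + 1)` reproduces the latent expression exactly.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param tau SD of the log2-scale TPM noise (default 0.1).
#' @param a,b Per-gene affine constants recycled across genes; defaults put
#'   TPM in a realistic tens-to-hundreds range.
#' @param seed Optional integer seed for the TPM noise.
#' @return Numeric genes x samples TPM matrix.
#' @export
paired_tpm <- function(sim, tau = 0.1, a = 3, b = 5, seed = NULL) {
  stopifnot(inherits(sim, "sim_cohort"), tau >= 0)
  genes <- colnames(sim$latent)
  a <- rep_len(a, length(genes))
  b <- rep_len(b, length(genes))
  with_local_seed(seed, {
    log2tpm <- t(sim$latent) * a + b +
      matrix(stats::rnorm(length(sim$latent), 0, tau),
             length(genes), nrow(sim$latent))
    tpm <- pmax(2^log2tpm - 1, 0)
    rownames(tpm) <- genes
    colnames(tpm) <- sim$cohort$sample_id
    tpm
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d samples, %d genes, days %d..%d (timing SD %.2g d)\n",
    nrow(x$cohort), nrow(x$spec$gene_models),
    x$spec$day_range[1], x$spec$day_range[2], x$spec$timing_noise_sd))
  invisible(x)
}
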