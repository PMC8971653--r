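#' Calibration reference from a trained qPCR panel
#'
#' Records, per panel gene, the mean and standard deviation of the
#' preprocessed qPCR expression values of a training cohort. RNA-seq values
#' moment-matched onto this reference ([tpm_to_pseudo_qpcr()]) can then be
#' scored against the profiles trained on that cohort.
#'
#' @param panel A preprocessed `expression_panel` (the training cohort).
#' @return A `calibration_ref`: list with named numeric vectors `mean` and
#'   `sd`.
#' @export
calibration_ref <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  m <- colMeans(panel$expr)
  s <- apply(panel$expr, 2, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene(s) in calibration reference: ",
         paste(names(s)[s == 0], collapse = ", "))
  structure(list(mean = m, sd = s), class = "calibration_ref")
}

#' Transform RNA-seq TPM into pseudo-qPCR expression
#'
#' Per panel gene: log2(TPM + pseudocount), standardize across the cohort's
#' samples, then rescale to the training reference's mean and SD. The output
#' lives on the same scale as the preprocessed qPCR panel the profiles were
#' trained on, so a single fixed-profile estimation pass applies directly.
#'
#' @param tpm Numeric genes x samples matrix of TPM values, row names being
#'   gene symbols; must contain every gene in `ref`.
#' @param ref A `calibration_ref`.
#' @param pseudocount Added to TPM before the log2 transform (default 1).
#' @param directions Per-gene direction flags for the resulting panel;
#'   defaults to [default_panel()] restricted to the reference genes.
#' @return An `expression_panel` (single batch).
#' @export
tpm_to_pseudo_qpcr <- function(tpm, ref, pseudocount = 1,
                               directions = NULL) {
  stopifnot(inherits(ref, "calibration_ref"))
  genes <- names(ref$mean)
  absent <- setdiff(genes, rownames(tpm))
  if (length(absent))
    stop("TPM matrix lacks panel gene(s): ", paste(absent, collapse = ", "))
  if (any(tpm[genes, ] < 0)) stop("TPM values must be non-negative")
  y <- log2(tpm[genes, , drop = FALSE] + pseudocount)
  out <- matrix(NA_real_, ncol(y), length(genes),
                dimnames = list(colnames(y), genes))
  for (g in genes) {
    v <- y[g, ]
    s <- stats::sd(v)
    if (is.na(s) || s == 0)
      stop("gene ", g, " has zero variance across RNA-seq samples")
    out[, g] <- (v - mean(v)) / s * ref$sd[[g]] + ref$mean[[g]]
  }
  if (is.null(directions)) {
    directions <- default_panel()[genes]
    directions[is.na(directions)] <- "increasing"
    names(directions) <- genes
  }
  structure(list(expr = out,
                 batch = rep("rnaseq", nrow(out)),
                 directions = directions),
            class = "expression_panel")
}

#' Estimate timings against frozen profiles
#'
#' A single estimation pass: every sample is scored against previously
#' trained temporal profiles, without any iteration and without rescaling
#' onto the new cohort's reported days — estimates remain on the training
#' cohort's time axis, which is what makes qPCR- and RNA-seq-derived
#' estimates for the same samples directly comparable. Used for RNA-seq
#' cohorts and for small batches that cannot support retraining. Works from
#' a single sample upwards.
#'
#' @param panel An `expression_panel` (pseudo-qPCR or preprocessed qPCR)
#'   whose genes cover the profile genes.
#' @param profiles A `gene_profiles` object from [run_endotime()] (or
#'   [read_profiles()]).
#' @param config An [endotime_config()].
#' @param reported_day Optional integer vector of reported days, recorded in
#'   the output but unused by the estimation.
#' @return A `timing_records` data frame; `eLH` is the raw argmax on the
#'   training time axis, `rLH_continuous` is `NA`.
#' @export
estimate_fixed <- function(panel, profiles, config = endotime_config(),
                           reported_day = NULL) {
  stopifnot(inherits(panel, "expression_panel"),
            inherits(profiles, "gene_profiles"))
  genes <- names(profiles)
  if (!setequal(intersect(genes, colnames(panel$expr)), genes))
    stop("panel genes do not cover the profile genes")
  w <- attr(profiles, "w")
  if (is.null(w)) w <- config$window_min
  res <- estimate_panel(panel, profiles, w)
  n <- nrow(panel$expr)
  asyn <- if (length(genes) >= 2L) res$asynchrony else rep(NA_real_, n)
  out <- if (n >= 10L && length(genes) >= 2L) flag_outliers(asyn, config)
         else list(outlier = rep(NA, n), cutoff = NA_real_)
  records <- data.frame(
    sample_id = rownames(panel$expr),
    reported_day = if (is.null(reported_day)) NA_integer_
                   else as.integer(reported_day),
    rLH_continuous = NA_real_,
    eLH = res$estimates,
    asynchrony = asyn,
    stringsAsFactors = FALSE
  )
  am <- res$gene_argmax
  colnames(am) <- paste0("argmax_", colnames(am))
  records <- cbind(records, as.data.frame(am), row.names = NULL)
  records$outlier <- out$outlier
  class(records) <- c("timing_records", "data.frame")
  attr(records, "outlier_cutoff") <- out$cutoff
  records
}
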