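#' Restrict an expression panel to a gene subset
#'
#' @param panel An `expression_panel`.
#' @param genes Character vector of genes to keep (order respected).
#' @return The restricted `expression_panel`.
#' @export
subset_panel <- function(panel, genes) {
  stopifnot(inherits(panel, "expression_panel"))
  absent <- setdiff(genes, colnames(panel$expr))
  if (length(absent))
    stop("gene(s) not in panel: ", paste(absent, collapse = ", "))
  structure(list(expr = panel$expr[, genes, drop = FALSE],
                 batch = panel$batch,
                 directions = panel$directions[genes]),
            class = "expression_panel")
}

# config whose panel is restricted to a gene subset
config_for_genes <- function(config, genes) {
  config$panel_genes <- config$panel_genes[genes]
  config
}

#' Leave-one-out timing estimation
#'
#' Re-runs the full iterative fit on the sub-panel that excludes one gene,
#' leaving the held-out gene's expression untouched. Used to check that the
#' inferred ordering sharpens temporal profiles of genes that did not
#' inform it.
#'
#' @param panel An `expression_panel` (all genes).
#' @param raw_days Integer reported days.
#' @param held_out Gene symbol to exclude.
#' @param config An [endotime_config()].
#' @return An `endotime_fit` for the sub-panel; see [run_endotime()].
#' @export
loo_estimate <- function(panel, raw_days, held_out,
                         config = endotime_config()) {
  genes <- colnames(panel$expr)
  if (!held_out %in% genes) stop("held-out gene not in panel: ", held_out)
  keep <- setdiff(genes, held_out)
  if (length(keep) < 2L)
    stop("sub-panel needs at least 2 genes after holding out ", held_out)
  run_endotime(subset_panel(panel, keep), raw_days,
               config_for_genes(config, keep))
}

#' Order a held-out gene's expression three ways
#'
#' Builds the three vectors compared by the leave-one-out test: the
#' held-out gene's expression values ordered by reported times (`v_P`), by
#' the timing estimates (`v_E`), and by expression level itself (`v_G`,
#' ascending for increasing genes, descending otherwise — the "perfect"
#' order under monotone regulation). Within-day ties in the reported times
#' are resolved in the gene's direction, i.e. in favour of agreement with
#' `v_G`: of all possible tie resolutions this one yields the largest
#' p-value in [wilcoxon_order_test()], so significance is conservative.
#'
#' @param expr_heldout Expression values of the held-out gene.
#' @param reported_days Integer reported days.
#' @param eLH Timing estimates from the sub-panel fit.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return List with `v_P`, `v_E`, `v_G` (permutations of `expr_heldout`).
#' @export
order_vectors <- function(expr_heldout, reported_days, eLH, direction) {
  stopifnot(length(expr_heldout) == length(reported_days),
            length(expr_heldout) == length(eLH),
            direction %in% c("increasing", "decreasing"))
  asc <- direction == "increasing"
  v_G <- sort(expr_heldout, decreasing = !asc)
  v_E <- expr_heldout[order(eLH)]
  tie_key <- if (asc) expr_heldout else -expr_heldout
  v_P <- expr_heldout[order(reported_days, tie_key)]
  list(v_P = v_P, v_E = v_E, v_G = v_G)
}

# Exact conditional one-sided rank-sum p-value, P(rank sum of a >= observed)
# under random reassignment of the pooled values. Midranks handle ties; the
# distribution of the rank sum is built by subset-sum dynamic programming
# over doubled ranks (integers even with .5 midranks).
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r2 <- as.integer(round(2 * rank(pooled)))
  na <- length(a)
  w_obs <- sum(r2[seq_along(a)])
  S <- sum(r2)
  f <- matrix(0, na + 1L, S + 1L)   # f[k+1, s+1] = #subsets of size k, sum s
  f[1L, 1L] <- 1
  for (r in r2) {
    kmax <- na
    for (k in kmax:1) {
      src <- f[k, 1:(S + 1L - r)]
      if (any(src != 0))
        f[k + 1L, (r + 1L):(S + 1L)] <- f[k + 1L, (r + 1L):(S + 1L)] + src
    }
  }
  tail_counts <- f[na + 1L, ]
  sum(tail_counts[(w_obs + 1L):(S + 1L)]) / choose(length(pooled), na)
}

#' One-sided rank-sum test of ordering improvement
#'
#' Tests whether the held-out gene's expression deviates more from its
#' perfect order when samples are arranged by reported times than when
#' arranged by the timing estimates: with `a = |v_G - v_P|` and
#' `b = |v_G - v_E|` elementwise, the one-sided Wilcoxon rank-sum
#' (Mann-Whitney) p-value for `a` stochastically greater than `b`. For
#' n <= 12 the exact conditional distribution is enumerated (ties handled
#' via midranks); larger samples use the normal approximation with tie
#' correction. A small p means the estimates order the samples closer to
#' the perfect order than the reported times do.
#'
#' @param v_P,v_E,v_G Vectors from [order_vectors()], equal length n >= 2.
#' @return One-sided p-value in (0, 1].
#' @export
wilcoxon_order_test <- function(v_P, v_E, v_G) {
  n <- length(v_G)
  stopifnot(length(v_P) == n, length(v_E) == n, n >= 2L)
  a <- abs(v_G - v_P)
  b <- abs(v_G - v_E)
  if (all(a == 0) && all(b == 0)) return(1)  # no evidence either way
  if (n <= 12L) return(exact_ranksum_p(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value)
}

#' Bonferroni correction
#'
#' @param p_values Vector of raw p-values in (0, 1].
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return Adjusted p-values, `min(1, p * m)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  pmin(1, p_values * m)
}

#' Leave-one-out validation of the whole panel
#'
#' For every gene: refit on the remaining genes ([loo_estimate()]), order
#' the held-out expression three ways ([order_vectors()]), test whether the
#' estimates beat the reported times ([wilcoxon_order_test()]), and
#' Bonferroni-correct across genes.
#'
#' @param panel An `expression_panel`.
#' @param raw_days Integer reported days.
#' @param config An [endotime_config()].
#' @return A data frame with one row per gene: `gene`, `p_raw`, `p_adj`.
#' @export
loo_validate <- function(panel, raw_days, config = endotime_config()) {
  genes <- colnames(panel$expr)
  p_raw <- vapply(genes, function(g) {
    fit <- loo_estimate(panel, raw_days, g, config)
    v <- order_vectors(panel$expr[, g], raw_days, fit$records$eLH,
                       panel$directions[[g]])
    wilcoxon_order_test(v$v_P, v$v_E, v$v_G)
  }, numeric(1))
  data.frame(gene = genes, p_raw = unname(p_raw),
             p_adj = unname(bonferroni_adjust(p_raw)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Greedy marker-panel reduction
#'
#' Starting from a larger candidate panel, repeatedly removes the gene
#' whose removal least affects the inferred sample ordering: at each step
#' the current panel's fit supplies reference ranks, every candidate gene
#' is dropped in turn and the Spearman correlation of the reduced fit's
#' ranks against the reference is computed; the gene with the highest
#' correlation is removed. Stops at `target_size` genes, or earlier with a
#' warning if the best achievable correlation falls below `corr_floor`.
#'
#' @param panel An `expression_panel` with at least `target_size + 1` genes.
#' @param raw_days Integer reported days.
#' @param target_size Number of genes to keep (>= 2).
#' @param config An [endotime_config()] covering the panel's genes.
#' @param corr_floor Minimum acceptable rank correlation per step.
#' @return List with `removed` (data frame: step, gene, correlation) and
#'   `final_genes`.
#' @export
reduce_panel <- function(panel, raw_days, target_size,
                         config = endotime_config(), corr_floor = 0.9) {
  stopifnot(target_size >= 2L)
  genes <- colnames(panel$expr)
  removed <- list()
  step <- 0L
  while (length(genes) > target_size) {
    step <- step + 1L
    cfg <- config_for_genes(config, genes)
    ref_fit <- run_endotime(subset_panel(panel, genes), raw_days, cfg)
    ref_rank <- rank(ref_fit$records$eLH)
    cors <- vapply(genes, function(g) {
      keep <- setdiff(genes, g)
      fit <- run_endotime(subset_panel(panel, keep), raw_days,
                          config_for_genes(config, keep))
      stats::cor(ref_rank, rank(fit$records$eLH), method = "spearman")
    }, numeric(1))
    best <- names(cors)[which.max(cors)]
    if (max(cors) < corr_floor) {
      warning(sprintf(
        "stopping at %d genes: removing any further gene drops rank correlation to %.3f",
        length(genes), max(cors)))
      break
    }
    removed[[step]] <- data.frame(step = step, gene = best,
                                  correlation = unname(max(cors)),
                                  stringsAsFactors = FALSE)
    genes <- setdiff(genes, best)
  }
  list(removed = if (length(removed)) do.call(rbind, removed)
                 else data.frame(step = integer(), gene = character(),
                                 correlation = numeric()),
       final_genes = genes)
}

#' Variance explained by time in a transcriptome matrix
#'
#' Principal component analysis of samples over a (transformed) expression
#' matrix, reporting how much variance the first two components capture and
#' how strongly the timing estimates align with the PC1-PC2 plane (the
#' multiple correlation of the estimates regressed on the two scores).
#'
#' @param expr_matrix Numeric genes x samples matrix, already on a
#'   variance-stabilized scale (see [log2_tpm()]).
#' @param eLH Timing estimates, one per sample.
#' @return List with `var_explained` (fractions for PC1 and PC2),
#'   `pc12_fraction` (their sum) and `time_correlation` (multiple
#'   correlation of `eLH` with the PC1-PC2 scores).
#' @export
pca_time_variance <- function(expr_matrix, eLH) {
  n <- ncol(expr_matrix)
  if (n < 3L) stop("PCA check needs at least 3 samples")
  stopifnot(length(eLH) == n)
  pca <- stats::prcomp(t(expr_matrix), center = TRUE, scale. = FALSE)
  frac <- pca$sdev^2 / sum(pca$sdev^2)
  s <- pca$x[, 1:2, drop = FALSE]
  r2 <- summary(stats::lm(eLH ~ s))$r.squared
  list(var_explained = frac[1:2],
       pc12_fraction = sum(frac[1:2]),
       time_correlation = sqrt(r2))
}

#' log2(TPM + pseudocount) transform
#'
#' @param tpm Non-negative numeric matrix.
#' @param pseudocount Added before the log (default 1).
#' @return Transformed matrix.
#' @export
log2_tpm <- function(tpm, pseudocount = 1) {
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  log2(tpm + pseudocount)
}
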