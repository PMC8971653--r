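# Shared fixtures: small cohorts and scaled-down loop configs so unit tests
# stay fast; acceptance tests use the full default regime.

# Window schedule scaled to small cohorts (n ~ 60-100).
small_config <- function(n_genes = 6, seed = 1) {
  genes <- names(default_panel())[seq_len(n_genes)]
  endotime_config(panel_genes = default_panel()[genes],
                  window_start = 24L, window_step = 4L, window_min = 8L,
                  converge = 1, rng_seed = seed)
}

small_sim <- function(n = 80, seed = 1, timing_sd = 2, expr_sd = 0.05,
                      n_batches = 3) {
  simulate_cohort(default_sim_spec(
    n_samples = n, rng_seed = seed,
    timing_noise_sd = timing_sd, expr_noise_sd = expr_sd,
    n_batches = n_batches))
}

quiet_fit <- function(...) suppressWarnings(endotime_train(...))

# Hand-built three-sample cohort data frame for io tests.
tiny_cohort_df <- function() {
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   batch = c("A", "A", "B"),
                   reported_day = c(8L, 9L, 10L),
                   stringsAsFactors = FALSE)
  for (g in names(default_panel()))
    df[[g]] <- c(-2, -4, -6) + stats::runif(3, -0.1, 0.1)
  df
}
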