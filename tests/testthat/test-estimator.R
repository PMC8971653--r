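mk_profile <- function(tau, mu, sigma) list(tau = tau, mu = mu, sigma = sigma)

test_that("gene likelihood curves peak where expression matches the profile", {
  p <- mk_profile(tau = c(5, 8, 11), mu = c(0.2, 0.5, 0.8), sigma = rep(0.05, 3))
  # x equal to one window's mean: argmax at that window
  expect_equal(gene_density(0.5, p)$argmax_tau, 8)
  # x beyond every mean: argmax at the boundary window
  expect_equal(gene_density(0.95, p)$argmax_tau, 11)
  expect_equal(gene_density(0.05, p)$argmax_tau, 5)
  # direct pdf evaluation oracle at x = 0.55
  cv <- gene_density(0.55, p)
  d_oracle <- stats::dnorm(0.55, p$mu, p$sigma)
  expect_equal(cv$density, d_oracle / max(d_oracle), tolerance = 1e-12)
  expect_equal(cv$argmax_tau, 8)
  expect_equal(max(cv$density), 1)
  # argmax invariant under a common rescaling of every sigma
  for (c_ in c(0.5, 2, 7)) {
    p2 <- mk_profile(p$tau, p$mu, p$sigma * c_)
    expect_equal(gene_density(0.55, p2)$argmax_tau, cv$argmax_tau)
  }
})

test_that("curve aggregation finds the consensus peak", {
  tau <- seq(4, 12, length.out = 41)
  peaked <- exp(-(tau - 9)^2)                      # unit-max at tau = 9
  flat <- rep(1, 41)
  mk <- function(d) structure(list(tau = tau, density = d / max(d),
                                   argmax_tau = tau[which.max(d)]),
                              class = "density_curve")
  six <- replicate(6, mk(peaked), simplify = FALSE)
  cc <- combine_curves(six, w = 5)
  expect_lt(abs(cc$argmax_tau - 9), 0.5)
  # five flat curves + one peaked: the peaked gene decides
  cc2 <- combine_curves(c(replicate(5, mk(flat), simplify = FALSE),
                          list(mk(peaked))), w = 5)
  expect_lt(abs(cc2$argmax_tau - 9), 0.5)
  # argmax stays inside the grid
  expect_gte(cc$argmax_tau, min(tau)); expect_lte(cc$argmax_tau, max(tau))
  # direct averaging oracle for the sliding bins
  curves <- list(mk(peaked), mk(flat))
  cc3 <- combine_curves(curves, w = 5)
  avg <- (peaked / max(peaked) + flat / max(flat)) / 2
  dens_oracle <- sapply(1:(41 - 5 + 1), function(s) mean(avg[s:(s + 4)]))
  taus_oracle <- sapply(1:(41 - 5 + 1), function(s) median(tau[s:(s + 4)]))
  expect_equal(cc3$density, dens_oracle, tolerance = 1e-12)
  expect_equal(cc3$bin_taus, taus_oracle, tolerance = 1e-12)
  # mismatched grids are rejected
  bad <- mk(peaked); bad$tau <- tau + 0.1
  expect_error(combine_curves(list(mk(peaked), bad), w = 5), "grids")
})

test_that("asynchrony is the sample SD of the per-gene maxima", {
  expect_equal(asynchrony_score(rep(8, 6)), 0)
  expect_equal(asynchrony_score(c(6, 8, 10, 6, 8, 10)), sqrt(16 / 5))
  v <- c(7, 7, 7, 7, 7, 11)
  expect_equal(asynchrony_score(v), sqrt(sum((v - mean(v))^2) / 5))
  # permutation- and translation-invariant
  set.seed(8)
  m <- runif(6, 4, 12)
  expect_equal(asynchrony_score(sample(m)), asynchrony_score(m))
  expect_equal(asynchrony_score(m + 3.7), asynchrony_score(m))
})

test_that("segmented fit flags the steep tail and gates kink-free data", {
  cfg <- endotime_config()
  # shallow ramp then steep rise: exactly the 5 tail samples flagged
  scores <- c(0.01 * (1:45), 0.45 + 1.0 * (1:5))
  out <- flag_outliers(scores, cfg)
  expect_identical(which(out$outlier), 46:50)
  expect_equal(out$cutoff, scores[45])
  # all-equal scores: no kink, nothing flagged
  out2 <- flag_outliers(rep(0.3, 20), cfg)
  expect_false(any(out2$outlier)); expect_identical(out2$cutoff, Inf)
  # a single straight slope: F-gate keeps it unflagged
  out3 <- flag_outliers(0.05 * (1:30), cfg)
  expect_false(any(out3$outlier))
  expect_error(flag_outliers(1:5, cfg), "at least 10")
})

test_that("segmented breakpoint matches an exhaustive per-candidate lm scan", {
  cfg <- endotime_config()
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(12:40, 1)
    kink <- sample(5:(n - 5), 1)
    y <- c(0.02 * (1:kink),
           0.02 * kink + cumsum(runif(n - kink, 0.2, 0.8))) +
      rnorm(n, 0, 0.01)
    scores <- sample(y)                      # scramble input order
    out <- flag_outliers(scores, cfg)
    ys <- sort(scores); x <- seq_len(n)
    sse <- sapply(3:(n - 3), function(c_)
      sum(resid(stats::lm(ys ~ x + pmax(x - c_, 0)))^2))
    best_rank <- (3:(n - 3))[which.min(sse)]
    sse_line <- sum(resid(stats::lm(ys ~ x))^2)
    f <- ((sse_line - min(sse)) / 2) / (min(sse) / (n - 4))
    if (f >= cfg$outlier_f_gate) {
      expect_equal(out$cutoff, ys[best_rank], tolerance = 1e-9)
      expect_identical(out$outlier, scores > ys[best_rank])
    } else {
      expect_identical(out$cutoff, Inf)
    }
  }
})
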