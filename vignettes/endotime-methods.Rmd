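---
title: "Methods: windowed likelihood staging of luteal-phase endometrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed likelihood staging of luteal-phase endometrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotime)
```

## The problem

Endometrial biopsies taken during the luteal phase are conventionally dated
by the patient-reported day of the urinary LH surge (rLH+). Self-reported
timings are noisy — ovulation tests are read at home, surges can be missed
by a day or more — and the tissue's molecular state is what actually
matters for questions such as locating the window of implantation. This
package re-dates each biopsy on a continuous day scale (eLH+) from the
expression of a small panel of marker genes whose expression changes
monotonically across days 4–12 after the surge: by default five rising
genes and one falling one, measured by RTq-PCR as ΔCT against the *L19*
reference gene, or by RNA-seq after calibration.

## Model and procedure

**Preprocessing.** ΔCT values fall as expression rises, so they are
sign-inverted, min–max scaled to [0, 1] per gene, and batch-corrected by a
per-gene additive constant that equalizes every batch's mean to the cohort
grand mean. Only location is touched — the correction is deliberately
modest; variances and within-batch ordering are preserved, and applying it
twice changes nothing. Integer reported days are *continuized*: uniform
jitter on (−0.5, 0.5) is added, the jittered values are sorted and replaced
by their fitted values from an ordinary least-squares regression on rank
(1…n). This spaces samples evenly through the time course while keeping
each close to its reported day, and provably never reorders samples whose
reported days differ. Regressing on rank rather than on the reported day
itself is a reconstruction choice: rank is the only regressor that yields
the even spacing the procedure is meant to produce, and it is exposed in
the code as the single smoothing step rather than hidden in a pipeline.

**Temporal profiles.** Given current timings, samples are sorted and
grouped into overlapping windows of `w` consecutive samples (stride 1).
Each window summarizes one gene's expression as a Gaussian: its time point
τ is the median of the members' timings; the mean μ and standard deviation
σ are weighted by each member's temporal distance from τ using a tricube
kernel, with the half-width inflated by 5% so the outermost member keeps a
small positive weight. The kernel's form is a design choice — the
requirement is only that central samples outweigh peripheral ones, and
tricube is the standard kernel for windowed smoothing. σ is floored at
`sigma_floor` (default 0.01 on the unit expression scale) so no window ever
yields a degenerate, infinitely spiky likelihood. An alternative reading of
the weighting — distance in *expression* from the mean rather than in time
from the window centre — is possible; the temporal reading is implemented
because it is the one consistent with centre-versus-edge weighting.

**Estimation.** For one sample and one gene, the likelihood of the
observed expression under each window's Gaussian, evaluated across all
windows, forms a curve over the window times. Every curve is scaled to
unit maximum, so each gene votes with equal weight regardless of how tight
its profile is. The per-gene curve maxima are the per-gene timing votes;
their sample standard deviation is the sample's **asynchrony score**
(days). The six scaled curves are averaged and then consolidated by a
moving average of `w` consecutive grid points — the same width used to
build the profiles — whose maximum gives the sample's new timing. The
consolidation windows slide with stride 1, exactly like the profile
windows; disjoint bins are available (`combine_curves(..., stride = w)`)
but quantize every estimate to a handful of values, which destroys the
sample ordering that the next iteration depends on. For the same reason
the moving-average width is capped at half the grid: a wider average spans
the entire curve and collapses every estimate into a single bin. The cap
is inactive at the intended cohort scale (n ≈ 250) and only protects
smaller cohorts run with the default schedule, which additionally triggers
a warning suggesting `window_start` near n/3.

**Iteration.** The window size starts at 80 samples and shrinks by 10 per
iteration to a floor of 20 — wide early windows average out unreliable
reported timings, narrow late windows sharpen the profiles, and the floor
keeps each likelihood curve smooth with a single clear maximum.
Convergence is declared once the Euclidean distance between successive
timing vectors (in days, over the whole cohort vector) drops below 2 *and*
the schedule has reached its floor; requiring both prevents a lucky early
iteration at coarse windows from stopping the fit. A guard of 100
iterations returns the last state with a warning if the loop fails to
settle; in practice default-scale synthetic cohorts converge in 7–25
iterations.

**Tie handling.** Wherever two samples carry exactly equal current
estimates — typically pile-ups at the ends of the time axis, where the
likelihood is flat — they are ordered by their continuized reported times,
both when sorting for window construction and in the final rescaling.
This is the only remaining timing information at a flat likelihood;
breaking such ties by arbitrary input order can let early coarse
iterations collapse into a degenerate bimodal state that the loop never
escapes.

**Rescaling.** The loop optimizes the *order* of samples, so raw timings
drift off the calendar scale. After the last iteration the sample ranked
r among the estimates receives the r-th order statistic of the continuized
reported times: the output multiset equals the reported-continuous
multiset exactly and the transform is monotone in the estimates.

**Outlier flagging.** Sorted asynchrony scores are fitted with a
continuous two-segment linear model over rank, scanning every breakpoint
candidate; the score at the best breakpoint becomes the cutoff and higher
scores are flagged. An ungated two-segment fit always "finds" a kink, so
the fit must beat a single line by an F-ratio of at least 4 (configurable)
or nothing is flagged. The method presumes the characteristic shape of a
reliable cohort — a shallow ramp with a short steep tail. Cohorts whose
score distribution has a long flat stretch near zero (common in synthetic
data, where many samples sit at the axis ends and all six votes coincide)
place the breakpoint low and flag many samples; the reported cutoff should
always be inspected alongside the flags.

## RNA-seq calibration

A trained model stores, besides the profiles, the per-gene mean and SD of
the preprocessed training expression. RNA-seq TPM values of the panel
genes are log2-transformed with a pseudocount of 1 (zeros are otherwise
undefined; the pseudocount is configurable), standardized across the new
cohort's samples, and rescaled to the stored reference moments. The new
cohort's own moments are used for standardization because they are the
only moment estimates available at estimation time. Estimation against
frozen profiles is then a single deterministic pass with no iteration and
no rescaling — estimates stay on the training time axis, which is what
makes qPCR- and RNA-seq-derived estimates for the same samples directly
comparable down to a single sample.

## Leave-one-out validation

For each gene the fit is repeated on the other five genes and the held-out
gene's expression is ordered three ways: by reported times (v_P), by the
timing estimates (v_E), and by expression itself, in the gene's direction
(v_G — the perfect order under monotone regulation). A one-sided Wilcoxon
rank-sum test asks whether |v_G − v_P| is stochastically greater than
|v_G − v_E|; small p means the estimates order samples closer to the
perfect order than the reported days do. Within-day ties in v_P are
resolved in the gene's direction, which makes the total deviation
Σ|v_G − v_P| minimal over all resolutions (a rearrangement argument) and
is therefore the resolution most favourable to the reported times. Note a
subtlety: minimality of the total deviation does *not* imply the resulting
p-value is the largest over all tie resolutions — enumeration on small
cohorts shows alternative resolutions can yield larger p — so the test
should be read as using a principled, favourable-to-the-null resolution
rather than a provable p-value upper bound. For n ≤ 12 the exact
conditional null distribution of the rank sum is enumerated by dynamic
programming over (doubled) midranks, which remains exact under ties;
larger samples use the tie-corrected normal approximation. P-values are
Bonferroni-corrected across the six genes.

## Panel reduction

Starting from a larger candidate panel, the gene whose removal least
changes the inferred sample ordering — highest Spearman correlation
between the ranks with and without it, measured against the *current*
panel at each step — is removed greedily until the target size, with an
early stop (default floor 0.9) if no removal keeps the ordering stable.
Because every candidate gene in a monotone panel is partially redundant
with the others, the criterion measures expendability relative to the
current consensus, not marker quality in isolation: an exact duplicate is
cheap to remove but not guaranteed to go first (removing it reweights the
per-gene average), and an occasional redundant informative gene may leave
before the last uninformative one. The per-step correlations are reported
so such decisions are auditable.

## The synthetic-data generator

`simulate_cohort()` produces the regime the package is tested under: true
tissue ages uniform over days 4–12 (biopsies arrive roughly uniformly
across the scheduling window); reported days equal to truth plus
Normal(0, 2) noise, rounded and clipped to 4–12 (the clinic only schedules
inside the range); expression equal to a monotone gene model evaluated at
the *true* age plus Normal(0, 0.05) noise on the unit scale plus a
per-batch, per-gene offset with SD 0.05 across 3 batches; and sign
inversion back onto the ΔCT scale. The default gene models mix linear
ramps with logistic switches whose midpoints are staggered across days
5.5–11, five rising and one falling; the assignment of the falling shape
to *SLC15A2* is arbitrary, as gene directions are user-editable metadata.
The generator reproduces the statistical structure the method assumes —
monotone profiles, day-resolution reporting noise, additive batch effects —
and deliberately omits features of real cohorts such as non-monotone genes,
patient-specific expression offsets, heteroscedastic qPCR noise and
clinical-subgroup structure. Tests passing on this generator therefore
certify the machinery under the method's own assumptions, not performance
on any clinical data set. A paired TPM matrix with the same latent signal,
an affine log2 scale and independent noise supports the cross-platform
checks.

## Problem sizes and numerical choices

The test-suite and acceptance checks run the full default regime — 100
seeded cohorts of 250 samples for the recovery and leave-one-out
properties, chosen as the smallest replication that makes the ≥95/100 and
≥80/100 pass criteria statistically meaningful; unit tests use cohorts of
40–150 samples with a proportionally scaled window schedule (24 → 8 by 4).
All randomness descends from explicit integer seeds; every stochastic
operation takes a seed and restores the caller's RNG stream. Exact ties in
likelihood argmaxes resolve to the earliest time point. Degenerate inputs
fail loudly: constant genes, missing panel columns, out-of-range days and
sub-minimum cohorts are errors, not warnings.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(default_sim_spec(rng_seed = 7))
cfg <- endotime_config(rng_seed = 7)
fit <- endotime_train(sim$cohort, cfg)
fit
cor(fit$records$eLH, sim$true_times, method = "spearman")
cor(sim$cohort$reported_day, sim$true_times, method = "spearman")
```

On this seed the fit converges in 21 iterations; the estimates correlate
with the true simulated ages at Spearman ρ = 0.971 against 0.713 for the
reported days (values printed by the code above; other seeds differ
slightly).

## Known limitations

- Estimates at the extremes of the time axis are compressed: window times
  are medians, so the earliest and latest profiles sit inside the data
  range and samples beyond them pile up at the boundary (their ordering
  then falls back to reported times).
- The breakpoint-based outlier rule needs the ramp-plus-tail score shape;
  inspect the cutoff before trusting the flags.
- Training needs cohorts comfortably larger than the initial window
  (n ≳ 2·`window_start`); smaller cohorts should either shrink the
  schedule or use `estimate_fixed()` against an existing model.
- The panel-reduction criterion measures expendability, not marker
  quality; on heavily redundant panels its removal order is not unique.
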