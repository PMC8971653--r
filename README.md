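# endotime

Continuous temporal staging of luteal-phase endometrial biopsies from a
small marker-gene panel.

## What it does and for whom

Endometrial biopsies are conventionally dated by the patient-reported day
of the urinary LH surge (rLH+), which is noisy at whole-day resolution and
often simply wrong. For reproductive-medicine researchers working with
RTq-PCR or RNA-seq measurements of luteal-phase tissue, this package
re-dates each biopsy on a continuous day scale (eLH+, days after the LH
surge) from the expression of six monotone marker genes (*IL2RB*,
*IGFBP1*, *CXCL14*, *DPP4*, *GPX3*, *SLC15A2*; ΔCT against the *L19*
reference gene), together with a per-sample reliability (asynchrony)
score, outlier flags, leave-one-out validation, cross-platform
calibration for RNA-seq, marker-panel reduction, and a synthetic-cohort
generator with known ground truth.

## The method in brief

Expression is sign-inverted (−ΔCT), unit-scaled per gene, and
batch-mean-centred; integer reported days are continuized by uniform
jitter followed by an OLS-on-rank smoothing. The core fit then alternates:

1. **Profiles** — sort samples by current timings and summarize each gene
   over sliding windows of *w* samples as a Gaussian
   N(μ<sub>τ</sub>, σ<sub>τ</sub>), with window time τ the median member
   timing and μ, σ tricube-weighted by temporal distance from τ;
2. **Estimates** — for each sample, evaluate the likelihood of its
   expression under every window's Gaussian, scale each gene's curve to
   unit maximum (one gene, one vote), average across genes, smooth by a
   *w*-point moving average, and take the argmax as the new timing.

The window size shrinks 80 → 20 by 10 per iteration; the loop stops when
the Euclidean distance between successive timing vectors falls below 2
days with the schedule at its floor. Final timings are rank-mapped onto
the continuized reported-time distribution. The asynchrony score is the
SD of the six per-gene curve maxima; a segmented regression of sorted
scores supplies an outlier cutoff. RNA-seq TPM values enter as
log2(TPM+1), moment-matched per gene to the training cohort, and are
scored against frozen profiles in a single pass.

See `vignette("endotime-methods")` for assumptions, parameter meanings,
numerical choices and limitations.

## A worked example

```r
library(endotime)

sim <- simulate_cohort(default_sim_spec(rng_seed = 7))   # 250 samples, known truth
cfg <- endotime_config(rng_seed = 7)
fit <- endotime_train(sim$cohort, cfg)
fit
#> <endotime_fit> 250 samples, 21 iterations (converged)
#>   final displacement: 1.846 days | outlier cutoff: 0.2215
#>   eLH range: 3.57..13.01 days | 145 outlier(s)

head(fit$records[, 1:6], 3)
#>   sample_id reported_day rLH_continuous       eLH asynchrony argmax_IL2RB
#> 1      S001           12      12.973471 12.973471  1.1875393    10.016203
#> 2      S002            8       7.589726  6.983107  0.2116281     7.086659
#> 3      S003            5       4.784112  4.518717  0.0000000     6.566056

cor(fit$records$eLH, sim$true_times, method = "spearman")        # 0.971
cor(sim$cohort$reported_day, sim$true_times, method = "spearman") # 0.713
```

Each record carries the reported day, its continuized value, the model
estimate `eLH` (days after the LH surge), the asynchrony score (days; 0 =
all six genes vote for the same time), the per-gene maximum-likelihood
times, and the outlier flag. Here the estimates recover the simulated true
tissue ages markedly better (ρ = 0.971) than the noisy reported days do
(ρ = 0.713). On this synthetic cohort the sorted asynchrony scores rise
gradually, so the breakpoint cutoff sits low and flags many samples —
inspect `fit$outlier_cutoff` before acting on the flags.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/endotime.R", package = "endotime"))')
Rscript $CLI simulate --n 250 --seed 1 --out sim.tsv --truth-out truth.tsv
Rscript $CLI train    --in sim.tsv --out estimates.tsv --profiles-out model.tsv --seed 1
Rscript $CLI estimate --profiles model.tsv --rnaseq tpm.tsv --out est_rnaseq.tsv
Rscript $CLI validate --in sim.tsv --out loo_report.tsv --seed 1
```

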