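---
title: "Testing differential translation efficiency with tediff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential translation efficiency with tediff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tediff)
```

## The statistical model

Ribosome footprint (RF) profiling and RNA-Seq measure, per gene, the
ribosome-occupied and the total mRNA pool. The footprint count is
confounded by mRNA abundance, so the quantity tested here is the
change in translation efficiency (TE) — the RF/RNA abundance ratio —
between a control and a treatment condition.

Counts are negative binomial, `y ~ NB(mu, kappa)` with variance
`mu + kappa mu^2`; `kappa = 0` recovers Poisson counting noise, and
`kappa > 0` absorbs biological variability between replicates. The
mean structure is a log-link GLM in which the two protocols share a
per-condition activity term:

* RNA-Seq libraries, condition `C`: `log mu = beta_C + beta_RNA`
* RF libraries, condition `C`: `log mu = beta_C + beta_RF + beta_Delta,C`

with `beta_Delta,0 = 0` by convention. Transcription and translation
are treated as successive steps with linearly related abundances, so
`beta_C` is a proxy for the shared activity in condition `C` and is
estimated from both assays at once — this is how mRNA abundance is
removed as a confounder. `beta_Delta,1` is the natural-log TE fold
change. The model is identical to the saturated factorial design
`protocol + condition + condition:protocol`, with `beta_Delta,1` the
interaction coefficient; `build_design()` constructs exactly that
matrix (intercept, protocol, condition, interaction), and the null
model simply drops the interaction column. The test has one degree of
freedom by construction.

Library depth enters as offsets: `log mu` includes `log s_j`, where
`s_j` are median-of-ratios size factors computed independently within
each protocol (RF and RNA-Seq depths are not comparable). Offsets
preserve the integer counts for the likelihood; normalized counts
`y/s_j` are used only for reporting TE values and as the abscissa of
the dispersion trend. Within each protocol the factors are rescaled to
geometric mean 1 — the absolute scale is absorbed by `beta_RNA` and
`beta_RF`, so only relative depths are identifiable.

## Fitting

Per gene, `alternating_fit()` iterates two maximizations until the
joint log-likelihood changes by less than 1e-6 (at most 50 rounds):

1. coefficients given dispersion — iteratively reweighted least
   squares on the log link with step halving, which makes the
   log-likelihood non-decreasing; convergence at `|delta loglik| <
   1e-10`, with a Nelder–Mead fallback if the weighted normal
   equations are numerically singular;
2. dispersion given coefficients — bounded 1-D maximization of the NB
   log-likelihood over `kappa` in `[1e-6, 10]` on the log scale.

Because the two sequencing protocols have distinct noise
characteristics, the default `SEPARATE` mode estimates one `kappa`
for the RNA-Seq libraries and one for the RF libraries of each gene;
the mean model is never split. `JOINT` mode shares a single `kappa`.
Initialisation is deterministic: least squares on
`log(normalized count + 0.5)` for the coefficients, a per-protocol
method-of-moments estimate for the dispersion, so identical inputs
give byte-identical outputs.

Numerical safeguards: fitted means are floored at 1e-8 and
coefficients clamped to ±50, so a (protocol, condition) group with
all-zero counts cannot drive the objective to −∞; the LRT is still
computed for such genes. Genes with zero counts in every library, or
in all libraries of one protocol, are not testable and are reported
with missing p-values — they are also excluded from the
multiple-testing denominator rather than being assigned p = 1. The
dispersion bounds `[1e-6, 10]` cover realistic biological
over-dispersion; estimates within 0.1% (log scale) of a bound are
flagged as boundary hits, a threshold chosen above the endpoint
resolution of the 1-D optimizer so the flag is stable under
relabelings of the data.

## Dispersion trend and shrinkage

With a handful of replicates, gene-wise dispersion estimates are
noisy. Following standard practice for count GLMs, `fit_trend()`
regresses the raw estimates on the mean normalized count with the
hyperbolic model `f(mu) = lambda1/mu + lambda0` (least squares on the
basis `(1, 1/mu)`, coefficients clipped at zero, two re-fits after
discarding genes whose raw/fitted ratio leaves `[0.1, 10]`).
`shrink_dispersion()` then computes a maximum a posteriori estimate
under a log-normal prior centred at the trend value, maximizing the
penalized likelihood in `kappa`; the estimate provably lies between
the raw MLE and the trend on the log scale, and the implementation
clamps to that interval to guard the invariant against optimizer
tolerance. The prior width is the normal-consistent MAD of
`log(raw/trend)` over non-boundary genes, floored at 0.25. The floor
prevents near-noiseless simulated data from collapsing the prior and
over-shrinking; the MAD itself is a deliberately simple, swappable
estimator isolated in `estimate_prior_sd()` — it makes no attempt to
subtract the sampling variance of the raw estimates from the observed
spread, so the prior is wider (shrinkage weaker) than a fully
calibrated empirical Bayes analysis would give. Boundary-flagged genes
are excluded from trend fitting and prior estimation (a boundary value
is not an MLE) but are still shrunken. In `SEPARATE` mode the whole
trend + shrinkage procedure runs twice, once per protocol, with no
sharing.

Dispersions are estimated once, under the alternative (saturated)
fit, and then frozen for the final scoring of both hypotheses. The
alternative fit uses them because its fitted means are unbiased for
the group means regardless of whether the null is true, whereas
null-model residuals would inflate the dispersion for genuinely
changed genes; freezing one set for both models guarantees the LRT
statistic is non-negative by construction (re-estimating per
hypothesis can make it negative). Should a refit still land below the
null (optimizer failure), the alternative is restarted from the null
solution padded with a zero interaction.

## Testing and output

`2 (loglik_alt − loglik_null)` is referred to the upper tail of
chi-squared with 1 degree of freedom. Benjamini–Hochberg correction is
applied over the testable genes (the method the output's FDR column
assumes; the choice of BH is the field default for this family of
tools). Reported TE values are ratios of mean normalized counts per
condition; the significant set at the chosen FDR is split by the sign
of the log2 TE fold change. Under the saturated fit with unit size
factors the fitted interaction coefficient and `log(TE_trt/TE_ctl)`
coincide, which the test suite uses as a closed-form oracle.

## The simulator

`simulate_dataset()` draws data from the model the test assumes, plus
the nuisances a real experiment would add:

* baseline abundance per gene: log-normal with `meanlog = log 100`,
  `sdlog = 1.5`, spanning realistic per-gene sequencing depths from a
  handful of reads to tens of thousands;
* dispersions `kappa_rna = 0.01`, `kappa_rf = 0.5` by default — the
  regime where footprint libraries are far noisier than RNA-Seq
  (ratio 50), which is where separate dispersion estimation matters;
  either may instead be given as trend coefficients `(lambda0,
  lambda1)`;
* 3 replicates per (protocol, condition) group, the typical size of a
  published ribosome-profiling comparison;
* 10% of genes affected, with natural-log TE fold change `log 4` and
  random sign — effects in both directions, as observed in real
  treatment responses;
* library-depth multipliers drawn log-uniformly from `[0.5, 2]`,
  exercising the size-factor machinery;
* no transcriptional change by default, isolating the translational
  signal; `rna_log_fc` adds an mRNA-level change to affected genes to
  probe confounder removal.

All draws flow from one seed. What the simulator does *not* emulate:
gene-length and positional biases, multimapping, count correlation
between the two protocols beyond the shared mean, batch effects, or
library-preparation artefacts. Passing benchmarks here shows the
estimator recovers the generative model it assumes — a necessary
check, not evidence about any particular real dataset.

`roc_curve()` scores a ranking against the simulation truth
(threshold sweep with ties grouped, trapezoid AUC, equal to the
normalized Mann–Whitney U statistic). `zscore_baseline()` implements
the classical comparison method: the per-gene log TE difference
standardized within equal-occupancy expression bins (20 by default).
With `bins = 1` it exposes the behaviour the GLM approach is designed
to fix: on null data the unbinned |z| is systematically larger for
low-count genes, because the same TE wobble is a larger z when its
counting noise is ignored.

## Problem sizes and design choices in the checks

The test suite validates the likelihood against an independent
gamma-form pmf, coefficient fits against a coordinate-wise
grid-refinement oracle and closed-form group means, dispersion and
shrinkage optima against dense grid searches, BH against a literal
step-up implementation, and AUC against the U-statistic identity (and
pROC). End-to-end checks use simulated datasets of 600–2000 genes:
large enough that fractions of p-values and AUCs are stable to a few
percent, small enough to run interactively. The separate-vs-joint
comparison uses 10 matched 600-gene datasets at dispersion ratio 50;
effect-size recovery uses 2000 genes at 5 replicates per group.

## Known limitations

* **Small-sample anticonservativeness.** Gene-wise ML dispersion
  estimates are biased low when few replicates are available (the
  fitted group means absorb part of the variability; nothing in the
  plain likelihood corrects for the estimated mean parameters). At 3
  replicates per group this halves the typical dispersion estimate
  and the LRT rejects a true null noticeably more often than the
  nominal rate; the effect shrinks with replication (near-nominal by
  8 replicates per group) but does not vanish. The shrinkage trend
  cannot repair it, since the trend is fitted to the same biased
  estimates. This also leaves a mild expression-dependent pattern in
  null p-values. Adjusted-profile-likelihood corrections are the
  standard remedy and are deliberately out of scope here; rankings
  (ROC) are much less affected than error rates, and the p-values at
  3 replicates should be read accordingly.
* **One-sided effect regimes.** Median-of-ratios size factors are
  robust to a minority of changed genes only when changes are roughly
  sign-balanced. If a large fraction of genes move in one direction
  in one protocol, part of the shift is absorbed into the size
  factors and effect estimates attenuate (about 10% at 10% of genes
  all moving 4-fold one way).
* **Unpaired design only.** The model treats all libraries as
  independent; paired RNA/RF samples from the same biological
  replicate are not modelled.
* **No independent filtering.** Beyond excluding degenerate all-zero
  genes, no low-count filter is applied before testing; very
  low-count genes simply carry little power.
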