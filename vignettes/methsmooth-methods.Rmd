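---
title: "Smoothed methylation profiles and DMR detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothed methylation profiles and DMR detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the binomial model for per-CpG counts, the local-likelihood
smoother, the biological-variability-aware t-statistic and its region
caller, the wide-window block caller with slow-component correction, the
Fisher's-exact-test baseline, the evaluation machinery, and the synthetic
data generator that the test suite and the acceptance script are built on.

## The data and the smoothing model

Whole-genome bisulfite sequencing yields, for each CpG locus $l_j$ and
sample $i$, a methylated count $M_{i,j}$ and unmethylated count $U_{i,j}$
with coverage $N_{i,j} = M_{i,j} + U_{i,j}$. We model
$M_{i,j} \sim \mathrm{Binomial}(N_{i,j}, \pi_{i,j})$. The raw proportion
$M/N$ is unbiased for $\pi$ but noisy: its standard error
$\sqrt{\pi(1-\pi)/N}$ still reaches $0.09$ at $30\times$ coverage
(`max_single_cpg_se(30)`). Methylation, however, varies smoothly along the
genome, and functional signals are regional, so we assume
$\pi_{i,j} = f_i(l_j)$ for a smooth sample-specific function $f_i$ and
estimate it by local likelihood:

* at each locus, the window is the smallest symmetric interval holding at
  least 70 CpGs and at least 2 kb wide (`smooth_params()`); both knobs are
  tuned to mammalian CpG density and should be revisited for other
  organisms;
* within the window, $\mathrm{logit} f$ is modelled as a quadratic in
  position, fitted by maximizing the binomial log-likelihood with weights
  that combine a tricube kernel in distance with the $N_k$ trials of each
  locus. The kernel uses the realized half-width $h$, so boundary loci get
  weight near zero. Weighting through the likelihood (rather than plugging
  $\hat\pi(1-\hat\pi)/N$ into a least-squares weight) keeps loci with
  observed proportions of exactly 0 or 1 well-defined and matches standard
  local-likelihood practice.

Numerical choices: the IRLS solver is capped at 50 iterations with
step-halving; fitted logits are clamped at $\pm 8$, so fully separated
windows (all reads methylated) return `plogis(8)` $\approx 0.9997$ rather
than diverging; on non-convergence the fit falls back to degree 1, then to
the kernel-weighted mean proportion. A locus is invalid only when its
whole window holds no covered CpG; zero-coverage loci inside covered
windows are interpolated by design. The solver is pinned, at $10^{-6}$
tolerance in the fitted value, to a brute-force maximizer of the same
weighted likelihood in the test suite.

## The DMR statistic

For a two-group design $X_i \in \{0, 1\}$ we assume
$f_i(l_j) = \alpha(l_j) + \beta(l_j) X_i + \varepsilon_{i,j}$, where
$\alpha$ is the baseline profile, $\beta$ the group difference of
interest, and $\varepsilon$ biological variability with smoothly varying
variance $\sigma^2(j)$. Crucially, deeper sequencing does not shrink
$\varepsilon$; only replicates do. From smoothed profiles
$\hat f_i$ we estimate $\hat\alpha$ (mean over samples), $\hat\beta$
(difference of group means), and a local standard deviation
$\hat\sigma$: the pooled within-group SD (denominator $n_1 + n_2 - 2$),
floored at its 75th percentile computed over all retained loci in the run,
then smoothed by a centered 101-CpG running mean that truncates at
chromosome ends. "Pooled within-group" is a deliberate reading of the
ambiguous phrase "across the two groups": between-group differences belong
in $\hat\beta$, not in the noise estimate. The statistic is

$$t(l_j) = \frac{\hat\beta(l_j)}{\hat\sigma(l_j)\sqrt{1/n_1 + 1/n_2}}.$$

DMRs are maximal runs of consecutive CpGs with all $t > c$ (hyper) or all
$t < -c$ (hypo), strict inequalities, split wherever consecutive CpGs are
more than 300 bp apart — which simultaneously enforces "at least one CpG
every 300 bp" inside any region, so no second pass is needed. Runs are
kept when they contain at least 3 CpGs and $|\overline{\hat\beta}|
\ge 0.1$. By default the cutoffs are the 2.5% and 97.5% quantiles of the
empirical $t$ distribution (`dmr_params(cutoff_quantile = 0.025)`); a
fixed $c$ can be supplied. Regions are ranked by area, the sum of $|t|$
over member CpGs. Masked loci (invalid in any sample, or $\hat\sigma = 0$
as happens when all profiles are identical) are excluded before grouping.

## Blocks and the slow-component correction

Cancer genomes carry megabase-scale blocks of modest hypomethylation in
CpG-sparse territory. `call_blocks()` is the same pipeline run with
500-CpG / 40 kb smoothing windows, a 10 kb grouping gap (the 300 bp rule
is meaningless between sparse CpGs; this default is our choice, reported
as such), a 10 kb minimum width, and — recommended for cancer/normal
designs — `normal_only = TRUE`, which estimates $\hat\sigma$ from the
normal samples alone because cancer samples are far more variable.

When blocks are present, $\beta = \beta_1 + \beta_2$ decomposes into a
sharp small-DMR component and a slowly varying block component, and so
does $t = t_1 + t_2$. To find small DMRs inside blocks,
`correct_tstat()` estimates the slow component $\tilde t_2$ by linear
interpolation of $t$ onto a 2 kb grid, robust local regression over 50 kb
windows (tricube weights, degree 2, biweight robustness iterations — the
`loess(family = "symmetric")` family), and evaluation back at the CpG
positions; small DMRs are then called on $t - \tilde t_2$. The exact
robust scheme is not uniquely determined by its verbal description, so
the package pins the semantics with tests: a constant track corrects to
zero within $10^{-8}$; a slow 200 kb sinusoid is attenuated by more than
80% while a sharp 2 kb bump keeps its height within 10%; isolated
outliers move the slow fit by less than 0.1. Chromosomes shorter than one
grid step fall back to the mean of $t$.

## The Fisher baseline

The comparison method pools counts within groups (discarding replicate
information), tests each covered CpG with a two-sided Fisher's exact test
(hypergeometric enumeration; ties counted at relative tolerance
$1 + 10^{-7}$), flags DM CpGs — by default at Benjamini-Hochberg adjusted
$p < 0.05$; the historical rule predates a fixed convention, so both the
adjustment and threshold are parameters — and reports regions satisfying
the classic construction: at least 2 kb long, at least 10 DM CpGs, and
every 1 kb window fully inside the region holding at least 4 DM CpGs
(sliding at bp resolution). The finder returns every *maximal* such
region with DM-CpG endpoints: extending one DM CpG on either side breaks
a constraint. Overlapping maximal regions are reported as-is rather than
unioned, because a union can violate the subregion constraint; an
exhaustive interval oracle in the test suite defines these semantics.

## Evaluation machinery

Gold standards come from a high-coverage experiment over predefined
regions: per-region, per-sample means over CpGs with coverage
$\ge 30\times$; the mean-difference definition labels positives at
$|\Delta| > 0.25$ and negatives at $|\Delta| < 0.03$ (eligibility: 5
high-coverage CpGs in at least 2 samples per group), while the Welch
definition labels positives at two-sided $p < 0.01$ and negatives at
$p > 0.25$ (eligibility: 4 high-coverage CpGs in every sample). ROC
points count a gold positive as hit when a call overlaps more than 50% of
the gold region's own length *and* matches its direction; negatives need
only the overlap (they have no direction). The denominator choice — the
gold region, not the call — is deliberate and documented because the
verbal rule does not name it. TSS enrichment is the log2 odds ratio of a
labeled TSS having a call within 5 kb (inclusive, minimal distance from
the interval), DE versus non-DE, with the Haldane 0.5 correction when a
cell is empty.

## The synthetic data generator

`simulate_dataset()` draws: clustered positions from a two-state process
(CpG islands of ~18 CpGs at ~20 bp spacing opened with probability 0.02
per background step; background spacing exponential with mean 150 bp); a
baseline $\alpha$ as a cubic spline through logit-scale knots every 10 kb
($\mathcal{N}(1.5, 1.2^2)$ — mostly methylated background), with a smooth
raised-cosine hypomethylation dip of 2.5 logits at each island, because
islands are unmethylated in mammalian genomes; planted DMRs (default 50,
widths 1-3 kb, probability-scale effects 0.2-0.4) *centered on islands*,
where real DMRs occur, with a balanced direction mix assigned by baseline
headroom — gain of methylation at low-methylation islands, loss where the
baseline is high; optional wide blocks (default effect $-0.15$) placed in
unconstrained territory; biological noise per sample as a 51-CpG running
mean of i.i.d. normals rescaled to marginal SD $\sigma_\varepsilon = 0.3$
logits, so the noise — like real inter-individual variation — is locally
smooth rather than white; coverage $N \sim$ Poisson(4 by default) and
counts $M \sim \mathrm{Binomial}(N, \pi)$ with $\pi$ clamped to
$[0.001, 0.999]$ (inconsequential at these coverages). A single integer
seed determines everything.

The default genome holds 30,000 CpGs, chosen so the planted load (about
1,500 affected loci, 5%) matches the capacity of the default two-tailed
2.5% cutoff: a generator whose planted signal exceeds the cutoff's tail
mass cannot be fully recovered by construction, and a genome where 8% of
CpGs are differentially methylated would not be biologically credible
either. Recovery is scored as: a planted DMR is recovered when a call of
matching direction overlaps it; a call is false when it overlaps no
planted region even after widening planted regions by 2 kb — the
smoother's minimum bandwidth — since calls hanging just off a planted
edge are boundary spread, not spurious discoveries. Under the default
conditions the pipeline recovers well over 70% of planted DMRs (pilot
design run, seed 101: 96%) with a false-call fraction around 10% that
fluctuates considerably seed to seed (5% at the pilot seed, up to ~17%
at others): the smooth, VMR-like biological noise produces occasional
runs that no marginal-t cutoff can separate from planted effects, which
is precisely why replication matters in this design.

What passing these tests shows — and what it does not: the generator
reproduces the statistical structure the method assumes (smooth profiles,
regional effects, smooth-variance biological noise, binomial sampling),
so the tests validate the estimation and calling machinery. It does not
emulate alignment artifacts, bisulfite conversion failure, copy-number
changes, quality-score structure, or non-CpG methylation, so test results
transfer to real data only to the extent those factors are handled
upstream (the M-bias module addresses the read-position component of
this).

`simulate_biased_reads()` generates read-level measurements over a
synthetic chromosome with a configurable per-cycle additive bias on the
call probability, exercising the M-bias table, its diagnostic plot, and
the filter that removes biased cycles.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at
genome sizes of 2,000-30,000 CpGs with 1-6 samples — sizes at which the
smoother fits in seconds to a couple of minutes per dataset while still
exercising adaptive windows, both callers, and the evaluation layer; all
simulations are seeded and every result in this vignette and the README
is produced by the package's own code at those sizes. Smoothing is
embarrassingly parallel over samples and chromosomes and the
implementation keeps results identical regardless of execution order by
construction (each locus is fitted independently).

## Known limitations

* No confidence bands for the smoothed profiles, and no p-values or FDR
  for DMRs — region ranking is by area, and significance assessment
  (e.g. by permutation) is out of scope.
* Two groups only; no covariate adjustment.
* The smoother assumes the truth is smooth: single-CpG events are
  invisible by design.
* The quantile cutoff calibrates itself on the marginal t distribution;
  when true signal occupies a large fraction of the genome the cutoffs
  migrate into the signal and recovery saturates (see the generator
  design note above).
* `local_sd()` requires at least two samples per contributing group; with
  fewer replicates the model is unidentifiable and the functions refuse
  to guess.
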