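---
title: "Methods: clonality-aware Bayesian driver gene discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality-aware Bayesian driver gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedriver)
```

## Overview

clonedriver ranks genes by evidence of positive somatic selection in a
cancer cohort. Three per-mutation signals feed the model: recurrence across
patients, cancer cell fraction (CCF — how early the mutation arose), and
functional impact. The contrast against a silent/non-coding neutral
background is expressed as two Bayesian posteriors, and a resampling null
converts the ranked posteriors into an FDR-based significance cutoff.

## CCF estimation

A clonal heterozygous SNV at a diploid locus in a pure tumor sample is
expected in half of the reads, so CCF = 2·VAF corrected for purity. In
general, with purity $p$ and local tumor total copy number $c$ and assuming
mutation multiplicity 1,

$$\mathrm{CCF} = \mathrm{VAF}\cdot\frac{p\,c + 2(1-p)}{p},$$

clipped into $[0,1]$ as the last step. When only a fraction $f$ of cancer
cells carries the overlapping CNV, the effective copy number is the
CCF-weighted average $2(1-f) + c f$. This is the standard purity/ploidy
correction consistent with the diploid special case; because multiplicity
is not modelled, amplified early mutations can be overestimated — which the
final clipping absorbs. Precomputed CCFs (e.g. from a clonal-deconvolution
tool) are accepted as-is: `add_ccf()` only fills missing values unless
`recompute = TRUE`.

*Numerical choices*: clipping happens after the CNV adjustment; purity 0 is
an error rather than a silent NaN; missing purity defaults to 1 and missing
copy number to 2, both logged by the reader.

## Damage probabilities

Raw CADD-like scores are mapped through the logistic
$1/(1+e^{-(x-\mu)/s})$ with midpoint $\mu = 15$ and scale $s = 2$ — scores
near 15 (the conventional "possibly deleterious" zone) get damage 0.5 and
scores above ~25 saturate towards 1. The logistic is the simplest sigmoid
parameterised by a mean and a scale factor; both are user-tunable via
`impact_params()`. Mutations without a score get an uninformative 0.5.

## Background mutation models

Both models produce, per gene, an expected nonsilent count under
neutrality, and both are normalised cohort-wide, so only *relative* rates
matter.

**CCF-adjusted Ka/Ks.** Counting each mutation by its CCF rather than by 1
down-weights late subclonal mutations. With $N_a$/$N_s$ nonsynonymous and
synonymous site counts and the CCF-weighted silent count $n_s^{CCF}$, the
neutral ($K_a/K_s = 1$) expectation is $\hat n_a = n_s'\,N_a/N_s$, where
$n_s' = \max(n_s^{CCF}, N_s/N_a)$. The floor is the silent count that would
make a *single* nonsilent mutation exactly neutral, so genes with zero
observed silent mutations cannot turn one nonsilent hit into a selection
signal.

**Non-coding rate.** Published per-gene non-coding mutation rates (per bp)
times coding length give an expected total count $\hat n_t$; its nonsilent
share under neutrality is $\hat n_t/(1 + N_s/N_a)$.

**From counts to probabilities.** The cohort scalar $r$ — the mean
per-patient number of clonal (CCF ≥ 0.85) nonsilent SNVs, taken as the
pre-tumor mutation load — is the number of binomial trials:
$\mathrm{bmp}_g = 1 - (1-p_g)^r$ with $p_g = \hat n_{a,g} / \sum_i \hat
n_{a,i}$. $r$ is a cohort mean and is used directly as a real exponent; the
power form is well defined for non-integer $r$ and agrees with the binomial
zero-class for integer $r$ (tested against exhaustive enumeration). The
final bmp is the arithmetic mean of the two models' probabilities. Indels
count as nonsilent but never as silent, and are excluded from $r$ by
default (`include_indels` switches this), since clonality estimates for
indels are less reliable than for SNVs.

Genes present in the cohort but absent from the gene-context table are
dropped with a warning: both background models are undefined without
$N_a$, $N_s$ and ncmr. The CCF sums are taken over all mutations with no
per-patient collapse, since they estimate a cohort-level rate rather than a
per-patient likelihood.

## Bayesian models

Per gene, the **evidence mass** is $m = \sum_{i=1}^n
\mathrm{CCF}_i\,\mathrm{damage}_i$ over the full cohort of $n$ patients,
keeping one mutation per patient — the highest-CCF one, with ties broken by
damage, then by position string. The damage tie-break is a documented
extension of the highest-CCF rule; it only matters for exactly tied CCFs.
Unmutated patients contribute zero, so $m/n$ is a per-patient rate in
$[0,1]$.

**Cancer-hazard model.** With likelihood $L = m/n$, background bmp and the
tumor-type incidence $\pi$ as prior:

$$P(\mathrm{cancer}\mid ns) = \frac{L\pi}{L\pi + \mathrm{bmp}\,(1-\pi)}.$$

The default incidence 0.1 is a generic order-of-magnitude lifetime risk;
the ranking is invariant to $\pi$ (monotone in $L/\mathrm{bmp}$), so the
prior matters only for the absolute posterior scale. If both $L$ and bmp
are zero the posterior is defined as 0: no evidence either way.

**Driver-inference model.** The prior is the known-driver fraction of
protein-coding genes ($\#\mathrm{drivers}/20{,}000$ by default); the
driver-channel likelihood $P(ns\mid d)$ is estimated as (nonsilent
mutations in listed driver genes)/(patients × listed drivers), assuming all
drivers equally likely to be hit (a user override is accepted); the
passenger channel is bmp. The posterior exponentiates both channels by the
real-valued $m$ and $n - m$:

$$P(d \mid D) = \frac{P(ns\mid d)^m (1-P(ns\mid d))^{n-m} P(d)}
 {P(ns\mid d)^m (1-P(ns\mid d))^{n-m} P(d) +
  \mathrm{bmp}^m (1-\mathrm{bmp})^{n-m} (1-P(d))}.$$

No binomial coefficient appears: it would cancel between numerator and
denominator. Evaluation is in log space so cohorts of thousands of
patients do not underflow; channel probabilities exactly 0 or 1 are clamped
to $[10^{-12}, 1-10^{-12}]$. The posterior equals the prior whenever the
two channels coincide (a calibration identity the tests exercise over 1000
random draws), is strictly increasing in $m$, and is strictly decreasing in
bmp in the regime $\mathrm{bmp} < m/n$ — beyond that point the
passenger-channel binomial likelihood turns over, which is expected
behaviour, not a defect.

Default ranking uses the driver model (ties: hazard posterior, then $m$,
then gene symbol — a deterministic total order); `rank_genes()` also offers
hazard-based and average-rank orderings.

## Resampling null and FDR

The null keeps every mutation's patient, CCF, damage and class but redraws
its gene label i.i.d. with probability proportional to bmp. Both Bayesian
models are then re-run. Two interpretive choices:

* the background/bmp vector and the driver-channel likelihood are **held
  fixed** at their observed values across replicates — the bmp vector
  *defines* the null, and re-estimating it from its own resamples would
  add noise without changing its expectation;
* FDR at rank $k$ compares the observed $k$-th posterior to each
  replicate's full posterior set: $\widehat{\mathrm{FDR}}(k) =
  \mathrm{median}_j\,\#\{\text{null posteriors}_j \ge \text{obs}_k\}/k$,
  capped at 1 and made nondecreasing by cumulative maximum. This uses
  exactly the per-replicate sorted profiles the null construction produces
  and reduces to the plain FDR-≤-0.1 rank rule.

Per model the cutoff is the largest rank with FDR ≤ α (default 0.1); the
suggested cutoff is the floored mean of the two models' ranks (floored
because a rank must be an integer, and flooring is the conservative
choice). One master seed spawns per-replicate seeds, so replicates are
reproducible independently of evaluation order. 100 replicates (the
default) makes the per-rank medians stable to well under 10% on the cohort
sizes used here.

## Synthetic cohorts

`simulate_cohort()` emulates the clonal architecture the method exploits.
Defaults define the reference study conditions used throughout the tests:
1000 genes, 200 patients, 10 driver genes.

* **Gene context**: coding lengths log-normal around 1.5 kb; ~3 possible
  substitutions per bp split 3:1 into nonsynonymous:synonymous sites;
  per-gene rates log-normal (sdlog 0.5) around a non-coding rate of
  10⁻⁶/bp.
* **Passengers**: Poisson per gene × patient, rates proportional to
  ncmr × length, scaled to 30 mutations/patient; silent with probability
  $N_s/(N_a+N_s)$; CCF a mixture of a clonal component (weight 0.35,
  Beta(30, 2) — hitch-hikers predating transformation) and a subclonal
  component (Beta(2, 5)); impact Gamma(2, scale 5) for nonsilent,
  Gamma(2, scale 2.5) for silent; 5% of nonsilent passengers are indels.
* **Drivers**: each of the listed genes hit per patient with probability
  0.15; CCF Beta(30, 2) (mass above 0.85), impact Normal(30, 5) truncated
  at 0 — clonal and damaging.
* **Patients**: purity Beta(8, 2); VAF derived by inverting the diploid
  CCF formula, so re-estimating CCF from the emitted table recovers the
  generating values exactly.

These choices give a clonal rate $r \approx 8$ and a clear but not
caricatured CCF separation (median driver-vs-passenger CCF difference
≈ 0.5). What the simulator does **not** emulate: clonal phylogenies
(CCFs are drawn independently, not from a tree), copy-number variation
(all loci diploid), sequencing noise in VAF, mutational signatures and
regional rate covariates, and correlated gene lengths/expression. Passing
tests therefore demonstrate correctness of the inference machinery under
the stated generative assumptions — not performance on any real cohort,
where purity estimation error and non-diploid loci blur CCF far more.

## Problem sizes and determinism

The test suite and the acceptance script replicate the cohort-level
properties 50 times each at the 1000 × 200 scale with fixed seeds; a full
scan including the 100-replicate null costs well under two seconds because
the scoring core is vectorised (sort/rowsum). Everything downstream of a
seed is deterministic, including file outputs.

## Known limitations

* Multiplicity-1 assumption in CCF estimation; use external CCFs where
  copy-number states are complex.
* The driver-model likelihood assumes all listed drivers equally mutable;
  the override exists precisely because this is the weakest assumption.
* The empirical-null FDR is as grainy as the number of replicates at small
  ranks; below ~20 genes the cutoff moves in integer steps.
* Genes absent from the gene-context table cannot be scored at all.
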