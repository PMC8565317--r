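---
title: "Methods: replication-linked mutational gradients in mtDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replication-linked mutational gradients in mtDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitogradient)
```

## The scientific model

Vertebrate mitochondrial DNA is thought to replicate by an asynchronous
strand-displacement mechanism: synthesis starts at the heavy-strand origin
(Ori_H, inside the non-coding control region, mCR), displaces the parental
heavy strand into a single-stranded state, and only once the fork passes the
light-strand origin (Ori_L, ~11 kb away) does the complementary strand begin
its counter-directional synthesis. Single-stranded DNA deaminates readily
(dC to dU, dA to dI), so positions that spend longer single-stranded should
mutate more. On the reference (light) strand this predicts **linear
gradients in G>A and T>C mutation frequency** along each of the two arcs
delimited by Ori_L and the mCR — and *flat* profiles for the complementary
classes C>T and A>G, because the strand asymmetry of the exposure is what
creates the signal.

`mitogradient` implements the analysis stack that quantifies this
prediction:

1. **Binned frequency.** The genome is tiled into fixed-width bins (100 bp
   by default; 163 bins on the 16,299-bp mouse genome, the last one 99 bp).
   For bin $i$ and mutation class $N$,
   $$F_i^N = \frac{\sum_j M_{ij}}{\sum_j S_{ij}},$$
   where $M_{ij}$ counts class-$N$ variants of sample $j$ in bin $i$ and
   $S_{ij}$ is sample $j$'s duplex depth summed over the bin's positions
   whose reference base is the class's wild-type base. This is a ratio of
   sums — a depth-weighted mean — so pooling samples before or after
   binning gives identical results (asserted exactly in the tests).
   Variants are admitted only when their allele fraction is strictly below
   1%, which suppresses inherited and early-arising mutations.
2. **Arc regression.** $F_i^N$ is regressed on bin index separately within
   the minor arc (mouse bins 1–47) and major arc (bins 53–153) with a Huber
   M-estimator; the Ori_L gap (bins 48–52) and the mCR (bins 154–163) are
   excluded by construction. Aging effects are estimated by
   $Y = \alpha + \beta_{bin} b + \beta_{age} a + \beta_{b \times a} (b\,a)$
   with $a \in \{0, 1\}$ coding young/old; $\beta_{b\times a}$ is the
   old-minus-young slope difference.
3. **Composition-aware permutation null.** Because base composition and
   coverage vary along the genome, slope significance is assessed by
   scattering the observed per-class mutation total across the coding bins
   (1–153) with probabilities proportional to each bin's mutable-base
   depth, re-forming frequencies with the *real* denominators, and
   refitting the arc regression — 10,000 times by default. The p-value is
   the fraction of permuted slopes at or above the observed one (one-tailed
   by design; a two-tailed variant is a flag). No pseudo-count is added, so
   the granularity is $1/n_{perm}$ and a raw zero prints as
   "< 1/n_perm".
4. **Control-region scan.** The mCR window is tiled into twenty 50-bp bins
   and the same depth-weighted scatter is repeated 100,000 times; per-bin
   empirical envelopes at the Bonferroni-corrected confidence
   $1 - 0.05/20 = 99.75\%$ (per-bin two-tailed threshold 0.0025) flag
   hot-spots ("over") and cold-spots ("under").
5. **SNP and composition gradients.** Population SNP lists are restricted
   to rare variants (frequency $\le$ 1:1000, inclusive) and recurrent
   entries collapse to a single de novo event; per-bin densities divide by
   the reference's wild-type base count, and gradients are summarized by a
   robust slope or a Spearman correlation. Across species, per-base
   composition slopes over the major arc are fit by OLS and the dG/dA (and
   dT/dC) slope pairs are rank-correlated: sustained G>A pressure predicts
   anti-correlation.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| bin size (somatic / mCR / SNP) | 100 / 50 / 200 | bp | resolution vs. per-bin counts at realistic mutation loads |
| VAF ceiling | 0.01 (exclusive) | fraction | excludes inherited/clonal variants |
| Huber constant `k` | 1.345 | standardized residuals | the conventional 95%-efficiency tuning; the estimator choice is named, constants follow common practice and are configurable |
| robust scale | MAD / 0.6745 | response units | standard M-estimation scale, re-estimated per iteration |
| permutations (gradient / mCR) | 10,000 / 100,000 | replicates | p-value granularity of 1e-4 / envelope tail resolution at 0.00125 |
| family alpha, K | 0.05, 20 | — | Bonferroni envelope level 99.75% |
| SNP frequency ceiling | 0.001 (inclusive) | fraction | rare variants minimize population structure |
| arc bounds | mouse bins 1–47 / 53–153 / 154–163 | bins | configuration, not constants: human coordinates differ |

The mouse mCR is stated as positions 15,400–16,299 (900 bp) yet the scan
uses twenty 50-bp bins; the package defaults to the 1,000-bp 20-bin window
15,300–16,299 implied by the Monte-Carlo analysis and exposes the window as
configuration.

## Numerical choices

* Reported fits use `MASS::rlm` (Huber psi, MAD scale, `acc = 1e-8`). On an
  exactly linear or constant response the robust scale degenerates, so the
  fit short-circuits to OLS — the point where the two estimators coincide;
  genuine IRLS non-convergence falls back to OLS with a warning, never
  silently. Standard errors are asymptotic; two-sided p-values use normal
  theory for the M-estimator (t for OLS fallbacks). A constant response
  reports slope 0 with p = 1.
* The permutation null refits tens of thousands of single-regressor Huber
  lines, so replicates are fit by a vectorized IRLS implementing the same
  estimator (OLS start, MAD/0.6745 scale per iteration, `min(1, k/|u|)`
  weights). A dual-route test requires agreement with `MASS::rlm` to 1e-6;
  columns whose robust scale collapses to zero are frozen at their exact
  solution.
* Bins with zero mutable-base depth are *missing*, not zero — 0/0 is not
  evidence of absence — and are dropped listwise from fits; zero-depth bins
  get zero permutation weight.
* Envelope bounds are nearest-rank empirical quantiles (`type = 1`), i.e.
  the "confidence interval over simulations" is an empirical envelope, and
  widening the family alpha can only narrow it.
* Coordinates are 1-based inclusive throughout; BED input is converted at
  the I/O boundary. The final partial bin is retained, never merged.
* Ties in Spearman correlations use the asymptotic approximation
  (`exact = FALSE`).

## What the generator emulates — and what it does not

`simulate_mutation_dataset()` realizes exactly the structure the stages
assume: for class $N$, arc bin $b$ and age multiplier $m$, the per-base
rate is $m\,(b_N + g_N b)$ inside the arcs and $m\,b_N$ elsewhere; counts
are Binomial(depth, rate) per position and sample, and each mutant molecule
becomes a VAF $= 1/\text{depth}$ record. This is a deliberate choice: the
analysis assumes linearity-in-bin, so the generator's mechanistic knob is
the minimal linear rate model, not a biophysical simulation of
single-strand exposure times.

Defaults are the documented study conditions: 16,299-bp genome, mouse-like
base composition (A 34.6%, C 24.3%, G 12.3%, T 28.8%), 40 young + 45 old
samples across eight tissue labels, constant duplex depth $10^4$ per
position, transition baselines of order $10^{-6}$, gradient slopes G>A
$3\times10^{-8}$ and T>C $5\times10^{-9}$ per bin at the young scale, and
an old-age multiplier of 2.5 — so the old-cohort G>A major-arc slope is
$7.5\times10^{-8}$ per bin and the expected burdens are roughly 230 (young)
and 580 (old) mutations per sample, a mean density of ~0.025 mutations/bp.

Real duplex data differ in ways the generator ignores: overdispersed and
position-correlated coverage (a negative-binomial depth option exists but
constant depth is the analytic default), sequence-context rate
heterogeneity within a bin, clonal expansions producing correlated VAFs,
tissue-specific spectra, and the mCR's peculiar structure. Passing tests
therefore demonstrate that the *statistical machinery* is calibrated and
recovers known truth under the model's assumptions — not that real data
satisfy those assumptions.

`simulate_species_set()` draws per-species (dG, dA) slope pairs from a
truncated bivariate normal (target correlation −0.6, sd 0.05 %/bin around
means ∓0.05) and samples arc sequences with linearly trending base
probabilities; the complementary C/T share takes up the remainder at a
fixed ratio. Truncation keeps every probability inside (0, 1); because
per-species fits add estimation noise, the recovered cross-species Spearman
correlation is mildly attenuated relative to the injected −0.6, which the
recovery band accounts for.

## Problem sizes used in the tests

Validation suites run at reduced but statistically adequate scale, chosen
once as part of the package design: slope recovery uses 200 replicates of a
10-sample, depth-$10^4$ design; null calibration uses 500 trials of a
4-sample, depth-$5\times10^3$ design at 1,000 permutations; the scan
coverage/detection suites use 200 null and 100 spiked windows at 20,000
replicates with per-bin expectations of 20 (null/cold-spot) and 3 (spike)
events; cross-species recovery uses 100 replicates of 300 species with
10-kb arcs; the end-to-end recovery loop uses 100 runs of an 8+8-sample
design at 400 permutations.

## Design decisions and limitations

* Permutations scatter pooled per-class totals, not per-sample sets,
  matching the definition of the null as "the same total load, placed by
  composition alone"; the frequency statistic is pooled anyway.
* The spiked-hot-spot detection scenario uses a moderate per-bin baseline
  (~3 expected events): a 10-fold spike inflates the window total and hence
  the envelope's center for every bin, so very large baselines would make
  innocent bins drift below the lower bound — a property of envelope tests
  generally, worth remembering when interpreting real scans.
* Composition-gradient extraction takes arcs from explicit coordinates
  (FASTA + coordinate table or in-code records); annotation-driven arc
  discovery from flat-file features is deliberately out of the tested
  surface, and heterogeneous annotation conventions across species mean
  genome-wide species counts are not reproducible desk-side.
* No haplogroup correction of SNP lists (they are consumed pre-corrected),
  no four-fold-degenerate-site analysis, no indel handling, no segmented
  regression: arc boundaries are configuration.
* One stated property of a 12-class null screen — "no class significant in
  ≥90% of runs" — cannot hold for 24 uniform one-tailed tests at 0.05
  (expected family rate ≈ 1 − 0.95²⁴ ≈ 0.7); the package instead verifies
  per-class type-I calibration, which is the well-posed version.
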