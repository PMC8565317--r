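# mitogradient

Somatic mutations in mitochondrial DNA are not spread evenly around the
genome: under the asynchronous strand-displacement model of mtDNA
replication, the parental heavy strand lingers single-stranded — and
deamination-prone — for a time that grows with distance from its origin, so
reference-strand **G>A and T>C mutation frequencies should rise linearly
along each replication arc** (the segments delimited by the light-strand
origin Ori_L and the control region, mCR), while their complementary
classes stay flat. `mitogradient` is an R toolkit for researchers analyzing
duplex-sequencing variant calls, population SNP lists, tumor variant
catalogs, or cross-species genome composition who want to quantify, test,
and simulate that replication-linked gradient.

## What it computes

For bin $i$ and mutation class $N$ (12 classes, labeled on the reference
L-strand; H-strand calls are complemented on input):

$$F_i^N = \frac{\sum_j M_{ij}}{\sum_j S_{ij}}, \qquad \text{VAF} < 1\%,$$

with $M_{ij}$ the class-$N$ mutation count of sample $j$ in bin $i$ and
$S_{ij}$ the duplex depth over the bin's wild-type bases. Within each arc,
$F_i^N$ is regressed on bin index with a Huber M-estimator
($k = 1.345$, MAD scale), optionally with the aging model
$Y = \alpha + \beta_{bin} b + \beta_{age} a + \beta_{b\times a} (ba)$,
$a \in \{0,1\}$. Slope significance comes from a composition-aware
permutation null (mutation totals scattered over bins with
depth-proportional weights, 10,000 replicates; $p$ = fraction of permuted
slopes $\ge$ observed). A 100,000-replicate Monte-Carlo envelope at the
Bonferroni-corrected 99.75% level (20 bins × 50 bp) flags control-region
hot- and cold-spots. Companion stages compute SNP-density gradients
(rare variants, frequency ≤ 1:1000, recurrences collapsed; density =
variants per wild-type base) and per-species base-composition slopes whose
dG/dA and dT/dC pairs are rank-correlated across species. A forward
simulator with recorded ground truth backs every stage.

## Worked example

Simulate the documented paired-cohort design (40 young + 45 old samples,
depth 10⁴, G>A gradient 3×10⁻⁸ per bin at the young scale, old multiplier
2.5) and run the gradient stage:

```r
library(mitogradient)

cfg <- simulation_config()            # the documented study design
sim <- simulate_mutation_dataset(cfg, seed = 7)
nrow(sim$records)
#> [1] 34081

mutation_summary(sim$records, 16299)$groups
#>   group n_mutations n_samples mean_per_sample
#> 1 young        8813        40        220.3250
#> 2   old       25268        45        561.5111

tab <- binned_frequency(sim$records, sim$depths, sim$genome, sim$bins)
fit <- fit_arc_gradient(tab, arc_bin_range(mouse_mt_arcs(), "major"),
                        class = "G>A", arc = "major")
fit
#> <arc_fit> G>A [major] slope = 5.052e-08 +/- 3.075e-09 per bin,
#>           p = 1.26e-60 (n = 101, huber)

ct <- tab[tab$class == "G>A", ]
S  <- ct$mutable_depth[match(1:153, ct$bin)]   # coding-region denominators
perm <- gradient_permutation_test(
  n_mutations = sum(ct$mutation_count[ct$bin %in% 1:153]),
  weights = compute_bin_weights(S, 1:153), bin_depths = S,
  arc_bins = 53:153, observed_slope = fit$slope, n_perm = 10000)
perm
#> <permutation_test> observed slope = 5.052e-08, p < 0.0001
#>   (0 of 10000 permuted slopes >= observed)
```

Reading the output: the pooled-cohort G>A major-arc slope (~5×10⁻⁸ per
100-bp bin, the depth-weighted blend of the injected young 3×10⁻⁸ and old
7.5×10⁻⁸ slopes) is recovered with a ~3×10⁻⁹ standard error, and none of
10,000 composition-aware permutations reaches it — the gradient is not an
artifact of base composition or coverage. `run_somatic_gradient()` wraps
this loop over all classes and arcs (plus the age-interaction model and
leave-one-tissue-out refits), and `run_mcr_scan()` produces the
control-region hot/cold-spot table.

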