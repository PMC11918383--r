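# haplopaint

Local ancestry painting, phase-switch correction and diversity statistics
for supergene haplotypes.

Inversion supergenes — large rearranged regions that hold divergent
haplotype groups together by suppressing recombination between
arrangements — still leak: crossovers occur between adjacent rearranged
modules, and occasionally within inversions. haplopaint is a toolkit for
finding those events in phased resequencing data. It is aimed at population
genomicists working with a cohort VCF, a set of reference individuals per
haplotype group, and a physical map of the supergene's modules.

## What it computes

* **Window-based ancestry painting.** Each phased query haplotype is
  classified in consecutive 200-SNP windows by its genetic distance
  (proportion of differing alleles over pairwise-complete sites, i.e.
  per-window d<sub>XY</sub>) to each reference panel. The nearest panel wins
  a window only when a one-sided Wilcoxon rank-sum test gives
  p ≤ 0.01 against **every** other panel; otherwise the window is
  `UNDEFINED`. Runs of identical labels merge into ancestry tracts.
* **Heuristic phase correction.** A statistical-phasing switch error turns a
  heterozygote carrying two intact haplotypes into two reciprocal painted
  mosaics. The corrector greedily exchanges tract labels between an
  individual's two haplotypes wherever that strictly increases the mean
  similarity to the three most similar other haplotypes in the cohort
  (left-to-right then right-to-left, iterated to convergence or a cap),
  minimising spuriously inferred recombination.
* **Windowed statistics.** Nucleotide diversity π, absolute divergence
  d<sub>XY</sub>, net divergence d<sub>a</sub> = d<sub>XY</sub> − (π₁+π₂)/2
  and Hudson's F<sub>ST</sub> = 1 − H<sub>w</sub>/H<sub>b</sub> in 50-kb
  windows; the diploid mean-pairwise-distance matrix (Neighbor-Net input);
  LD r² from phased haplotype frequencies; the effective-migrants conversion
  M<sub>e</sub> = 4 N<sub>e</sub> m<sub>e</sub>.
* **Filters.** Genotype DP ≥ 7 / GQ ≥ 30 masking and site-level
  missingness / heterozygosity-excess / minor-allele-count rules.
* **Evaluation.** Breakpoint recall and localization against simulation
  truth, classification of breakpoints as between-module, within-module or
  outside the supergene, detection of shared recombinant mosaics, and
  switch-error recovery scoring.
* **Simulation.** A Balding–Nichols cohort generator (group differentiation
  parameter F = expected F<sub>ST</sub>) with planted recombinant mosaics,
  phase-switch errors, missing data, a masked CNV gap, and exact truth
  tables.

All user-facing functions take and return tibbles (or small S3 containers
with `tidy()` / `glance()` methods), so results chain with the usual
dplyr/ggplot2 workflow; `plot_painting()` and `plot_window_stats()` give
quick figures.

## Worked example

Simulate a cohort of six heterozygous individuals, one heterozygote with a
planted phase-switch error at 600 kb, and one true recombinant with an
A→B crossover at 500 kb; paint, correct, and score:

```r
library(haplopaint)
library(dplyr)
library(tibble)

cohort <- tibble(
  sample = c(sprintf("d%02d", 1:6), "het1", "rec1"),
  hap_a  = c(as.list(rep(c("A", "B"), 3)), list("A"),
             list(mosaic(c("A", "B"), c(5e5, 1e6)))),
  hap_b  = c(as.list(rep(c("B", "A"), 3)), list("B"), list("B")))
cfg <- sim_config(seed = 11, chrom_length = 1e6, n_sites = 10000L,
                  groups = tibble(label = c("A", "B"), f = 0.3, n_panel = 10L),
                  cohort = cohort,
                  switch_errors = tibble(sample = "het1", pos = 6e5))
sim <- simulate_cohort(cfg)

h       <- split_haplotypes(sim$genos)
queries <- paste0(rep(cohort$sample, each = 2), c("_A", "_B"))
painted <- paint_all(h, sim$panels, paint_config(window_snps = 200L),
                     queries = queries)
glance(painted)
#> # A tibble: 1 × 4
#>   n_haplotypes n_windows assigned_fraction n_tracts
#> 1           16        50                 1       19

corrected <- phasepaint_correct(build_label_matrix(painted))
switch_recovery(corrected$labels, sim$truth)
#> # A tibble: 1 × 3
#>   n_switches n_eliminated switch_recovery
#> 1          1            1               1

painting_accuracy(label_matrix_to_tracts(corrected$labels), sim$truth$tracts)
#> # A tibble: 1 × 2
#>   assigned_fraction accuracy
#> 1             1.000    1.000

tidy(painted) %>% filter(haplotype_id == "rec1_A")
#> # A tibble: 2 × 5
#>   haplotype_id chrom  start    end label
#> 1 rec1_A       chr15    147 498418 A
#> 2 rec1_A       chr15 498432 999923 B
```

Every window was assigned (`assigned_fraction = 1`), the planted switch
error was eliminated, post-correction painting matches the planted truth
everywhere, and the recombinant's inferred breakpoint (between positions
498,418 and 498,432) sits within one window of the planted crossover at
500,000. Windowed statistics on the same cohort give a mean
F<sub>ST</sub> of 0.284 across 50-kb windows against the generating
F = 0.3 at this panel size.

## Acceptance script

`scripts/acceptance.R` exercises the installed package end to end from a
seed: it simulates a supergene cohort (two diverged groups over a modular
supergene map with a masked CNV gap, heterozygotes, one planted switch
error, one between-module and one within-module crossover), round-trips the
VCF, filters, paints, phase-corrects, scores painting accuracy, switch
recovery and breakpoint classification, and writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
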