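---
title: "Painting supergene haplotypes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting supergene haplotypes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(haplopaint)
library(dplyr)
library(tibble)
```

## The problem

Inversion supergenes hold together divergent haplotype groups by suppressing
recombination between structurally distinct arrangements. Recombination
suppression is rarely complete: crossovers between adjacent rearranged
modules, double crossovers within inversions, and gene conversion all leak
genetic material between haplotype groups. Detecting those events from
population resequencing data requires (i) assigning each segment of each
phased haplotype to the reference group it most resembles (local ancestry
painting), (ii) cleaning up statistical-phasing switch errors that masquerade
as reciprocal recombination events, and (iii) classifying the surviving
ancestry breakpoints against the physical layout of the supergene's modules.
haplopaint implements that pipeline, together with the windowed diversity and
divergence statistics used to characterise the haplotype groups, and a
simulator that generates cohorts with known truth for validating every step.

## The painter

A query haplotype is compared window by window against reference panels of
haplotypes with known group membership. Windows are consecutive blocks of a
fixed number of SNPs (default 200; a trailing block shorter than half a
window is dropped). Within a window, the distance from the query to each
panel haplotype is the proportion of differing alleles over the sites
non-missing in both (pairwise deletion). The candidate group is the panel
with the lowest mean distance; the window is assigned to the candidate only
when a one-sided Wilcoxon rank-sum test finds the query's distances to the
candidate significantly lower than its distances to *every* other panel at
`p <= alpha` (default 0.01); otherwise the window is `UNDEFINED`. Runs of
identically labelled windows merge into tracts.

Choices that matter and why:

* **Windows are disjoint, not stepped.** Tract output implies disjoint
  support; overlapping windows would double-count evidence. A window size of
  200 SNPs trades breakpoint resolution against the power of the rank-sum
  gate; with 20-haplotype panels the exact null is left behind
  (n1 + n2 > 20) and the normal approximation with tie and continuity
  correction is used.
* **All-pairwise gating.** With more than two panels, the candidate must beat
  every alternative at `alpha`. This is the conservative generalisation of
  the two-panel rule; a candidate that dominates one panel but not another
  leaves the window `UNDEFINED`.
* **No multiple-testing correction across windows.** The gate is a fixed
  per-window threshold, which is a liberal choice made for fidelity to the
  procedure the pipeline reproduces; treat per-window assignments as
  descriptive, not as hypothesis tests.
* **Ties and thin panels.** Exactly equal candidate means give `UNDEFINED`.
  A panel haplotype sharing fewer than 25% of a window's sites with the
  query is dropped from that window's sample, preventing near-empty
  distance samples under heavy missingness.
* **Leave-one-out.** A query that is itself a panel member is painted with
  itself excluded from its panel's distance sample, so panels can be painted
  without self-matching bias.
* **Breakpoint resolution.** Tract boundaries always coincide with window
  boundaries; an inferred breakpoint coordinate is the midpoint of the gap
  between the flanking windows' edge SNPs and is only accurate to window
  resolution. Nothing downstream assumes finer accuracy.

## The phase corrector

Statistical phasing makes switch errors: downstream of some point, the
maternal/paternal assignment of alleles is exchanged. In a heterozygous
individual carrying two intact supergene haplotypes, a single switch error
paints as two reciprocal mosaics — apparently two recombination events at the
same position, which is far less likely than one phasing mistake. The
corrector works on painted labels over the *atomic partition* (the union of
all tract boundaries across all haplotypes). For each individual, each
interval is visited left to right; the labels of the individual's two
haplotypes at that interval are tentatively exchanged, and the exchange is
kept only if it strictly increases the sum, over the two haplotypes, of the
mean similarity to the three most similar other haplotypes in the cohort,
evaluated over intervals up to and including the focal one. A right-to-left
pass follows, evaluating from the focal interval to the chromosome end. One
iteration is both passes over all individuals; iteration stops at
convergence (an iteration with no accepted swap) or at `max_iter`.

Similarity between two label vectors is the length-weighted fraction of
intervals with equal labels, over intervals where both labels are defined;
`UNDEFINED` intervals carry no evidence either way. The individual's own
partner haplotype is excluded from the top-three pool, since its similarity
is an artefact of the very swap being evaluated. Comparisons use the current
state of the cohort (samples in input order), which makes the procedure
deterministic; a switch log records every accepted swap and replays exactly.

Known behaviour worth understanding:

* **Shared mosaics are preserved by design.** The objective rewards
  similarity to other haplotypes, so two or more individuals carrying the
  *same* mosaic support each other and are not "corrected". That is the
  desired behaviour for real shared recombinants, but it also means that
  coincident switch errors in several samples of the same heterozygous
  combination — coincident at window resolution — are indistinguishable from
  shared recombinants and will survive correction. Benchmarks should plant
  switches in distinct windows.
* **Directional livelock.** The left-to-right pass evaluates a prefix and
  the right-to-left pass a suffix. A swap can strictly improve the prefix
  objective while its reversal strictly improves the suffix objective, in
  which case the two passes oscillate; the iteration cap bounds this. The
  oscillation only arises for intervals where the evidence genuinely
  conflicts (typically around real recombinant boundaries), and the label
  multiset per sample and interval is conserved regardless, so no ancestry
  is created or destroyed.
* **Strict increase.** Ties are rejected, which guarantees that each pass
  can only improve its own objective and that a convergent iteration is a
  fixed point.

## Windowed statistics

Diversity and divergence are computed in non-overlapping physical windows
(default 50 kb, half-open `[start, start + size)` on 1-based starts):
nucleotide diversity `pi` within each population (mean pairwise difference
proportion), absolute divergence `dxy` between populations, net divergence
`da = dxy - (pi1 + pi2) / 2` (an identity that holds to machine precision on
every emitted row), and FST. Each haplotype pair uses its own
pairwise-complete site count. The package uses Hudson's FST estimator,
`1 - Hw/Hb`, with the within and between mean distances computed as ratios
of window sums; under the simulator's Balding-Nichols model its expectation
equals the differentiation parameter F, which provides a closed-form check
(see below). Windows with fewer than 20 usable sites are emitted with `NA`
statistics rather than noise. LD is summarised as `r^2` from phased
haplotype frequencies, with complete-case site handling, a minor allele
frequency floor (default 0.2) and seeded thinning.

The effective-migrants conversion `Me = 4 Ne me` is exposed as a pure
function that records which `Ne` it was given; published tables mixing
"source" and "recipient" conventions can be reproduced by passing the
corresponding `Ne` explicitly.

## Genotype and site filters

Genotype-level: calls with depth below 7 or genotype quality below 30
(inclusive thresholds) become missing. Site-level, applied after the
genotype filter: a site is dropped when its called-haplotype count falls
below `floor((1 - f) * N)` for missing-fraction ceiling `f` (at `f = 0.10`,
348 haplotypes give a minimum count of 313, and 249 give 224), when more
than 75% (or 60% upstream of painting) of called individuals are
heterozygous — a mis-mapping signature that breaks ancestry tracts — or when
the minor allele is present fewer than twice. The heterozygosity denominator
is the individuals *called* at the site, so high missingness is not
penalised twice. Filtering is idempotent and monotone: a stricter
configuration never resurrects a site.

## The simulator and what a green test establishes

The generator is a Balding-Nichols frequency model, not a coalescent: each
site draws an ancestral frequency `p ~ Uniform(0.05, 0.95)`, each haplotype
group draws its frequency from `Beta(p(1-F)/F, (1-p)(1-F)/F)` (degenerating
to `p` at `F = 0`), and haplotypes are Bernoulli draws. Recombinant mosaics
draw each site from the group owning its tract, so planted breakpoints are
exact; switch errors exchange the A/B assignment downstream of a point; and
missingness is independent per genotype. A masked module interval (the
copy-number-variable region that cannot be genotyped in real data) carries
no sites. One seeded stream drives positions, then frequencies, then
alleles, so a seed pins the whole cohort byte for byte.

Default scale is one 2 Mb chromosome arm with 20,000 SNPs — the SNP density
at which 200-SNP painting windows span about 20 kb, comparable to the
resolution of the analyses the pipeline supports — and two groups at
`F = 0.2` with 20 panel haplotypes each, a moderate differentiation at which
both the FST expectation and painting are non-trivial. The model gives
labelled divergence with closed-form expectations (`E[FST] = F` under
Hudson's estimator; expected between-group distance exceeds within-group
diversity for `F > 0`), which is exactly what the painter, corrector and
statistics need for validation. It deliberately omits genealogical
correlation between sites, LD decay, recombination-rate variation and
selection; a green test therefore establishes correctness of the *methods*
on data satisfying their assumptions, not robustness to every property of
real resequencing data.

## Numerical and degenerate-input conventions

* Coordinates: VCF positions are 1-based; tracts and module intervals are
  1-based inclusive; stat windows are half-open. Every writer states the
  convention in its header.
* Distances with no pairwise-complete sites, windows with too few sites,
  accuracy with no assigned span, and FST with zero between-group
  denominator all yield `NA`, never 0.
* Half-called genotypes (`0|.`) are treated as fully missing; unphased
  *called* genotypes are a refusal, not a silent guess, when splitting
  haplotypes.
* Haploid samples (e.g., W-linked haplotypes in females) emit a single
  flagged haplotype rather than a duplicated pair, so they contribute one
  haplotype to allele counts and panels can address them explicitly.
* The exact rank-sum branch is used when `n1 + n2 <= 20` and the combined
  sample is tie-free; otherwise the normal approximation with midrank tie
  correction and continuity correction.
* Breakpoint matching in evaluation is greedy nearest-first with each
  inferred boundary used once; boundaries adjacent to `UNDEFINED` tracts are
  excluded as unevidenced.

## A worked example

Simulate a cohort with one heterozygous individual carrying a planted switch
error and one recombinant, paint it, correct it, and score it:

```{r example}
cohort <- tibble(
  sample = c(sprintf("d%02d", 1:6), "het1", "rec1"),
  hap_a = c(as.list(rep(c("A", "B"), 3)), list("A"),
            list(mosaic(c("A", "B"), c(5e5, 1e6)))),
  hap_b = c(as.list(rep(c("B", "A"), 3)), list("B"), list("B")))
cfg <- sim_config(seed = 11, chrom_length = 1e6, n_sites = 10000L,
                  groups = tibble(label = c("A", "B"), f = 0.3, n_panel = 10L),
                  cohort = cohort,
                  switch_errors = tibble(sample = "het1", pos = 6e5))
sim <- simulate_cohort(cfg)

h <- split_haplotypes(sim$genos)
queries <- paste0(rep(cohort$sample, each = 2), c("_A", "_B"))
painted <- paint_all(h, sim$panels, paint_config(window_snps = 200L),
                     queries = queries)
glance(painted)

corrected <- phasepaint_correct(build_label_matrix(painted))
glance(corrected)
switch_recovery(corrected$labels, sim$truth)
painting_accuracy(label_matrix_to_tracts(corrected$labels), sim$truth$tracts)
```

The painted set can be drawn with `plot_painting(painted)` (or `autoplot`),
and windowed statistics with `plot_window_stats(windowed_stats(h, sim$panels))`.

## Limitations

* The painter is a window classifier, not an HMM: it has no transition
  model, so breakpoint positions are window-resolution estimates and short
  introgressed tracts below the window size are invisible.
* The rank-sum gate controls per-window error only; genome-wide, some
  windows will be assigned by chance at `alpha = 0.01`.
* The phase corrector is greedy and cohort-driven: it requires intact
  carrier haplotypes to act as donors, preserves shared mosaics (real or
  artefactual), and optimises a directional objective that can oscillate up
  to the iteration cap.
* The simulator's independence across sites makes statistical power on
  simulated data an upper bound on power for autocorrelated real data.
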