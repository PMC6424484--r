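---
title: "Methods: functional phylogeography of domestication alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional phylogeography of domestication alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A domesticated crop differs from its wild progenitor by a handful of causal
mutations — loss of seed shattering, erect growth, and similar domestication-
syndrome traits. Where did each mutation arise? The procedure implemented
here answers this per locus: find the haplotype on which the mutation
occurred, find the most closely related haplotype *without* the mutation
(usually surviving in the wild relative), and map where the two co-occur.
The region where the ancestral and derived haplotype ranges overlap is the
best-supported place of origin. Different loci may point to different
regions — evidence for a non-centric, multiregional domestication.

Everything downstream of genotype calling is in scope: group curation,
window statistics and sweep scans, read-depth deletion genotyping,
four-gamete screening, network construction and the origin call. Alignment,
variant calling, imputation/phasing and admixture-graph fitting are not.

## Pipeline stages and their assumptions

### Site filters and windows

Sites are kept when their genotype call rate is at least 80% and their
minor allele frequency at least 2% (`filter_sites()`); both cutoffs are
`pipeline_config()` fields. Diversity statistics use non-overlapping
10,000 bp windows. Within a window, sites with call rate ≥ 80% are
*accessible* and form the denominator of the per-site estimates; windows
with under 30% accessible sites are discarded. Missing genotypes are never
imputed — every statistic uses pairwise deletion, with per-site `n` equal
to the number of non-missing haplotypes.

π is the mean pairwise difference per accessible site,
θ̂~W~ sums 1/a~n−1~ over segregating sites, and Tajima's D uses the
standard e₁/e₂ constants evaluated at the window's mean per-site `n`
(rounded). D is reported only when at least four haplotypes are typed and
the variance term is positive. Because the denominator is accessible
*segregating-panel* sites rather than base pairs, absolute levels are not
comparable across panels; ratios and window ranks (all this package uses
them for) are unaffected.

### Sweep scan

The scan statistic is π~w~/π~D~ per window: wild diversity over the
diversity of the domesticates *carrying the causal allele* (carrier status
is observed — the causal-SNP genotype or the read-depth deletion call, via
`observed_carriers()`). Within a sweep the carriers descend from a single
selected haplotype, so their π collapses and the ratio diverges; windows
with π~D~ = 0 get an infinite ratio and are always flagged. Finite ratios
are flagged at the empirical 99th percentile (type-7 quantile over finite
ratios), with the extra requirement of strictly exceeding the genome-wide
minimum so that a degenerate all-equal ratio distribution flags nothing.

Hudson's F~ST~ uses the unbiased ratio-of-averages estimator. Its
sampling-correction terms make the estimate slightly *negative* when two
samples have identical observed frequencies; this is expected behaviour of
the estimator, not a bug, and the tests assert exactly that.

LD is the squared Pearson correlation of alt-allele dosages (phase-free,
the PLINK convention), restricted to pairs within 1 Mb windows and averaged
in 1 kb distance bins; a centred moving average (`ld_smooth()`) is provided
for plotting instead of curve fitting. The f4 statistic is the mean of
(p~A~−p~B~)(p~C~−p~D~) with a delete-one jackknife over consecutive
100-SNP blocks.

### Group curation (silhouette core sets)

Group labels come from the metadata, not from clustering; the silhouette
filter *curates* given labels. Distances are 1 − IBS over mutually typed
sites, computed after LD thinning (one random site per 50 kb window, ≥25 kb
spacing). For sample *i*, a(i) is the mean distance to its own group and
b(i) the mean distance to the *nearest* foreign group — the standard
Rousseeuw convention; the all-foreign-mean reading of "the foreign group"
is available via `b_mode = "all-foreign-mean"`. Each iteration removes all
negative-score samples if any exist, otherwise all samples at or below the
threshold; iteration stops when every score exceeds the threshold or a
group would fall below two members (then the run stops and is flagged).
Batch removal keeps the procedure order-free and deterministic. The default
threshold is 0.1; 0.12 is equally defensible (both appear in practice) and
is exposed as `silhouette_threshold`. NJ trees delegate to `ape::nj`
(branch lengths clamped at zero) and MDS to classical Torgerson scaling
with a fixed sign convention (first non-zero loading of each axis
positive), so outputs are reproducible.

### Deletion genotyping

A sample's gene is called deleted when its median read depth over the gene
is exactly zero, or at most `deletion_ratio_threshold` (default 0.1) times
the median depth of a control gene outside the deletion region; samples
whose control median is below `control_min_depth` (default 1×) are
no-calls. The zero-median rule keeps the caller usable at ~1× coverage,
where a present gene still shows a median near 1 but a deleted gene shows
exactly 0. Deletion frequency per group counts individuals,
deleted/(deleted+present), no-calls excluded. Hemizygous carriers are not
modelled by the rule: an intermediate ratio is reported as-is and
classified by the single threshold. Shared deletions are also visible as
SNP deserts — `snp_desert_regions()` reports gaps between consecutive
filter-passing sites above a minimum length, with the flanking passing
coordinates.

### Four-gamete screening and networks

Haplotype analysis requires phased input (the generator is phased by
construction); haplotypes with any missing site in the region are excluded
and counted. All site pairs are tested for the four-gamete condition
separately within the wild and domesticate partitions; a fourth gamete
below 1% frequency is treated as genotyping error. Recombination inside the
domesticate partition rejects the region — `select_nonrecombining_region()`
then shrinks the region (×0.75 per attempt) until it passes. Wild-only
recombination removes the haplotypes carrying the minority (fourth) gamete
at each failing pair (ties broken toward the gamete carrying the rarer
allele at the first site, then the second) and re-scans until clean, so the
output always passes a full re-scan.

Identical haplotypes collapse into nodes labelled by roman numerals
(descending count, then first occurrence). The network is the minimum
spanning tree of the complete hamming graph, built by Kruskal's algorithm
with ties broken toward earlier node labels: MSTs are not unique, so
determinism has to be imposed; the total weight is minimal regardless.

### Origin inference

Nodes are polarized by the allele at the causal site (or by deletion-call
carrier status). Each derived node is paired with the ancestral node at
minimum tree-path weight (ties reported as multiple pairs), and the derived
node closest to any ancestral node is flagged as the putative founding
haplotype — later derived haplotypes are treated as expansion range, so the
founding pair drives the origin call. Per region, the overlap score is
min(freq~anc~, freq~der~), frequencies being carrier haplotypes over
haplotypes sampled in the region; the top-scoring region(s) are the call,
and fully disjoint ranges return an explicit "indeterminate" status. The
min() rule rewards joint presence without letting one abundant haplotype
dominate; the product rule is available as `method = "product"`. No formal
confidence level is attached — ancestral haplotypes are typically carried
by a handful of wild individuals, so both carrier counts are always
reported alongside the call.

### Threshability

Percent shattering maps to the SES scale: <1% → 1, 1–5% → 3, (5, 25]% → 5,
(25, 50]% → 7, (50, 100]% → 9. The published band labels leave 16–25%
unassigned; this implementation maps the gap to score 5, which keeps the
scale monotone and matches the standard evaluation system. Band boundaries
are closed above. Group comparisons use the two-sided Mann-Whitney U test —
exact enumeration of the permutation distribution of U up to a combined
n of 20 (ties handled exactly), a tie-corrected normal approximation
beyond — with Bonferroni correction by the number of pairs. The concordance
table cross-tabulates allele statuses against score bands per group and
flags groups where identical genotype combinations span more than one score
band: the signature of an unmodelled causal gene.

## The synthetic metapopulation generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, not any particular demography. Geography is a one-dimensional
west→east axis of `n_regions` cells (5), because the inference concerns
coastal↔inland gradients; cells map to synthetic country labels and
coordinates are jittered uniformly within a cell.

**Founder pools on a perfect phylogeny.** Each region holds `k_founders`
(12) wild founder haplotypes. Every site receives exactly one mutation, on
one branch of a founder genealogy: a regional stem (mass
`region_mut_rate` = 0.03), a nested within-region clade or founder-private
tip (`founder_mut_rate` = 0.10), a domestication-drift tip private to the
domesticate copy of a pool founder (`dom_drift_rate` = 0.02), or the
domestication stem — sites fixed derived across the whole domesticate pool
(`dom_stem_rate` = 0.08). One mutation per site makes the pool
infinite-sites compatible, so recombination-free regions pass the
four-gamete test by construction, as real non-recombining regions do. The
mass split was chosen so that within-population diversity dominates
between-region divergence (as in real wild rice), which is what puts wild
LD below domesticate and feral LD; the domestication stem supplies the
fixed differences behind the large wild–domesticate F~ST~.

**Sampling.** Wild samples draw two haplotypes uniformly from their
region's pool; domesticates draw from a bottlenecked pool of `b_founders`
(4) drifted children of the first wild founders, with skewed weights
(0.4/0.3/0.2/0.1) — haplotype frequencies are never uniform in a real
bottlenecked crop. The feral group is a de-domesticated hybrid population:
per chromosome, each of `n_feral_founders` (6) founder haplotypes is copied
from a random source haplotype (wild with probability `feral_admixture`
= 0.25, else domesticate), and each feral individual draws its two copies
from that founder pool. Routing the mosaics through a small founder pool
reproduces the founder-effect LD that distinguishes real feral populations;
fully independent first-generation hybrids would have near-source LD.

**Causal loci.** The default loci are a causal SNP and two whole-gene
deletions, seeded in regions 3, 2 and 4. A domesticate in region r carries
a locus's derived haplotype with probability d^|r−origin| (`diffusion`
d = 0.5); carriers are homozygous for the single derived founder segment
within `sweep_halfwidth` of the locus (12 kb for the SNP, 10 kb for the
deletions — sweeps extend past the deleted span, which is itself blanked to
missing over ±3 kb and zeroed in read depth). The derived segment is the
origin region's first *wild* founder plus the causal mutation, so the
mutation's closest ancestral haplotype survives only in origin-region wild
plants — the structure the origin inference is designed to detect, with
ancestral carrier counts of the same order (a few) as real studies report.
Ferals inherit carrier status per copied haplotype; deletion zygosity is
tracked as 0/1/2 deleted copies and read depth scales accordingly
(homozygous deletions are exactly zero).

**Depths and phenotypes.** Per (sample, gene), the reported depth is the
median of per-base Poisson(`mean_coverage` = 15) draws. Percent shattering
decreases with the number of derived shattering-trait alleles (two →
<1%, one → 1–15%, none → 26–100%, wild always ≥51%), then maps through
`ses_score()`.

**Scale.** The default genome is 4 chromosomes × 2 Mb at one segregating
site per ~100 bp (80,000 sites, 245 samples) — large enough that the 10 kb
window count (800) makes a top-1% sweep tail meaningful and that a
replicate simulates and analyses in seconds on one core; the recovery
checks run 20 replicates at exactly these conditions.

**What it does not emulate** — and what passing tests therefore do not
show: recombination within chromosomes (LD does not decay with distance;
only level comparisons are meaningful), genotyping error and allele-calling
bias, realistic coalescent genealogies or demographic parameters (Ne,
growth, migration rates), heterozygous causal carriers among domesticates,
and sequence context (sites are abstract biallelic positions). Results on
real data additionally depend on upstream calling quality, which is out of
scope.

## Numerical and degenerate-input choices

* Coordinates are 1-based internally (VCF convention); windows tile
  half-open [1, w+1), [w+1, 2w+1), … per chromosome.
* Empirical percentiles use the type-7 (linear interpolation) quantile.
* Tajima's D is `NA` (flagged, never fabricated) below four typed
  haplotypes or at non-positive variance; windows with no accessible sites
  are omitted rather than zero-filled.
* F~ST~ windows with no usable site or a zero denominator are omitted;
  LD pairs with zero dosage variance at either site are skipped.
* `pairwise_distance()` errors (naming the pair) when two samples share no
  typed site, rather than returning a silent NA.
* The four-gamete "fourth gamete" at a failing pair is the minority-count
  gamete, with the documented two-step tie-break.
* All stochastic steps (simulation, site thinning, LD subsampling, depth
  draws) take explicit seeds; `run_pipeline()` writes byte-identical
  outputs for identical inputs and configuration.

## Known limitations

Origin calls rest on few ancestral carriers and carry no confidence level;
the report exposes both ns instead. The silhouette filter curates labels
but cannot invent better ones — mislabelled *groups* (as opposed to
individuals) survive curation. The deletion caller assumes an intact
control gene and homozygous deletions; hemizygotes land on the `present`
side of the default threshold. The sweep scan's carrier partitioning
requires the causal variant (or its deletion call) to be observable.
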