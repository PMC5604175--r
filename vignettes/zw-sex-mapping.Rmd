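---
title: "Mapping a ZW sex locus in a heterozygous F1 cross"
author: "zwmap developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a ZW sex locus in a heterozygous F1 cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dioecious crops with female-heterogametic (ZW) sex determination pose a
mapping problem that classical inbred-line designs cannot touch: both
parents of any cross are highly heterozygous, there is no BC1 generation,
and the trait of interest — sex — segregates in the F1 itself. `zwmap`
implements the analysis path for locating a female-specific (W-linked)
genomic region from a single F1 family:

1. **F1-adapted QTL-seq.** Bulked-segregant whole-genome sequencing of a
   female bulk and a male bulk, scored at *parent-specific heterozygous
   sites* — positions heterozygous in one parent and homozygous in the
   other, which segregate 1:1 in the F1 exactly like a backcross marker.
2. **W-region delineation by depth differential.** Mapping both bulks to a
   combined reference of the two parental assemblies and finding bases
   covered only by uniquely-mapping female-bulk reads.
3. **Pseudo-testcross RAD linkage mapping**, scaffold splitting and
   pseudo-molecule construction, which provide the coordinate system the
   first two steps are interpreted on.
4. Supporting estimators: k-mer and flow-cytometry genome size, assembly
   and annotation summaries, SSR scanning, and in silico PCR/CAPS
   genotyping of sex-diagnostic markers with exact association tests.

Every step can be exercised end-to-end on a synthetic dioecious
population with a known truth table.

## The SNP-index model

At a site, the SNP-index is the fraction of aligned reads carrying a
non-reference allele; the package uses the biallelic form
$\mathrm{index} = n_\mathrm{alt} / (n_\mathrm{ref} + n_\mathrm{alt})$,
discarding reads with a third base. For a site heterozygous in the female
parent (index in $[0.4, 0.6]$, zero non-reference reads in the male
parent, both depths $\ge 16$):

* if the alternate allele sits on the W haplotype inside the
  non-recombining sex-determining region, the female bulk (all ZW) has
  expected index $1/2$ and the male bulk (all ZZ) $0$, so
  $\Delta = \mathrm{index}_♀ - \mathrm{index}_♂ = 1/2$;
* at an unlinked site, each F1 is heterozygous with probability $1/2$,
  giving expected index $1/4$ in both bulks and $\Delta = 0$.

Significance is judged against a simulated null: for each observed depth,
10,000 replicates draw a bulk of 50 individuals (each heterozygous with
probability 1/2), then binomial read counts at that depth, in both bulks
independently; empirical quantiles of $\Delta$ give per-depth confidence
bounds. Per-site bounds are averaged inside each 1-Mb window (50-kb step)
and a window is significant when its mean $\Delta$ leaves the averaged
band; overlapping significant windows merge into candidate intervals.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| heterozygous band (parents) | [0.4, 0.6] | sampling scatter of a true het at depth ~40 |
| parent depth floor | 16 | "more than 15" read literally |
| bulk depth floor | 6 | excludes sites where the index is dominated by noise |
| window / step | 1 Mb / 50 kb | resolution vs. per-window site count at ~13x |
| CI replicates | 10,000 | quantile Monte-Carlo error ~ one lattice step of k/100 |
| calling level | 95% | conventional; 99% also tabulated |

The null simulation uses common random numbers across depth bins (shared
uniforms mapped through `qbinom`), so the tabulated half-widths are
weakly decreasing in depth up to residual Monte-Carlo noise.

## The W-region mapper

The mini-mapper is exact-seed (both read ends and the middle) with
bounded-Hamming extension and no indels; the MAPQ analog is binary:
a read is *unique* when exactly one placement attains the best mismatch
count. Ties are broken uniformly at random — a deterministic tie-break
would pile all multi-reads of a duplicated segment onto one copy and
fabricate "specific" coverage on the others. Bulk-specific regions are
maximal runs where the own bulk has unique coverage, the other bulk's
depth is at most 0 (configurable), and at least 90% of overlapping own
reads are unique. Contigs carrying fragments strictly longer than the
N20 of all specific-region lengths (or an explicit threshold) are
anchored on the reference by chained exact matches, and the minimal
interval covering the anchored female-specific regions is the W-region
call; coverage by a ZZ-genotype bulk can only remove bases from it.

## What the synthetic population emulates

`sim_config()` describes the stated world: two parents at per-bp
heterozygosity 0.002 each (plus shared-het and homozygous-different
sites), a 50-kb female-specific W insertion inside a 1.2-Mb
sex-determining region (SDR) in which every female-het site is Z/W
divergence (alternate allele on W) at elevated density 0.005/bp, 253 F1
progeny, bulks of 50, Poisson depth 13 per site, 100-bp reads with
substitution errors at 0.001/bp, Poisson crossovers (one per chromosome
per meiosis, no interference), and labile sex expression of ZW
individuals (ZZ is deterministically male). Two 3-Mb chromosomes keep
end-to-end runs inside seconds while leaving the 1-Mb window geometry
meaningful: the SDR spans multiple windows, so the windowed delta track
shows the same broad peak shape as real data.

Deliberately not modelled: read-quality variation (fixed Q40), PCR
duplicates, insert-size structure, indel errors and indel polymorphism,
crossover interference, reference mis-assembly. A green end-to-end test
therefore establishes that the statistics and region logic recover a
planted signal under the stated sampling model — not that the mapper
tolerates structural variation or that thresholds are optimal for any
particular real genome.

Two W-region validation worlds are used. With default heterozygosity the
SDR's divergence SNPs correctly produce short W-linked regions outside
the insertion (the analog of the many small female-specific fragments
seen in real data), so that world checks insertion *recovery* and
containment. The "boundaries within one read length" statement is only
about the method itself in a world where the parents are identical
outside the insertion, and is checked there.

## Numerical and design choices

* Coordinates are 0-based half-open internally; emitted BED is 0-based,
  TSV pileups 1-based (stated in their headers).
* All stated filter bounds are inclusive; "more than 15" and "fewer than
  6" become $\ge 16$ and $\ge 6$-retained.
* Reference substitution requires index exactly 1 at depth $\ge 5$; the
  synthetic world includes homozygous-different sites so this step has
  real work to do.
* Per-site CI lookup uses the smaller of the two bulk depths (the
  limiting sample), binned to the nearest tabulated depth.
* The linkage engine approximates an external package's backcross model:
  single-linkage grouping (LOD > 3, rf < 0.25), greedy nearest-neighbour
  seriation seeded at the marker with maximal mean rf, Haldane map
  function (Kosambi by flag), adjacent rf capped at 0.499 before the map
  function to avoid infinities. Repulsion conversion two-colours each
  linkage component by BFS over coupling/repulsion edges at LOD
  thresholds 10, 5, 3; the larger colour class keeps its phase.
* Scaffold splitting cuts at the integer midpoint of the first adjacent
  marker pair with rf > 0.25 and restarts after the cut
  (anchor-to-initial-marker mode available by flag).
* Map merging pairs linkage groups by shared scaffold count (ties: the
  lower-numbered second-map group); the first map's scaffold order wins
  all conflicts.
* Fisher's exact test uses the probability-mass two-sided criterion with
  the conventional $1+10^{-7}$ tie tolerance, in log space.
* EcoRI is modelled as GAATTC cut after position 1; the enzyme table is
  an argument, not a constant.
* k-mer coverage is taken as the histogram mode above the first local
  minimum (error-peak exclusion); a direct-parameter mode reproduces the
  genome-size arithmetic from reported summary values. With the values
  reported for the Guinea yam genome (Kc 25.66, Rl 228.8, k 25,
  16.77 Gb) the formulas give ~585 Mb; the difference from the reported
  579 Mb presumably reflects upstream rounding of Kc/Rl and is left
  as-is.
* The flow-cytometry size is reported both at full precision and with
  the ratio rounded to one decimal (the conventional reporting mode,
  which is how 380 Mb x 1.5 = 570 Mb arises).

## Limitations

The mapper is heuristic under sequencing errors at both read ends; the
brute-force equivalence guarantee holds for error-free reads. The
phenotype-bulked QTL-seq signal is attenuated when ZW individuals
express maleness (the male bulk then contains ZW plants); the package
quantifies this through the lability parameters but the analytic
$\Delta = 1/2$ expectation assumes uncontaminated bulks — with
genotype-selected bulks (the sp16-minus design) the attenuation
disappears. Marker thinning, PA-marker depth rules and the 120-individual
informativeness floor follow fixed literal thresholds; they are
arguments, but no adaptive calibration is attempted.
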