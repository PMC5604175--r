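# zwmap

Sex-locus discovery in dioecious, highly heterozygous crops from a single
F1 cross. `zwmap` is aimed at researchers mapping a female-heterogametic
(ZW) sex-determining region when no inbred lines exist: both parents are
heterozygous, the trait segregates in the F1, and the W-linked region is
present in only one parent.

## What it does

* **F1-adapted QTL-seq.** Build a parent-substituted reference
  (reference base replaced wherever the parent's SNP-index is exactly 1),
  classify *parent-specific heterozygous sites* (index in [0.4, 0.6] in
  one parent, 0 in the other, both depths ≥ 16), score the female and
  male bulks at those sites, and test the windowed
  ΔSNP-index = index♀ − index♂ against simulation-based confidence
  limits (10,000 bulked-sampling replicates per observed depth; 1-Mb
  windows, 50-kb step). At a W-linked site E[Δ] = 0.5; at an unlinked
  site both bulk indices have expectation 0.25 and E[Δ] = 0.
* **W-region delineation.** A uniqueness-aware mini-mapper (exact seed +
  bounded Hamming, binary MAPQ-60 analog) maps both bulks to the
  combined dual-parent reference; maximal runs covered by unique
  female-bulk reads with (near-)zero male-bulk depth are female-specific
  regions, filtered by an N20 fragment-length rule, anchored by exact-
  match chaining, and collapsed into a W-interval call (optionally
  trimmed by a ZZ-selected bulk).
* **Pseudo-testcross linkage mapping.** SNP-type and presence/absence
  RAD markers, exact binomial 1:1 segregation filter, two-point rf/LOD
  (backcross model), rf-based scaffold splitting, repulsion-phase
  conversion (LOD schedule 10 → 5 → 3), single-linkage grouping with
  greedy seriation, dual-map merging, and pseudo-molecules joined by
  1000-bp N gaps with an AGP-style table.
* **Estimators and assays.** k-mer (Rc = Kc·Rl/(Rl−k+1), size =
  total/Rc) and flow-cytometry genome sizes, assembly/annotation
  summaries (N50/N75, per-gene exon/intron averages), SSR scanning
  (motifs 2–10 bp, ≥ 10 copies, primitive motifs only), in silico PCR,
  CAPS genotyping, dominant ZW/ZZ genotype inference and exact Fisher
  association tests.
* **Synthetic populations.** `sim_config()` / `simulate_parents()` /
  `cross_f1()` generate a ZW × ZZ cross with configurable
  heterozygosity, a female-specific W insertion inside a divergent
  sex-determining region, labile ZW sex expression, and a complete truth
  table — the substrate for every end-to-end test.

## Worked example

```r
library(zwmap)

# flow-cytometry genome size from G1 peak means (rice standard, 380 Mb)
fcm <- fcm_genome_size(281.7, 188.7, ref_size = 380)
cat(sprintf("G1 peak ratio: %.3f -> genome size %.1f Mb (%.0f Mb with 1-decimal ratio)\n",
            fcm$ratio, fcm$size, fcm$size_rounded_ratio))
#> G1 peak ratio: 1.493 -> genome size 567.3 Mb (570 Mb with 1-decimal ratio)

# end-to-end QTL-seq on a synthetic 253-progeny cross, bulks of 50, 13x
set.seed(101)
cfg <- sim_config(lability = c(male = 0, monoecious = 0.04, nonflowering = 0.10),
                  seed = 101)
pop <- cross_f1(simulate_parents(cfg), cfg)
res <- qtlseq_run(pop, reps = 10000, seed = 102)
res$regions
#>   chrom start     end sign n_windows peak_delta
#> 1 chr02 6e+05 2400000    1        17  0.4293246
```

The single called interval (0.6–2.4 Mb on chr02) covers the simulated
sex-determining region; its peak windowed Δ of ~0.43 reflects the
expected 0.5 at fully W-linked sites attenuated by recombination toward
the region's edges. `plot_qtlseq(res$windows, res$records, "chr02")`
draws the index/Δ/CI tracks.

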