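# rtarch

Replication timing meets nuclear architecture: an R toolkit for asking
how a chromatin organiser (here modelled on Rif1, the conserved
regulator of the replication-timing program) shapes *when* the genome
replicates and *how* it folds.

## Who this is for

Genomicists analysing Repli-seq, broad-domain ChIP-seq (Rif1, Lamin
B1), and 4C-seq from a wild-type / knockout comparison — or anyone who
needs a fully testable, self-contained model of that analysis. The
package ships a seeded synthetic-genome simulator with a planted-truth
record, so the entire pipeline runs and validates without any external
sequencing data.

## What it computes

* **Replication timing.** `RT = log2(early/late)` per fixed-width bin;
  loess smoothing (span in bp); segmentation into early
  (`RT > 0.5`) / late (`RT < −0.5`) / intermediate domains; per-domain
  switch classification between genotypes
  (`ΔRT = KO − WT`; `LtoE` when a late domain gains more than +1,
  `EtoL` when an early domain loses more than −1); genome-wide RT
  distributions on 60-bp tiles with Sarle's bimodality coefficient.
* **Broad occupancy domains.** A RAD/LAD-style caller: binarize
  enrichment (`log2(ChIP/input)`) against the chromosome median, extract
  maximal positive-scoring segments, permutation significance with BH
  control. Plus exact base-pair interval algebra: Venn overlaps with
  Jaccard, lamin co-occupancy partition (RAD-LB⁺/RAD-LB⁻), late-genome
  coverage fractions.
* **Meta-profiles.** Scaled meta-domain matrices (body rescaled to 40
  columns, ±0.2 Mb flanks) and point-centred matrices (±5 kb), k-means
  clustering with deterministic relabelling, per-cluster RT summaries.
* **Sequence features.** GC content, CpG observed/expected ratio
  `CpG/(GC/2)²`, G-quadruplex scanning (`G{3,}(N{1,7}G{3,}){3}`, both
  strands), G-density (OGRE-like) elements, and origin/TSS
  stratification by RT class on a 200-kb grid.
* **4C contacts.** In-silico HindIII digestion, RPM normalisation with
  viewpoint exclusion, replicate-consistent contact calling against a
  fitted distance-decay background, genotype comparison by RPM range
  (10–200, 200–∞) with paired t-tests, intra- versus inter-RT-domain
  scope, and TAD-level RT specificity of gained contacts.

## Worked example

```r
library(rtarch)

spec   <- synthetic_genome_spec(seed = 42)        # 2 x 20 Mb, 50-kb bins
sim    <- simulate_genome(spec, with_sequence = FALSE)
assays <- simulate_replication_assays(spec, sim$truth)

rt_wt <- compute_rt(assays$early_wt, assays$late_wt, pseudocount = 1)
rt_ko <- compute_rt(assays$early_ko, assays$late_ko, pseudocount = 1)
domains  <- segment_rt_domains(loess_smooth(rt_wt, 300000))
switches <- classify_switches(rt_wt, rt_ko, domains)
table(S4Vectors::mcols(switches)$switch_class)
#>         EtoE         EtoL         LtoE         LtoL unclassified
#>           16            4            3           17           22

enr  <- compute_enrichment(assays$chip_rif1, assays$input, 1)
rads <- call_broad_domains(enr, n_perm = 300, seed = 42)
length(rads)
#> [1] 12
overlap_venn(rads, sim$truth$lads)$jaccard   # RAD/LAD base-pair overlap
#> [1] 0.649...   (8.9 Mb shared)

late <- domains[S4Vectors::mcols(domains)$class == "late"]
round(late_genome_coverage(late, rads, sim$truth$lads), 3)
#>  by_rads  by_lads by_union
#>    0.616    0.521    0.679
```

Reading the output: most domains keep their timing (`LtoL`, `EtoE`);
the `LtoE` calls are exactly the planted Rif1-bound, lamin-free late
domains that switch to early replication in the knockout; the
`unclassified` entries are thin intermediate transition slivers between
early and late runs. The called RADs overlap LADs extensively, and
together they cover ~two-thirds of the late-replicating genome in this
seed's draw.

The full pipeline — simulation through 4C — with plain-text outputs and
a JSON manifest:

```r
run_pipeline(pipeline_config(outdir = "out", seed = 1))
```

or from the shell:

```sh
Rscript inst/cli/rtarch.R run --outdir out --seed 1
```

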