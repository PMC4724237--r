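---
title: "Methods: replication timing and nuclear architecture in rtarch"
author: "rtarch developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replication timing and nuclear architecture in rtarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`rtarch` implements the computational chain that links DNA replication
timing (RT) to nuclear organisation in a Rif1-perturbation design: RT
profiling and switch classification, broad Rif1/lamin occupancy domain
calling and interval algebra, meta-domain clustering, sequence-feature
stratification of replication origins, and 4C-seq viewpoint contact
analysis. Because the published genome-scale numbers rest on sequencing
data that is not redistributable, every stage is validated against a
seeded synthetic genome whose planted truth the pipeline must recover.

# Models and procedures

## Replication timing

RT is the per-bin log2 ratio of early-fraction to late-fraction
Repli-seq reads, `RT = log2((early + p)/(late + p))`; positive values
replicate early. The pseudocount `p` (pipeline default 1 read) only
matters in empty bins; with `p = 0` bins with a zero count are masked
rather than mapped to ±Inf. ChIP enrichment uses the same form,
`log2(ChIP/input)`.

Profiles are smoothed by local linear (degree-1) loess with the span
expressed in base pairs (default 300 kb — a few bins at the 50-kb
working resolution, typical for RT profiles which vary on the
megabase scale). Degree-1 loess reproduces constant and linear signals
exactly, which the tests exploit as oracles. Output bins whose window
holds fewer than 5 informative bins are masked rather than
extrapolated.

Domain segmentation thresholds the smoothed profile at `+0.5` (early)
and `-0.5` (late), keeping an explicit intermediate class for bins in
between — lamina-only domains genuinely have poorly defined timing, and
forcing binary labels would misstate that. Gaps shorter than
`min_len_bp` (default 200 kb) inside a run are absorbed, early runs
taking precedence over late when closures compete (a documented,
deterministic tie-break; the competing case requires a sub-200-kb
oscillation across both thresholds and does not arise in smoothed
data). Switch classification compares genotypes per baseline domain on
*unsmoothed* RT means — smoothing is for display and segmentation only,
and using it twice would bias boundary domains. A domain switches when
its mean RT change exceeds ±1 (`LtoE` for late domains gaining more
than +1, `EtoL` for early domains losing more than −1); others keep
their class. The genome-wide RT score distribution is summarised on
60-bp tiles with Sarle's bimodality coefficient `b`, with `b > 5/9` the
usual benchmark for departure from unimodality; loss of the early/late
bimodal structure appears as a drop in `b`.

## Broad occupancy domains

The RAD/LAD-style caller binarizes each chromosome's enrichment track
against its median (robust to depth), scores enriched bins +1 and
depleted bins `-gap_penalty`, extracts all disjoint maximal
positive-scoring segments (greedy best-first with leftmost-longest
tie-breaks; an exhaustive O(n²) oracle checks it exactly in the test
suite), and assesses segments against a permutation null: binarized
labels are shuffled within the chromosome and the pooled positive
segment scores across permutations form the null distribution, with
Benjamini–Hochberg control across segments.

The gap penalty default is 4. This is a deliberate design decision:
because binarization against the median marks roughly half of all bins
enriched, any penalty below 1 gives maximal segments a positive
expected drift and they degenerate to chromosome scale. Penalties in
the 2–5 range make the drift comfortably negative while still bridging
isolated noisy bins; 4 additionally resists boundary creep (extending a
segment across one depleted bin then requires five consecutive enriched
bins, which background produces rarely). Adjacent significant calls
separated by fewer than 2 bins are merged so a single noisy bin cannot
split one domain.

Interval algebra (base-pair Venn, lamin co-occupancy partition at 50%
coverage, late-genome coverage fractions) is exact arithmetic on merged
interval sets; a per-base boolean-mask oracle checks it in the tests.
The 50% lamin-coverage threshold defining RAD-LB+ versus RAD-LB- is a
package choice (the distinction is described only qualitatively in the
literature as "mostly bound by Rif1 alone") and is exposed in the
configuration.

## Meta-profiles and clustering

Meta-domain matrices rescale each domain body to 40 columns by
length-weighted averaging over interpolated cumulative sums — equal-width
slots conserve the domain mean to floating-point accuracy — and add
±0.2 Mb flanks at 20 fixed columns per side. Point-centred matrices use
±5 kb at the track's native resolution by default (±250 kb for RT-change
windows; "within 500 kb" is read as a total width of 500 kb). Rows keep
input order so heatmaps are comparable across tracks; TSS windows are
strand-oriented (upstream left), origin windows are not (origins have
no strand).

Clustering is k-means with 10 restarts (k = 4 for the LAD classes; no
algorithm is prescribed by the source analysis, and k-means is
oracle-checkable on planted archetypes). Masked cells are imputed with
column means; labels are relabelled by decreasing cluster mean signal
so solutions are reproducible and comparable across runs.

## Sequence features

GC content excludes ambiguous bases from both numerator and
denominator. The CpG ratio is `observed / expected` with observed the
overlapping CG dinucleotide count over `L - 1` and expected `(GC/2)²` —
both per-position frequencies, which is what makes the printed formula
dimensionally consistent. The G-quadruplex scanner matches the
canonical four-tract pattern `G{3,}(N{1,7}G{3,}){3}` (and the
complementary C-pattern for the minus strand) with leftmost-longest
resolution; loop bounds are configurable since published G4 definitions
vary. The OGRE-like scanner is a configurable G-density rule (≥ 67% G
over ≥ 30 bp windows, strand-specific) rather than a fixed consensus,
with qualifying windows merged into maximal regions; runs separated by
less than one window length join, because integer-count phase effects
can briefly drop one region below the cutoff.

Origin (SNS) stratification classifies each locus by the RT of the
200-kb bin containing its centre (late < −0.5, early > +0.5; the band in
between is excluded) and by TSS overlap within ±500 bp (a 1-kb window,
unstated in the source and exposed as a parameter).

## 4C contacts

Contacts are resolved at primary restriction fragments (HindIII
`AAGCTT`, cut offset 1); the secondary digest is treated as a library
preparation detail. RPM normalisation excludes a ±10 kb viewpoint zone
(self-ligation and undigested signal) from the library total. The
contact caller is a deliberately simple, oracle-checkable stand-in for
published 4C callers: per replicate a fragment is called when its RPM
reaches 10 *and* exceeds a distance-decay background by 3×, where the
background is a power law fitted to the library's own cis profile
(log-binned distance versus mean RPM); trans fragments are compared to
the mean trans RPM. Consistent contacts are the intersection of the two
replicate calls. Genotype comparison counts consistent contacts per RPM
range ([10, 200) and [200, ∞)), reports knockout/wild-type fold
increases, and tests per-viewpoint log2 fold increases with a two-sided
paired t-test. TAD-level analysis assigns contacts to TADs by fragment
midpoint; TADs hit in both genotypes are shared, knockout-only TADs are
gained, and the RT values of knockout contacts in each class are
summarised by their median.

# The synthetic genome

The generator is a first-class, tested module, and its defaults are the
stated world of the validation suite: 2 chromosomes × 20 Mb at 50-kb
bins, alternating early/late RT domains of 0.8–1.2 Mb at planted RT ±2,
Poisson coverage at 100 reads/bin, ChIP effect 1.5 log2. A late domain
is a RAD with probability 0.65; a RAD is lamin co-occupied with
probability 0.6; lamin-only domains occur on 25% of the remaining late
domains — jointly making RADs and LADs cover ≈ 73% of the late genome,
matching the published coverage figure. The knockout layout flips
RAD-LB- late domains to early and 15% of early domains reciprocally to
late; all other domains keep their RT. Sequence is drawn at GC 0.42
with background CpG dinucleotides depleted to an observed/expected of
≈ 0.2 (vertebrate-like; without depletion CpG islands would be
invisible), CpG islands planted at half of the early TSSs, and two
planted motif families: `GGGATGGGATGGGATGGG` (G4) and `GGAG` repeats
(75% G, no G3 run, so OGRE-like hits never double as G4 hits).

4C libraries use 5 viewpoints placed mid-RAD, a power-law distance
decay with exponent 2 (steep, viewpoint-centred, as 4C profiles are),
a 2× same-RT compartment preference computed from the wild-type layout
for *both* genotypes — so the only planted genotype difference is the
gained contacts, and a zero gained-rate simulation is exactly
exchangeable between genotypes — 5 × 10⁵ reads per library, 30 planted
replicate-consistent contacts per viewpoint (RPM 20–500, half inside
the viewpoint's own RT domain, the rest elsewhere in its RT class), and
knockout-only gained contacts planted on 1% of inter-domain cis
fragments at RPM 15–100, the low-to-mid frequency band. Replicates
share true contact positions and draw independent Poisson noise.

What the simulator does not emulate: mappability and GC bias,
read-level errors, diploidy, copy-number variation, the secondary 4C
digest, S-phase population structure, and distance-dependent noise
heteroscedasticity beyond Poisson. A green test therefore establishes
that the algorithms recover planted structure through Poisson sampling
noise at realistic effect sizes — not that they are robust to every
artefact of real sequencing data.

# Numerical choices and degenerate inputs

* Ties in segment extraction break leftmost, then longest; scores are
  sums of +1/−4 and exact in binary floating point.
* Zero-count bins are masked at `p = 0`; all-N windows, GC-free windows
  and empty 4C libraries raise flags or errors rather than NaNs.
* k-means on identical rows cannot split them: the solution collapses to
  one flagged cluster instead of erroring.
* The RPM fold increase is undefined (flagged) for ranges with a zero
  wild-type count; the paired t-test is flagged, not computed, under
  degenerate variance.
* All randomness flows from explicit seeds (spec seed for layout,
  seed+1 for assay noise, seed+2 for 4C), so a run is reproducible from
  its configuration alone and skipping the sequence stage cannot change
  the planted truth.

# Known limitations

The broad-domain caller reimplements the *idea* of enriched-domain
detection, not any published implementation's exact scores; its default
gap penalty deliberately departs from naive parameter choices that
degenerate under median binarization (see above). The 4C caller is not
a reimplementation of r3Cseq or FourCSeq and should not be used to
reproduce their outputs. Published genome-scale numbers (e.g. percent
coverage of the late genome, origin-peak association rates) depend on
the original unreleased data; the package recovers the corresponding
*planted* quantities on synthetic data instead, and the stratification
machinery reproduces a constructed association rate exactly.
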