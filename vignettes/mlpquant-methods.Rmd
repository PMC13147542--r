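---
title: "Quantifying multicellular-like phenotypes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multicellular-like phenotypes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpquant)
```

Multicellular-like phenotypes (MLPs) -- flocculation, adhesion to surfaces,
filamentous and biofilm-like growth -- are scored in yeasts by simple but
noisy assays. `mlpquant` implements a quantitative toolkit around two
high-throughput assays (a plate washing assay scored from flatbed scans, and
a multi-point OD600 plate-reader assay), the statistics used to call hits in
deletion screens, a variant-consequence caller, and a random-forest QTL
mapper with a permutation null. This vignette records the models, the
tunable parameters and the design decisions, including those that were
genuinely open.

## Adhesion from washed plates

A pinning robot deposits each of 96 strains as a 7 x 7 block of colony
patches on agar. Plates are scanned before and after a standardized wash;
cell density blocks transmitted light, so *inverse pixel intensity*
(`white_level - pixel`) is the densitometric signal.

The measurement model, per plate image:

1. **Normalization.** Each image's inverse intensities are divided by the
   image maximum (the darkest pixel), mapping densities to `[0, 1]`. This
   makes pre- and postwash scans comparable even when the scanner reports
   slightly darker colonies after washing. It presumes every scan contains
   at least one effectively saturated dense colony; plate layouts should
   include a strongly adhesive positive control for this reason.
2. **Segmentation.** A raw 8 x 12 box layout is built once from a
   "filled-out" example plate: the inverted image is projected onto each
   axis, the 8 (12) strongest profile runs are taken as colony rows
   (columns), a least-squares line through the run centers enforces an
   exactly regular pitch, and boxes are sized to the median run width so a
   box hugs one colony block. The layout is then *fitted* to every prewash
   image by exhaustive integer-pixel translation search (default
   `max_shift_px = 20`) maximizing total in-box inverse intensity. Flatbed
   scans are rigid, so no rotation or scale freedom is allowed; this was an
   open choice and translation-only search is the package's position. The
   prewash fit is reused unchanged for the matching postwash image -- the
   assay guarantees pre/post pairs are not misaligned relative to each
   other.
3. **Densitometry.** Per-box means are taken over the box interior (boxes
   eroded by `inner_margin = 2` px) so that soft colony edges and residual
   1-px misalignment do not bias the means. The mean over the `EMPTY`
   negative-control squares estimates background and is subtracted from
   every position, flooring at 0. The order -- normalize, then subtract,
   then floor -- was not fixed by the assay description; it is fixed here
   and documented. At least one empty control square per plate is required.
4. **Adhesion ratio.** `ratio = post / pre` per position. Positions with
   prewash density below `growth_min = 0.1` are flagged as not growing and
   excluded; strains whose *mean* prewash density is below 0.1 are excluded
   entirely. Ratios above 1 (a scanner artefact) are reported as-is and
   flagged, never clipped. Perimeter positions (36 of 96) are unreliably
   adhesive; `interior_only` restricts analyses to the middle 60.

Key thresholds, all dimensionless normalized densities: `growth_min = 0.1`
(growing), postwash `> 0.05` for robust quantification in screens, ratio
`> 0.2` for a *strong* adhesion phenotype.

## Flocculation

A plate reader measures OD600 at up to 15 x 15 points inside each well.
Flocs concentrate biomass in a few spots, so the flocculation score of a
well is the coefficient of variation (CV = sd / mean) of its
background-corrected readings; the mean OD of an empty-media control well
is subtracted from every reading first. Design points:

* The well's grid is the complete measurement population, so the population
  standard deviation (divisor $n^2$) is the default; the sample convention
  is available (`population = FALSE`).
* A non-positive corrected mean makes the CV undefined; such wells get a
  flagged missing score rather than a sign-flipped value.
* No further normalization is applied before the CV; background subtraction
  is the only correction the assay defines.
* The scan CSV dialect (one row per well: id plus $n^2$ readings) is the
  package's own documented fixture format; instrument exports vary.

The complementary filtering assay pours a culture through a 30 um filter
and resuspends the retained flocs; the flocculating fraction is
`OD(B) / (OD(A) + OD(B))`.

## Screen statistics

* **Thresholds.** Screen positives are strains above the 95th percentile of
  adhesion values (type-7 linear interpolation -- the convention matters
  because downstream ratio cutoffs are percentile values). The
  strong-phenotype threshold can instead be read from an elbow plot:
  values are sorted in decreasing order and the point with maximum
  perpendicular distance to the chord between the first and last point is
  the knee; the value *at* the knee is returned, so exactly the strains
  before the break exceed it. Degenerate (linear or constant) curves warn
  and return the midpoint value.
* **Hit confirmation.** A replicate is valid when prewash `> 0.1` and
  postwash `> 0.05`; a strain is a hit with at least 5 valid replicates and
  mean ratio over valid replicates above the cutoff (0.086 in the original
  deletion-screen usage, itself a 95th-percentile value). Whether each
  replicate or the mean must pass was ambiguous; the mean reading is the
  default and the per-replicate reading is available (`rule = "each"`).
* **Permutation T-test.** The statistic is the difference of means --
  monotone in the t statistic at fixed group sizes and deterministic.
  All `choose(n, nx)` relabelings are enumerated when they fit in the
  permutation budget, otherwise the budget is sampled; in both cases
  `p = (1 + #extreme) / (1 + #draws)`. Sidedness is a per-call flag with no
  global default: callers must state it.
* **Corrections.** Bonferroni and Benjamini-Hochberg go through
  `stats::p.adjust`.
* **Count normalization** uses the median-of-ratios construction (per-gene
  geometric-mean pseudo-reference; per-sample median ratio over genes
  expressed everywhere).
* **Expression-phenotype correlation** defaults to Spearman's rank
  correlation: the relation between the two MLP assays is monotone but not
  linear, and rank correlation is robust to that. Pearson is available.
  Zero-variance genes are excluded from the FDR rather than given p = 1.

## Variant consequences

The caller takes a genome FASTA, a GFF3 annotation (1-based inclusive
coordinates; the longest annotated CDS per gene is used) and VCF-style
variants (anchored indels). An edit is applied to the chromosome, the CDS
intervals are re-derived, and reference and edited coding sequences are
translated to the first stop codon (standard nuclear code; trailing partial
codons dropped; protein lengths exclude the stop). Categories:

* substitutions: `synonymous`, `missense`, or `nonsense` (new stop before
  the reference one);
* indels inside a CDS: `frameshift` when the length change is not a
  multiple of 3, else `inframe_indel`;
* anything outside every CDS: `non_coding`. Variants straddling a CDS
  boundary or splice junction are conservatively called `non_coding` with a
  warning -- their effect depends on splicing behavior the annotation does
  not determine.

`premature_stop` is true when translation terminates earlier than the edit
alone accounts for: an in-frame deletion shortening the protein by its own
length is not a premature stop, while a frameshift that runs into a stop
codon is. The classic test case is a single-base `TA > T` deletion that
truncates a 228-residue cyclin to 77 residues; the package ships a
*synthetic* gene (`synthetic_srb11_example()`) engineered with the same
arithmetic, because the real reference sequence is third-party data and the
check must run offline.

Sequencing-pipeline QC mirrors haploid genotyping practice: calls flagged
heterozygous under a diploid model are discarded
(`drop_heterozygous()`), and uncalled markers whose nearest called
neighbors on both sides carry the same parental haplotype are imputed to
that haplotype (`impute_flanked()` -- idempotent, never touches called
genotypes, never fills chromosome ends).

## Random-forest QTL mapping

Markers are first collapsed into haplotype blocks (maximal runs of adjacent
markers with identical genotype columns); blocks are the mapping units.
Residual missing calls at mapping time are filled per strain from the
*nearest called marker* on the chromosome. A per-column majority fill was
considered and rejected: it fabricates block boundaries out of missingness
patterns, splitting a QTL's importance across artificial near-duplicate
blocks.

The importance measure is the **selection frequency**: over `n_forests`
independent regression forests of `n_trees` CART trees (bootstrap rows,
`mtry` random candidate blocks per node, binary haplotype splits, minimum
child size `min_leaf`), the fraction of all trees in which a block is
chosen for at least one split. Defaults: 100 forests x 100 trees,
`mtry = ceiling(sqrt(n_blocks))`, `min_leaf = 5`, unlimited depth -- the
forest hyperparameters were unspecified upstream and are all configurable.
Whether the original importance counted root splits only or any split was
not documented; any-split participation is the default and root-only
counting is available (`root_only = TRUE`). Because candidate blocks
compete within nodes, linked and epistatic blocks can share splits; no
explicit interaction statistic is reported.

Significance comes from a permutation null: the phenotype vector is
shuffled across strains and the full selection-frequency computation is
repeated per permutation ("permutation" rather than data bootstrap was
chosen as the stated significance mechanism). Per block,
`p = (1 + #{null >= observed}) / (1 + n_perm)`, Bonferroni-corrected over
the blocks tested. The smallest achievable corrected p-value is
`n_blocks / (1 + n_perm)`, so genome-wide significance at level $\alpha$
requires `n_perm > n_blocks / alpha` (`min_permutations()`); at full
study scale -- ~800 blocks -- that means more than 16,060 permutations.

The engine is compiled (Rcpp) and draws from R's RNG, so `set.seed()`
governs every tree; identical seeds give bitwise-identical importance
profiles.

## Synthetic data: what it emulates, and what it does not

Every module is exercised against generators whose ground truth is recorded
at construction time.

**Plate images.** 96 positions of 7 x 7 colony patches on a noisy agar
background (Gaussian pixel noise, default sd 3 on the 0-255 scale; soft
1-px colony edges). The default layout plants a saturated, fully adhesive
positive-control colony and an `EMPTY` square, mirroring confirmation-plate
practice and anchoring the per-image normalization. Densities are drawn
from `[0.25, 0.95]`, ratios from `{0, 0.1, ..., 1}`. The renderer does not
model colony morphology, vignetting or glare; recovery tests therefore
demonstrate the correctness of the measurement pipeline, not robustness to
optical artefacts.

**Plate-reader scans.** Baseline OD plus Poisson-many exponential clump
spikes whose number and mass grow with a clump parameter; a shared
background absorbance and an empty control well. The median CV is monotone
in the clump parameter, which is the property the assay relies on.

**Segregant cross.** 100 strains, 2 chromosomes, 4 marker clusters of 25
markers each (200 markers total). Markers within a cluster are in perfect
linkage -- they are the haplotype blocks -- and adjacent clusters recombine
near-freely (probability 0.45), so the 8 blocks are quasi-independent
mapping units; clusters are 50 kb apart with 1 kb within-cluster spacing,
so a masked call's nearest neighbor is always in its own cluster. One
cluster carries the QTL (default effect: 2 residual standard deviations);
5% of calls are masked. The block count is deliberately small: by the
`min_permutations()` rule, 8 blocks are the scale at which a desk-sized
null of 200 permutations can reach Bonferroni-corrected genome-wide
significance, standing in for the full-scale regime of ~800 blocks and
20,000 permutations. A uniformly-low-recombination cross was tried and
rejected: its adjacent blocks are near-duplicate columns that split the
QTL's selection frequency and destroy power -- a real phenomenon worth
knowing about when interpreting selection frequencies in tightly linked
regions.

**Toy genome.** Two chromosomes, 12 genes on both strands (one- and
two-exon), and 220 variants of every consequence class, labelled by editing
and translating the CDS directly in CDS coordinate space with the
generator's own codon table -- a fully independent oracle for the
genomic-space caller.

**Deletion screen.** 3,600 strains, 5% planted adhesives (ratio
0.4 ± 0.08 against a background of 0.03 ± 0.015), 6 replicates, prewash
densities 0.5 ± 0.1. The planted separation is deliberately clean; the
fixture validates the thresholding and confirmation logic, not the
difficulty of a real screen.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 20 plate pairs (noise sd 3,
planted translations up to ±6 px); 50 seeds per clump level; 2,000
simulated null T-tests (n = 50 per group, 400 sampled permutations each);
220 labelled variants; 100 random matrices for the imputation oracle; 20
cross seeds with 100 forests x 100 trees and 200 permutations each. One
permutation-null ensemble per cross serves both the observed scan and the
permuted-phenotype calibration run -- the null depends only on the multiset
of phenotype values, so recomputing it would be redundant.

Numerical conventions worth stating: quantiles are type-7; permutation
p-values use the add-one convention and count ties as extreme (with a
small floating-point tolerance); CV scale invariance is exact for
power-of-two factors and holds to ~1e-15 otherwise; layout fitting breaks
score ties toward the smallest translation; `elbow_threshold` warns on
curvature-free input.

## Known limitations

* The imaging model is translation-only; scans with rotation or scale
  differences (different scanner models) need external registration first.
* The consequence caller handles one variant at a time; compound
  haplotypes (two nearby edits in one gene) are not composed.
* Selection frequencies saturate when very few blocks compete (each tree
  eventually uses most of them); with small block counts, compare against
  the permutation null rather than interpreting absolute frequencies.
* The generators produce idealized data; none of the acceptance results
  certify performance on real scanner images or real sequencing calls.
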