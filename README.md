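# mlpquant

Quantification and genetic dissection of multicellular-like phenotypes
(MLPs) in yeast.

Yeasts such as *Schizosaccharomyces pombe* switch between unicellular
growth and multicellular-like states — flocculation (cell aggregates in
liquid culture), adhesion to agar, filamentous growth. These phenotypes are
scored by assays that are simple to run but nontrivial to quantify:
washing a pinned colony plate and asking how much material stuck, or
scanning a 96-well plate at many points per well and asking how unevenly
the biomass is distributed. `mlpquant` is for groups running such screens:
it turns raw plate scans and plate-reader exports into per-strain phenotype
scores, calls hits with the appropriate statistics, annotates the coding
consequences of candidate variants, and maps quantitative trait loci (QTL)
with a random-forest importance statistic against a permutation null.

## What it computes

**Adhesion (washing assay).** Cell density on a transmitted-light flatbed
scan is inverse pixel intensity. Per image, densities are rescaled by the
darkest pixel to $[0,1]$; a 96-box layout built from a filled-out example
plate is translation-fitted to each prewash scan; per-box mean densities
are background-corrected against empty control squares; and the adhesion
ratio of a position is

$$\mathrm{ratio} = \frac{\text{density after wash}}{\text{density before wash}},$$

with positions below 0.1 prewash density treated as not growing and ratios
above 0.2 called strong adhesion.

**Flocculation (multi-point OD600).** For the $n \times n$
background-corrected readings $x$ of one well, the score is the
coefficient of variation $\mathrm{CV} = \sigma(x)/\bar{x}$ — flocs inflate
spatial variance relative to the mean. The filter-based companion assay
reports the flocculating fraction $\mathrm{OD_B} / (\mathrm{OD_A} +
\mathrm{OD_B})$.

**Screen statistics.** Percentile and elbow thresholds for calling screen
positives; replicate confirmation rules (≥ 5 valid repeats, prewash > 0.1,
postwash > 0.05, mean ratio above the screen's 95th-percentile cutoff);
permutation T-tests (difference of means, exhaustive when feasible,
$p = (1+\#\mathrm{extreme})/(1+\#\mathrm{draws})$); Bonferroni and
Benjamini–Hochberg corrections; median-of-ratios size factors for count
data; rank-based expression–phenotype correlation at a chosen FDR.

**Variant consequences.** From genome FASTA + GFF3 + VCF-style variants:
strand-aware CDS splicing, edit application, translation to the first stop,
and classification into synonymous / missense / nonsense / frameshift /
in-frame indel / non-coding, with reference and truncated protein lengths.
Includes the haploid-sequencing QC rules: heterozygous-call filtering and
flank-agreement genotype imputation.

**RF-QTL mapping.** Markers collapse into haplotype blocks; each block is
scored by its *selection frequency* — the fraction of trees, over many
small regression forests, that use the block in at least one split. A
permutation null (phenotype shuffles, full recomputation) gives per-block
p-values, Bonferroni-corrected genome-wide. The permutation budget must
exceed `n_blocks / alpha` for genome-wide significance to be attainable:
`min_permutations(803, 0.05)` = 16,060.

A family of generators (`plate_spec()`/`render_plate_pair()`,
`simulate_plate_scan()`, `cross_spec()`/`simulate_cross()`, `toy_genome()`,
`simulate_screen()`) produces ground-truth-labelled fixtures for every one
of these steps.

## Worked example

Render a synthetic plate pair with known adhesion ratios, run the full
imaging pipeline, and map a planted QTL:

```r
library(mlpquant)

sp      <- plate_spec(seed = 1)
pp      <- render_plate_pair(sp)
layout  <- build_reference_layout(render_filled_plate(sp))
fitted  <- fit_layout(layout, pp$pre, max_shift_px = 20)
controls <- which(sp$densities == 0, arr.ind = TRUE)
rec <- adhesion_from_pair(measure_grid(pp$pre, fitted, controls),
                          measure_grid(pp$post, fitted, controls))
head(rec[rec$grew, ], 3)
#>   row col pre_density post_density grew     ratio flagged_gt1
#> 1   1   1   0.9823573    0.9822309 TRUE 0.9998714       FALSE
#> 2   2   1   0.5034902    0.0000000 TRUE 0.0000000       FALSE
#> 3   3   1   0.6417081    0.2561917 TRUE 0.3992341       FALSE
table(strong = strong_adhesion_call(rec$ratio[rec$grew]))
#> strong
#> FALSE  TRUE
#>    33    62
```

Row 1 is the saturated positive-control colony (ratio ≈ 1: everything
stuck); row 2 washed off completely (ratio 0); row 3 kept ~40% of its
material — planted values were 1.0, 0.0 and 0.4. `strong_adhesion_call`
applies the ratio > 0.2 cutoff.

```r
sim <- simulate_cross(cross_spec(seed = 1))   # 100 segregants, 200 markers
res <- map_qtl(sim$genotypes, sim$phenotype,
               n_forests = 25, n_trees = 50, n_perm = 200, seed = 1)
res[order(res$p_bonferroni)[1:3], ]
#>   chrom    pos  start    end n_markers importance           p p_bonferroni significant
#> 2  chr1  87000  75000  99000        25     0.9800 0.004975124     0.039801        TRUE
#> 1  chr1  13000   1000  25000        25     0.8888 0.850746269     1.000000       FALSE
#> 3  chr1 161000 149000 173000        25     0.8528 0.701492537     1.000000       FALSE
```

The planted QTL sits at chr1:75000 — the one Bonferroni-significant block
(p = 1/201, the floor for 200 permutations, times 8 blocks) contains it.

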