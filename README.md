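# AbLineage

Unseeded clonal lineage assignment for antibody (BCR heavy-chain)
repertoires, with UAID/UMI consensus error correction, data-driven
threshold calibration, a ground-truth simulator and evaluation tooling.

## Who this is for

Immunologists and computational biologists analysing AIRR-seq data who
need to partition an annotated heavy-chain repertoire into clonal
lineages — all sequences descending from one naive B cell — *without* a
seed antibody, and to correct barcoded read libraries for amplification
bias and sequencing error before doing so.

## The method

For each pair of annotated sequences an antibody-specific distance is
computed:

    d(a, b) = [ edit(c_a, c_b) + 10·[V_a ≠ V_b] + 8·[J_a ≠ J_b]
                − 0.35 · |shared somatic mutations| ]₊  /  min(|c_a|, |c_b|)

where `edit` is the Levenshtein distance on the CDR3 with indels costing
2 and substitutions 1 (forced gapless when the CDR3 lengths are equal), V
and J are allele-stripped gene calls, a *shared mutation* is the same
substitution event — identical (position, germline base, observed base) —
in both mutation lists, `[·]₊` clamps at zero, and the score is
normalized by the shorter CDR3. Pairs from different V-gene families skip
the computation and receive a large sentinel distance. The condensed
distance matrix (n(n−1)/2 scores; 499,500 for n = 1000) is clustered by
average-linkage agglomeration and cut at a threshold placed in the trough
between the two modes of the pairwise-score histogram: related pairs pile
up near 0, unrelated pairs form a broad mass near 1–3.

Upstream of assignment, reads carrying a 5' random 20-nt barcode (UAID)
are binned by barcode, singleton bins discarded, and each bin collapsed
to a per-column plurality consensus with the germline V sequence as a
vote tiebreaker. A 20-nt barcode gives 4^20 ≈ 10^12 identifiers and a
97.2% probability that every transcript in a 250,000-transcript pool is
uniquely labeled.

## Worked example

```r
library(AbLineage)

## a truth-labeled synthetic repertoire: 300 lineages, 2 donors
cfg <- simConfig(nLineages = 300, nDonors = 2, seed = 42)
sim <- simulateRepertoire(cfg)
nrow(sim$records)
#> [1] 388

## calibrate the clustering threshold from the score histogram trough
calibrateThreshold(sim$records, nSample = 388, seed = 42)
#> [1] 0.175

## assign lineages (default parameters)
part <- assignLineages(sim$records)
part
#> LineagePartition: 388 sequences in 300 lineages
#>   singletons: 251 (83.7% of lineages)
#>   largest lineage: 11 members
#>   clonality fraction: 0.353

head(lineages(part)[, 1:6], 3)
#>   lineage_id size representative_junction v_family   v_gene j_gene
#> 1      L0001   11              EHKGRKEFCT    IGHV3 IGHV3-30  IGHJ6
#> 2      L0002    6        VHNYLWYPRVRQRLLY    IGHV4 IGHV4-34  IGHJ5
#> 3      L0003    5       CGHT*CVPTLPCGYYGD    IGHV1 IGHV1-69  IGHJ3

## accuracy against the simulation truth
truth  <- setNames(sim$truth$true_lineage_id, sim$truth$sequence_id)
donors <- setNames(sim$truth$donor_id,        sim$truth$sequence_id)
unlist(pairwisePrecisionRecall(part, truth))
#> precision    recall
#>         1         1
crossDonorContamination(part, donors)
#> [1] 0

## barcode-collision probability at study scale
uniqueLabelingProbability(250000, 20)
#> [1] 0.9719785
```

Reading: the simulator drew 388 sequences from 300 lineages (83.7% of
them singletons, the size spectrum expected of IgG+ memory). The trough
of the bimodal score histogram puts the cutoff at 0.175, every
within-lineage pair scores below it and every between-lineage pair above,
so the partition reproduces the truth exactly (precision = recall = 1)
and no lineage mixes donors.

A shell interface covering the same pipeline
(`simulate`, `correct-uaids`, `calibrate`, `assign`, `evaluate`,
`graph`) ships as `inst/scripts/ablineage`; each stage writes a JSON run
manifest alongside its outputs.

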