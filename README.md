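# TraDISect

Gene essentiality from saturated transposon-insertion libraries
(TraDIS/Tn-seq), with the comparative analyses that usually follow an
essential-genome screen: cross-species ortholog agreement, COG
functional-class profiles, and phylogenetic profiling of gene-cluster
presence/absence.

## The problem and the model

A saturated transposon library disrupts a bacterial genome roughly once per
handful of base pairs. Genes whose disruption kills the cell are depleted of
insertions; tolerant genes accumulate them. For every gene the pipeline
computes the **insertion index**

    ii = unique insertion sites in the gene / gene length (bp)

whose genome-wide distribution is bimodal: a near-zero mode (essential
genes) and a broad mode around the genome-wide insertion density (about one
unique site per 12 bp in a saturated library, so ii near 0.08). The
distribution is split at two manually chosen cut-offs (0.006 and 0.03); the
low section is fitted with an exponential (rate lambda = 1/mean, closed
form), the high section with a gamma(k, theta) by maximum likelihood of the
left-truncated gamma (the section only sees indices above the cut-off).
Every gene is then scored by

    llr = log2[ f_exp(ii; lambda) / f_gamma(ii; k, theta) ]

and called **essential** when llr > log2(12) (twelve times more likely under
the essential mode), **non-essential** when llr < -log2(12), and **unclear**
in between. A sliding window (300 bp, stride 150 bp, 3'-anchored terminal
window) then re-interrogates non-essential and unclear genes: a window with
zero insertions marks an essential domain inside an otherwise tolerant gene,
and such genes are promoted to essential.

Downstream, orthologs between two screened species are detected as
reciprocal best hits in 14-column tabular alignment output (E-value <=
1e-5, query and subject coverage >= 70%, proteins with within-proteome
paralogs excluded) and their calls tabulated into an agreement summary; COG
category labels are split per letter and counted per call; and
ortholog-group presence/absence matrices are clustered with complete-linkage
Euclidean clustering.

Because real screens need a deposited sequencing library, the package ships
a fully seeded synthetic-data generator (`simulateBundle()` and friends)
that emits genomes, GFF3 annotations, insertion-site tables, tagged FASTQ
reads, homology tables with planted confounders and functional annotations,
each with a ground-truth manifest used by the test suite.

## Worked example

```r
library(TraDISect)

cfg    <- simulationConfig(seed = 42)      # 2,000 genes, 10% essential,
bundle <- simulateBundle(cfg)              # one insertion per 12 bp

stats  <- geneInsertionStats(bundle$sites, bundle$annotation)
calls  <- callGenome(stats)                # cut-offs 0.006/0.03, fold 12
calls  <- domainCorrection(calls, bundle$annotation, bundle$sites)$calls
calls
#> GeneCallSet: 2000 genes classified (threshold log2(12))
#>   essential 210 (10%), non-essential 1790 (90%), unclear 0 (0%)
#>   domain-scan flagged: 10 genes

essentialityFit(calls)
#> EssentialityFit: exponential rate = 47385.75
#>   gamma shape = 4.834647  scale = 0.01727355
#>   sections (<= 0.006 / between / >= 0.03 ): 201 / 88 / 1711

partitionSites(bundle$sites, bundle$annotation)
#> $cds_sites          [1] 134233
#> $intergenic_sites   [1] 25230
#> $total_unique_sites [1] 159463
```

The 210 essential calls are the 200 planted essential genes (all
insertion-free, every one recovered) plus the 10 planted domain-essential
genes rescued by the window scan; the fitted gamma (k = 4.83, theta =
0.0173) recovers the generator's non-essential mode (k = 5, theta = 1/60)
within 4%, the residual gap coming from the binomial noise the per-base
insertion process adds on top of the per-gene rates. The site partition sums
exactly to the unique-site total.

`runPipeline(pipelineConfig(...))` wires these stages together from file
inputs (GFF3 + site TSV, or raw FASTQ + FASTA) and writes per-stage TSVs and
a JSON summary; `inst/scripts/tradisect.R` wraps it for shell use.

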