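---
title: "Insertion-index essentiality calling: model, parameters and design choices"
author: "TraDISect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion-index essentiality calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TraDISect)
```

## The statistical model

A saturated transposon-insertion library samples, for every position of a
bacterial chromosome, whether a disruption there is tolerated. After
deduplication the data reduce to a set of unique insertion sites, and the
per-gene statistic is the insertion index: unique sites in the gene divided
by gene length in bp. In a saturated library (about one unique site per
12 bp of tolerant sequence) the index distribution is bimodal. The left
mode, pressed against zero, collects essential genes; the right mode,
centred near the genome-wide density, collects tolerant genes.

TraDISect models the two modes separately. The distribution is first split
at two fixed cut-offs, 0.006 and 0.03 by default, chosen to sit inside the
valley between the modes so that each fit sees essentially pure data from
one mode. The low section (index <= 0.006) is fitted with an exponential;
its maximum-likelihood rate is the closed form lambda = 1/mean. The high
section (index >= 0.03) is fitted with a gamma(k, theta). Genes strictly
between the cut-offs take no part in the fitting but are classified like
every other gene.

Each gene is scored by a log2 likelihood ratio,
`llr = log2(f_exp(ii) / f_gamma(ii))`, and called essential when
`llr > log2(12)` — the gene is at least twelve times more likely under the
essential mode — non-essential when `llr < -log2(12)`, and unclear in the
band between. The trichotomy is exhaustive and exclusive by construction.
The orientation (exponential density in the numerator, essential =
positive) is fixed here once; the published descriptions of this family of
methods state the inequality in both directions in different places, and
only this orientation is self-consistent with the "twelve times more
likely" reading.

### Numerical guards

Both densities are floored at `DENSITY_FLOOR` (1e-300) before the ratio and
the log2 ratio is clamped to +/- `LLR_CAP` (1000). The limit case that
motivates this is an index of exactly 0 under a shape > 1 gamma: the gamma
density is exactly 0, and the guard turns the ratio into the maximal
essential-like score instead of +Inf, preserving ordering without breaking
arithmetic downstream.

If every low-section index is 0 — a perfectly clean library with zero
leakage into essential genes — the exponential mean is degenerate. The fit
then applies a zero-inflation rule: one pseudo-insertion spread across the
section's total gene length (lambda = summed length in bp), with a warning.
This keeps a saturated-library analysis from crashing while keeping the
fitted essential mode pressed against zero, which is the only property of
lambda the classifier actually uses in that regime.

### Fitting the truncated gamma

The high section is not a sample from the gamma; it is a sample from the
gamma *conditioned on exceeding the cut-off*. The package therefore
maximises the conditional likelihood — each density term divided by the
gamma's mass above 0.03 — by quasi-Newton optimisation on log-parameters,
seeded by method of moments, with relative tolerance 1e-9. The distinction
matters: on sections with only ~4% of their mass truncated, an
unconditional gamma fit overestimates the shape by 13-23%, while the
conditional fit recovers simulated parameters to better than 1% on pure
draws. A test verifies that the conditional fit agrees with an
unconstrained `fitdistrplus` fit (to 1%) when the cut-off truncates
nothing, keeping the two routes independent.

## The sliding-window domain correction

A gene can be tolerant at its termini yet indispensable in a core domain;
whole-gene indices miss this. Every gene called non-essential or unclear is
re-scanned with 300 bp windows placed every 150 bp from the gene start. A
window containing zero insertion sites flags the gene, and flagged genes
are promoted to essential by default (`promote = FALSE` gives a report-only
run). Genes already called essential are never scanned.

Two placement details are deliberate choices where the procedure is
otherwise underspecified. Genes shorter than one window get a single window
spanning the whole gene; and when the gene length is not stride-aligned, a
final window is anchored at the 3' end. Together these guarantee every base
of every gene lies under some window. Both behaviours sit behind
`terminal_window`; disabling it reproduces a strict full-windows-only scan
in which a short gene is never scanned at all and a 3' tail shorter than
the stride goes uninspected.

The correction has a known failure mode in both directions: an unaligned
insertion-free stretch shorter than window + step - 1 (449 bp at the
defaults) can be missed, and a sparsely inserted tolerant gene can be
falsely promoted when its few sites happen to leave one window empty (about
0.2% of tolerant genes at saturation in our simulations). Neither is an
implementation artefact; both follow from the window geometry.

## Ortholog comparison

Cross-species agreement uses reciprocal best hits on 14-column tabular
alignment output (the standard 12 columns plus query and subject lengths,
which coverage filtering needs). Hits are kept at E-value <= 1e-5 and query
and subject coverage >= 70%, both bounds inclusive; coverage comes from the
single best HSP, with no chaining — a conservative bias for fragmented
alignments, noted rather than corrected. Best hits break bitscore ties by
E-value, then identity, then subject id, making pairing deterministic. A
protein is treated as having a paralog when any non-self within-proteome
hit passes the same filters, and pairs touching such proteins are removed,
because an intact paralog can complement a disruption and silently decouple
the two species' calls. This operational definition of "paralog" is the
strictest defensible one; it is a package decision, recorded in output
provenance, and switchable.

One caution about sweeping thresholds: the *hit* set shrinks monotonically
as filters tighten, but the *pair* set need not — removing a best hit can
promote a second-best hit into a new reciprocal pair. The tests therefore
assert monotonicity at the hit level, where it genuinely holds.

## Functional profiles

COG labels are split into single letters, each letter counting once per
gene per call, so a two-letter gene contributes two label counts; genes
with no ortholog group or an empty label count under "unannotated".
Presence/absence profiling reduces each proteome to a binary vector over a
chosen ortholog-group universe (repeat occurrences collapse to 1, absent
groups keep their all-zero column) and clusters proteome rows by
complete-linkage agglomeration on Euclidean distances over the raw 0/1
values — no scaling, matching the common clustered-heatmap default. The
number of clusters k is a user parameter cut from the dendrogram, not an
automatic criterion, since in practice it is chosen by inspecting the tree.

## What the synthetic data emulate — and what they do not

The generator builds one contig of i.i.d. random sequence carrying
non-overlapping genes (lengths ~ Normal(900, 200) bp, floored at 150;
Poisson(150)+1 bp intergenic gaps). Defaults: 2,000 genes, 10% essential,
0.5% domain-essential, one expected unique insertion per 12 bp of tolerant
sequence, zero leakage into essential genes — a scale on which the
0.006/0.03 cut-offs apply without retuning, and small enough that the whole
suite runs in about a minute.

Non-essential genes draw a per-gene insertion rate from
Gamma(shape = 5, scale = (1/12)/5) — mean exactly the configured density —
and each base then carries an independent insertion at that rate. The
gamma layer gives the non-essential index mode the gamma shape the
classifier fits and provides exact ground-truth (k, theta) for
parameter-recovery tests; the per-base layer adds binomial noise on top,
which is why recovered parameters sit a few percent from truth even at
n = 2,000 (the index of a 900 bp gene is a binomial proportion, not the
rate itself). Domain-essential genes keep an insertion-free core of 500 bp:
at least window + step - 1 = 449 bp is required for a zero window to be
guaranteed wherever the core sits, so 500 makes every planted core
detectable by construction. Reads, when emitted, are
primer + tail + 50 genomic bases from a randomly chosen feasible
orientation at each site, plus 2% tag-less decoys.

What the simulation does not model: sequencing errors and quality trimming,
GC or replication-origin insertion bias, fitness gradients (a gene here is
binary essential/tolerant, not partially depleted), overlapping genes,
multi-contig genomes, and non-CDS feature classes (the feature-class logic
is exercised by hand-built fixtures in the tests instead). Passing the
recovery suites therefore demonstrates that the statistical machinery is
correct under the model's own assumptions — not that real libraries are
free of the biases the non-goals exclude.

All randomness flows from a single config seed through `withr::with_seed`;
stage seeds are derived (seed, seed+1, seed+2) so a bundle is reproducible
end to end and byte-identical across runs.

## Problem sizes and determinism in the test suite

The packaged checks use 2,000 genes (about 2.1 Mb and 160,000 unique
sites) for classifier recovery, 500 random genes up to 5 kb for the
window-scan oracle, 100 random toy tables (up to 20 proteins a side)
against an exhaustive reciprocal-best-hit enumeration, a 150-gene bundle
for the FASTQ round-trip identity, and a 12 x 18 three-block matrix for
clustering recovery. These sizes were chosen so every property is measured
at meaningful scale while the whole suite stays fast enough to run on
every change. All stochastic tests fix their seeds; reruns are exactly
reproducible.

## Known limitations

* Calls are binary per gene (plus the domain flag); partially depleted
  genes, condition-specific essentiality and replicate structure are out of
  scope.
* The insertion-index denominator is the full annotated gene span; no 5'/3'
  trimming is applied, so tolerant termini dilute the index (the domain
  scan exists precisely to catch the resulting misses).
* The exact mapper requires perfect substring matches and is intended for
  synthetic genomes; real libraries should be mapped externally and
  ingested as site tables.
* Coverage filtering from single HSPs undercounts coverage for genuinely
  split alignments (fusions, long insertions), which can exclude true
  orthologs of such genes from the comparison.
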