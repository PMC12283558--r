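test_that("the generator is deterministic and byte-stable under a seed", {
    cfg <- simulationConfig(seed = 42, n_genes = 40)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    simulateBundle(cfg, dir = d1)
    simulateBundle(cfg, dir = d2)
    for (f in c("genome.fasta", "annotation.gff3", "sites.tsv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("class fractions and gene geometry follow the config", {
    sim <- simulateGenome(simulationConfig(seed = 1, n_genes = 500,
                                           essential_fraction = 0))
    expect_true(all(sim$manifest$genes$class %in%
                    c("non_essential", "domain_essential")))
    sim2 <- simulateGenome(simulationConfig(seed = 2, n_genes = 500))
    g <- sim2$manifest$genes
    expect_equal(sum(g$class == "essential"), 50L)
    expect_equal(sum(g$class == "domain_essential"), 2L)  # 0.5% of 500
    # total gene span ~ n * mean length
    expect_lt(abs(sum(g$length_bp) - 500 * 900) / (500 * 900), 0.05)
    # genes do not overlap and fit the contig
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    expect_true(all(g$end <= sim2$manifest$contig_lengths))
    expect_error(simulateGenome(simulationConfig(seed = 2, n_genes = 500,
                                                 genome_length = 1000)),
                 "cannot fit")
})

test_that("insertion process respects classes and matches its density", {
    cfg <- simulationConfig(seed = 3, n_genes = 300)
    sim <- simulateGenome(cfg)
    ins <- simulateInsertions(sim)
    g <- ins$manifest$genes
    expect_true(all(g$n_sites[g$class == "essential"] == 0L))  # leakage 0
    # domain-essential cores are insertion-free
    dom <- g[g$class == "domain_essential", ]
    pos <- BiocGenerics::start(siteRanges(ins$sites))
    for (i in seq_len(nrow(dom)))
        expect_equal(sum(pos >= dom$core_start[i] & pos <= dom$core_end[i]), 0L)
    # intergenic sites follow the flat density within 3 sd
    part <- partitionSites(ins$sites, sim$annotation)
    inter_len <- sim$manifest$contig_lengths[[1]] - sum(g$length_bp)
    expected <- inter_len * cfg$insertion_density
    expect_lt(abs(part$intergenic_sites - expected), 3 * sqrt(expected))
    # per-gene counts in the manifest reconcile with the stats module
    st <- geneInsertionStats(ins$sites, sim$annotation)
    expect_equal(st$unique_insertions, g$n_sites)
})

test_that("leakage plants sites inside essential genes at its rate", {
    cfg <- simulationConfig(seed = 4, n_genes = 300, leakage_rate = 0.01)
    ins <- simulateInsertions(simulateGenome(cfg))
    g <- ins$manifest$genes
    ess_len <- sum(g$length_bp[g$class == "essential"])
    ess_sites <- sum(g$n_sites[g$class == "essential"])
    expect_lt(abs(ess_sites - ess_len * 0.01), 3 * sqrt(ess_len * 0.01))
})

test_that("simulated reads reproduce the site table through the pipeline", {
    cfg <- simulationConfig(seed = 5, n_genes = 60)
    b <- simulateBundle(cfg, emit_reads = TRUE)
    expect_equal(b$reads$n_skipped_sites, 0L)
    sel <- selectTransposonReads(b$reads$reads, cfg$primer, cfg$tail)
    expect_equal(sel$report$discarded_no_tag, b$reads$n_decoys)
    m <- mapReadsExact(sel$reads, b$genome)
    expect_equal(BiocGenerics::start(siteRanges(m$sites)),
                 BiocGenerics::start(siteRanges(b$sites)))
    expect_equal(S4Vectors::mcols(siteRanges(m$sites))$read_count,
                 S4Vectors::mcols(siteRanges(b$sites))$read_count)
})

test_that("every emitted file parses back consistently with the manifest", {
    cfg <- simulationConfig(seed = 6, n_genes = 30)
    dir <- withr::local_tempdir()
    b <- simulateBundle(cfg, dir = dir, emit_reads = TRUE)
    ann <- readAnnotation(file.path(dir, "annotation.gff3"))
    expect_equal(length(ann), 30L)
    genome <- readGenome(file.path(dir, "genome.fasta"))
    expect_equal(unname(Biostrings::width(genome)),
                 unname(b$manifest$contig_lengths))
    sites <- readSiteTable(file.path(dir, "sites.tsv"))
    expect_equal(siteCount(sites), b$manifest$total_unique_sites)
    reads <- readFastqReads(file.path(dir, "reads.fastq"))
    expect_equal(length(reads), b$reads$n_tag_reads + b$reads$n_decoys)
})

test_that("config invariants are enforced", {
    expect_error(simulationConfig(essential_fraction = 0.9,
                                  domain_essential_fraction = 0.2), "<= 1")
    expect_error(simulationConfig(insertion_density = 1.5), "exceed 1")
    expect_error(simulationConfig(leakage_rate = -0.1), ">= 0")
})
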