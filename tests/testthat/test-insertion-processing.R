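tag <- paste0(TN_PRIMER, TN_TAIL)

test_that("tag selection trims at the junction and applies the length bound", {
    withr::local_seed(1)
    g30 <- random_dna(30)
    g21 <- random_dna(21)
    g20 <- random_dna(20)
    reads <- c(paste0(tag, g30),          # kept, trimmed to the genomic part
               g30,                       # no tag
               paste0(tag, g20),          # exactly 20 -> discarded
               paste0(tag, g21),          # 21 > 20 -> kept
               paste0("TTTT", tag, g30))  # tag mid-read: 5' side removed too
    sel <- selectTransposonReads(reads)
    expect_equal(sel$report$input, 5L)
    expect_equal(sel$report$selected, 3L)
    expect_equal(sel$report$discarded_no_tag, 1L)
    expect_equal(sel$report$discarded_short, 1L)
    expect_equal(as.character(sel$reads), c(g30, g21, g30),
                 ignore_attr = TRUE)
    expect_error(selectTransposonReads(reads, primer = ""), "empty primer")
})

test_that("tag selection is idempotent on its own output", {
    cfg <- simulationConfig(seed = 3, n_genes = 30)
    b <- simulateBundle(cfg, emit_reads = TRUE)
    sel1 <- selectTransposonReads(b$reads$reads)
    sel2 <- selectTransposonReads(sel1$reads)
    expect_equal(sel2$report$selected, 0L)  # no residual tag anywhere
    expect_equal(sel2$report$discarded_no_tag, sel1$report$selected)
})

test_that("exact mapping reports the junction base on either strand", {
    withr::local_seed(42)
    genome <- Biostrings::DNAStringSet(c(toy = random_dna(200)))
    fwd <- Biostrings::subseq(genome[[1]], 101, 130)
    rev <- Biostrings::reverseComplement(fwd)
    m <- mapReadsExact(Biostrings::DNAStringSet(c(as.character(fwd),
                                                  as.character(rev))),
                       genome)
    # forward read starts at 0-based 100 (internal 101); the reverse read's
    # 5'-most genomic base is 0-based 129 (internal 130)
    expect_equal(BiocGenerics::start(siteRanges(m$sites)), c(101L, 130L))
    expect_equal(m$report$mapped, 2L)

    # brute-force confirmation by string scanning: the reverse read aligns
    # where its reverse complement occurs, and its 5' base sits at the
    # alignment's right edge
    gs <- as.character(genome[[1]])
    rc_of_read <- as.character(Biostrings::reverseComplement(rev))
    hits <- integer()
    for (p in 1:(nchar(gs) - 29)) {
        if (substr(gs, p, p + 29) == rc_of_read)
            hits <- c(hits, p + 29L)
    }
    expect_equal(hits, 130L)
})

test_that("multi-mapping and duplicate reads are handled", {
    withr::local_seed(9)
    left <- random_dna(40)
    mid <- random_dna(20)
    genome <- Biostrings::DNAStringSet(
        c(toy = paste0(left, mid, random_dna(40), mid, random_dna(40))))
    dup <- substr(left, 1, 30)
    m <- mapReadsExact(Biostrings::DNAStringSet(c(mid, dup, dup)), genome)
    expect_equal(m$report$multimapped, 1L)
    expect_equal(m$report$mapped, 2L)
    expect_equal(siteCount(m$sites), 1L)   # duplicates collapse
    expect_equal(S4Vectors::mcols(siteRanges(m$sites))$read_count, 2L)
    expect_warning(
        mapReadsExact(Biostrings::DNAStringSet(random_dna(500)), genome),
        "longer")
})

test_that("insertion indices are exact arithmetic", {
    ann <- GenomeAnnotation(
        gene_id = c("g1", "g2", "g3"), contig = "c1",
        start = c(1, 1101, 2101), end = c(1000, 1333, 2200),
        strand = "+", feature_class = "CDS",
        contig_lengths = c(c1 = 3000L))
    sites <- toy_sites(c(seq(10, 990, length.out = 30),
                         1101 + c(0, 10, 50, 99, 150, 200, 232)),
                       len = 3000L)
    st <- geneInsertionStats(sites, ann)
    expect_equal(st$insertion_index[1], 0.03)      # 30 / 1000
    expect_equal(st$unique_insertions[2], 7L)
    expect_equal(st$insertion_index[2], 7 / 233)   # 0.0300429...
    expect_equal(st$insertion_index[3], 0)
    bad <- toy_sites(5, contig = "cX", len = 100L)
    expect_error(geneInsertionStats(bad, ann), "unknown")
})

test_that("sites in overlapping genes count once per gene", {
    ann <- toy_annotation()
    s <- toy_sites(c(190, 250, 450))  # 190 inside both gA and gB
    st <- geneInsertionStats(s, ann)
    expect_equal(st$unique_insertions, c(1L, 2L, 1L, 0L))
})

test_that("gene stats match a per-base brute force on toy genomes", {
    for (seed in 1:3) {
        withr::local_seed(seed)
        len <- 8000L
        starts <- sort(sample(1:7000, 8))
        ends <- pmin(starts + sample(200:800, 8), len)
        ann <- GenomeAnnotation(gene_id = sprintf("g%d", 1:8), contig = "c1",
                                start = starts, end = ends, strand = "+",
                                feature_class = "CDS",
                                contig_lengths = c(c1 = len))
        pos <- sort(sample(1:len, 400))
        st <- geneInsertionStats(toy_sites(pos, len = len), ann)
        for (i in 1:8) {
            n <- 0L
            for (p in pos) if (p >= starts[i] && p <= ends[i]) n <- n + 1L
            expect_equal(st$unique_insertions[i], n)
        }
    }
})

test_that("the CDS/intergenic partition conserves the site total", {
    ann <- toy_annotation()
    # 190 in two overlapping CDSs (once), 450 in one CDS, 720 in the tRNA
    # only (intergenic by the CDS-literal rule), 900 outside everything
    part <- partitionSites(toy_sites(c(190, 450, 720, 900)), ann)
    expect_equal(part$cds_sites, 2L)
    expect_equal(part$intergenic_sites, 2L)
    expect_equal(part$total_unique_sites, 4L)

    b <- simulateBundle(simulationConfig(seed = 13, n_genes = 50))
    p <- partitionSites(b$sites, b$annotation)
    expect_equal(p$cds_sites + p$intergenic_sites, siteCount(b$sites))
    expect_equal(p$total_unique_sites, b$manifest$total_unique_sites)
})
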