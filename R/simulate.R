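## Seeded generator for every fixture the pipeline consumes: genome +
## annotation, insertion-site tables (and optionally tagged reads), homology
## hit tables with planted confounders, and functional-annotation tables,
## each paired with a ground-truth manifest. All randomness flows from the
## config seed through withr::with_seed; no global RNG state leaks.

#' Simulation configuration
#'
#' Defaults emulate a saturated transposon library in a mid-sized bacterial
#' genome: 2,000 non-overlapping genes of ~900 bp, 10% essential (plus a
#' small fraction carrying only an essential core domain), and a unique-site
#' density of one insertion per 12 bp of tolerant sequence, so synthetic
#' insertion indices live on the same scale as the 0.006 / 0.03 section
#' cut-offs without retuning. Non-essential genes draw their per-gene
#' insertion rate from Gamma(density_shape, density / density_shape), mean
#' exactly \code{insertion_density}, which shapes the non-essential index
#' mode as the gamma the classifier fits and makes (shape, scale) available
#' as ground truth; intergenic sequence and essential-gene leakage use flat
#' per-base rates.
#'
#' @param seed Master seed; stage seeds are derived as seed, seed+1, seed+2.
#' @param n_genes Number of genes.
#' @param gene_length_mean,gene_length_sd,min_gene_length Gene length draw
#'   (normal, floored) in bp.
#' @param intergenic_mean Mean intergenic gap in bp (Poisson + 1).
#' @param genome_length Optional total contig length; an error is raised if
#'   the genes cannot fit, and the remainder pads the 3' end. Default: sized
#'   by the genes and gaps themselves.
#' @param essential_fraction,domain_essential_fraction Fractions of genes
#'   that are fully essential / essential only in a core domain; their sum
#'   must be <= 1.
#' @param insertion_density Expected unique insertions per bp of tolerant
#'   sequence (default 1/12).
#' @param density_shape Gamma shape of per-gene non-essential rates
#'   (default 5); \code{Inf} gives a flat rate.
#' @param leakage_rate Per-base insertion rate inside essential genes
#'   (default 0).
#' @param domain_core_length Length of the insertion-free core in
#'   domain-essential genes. The default 500 bp exceeds window + step - 1
#'   (449 bp for the 300/150 scan), the smallest span guaranteed to contain
#'   a whole window wherever the core sits; shorter cores are only
#'   detectable when they happen to align with a window placement.
#' @param read_length Genomic bases carried by each simulated read.
#' @param primer,tail Transposon tag prepended to simulated reads.
#' @param decoy_fraction Fraction of tag-less decoy reads added to simulated
#'   FASTQ output.
#' @return A config list (class \code{tradis_sim_config}).
#' @export
simulationConfig <- function(seed = 42L, n_genes = 2000L,
                             gene_length_mean = 900, gene_length_sd = 200,
                             min_gene_length = 150L, intergenic_mean = 150,
                             genome_length = NULL,
                             essential_fraction = 0.10,
                             domain_essential_fraction = 0.005,
                             insertion_density = 1 / 12,
                             density_shape = 5,
                             leakage_rate = 0,
                             domain_core_length = 500L,
                             read_length = 50L,
                             primer = TN_PRIMER, tail = TN_TAIL,
                             decoy_fraction = 0.02) {
    if (essential_fraction + domain_essential_fraction > 1)
        stop("essential_fraction + domain_essential_fraction must be <= 1")
    if (insertion_density < 0 || leakage_rate < 0)
        stop("densities must be >= 0")
    if (insertion_density > 1 || leakage_rate > 1)
        stop("per-base densities cannot exceed 1")
    structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                   gene_length_mean = gene_length_mean,
                   gene_length_sd = gene_length_sd,
                   min_gene_length = as.integer(min_gene_length),
                   intergenic_mean = intergenic_mean,
                   genome_length = genome_length,
                   essential_fraction = essential_fraction,
                   domain_essential_fraction = domain_essential_fraction,
                   insertion_density = insertion_density,
                   density_shape = density_shape,
                   leakage_rate = leakage_rate,
                   domain_core_length = as.integer(domain_core_length),
                   read_length = as.integer(read_length),
                   primer = primer, tail = tail,
                   decoy_fraction = decoy_fraction),
              class = "tradis_sim_config")
}

#' Simulate a genome, its annotation and the truth manifest
#'
#' Draws gene lengths, assigns true classes (essential, non_essential,
#' domain_essential) by the configured fractions, places the genes without
#' overlap separated by Poisson gaps on one contig of random sequence, and
#' records everything in the manifest: per-gene coordinates, true class,
#' true per-gene insertion rate, and the insertion-free core coordinates of
#' domain-essential genes. Deterministic under the config seed.
#'
#' @param config From \code{\link{simulationConfig}}.
#' @return A list with genome (\code{DNAStringSet}), annotation
#'   (\code{\link{GenomeAnnotation}}) and manifest (list with genes
#'   data.frame, contig_lengths, config).
#' @export
simulateGenome <- function(config) {
    withr::with_seed(config$seed, {
        n <- config$n_genes
        len <- pmax(as.integer(round(stats::rnorm(n, config$gene_length_mean,
                                                  config$gene_length_sd))),
                    config$min_gene_length)
        n_ess <- round(config$essential_fraction * n)
        n_dom <- round(config$domain_essential_fraction * n)
        cls <- rep("non_essential", n)
        need <- config$domain_core_length + 300L
        pick <- sample.int(n)
        cls[pick[seq_len(n_ess)]] <- "essential"
        dom_idx <- pick[n_ess + seq_len(n_dom)]
        cls[dom_idx] <- "domain_essential"
        len[dom_idx] <- pmax(len[dom_idx], need)

        gaps <- stats::rpois(n + 1L, config$intergenic_mean) + 1L
        starts <- cumsum(c(gaps[1], len[-n] + gaps[2:n])) + 1L
        ends <- starts + len - 1L
        required <- ends[n] + gaps[n + 1L]
        glen <- if (is.null(config$genome_length)) required else
            as.integer(config$genome_length)
        if (glen < required)
            stop("genes cannot fit in genome_length (need ", required, " bp)")

        seq <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                     collapse = "")
        genome <- Biostrings::DNAStringSet(stats::setNames(seq, "contig_1"))

        rate <- numeric(n)
        rate[cls == "essential"] <- config$leakage_rate
        tolerant <- cls != "essential"
        rate[tolerant] <- if (is.finite(config$density_shape)) {
            stats::rgamma(sum(tolerant), shape = config$density_shape,
                          scale = config$insertion_density / config$density_shape)
        } else config$insertion_density
        rate <- pmin(rate, 1)

        core_start <- rep(NA_integer_, n)
        core_end <- rep(NA_integer_, n)
        if (length(dom_idx)) {
            off <- vapply(len[dom_idx] - config$domain_core_length,
                          function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
            core_start[dom_idx] <- starts[dom_idx] + off
            core_end[dom_idx] <- core_start[dom_idx] +
                config$domain_core_length - 1L
        }

        genes <- data.frame(
            gene_id = sprintf("GENE_%04d", seq_len(n)),
            contig = "contig_1",
            start = starts, end = ends,
            strand = sample(c("+", "-"), n, replace = TRUE),
            feature_class = "CDS",
            length_bp = len,
            class = cls,
            rate = rate,
            core_start = core_start, core_end = core_end,
            stringsAsFactors = FALSE)
        annotation <- GenomeAnnotation(
            gene_id = genes$gene_id, contig = genes$contig,
            start = genes$start, end = genes$end, strand = genes$strand,
            feature_class = genes$feature_class,
            contig_lengths = c(contig_1 = glen))
        list(genome = genome, annotation = annotation,
             manifest = list(genes = genes,
                             contig_lengths = c(contig_1 = glen),
                             config = config))
    })
}

.bernoulli_positions <- function(offsets, rate) {
    # offsets: candidate absolute positions; per-base Bernoulli(rate)
    if (!length(offsets) || rate <= 0) return(integer())
    n <- stats::rbinom(1L, length(offsets), rate)
    if (!n) return(integer())
    sort(sample(offsets, n))
}

#' Simulate unique insertion sites from a truth manifest
#'
#' Each base of tolerant sequence carries an independent insertion with its
#' region's rate: the per-gene true rate for non-essential genes (and the
#' flanks of domain-essential genes, whose core stays insertion-free), the
#' leakage rate inside essential genes, and the genome-wide density in
#' intergenic sequence. Read counts per site are 1 + Poisson(2). The
#' manifest gains per-gene realised site counts and the site total.
#'
#' @param sim Output of \code{\link{simulateGenome}}.
#' @param seed Seed for the insertion stage (default config seed + 1).
#' @return A list with sites (\code{\link{InsertionSites}}) and the updated
#'   manifest.
#' @export
simulateInsertions <- function(sim, seed = NULL) {
    config <- sim$manifest$config
    if (is.null(seed)) seed <- config$seed + 1L
    genes <- sim$manifest$genes
    glen <- sim$manifest$contig_lengths[["contig_1"]]
    withr::with_seed(seed, {
        pos <- vector("list", nrow(genes) + 1L)
        for (i in seq_len(nrow(genes))) {
            gi <- genes[i, ]
            cand <- seq.int(gi$start, gi$end)
            if (gi$class == "domain_essential")
                cand <- cand[cand < gi$core_start | cand > gi$core_end]
            pos[[i]] <- .bernoulli_positions(cand, gi$rate)
        }
        covered <- rep(FALSE, glen)
        for (i in seq_len(nrow(genes)))
            covered[genes$start[i]:genes$end[i]] <- TRUE
        pos[[nrow(genes) + 1L]] <- .bernoulli_positions(
            which(!covered), config$insertion_density)
        all_pos <- sort(unique(unlist(pos)))
        counts <- 1L + stats::rpois(length(all_pos), 2)
        sites <- InsertionSites(contig = rep("contig_1", length(all_pos)),
                                position = all_pos, read_count = counts,
                                contig_lengths = sim$manifest$contig_lengths)
        manifest <- sim$manifest
        manifest$genes$n_sites <- vapply(seq_len(nrow(genes)), function(i)
            sum(all_pos >= genes$start[i] & all_pos <= genes$end[i]),
            integer(1))
        manifest$total_unique_sites <- length(all_pos)
        list(sites = sites, manifest = manifest)
    })
}

#' Simulate transposon-tagged reads for a site table
#'
#' Emits one read per supporting read count of every unique site:
#' primer + tail + read_length genomic bases starting at the insertion
#' point, on a randomly chosen feasible orientation (forward reads run
#' rightwards from the site; reverse reads cover the bases ending at the
#' site and are reverse-complemented, so the junction base is always the
#' read's first genomic base). Adds a configurable fraction of tag-less
#' decoy reads. Sites too close to both contig ends to fit a read are
#' skipped and counted.
#'
#' @param genome \code{DNAStringSet} from \code{\link{simulateGenome}}.
#' @param sites An \code{\link{InsertionSites}}.
#' @param config From \code{\link{simulationConfig}}.
#' @param seed Seed for the read stage (default config seed + 2).
#' @return A list with reads (\code{DNAStringSet}, shuffled), n_tag_reads,
#'   n_decoys and n_skipped_sites.
#' @export
simulateReads <- function(genome, sites, config, seed = NULL) {
    if (is.null(seed)) seed <- config$seed + 2L
    s <- siteRanges(sites)
    stopifnot(length(genome) == 1L)
    L <- Biostrings::width(genome)[1]
    rl <- config$read_length
    withr::with_seed(seed, {
        pos <- rep(BiocGenerics::start(s), S4Vectors::mcols(s)$read_count)
        fwd_ok <- pos + rl - 1L <= L
        rev_ok <- pos - rl + 1L >= 1L
        feasible <- fwd_ok | rev_ok
        n_skipped <- sum(!feasible)
        pos <- pos[feasible]
        use_fwd <- ifelse(fwd_ok[feasible] & rev_ok[feasible],
                          stats::runif(length(pos)) < 0.5,
                          fwd_ok[feasible])
        subj <- genome[[1]]
        gseq <- character(length(pos))
        if (any(use_fwd)) {
            v <- Biostrings::Views(subj, start = pos[use_fwd],
                                   width = rl)
            gseq[use_fwd] <- as.character(Biostrings::DNAStringSet(v))
        }
        if (any(!use_fwd)) {
            v <- Biostrings::Views(subj, end = pos[!use_fwd], width = rl)
            gseq[!use_fwd] <- as.character(
                Biostrings::reverseComplement(Biostrings::DNAStringSet(v)))
        }
        tag <- paste0(config$primer, config$tail)
        reads <- paste0(tag, gseq)
        n_decoys <- round(config$decoy_fraction * length(reads))
        decoys <- vapply(seq_len(n_decoys), function(i)
            paste(sample(c("A", "C", "G", "T"), nchar(tag) + rl,
                         replace = TRUE), collapse = ""), character(1))
        all_reads <- c(stats::setNames(reads,
                           sprintf("tnread_%06d", seq_along(reads))),
                       stats::setNames(decoys,
                           sprintf("decoy_%06d", seq_len(n_decoys))))
        all_reads <- all_reads[sample.int(length(all_reads))]
        list(reads = Biostrings::DNAStringSet(all_reads),
             n_tag_reads = length(reads), n_decoys = n_decoys,
             n_skipped_sites = n_skipped)
    })
}

#' Simulate reciprocal homology tables with planted confounders
#'
#' Builds directional A->B and B->A hit tables plus within-proteome self
#' tables for two simulated gene sets. True ortholog pairs receive
#' full-coverage, low-E-value reciprocal top hits (plus weaker noise hits);
#' three confounder classes are planted and recorded in the truth table:
#' \code{near_threshold} pairs whose A->B hit has 69% query coverage (lost
#' at the filter), \code{asymmetric} pairs whose B gene prefers a different
#' A gene (lost at reciprocity), and \code{paralog} pairs whose A gene has a
#' within-proteome partner passing the filters (lost at paralog exclusion).
#'
#' @param manifest_a,manifest_b Manifests from \code{\link{simulateGenome}}.
#' @param seed Seed for this stage.
#' @param ortholog_fraction Fraction of the smaller gene set given a true
#'   ortholog.
#' @param n_near_threshold,n_asymmetric,n_paralog Confounders planted.
#' @return A list with ab, ba, self_a, self_b (14-column hit data.frames)
#'   and truth (gene_a, gene_b, confounder).
#' @export
simulateHomology <- function(manifest_a, manifest_b, seed = 1L,
                             ortholog_fraction = 0.7,
                             n_near_threshold = 3L, n_asymmetric = 3L,
                             n_paralog = 3L) {
    ga <- manifest_a$genes
    gb <- manifest_b$genes
    withr::with_seed(seed, {
        plen_a <- stats::setNames(pmax(ga$length_bp %/% 3L, 50L),
                                  paste0("A_", ga$gene_id))
        plen_b <- stats::setNames(pmax(gb$length_bp %/% 3L, 50L),
                                  paste0("B_", gb$gene_id))
        n_pairs <- floor(min(length(plen_a), length(plen_b)) *
                         ortholog_fraction)
        a_ids <- sample(names(plen_a))
        b_ids <- sample(names(plen_b))
        pair_a <- a_ids[seq_len(n_pairs)]
        pair_b <- b_ids[seq_len(n_pairs)]
        spare_a <- a_ids[-seq_len(n_pairs)]
        n_conf <- n_near_threshold + n_asymmetric + n_paralog
        if (n_pairs <= n_conf || length(spare_a) < n_asymmetric + n_paralog)
            stop("too few genes for the requested confounders")
        confounder <- rep("none", n_pairs)
        ci <- sample.int(n_pairs, n_conf)
        near_i <- ci[seq_len(n_near_threshold)]
        asym_i <- ci[n_near_threshold + seq_len(n_asymmetric)]
        par_i <- ci[n_near_threshold + n_asymmetric + seq_len(n_paralog)]
        confounder[near_i] <- "near_threshold"
        confounder[asym_i] <- "asymmetric"
        confounder[par_i] <- "paralog"

        hit_row <- function(q, s, qlen, slen, bitscore, evalue = 1e-80,
                            pident = NULL, q_end = NULL) {
            if (is.null(pident)) pident <- round(stats::runif(1, 60, 95), 1)
            if (is.null(q_end)) q_end <- qlen
            aln <- min(q_end, slen)
            data.frame(query_id = q, subject_id = s,
                       percent_identity = pident, aln_length = aln,
                       mismatches = as.integer(round(aln * (100 - pident) / 100)),
                       gap_opens = 0L, q_start = 1L, q_end = as.integer(q_end),
                       s_start = 1L, s_end = as.integer(slen),
                       evalue = evalue, bitscore = bitscore,
                       q_len = as.integer(qlen), s_len = as.integer(slen),
                       stringsAsFactors = FALSE)
        }

        ab <- list(); ba <- list(); self_a <- list(); self_b <- list()
        top <- round(stats::runif(n_pairs, 400, 800))
        for (i in seq_len(n_pairs)) {
            a <- pair_a[i]; b <- pair_b[i]
            qa <- plen_a[[a]]; qb <- plen_b[[b]]
            q_end_ab <- if (confounder[i] == "near_threshold")
                floor(qa * 0.69) else qa
            ab[[length(ab) + 1L]] <- hit_row(a, b, qa, qb, top[i],
                                             q_end = q_end_ab)
            ba[[length(ba) + 1L]] <- hit_row(b, a, qb, qa, top[i])
            # weaker cross noise to exercise best-hit selection
            if (stats::runif(1) < 0.3 && n_pairs > 1L) {
                j <- sample(setdiff(seq_len(n_pairs), i), 1L)
                ab[[length(ab) + 1L]] <- hit_row(a, pair_b[j], qa,
                                                 plen_b[[pair_b[j]]],
                                                 top[i] * 0.4, evalue = 1e-20)
            }
        }
        # asymmetric: b's best hit goes to a spare A gene
        spare_pool <- spare_a
        for (k in seq_along(asym_i)) {
            i <- asym_i[k]
            a2 <- spare_pool[k]
            ba[[length(ba) + 1L]] <- hit_row(pair_b[i], a2, plen_b[[pair_b[i]]],
                                             plen_a[[a2]], top[i] + 100)
        }
        # paralogs: the A gene has a filtered-passing within-proteome partner
        for (k in seq_along(par_i)) {
            i <- par_i[k]
            partner <- spare_pool[n_asymmetric + k]
            self_a[[length(self_a) + 1L]] <- hit_row(
                pair_a[i], partner, plen_a[[pair_a[i]]], plen_a[[partner]],
                350, pident = 95)
        }
        empty_hits <- function() {
            df <- as.data.frame(stats::setNames(rep(list(character()), 14),
                                                .HIT_COLS))
            for (cn in .HIT_NUM) df[[cn]] <- numeric()
            df
        }
        list(ab = do.call(rbind, ab),
             ba = do.call(rbind, ba),
             self_a = if (length(self_a)) do.call(rbind, self_a) else empty_hits(),
             self_b = if (length(self_b)) do.call(rbind, self_b) else empty_hits(),
             truth = data.frame(gene_a = pair_a, gene_b = pair_b,
                                confounder = confounder,
                                stringsAsFactors = FALSE))
    })
}

#' Simulate emapper-style functional annotations
#'
#' Assigns each CDS gene an ortholog group and COG category: a configurable
#' fraction stays unannotated (empty label and group) and a fraction gets
#' two distinct category letters, exercising the downstream label
#' splitting.
#'
#' @param manifest Manifest from \code{\link{simulateGenome}}.
#' @param seed Stage seed.
#' @param multi_fraction Fraction of annotated genes with two labels.
#' @param unannotated_fraction Fraction with no group/label.
#' @param cog_letters Category alphabet to draw from.
#' @return A data.frame with gene_id, cog_labels, og_ids.
#' @export
simulateAnnotations <- function(manifest, seed = 1L, multi_fraction = 0.1,
                                unannotated_fraction = 0.1,
                                cog_letters = c("C", "D", "E", "F", "G", "H",
                                                "I", "J", "K", "L", "M", "N",
                                                "O", "P", "S", "T")) {
    genes <- manifest$genes
    withr::with_seed(seed, {
        n <- nrow(genes)
        u <- stats::runif(n)
        unann <- u < unannotated_fraction
        multi <- !unann & u < unannotated_fraction + multi_fraction *
            (1 - unannotated_fraction)
        cog <- character(n)
        og <- character(n)
        single <- !unann & !multi
        cog[single] <- sample(cog_letters, sum(single), replace = TRUE)
        cog[multi] <- vapply(seq_len(sum(multi)), function(i)
            paste(sample(cog_letters, 2L), collapse = ""), character(1))
        og[!unann] <- sprintf("OG%05d", which(!unann))
        data.frame(gene_id = genes$gene_id, cog_labels = cog, og_ids = og,
                   stringsAsFactors = FALSE)
    })
}

#' Simulate a block-structured presence/absence fixture
#'
#' Proteomes and ortholog groups are partitioned into k blocks; a group is
#' present in a proteome iff they share a block (plus optional random
#' flips), giving a matrix whose complete-linkage clustering at k recovers
#' the blocks exactly when noise is 0.
#'
#' @param n_proteomes,n_groups,k Matrix dimensions and block count.
#' @param seed Stage seed.
#' @param noise Per-cell flip probability (default 0).
#' @return A list with tables (per-proteome annotation data.frames),
#'   group_universe, blocks (named proteome -> block) and values (the truth
#'   matrix).
#' @export
simulatePresenceBlocks <- function(n_proteomes = 12L, n_groups = 18L, k = 3L,
                                   seed = 1L, noise = 0) {
    stopifnot(k >= 1L, k <= n_proteomes, k <= n_groups)
    withr::with_seed(seed, {
        prot <- sprintf("proteome_%02d", seq_len(n_proteomes))
        grp <- sprintf("OGBLK%03d", seq_len(n_groups))
        pb <- rep(seq_len(k), length.out = n_proteomes)
        gb <- rep(seq_len(k), length.out = n_groups)
        values <- outer(pb, gb, `==`) * 1
        dimnames(values) <- list(prot, grp)
        if (noise > 0) {
            flip <- matrix(stats::runif(length(values)) < noise,
                           nrow = nrow(values))
            values[flip] <- 1 - values[flip]
        }
        tables <- lapply(prot, function(p) {
            present <- grp[values[p, ] == 1]
            data.frame(gene_id = paste0(p, "_g", seq_along(present)),
                       cog_labels = rep("S", length(present)),
                       og_ids = present, stringsAsFactors = FALSE)
        })
        names(tables) <- prot
        list(tables = tables, group_universe = grp,
             blocks = stats::setNames(pb, prot), values = values)
    })
}

#' Generate and optionally write a complete synthetic bundle
#'
#' Runs \code{\link{simulateGenome}} and \code{\link{simulateInsertions}}
#' (and optionally \code{\link{simulateReads}}), and when \code{dir} is
#' given writes genome.fasta, annotation.gff3, sites.tsv, reads.fastq and a
#' manifest (genes TSV + summary JSON) there.
#'
#' @param config From \code{\link{simulationConfig}}.
#' @param dir Optional output directory.
#' @param emit_reads Also simulate reads (default FALSE).
#' @return A list with genome, annotation, sites, manifest, reads (or NULL)
#'   and paths (or NULL).
#' @export
simulateBundle <- function(config = simulationConfig(), dir = NULL,
                           emit_reads = FALSE) {
    sim <- simulateGenome(config)
    ins <- simulateInsertions(sim)
    reads <- if (emit_reads) simulateReads(sim$genome, ins$sites, config)
             else NULL
    paths <- NULL
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        paths <- list(
            fasta = file.path(dir, "genome.fasta"),
            gff = file.path(dir, "annotation.gff3"),
            sites = file.path(dir, "sites.tsv"),
            manifest = file.path(dir, "manifest_genes.tsv"),
            summary = file.path(dir, "manifest.json"))
        writeGenome(sim$genome, paths$fasta)
        writeAnnotation(sim$annotation, paths$gff)
        writeSiteTable(ins$sites, paths$sites)
        utils::write.table(ins$manifest$genes, paths$manifest, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(
            seed = config$seed, n_genes = config$n_genes,
            total_unique_sites = ins$manifest$total_unique_sites,
            class_counts = as.list(table(ins$manifest$genes$class))),
            paths$summary, auto_unbox = TRUE)
        if (emit_reads) {
            paths$fastq <- file.path(dir, "reads.fastq")
            writeFastqReads(reads$reads, paths$fastq)
        }
    }
    list(genome = sim$genome, annotation = sim$annotation,
         sites = ins$sites, manifest = ins$manifest, reads = reads,
         paths = paths)
}
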