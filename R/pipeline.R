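## End-to-end orchestration: ingest -> stats -> call -> domain correction
## (-> orthologs, COG profile when inputs are present), with per-stage TSV
## outputs and a JSON summary whose defaults reproduce the published
## analysis settings exactly.

#' Pipeline configuration
#'
#' Collects input locations (paths or in-memory objects) and every module
#' parameter, with defaults matching the published analysis: primer/tail
#' tag, minimum read remainder 20 bp, index cut-offs 0.006/0.03, likelihood
#' threshold fold 12, 300/150 bp window scan, E-value 1e-5 and 70% coverage.
#'
#' @param annotation GFF3 path or \code{\link{GenomeAnnotation}} (required).
#' @param sites Site-table TSV path or \code{\link{InsertionSites}}; may be
#'   omitted when reads + genome are given.
#' @param reads FASTQ path or \code{DNAStringSet} of raw tagged reads.
#' @param genome FASTA path or \code{DNAStringSet}; needed with reads, or
#'   for contig lengths when the GFF3 lacks sequence-region directives.
#' @param hits_ab,hits_ba,self_a,self_b,calls_b Ortholog-comparison inputs
#'   (hit-table paths or data.frames; calls_b a call-table path, data.frame
#'   or \code{\link{GeneCallSet}}). Optional.
#' @param functional_annotation Emapper-style TSV path or data.frame for the
#'   COG profile. Optional.
#' @param out_dir Output directory (default: none, nothing written).
#' @param primer,tail,min_len Tag selection parameters.
#' @param cutoff_low,cutoff_high,threshold_fold Classifier parameters.
#' @param window,step,terminal_window,promote Domain-scan parameters.
#' @param max_evalue,min_cov Ortholog filter parameters.
#' @param collapse_strand Collapse site strands on reading (default TRUE).
#' @return A config list for \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(annotation, sites = NULL, reads = NULL,
                           genome = NULL, hits_ab = NULL, hits_ba = NULL,
                           self_a = NULL, self_b = NULL, calls_b = NULL,
                           functional_annotation = NULL, out_dir = NULL,
                           primer = TN_PRIMER, tail = TN_TAIL, min_len = 20L,
                           cutoff_low = 0.006, cutoff_high = 0.03,
                           threshold_fold = 12, window = 300L, step = 150L,
                           terminal_window = TRUE, promote = TRUE,
                           max_evalue = 1e-5, min_cov = 70,
                           collapse_strand = TRUE) {
    if (is.null(sites) && (is.null(reads) || is.null(genome)))
        stop("config error: need either sites or reads + genome")
    as.list(environment())
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full essentiality pipeline
#'
#' Executes ingest (tag selection and exact mapping when raw reads are
#' given), per-gene insertion statistics, the CDS/intergenic site partition,
#' two-mode fitting and classification, and the essential-domain
#' correction; when ortholog or functional-annotation inputs are present
#' the comparison and COG profile run too. When \code{out_dir} is set,
#' per-stage TSVs and a JSON summary (counts, partition, fit parameters,
#' agreement, provenance) are written; reruns with the same config are
#' byte-identical.
#'
#' @param config From \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with annotation, sites, stats, calls,
#'   domain_report, comparison, cog and summary.
#' @export
runPipeline <- function(config) {
    annotation <- .stage("annotation", {
        a <- config$annotation
        if (methods::is(a, "GenomeAnnotation")) a
        else readAnnotation(a, fasta = if (is.character(config$genome))
            config$genome else NULL)
    })
    map_report <- NULL
    sites <- .stage("sites", {
        if (!is.null(config$sites)) {
            s <- config$sites
            if (methods::is(s, "InsertionSites")) s
            else readSiteTable(s, collapse_strand = config$collapse_strand,
                               contig_lengths = contigLengths(annotation))
        } else {
            reads <- if (is.character(config$reads))
                readFastqReads(config$reads) else config$reads
            genome <- if (is.character(config$genome))
                readGenome(config$genome) else config$genome
            sel <- selectTransposonReads(reads, config$primer, config$tail,
                                         config$min_len)
            m <- mapReadsExact(sel$reads, genome)
            map_report <- c(sel$report, m$report)
            m$sites
        }
    })
    stats <- .stage("stats", geneInsertionStats(sites, annotation))
    partition <- .stage("partition", partitionSites(sites, annotation))
    calls <- .stage("call", callGenome(stats, config$cutoff_low,
                                       config$cutoff_high,
                                       config$threshold_fold))
    domain <- .stage("domains", domainCorrection(
        calls, annotation, sites, window = config$window, step = config$step,
        terminal_window = config$terminal_window, promote = config$promote))
    calls <- domain$calls

    comparison <- NULL
    if (!is.null(config$hits_ab) && !is.null(config$hits_ba) &&
        !is.null(config$calls_b)) {
        comparison <- .stage("orthologs", {
            ab <- if (is.character(config$hits_ab)) readHits(config$hits_ab)
                  else config$hits_ab
            ba <- if (is.character(config$hits_ba)) readHits(config$hits_ba)
                  else config$hits_ba
            fab <- filterHits(ab, config$max_evalue, config$min_cov,
                              config$min_cov)
            fba <- filterHits(ba, config$max_evalue, config$min_cov,
                              config$min_cov)
            pairs <- reciprocalPairs(bestHits(fab), bestHits(fba))
            if (!is.null(config$self_a) && !is.null(config$self_b)) {
                sa <- if (is.character(config$self_a))
                    readHits(config$self_a) else config$self_a
                sb <- if (is.character(config$self_b))
                    readHits(config$self_b) else config$self_b
                pairs <- excludeParalogs(pairs, sa, sb, config$max_evalue,
                                         config$min_cov, config$min_cov)
            }
            calls_b <- if (is.character(config$calls_b))
                readCallTable(config$calls_b) else config$calls_b
            # cross-species comparison restricted to the CDS universe;
            # simulated hit tables prefix gene ids with the species tag
            d <- geneCalls(calls)
            lookup_a <- stats::setNames(as.character(d$call), d$gene_id)
            lookup_a <- c(lookup_a,
                          stats::setNames(lookup_a, paste0("A_", names(lookup_a))))
            cds_only <- d$gene_id[d$feature_class == "CDS"]
            stripped <- sub("^A_", "", pairs$gene_a)
            pairs_cds <- pairs[stripped %in% cds_only, , drop = FALSE]
            compareEssentiality(pairs_cds, lookup_a, calls_b)
        })
    }
    cog <- NULL
    if (!is.null(config$functional_annotation)) {
        cog <- .stage("cog", {
            fa <- if (is.character(config$functional_annotation))
                readFunctionalAnnotation(config$functional_annotation)
            else config$functional_annotation
            cogDistribution(fa, calls)
        })
    }

    cs <- callSummary(calls)
    summary <- list(
        n_genes = length(annotation),
        partition = partition,
        fit = list(exp_rate = expRate(essentialityFit(calls)),
                   gamma_shape = gammaShape(essentialityFit(calls)),
                   gamma_scale = gammaScale(essentialityFit(calls)),
                   sections = as.list(sectionCounts(essentialityFit(calls)))),
        calls = list(counts = as.list(cs$counts),
                     percent = as.list(cs$percent),
                     percent_all = as.list(cs$percent_all),
                     denominator = cs$denominator,
                     total = cs$total),
        domain = list(n_flagged = nrow(domain$report)),
        mapping = map_report,
        agreement = if (!is.null(comparison))
            c(comparison$summary, as.list(comparison$counts)) else NULL,
        provenance = list(
            package = as.character(utils::packageVersion("TraDISect")),
            parameters = config[c("primer", "tail", "min_len", "cutoff_low",
                                  "cutoff_high", "threshold_fold", "window",
                                  "step", "max_evalue", "min_cov",
                                  "collapse_strand")]))

    if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        writeCallTable(calls, file.path(config$out_dir, "gene_calls.tsv"))
        utils::write.table(domain$report,
                           file.path(config$out_dir, "domain_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(comparison))
            utils::write.table(comparison$pairs,
                               file.path(config$out_dir, "ortholog_pairs.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(cog))
            utils::write.table(cog, file.path(config$out_dir,
                                              "cog_distribution.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(summary,
                             file.path(config$out_dir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(list(annotation = annotation, sites = sites, stats = stats,
                   calls = calls, domain_report = domain$report,
                   comparison = comparison, cog = cog, summary = summary))
}
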