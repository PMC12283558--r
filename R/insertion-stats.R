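#' Per-gene insertion statistics
#'
#' Counts unique insertion sites per gene and computes the insertion index,
#' unique insertions divided by gene length in bp. A site counts for every
#' gene whose span contains it (overlapping genes each count it); gene spans
#' are taken as annotated, with no 5'/3' trimming.
#'
#' @param sites An \code{\link{InsertionSites}}.
#' @param annotation A \code{\link{GenomeAnnotation}} on the same contigs.
#' @return A data.frame with columns gene_id, feature_class, length_bp,
#'   unique_insertions, insertion_index.
#' @export
geneInsertionStats <- function(sites, annotation) {
    g <- geneRanges(annotation)
    s <- siteRanges(sites)
    unknown <- setdiff(unique(as.character(GenomeInfoDb::seqnames(s))),
                       names(contigLengths(annotation)))
    if (length(unknown))
        stop("sites on contig(s) unknown to the annotation: ",
             paste(unknown, collapse = ", "))
    n <- GenomicRanges::countOverlaps(g, s, ignore.strand = TRUE)
    len <- BiocGenerics::width(g)
    data.frame(gene_id = S4Vectors::mcols(g)$gene_id,
               feature_class = S4Vectors::mcols(g)$feature_class,
               length_bp = len,
               unique_insertions = as.integer(n),
               insertion_index = n / len,
               stringsAsFactors = FALSE)
}

#' Partition unique sites into CDS and intergenic
#'
#' Each unique site is assigned to exactly one category: CDS when it falls
#' inside at least one CDS-class gene, intergenic otherwise. RNA genes and
#' pseudogenes are not CDS for this partition (their sites fall to the
#' intergenic side) even though they receive insertion indices for
#' classification.
#'
#' @param sites An \code{\link{InsertionSites}}.
#' @param annotation A \code{\link{GenomeAnnotation}}.
#' @return A list with cds_sites, intergenic_sites and total_unique_sites;
#'   the first two always sum to the third.
#' @export
partitionSites <- function(sites, annotation) {
    g <- geneRanges(annotation)
    cds <- g[S4Vectors::mcols(g)$feature_class == "CDS"]
    s <- siteRanges(sites)
    in_cds <- IRanges::overlapsAny(s, cds, ignore.strand = TRUE)
    librarySummary(cds_sites = sum(in_cds), intergenic_sites = sum(!in_cds))
}

#' Library partition bookkeeping
#'
#' Assembles the unique-site partition block of the run report from CDS and
#' intergenic site counts; the total is their sum by construction.
#'
#' @param cds_sites Unique sites inside CDS-class genes.
#' @param intergenic_sites Unique sites outside all CDS-class genes.
#' @return A list with cds_sites, intergenic_sites, total_unique_sites.
#' @export
librarySummary <- function(cds_sites, intergenic_sites) {
    list(cds_sites = as.integer(cds_sites),
         intergenic_sites = as.integer(intergenic_sites),
         total_unique_sites = as.integer(cds_sites) + as.integer(intergenic_sites))
}
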