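#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GenomeAnnotation
#'
#' @param gene_id Character vector of unique locus tags.
#' @param contig Character vector of contig names.
#' @param start,end 1-based closed coordinates.
#' @param strand "+" or "-".
#' @param feature_class One of CDS, tRNA, rRNA, other_RNA, pseudogene.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return A \code{GenomeAnnotation}.
#' @export
GenomeAnnotation <- function(gene_id, contig, start, end, strand,
                             feature_class, contig_lengths) {
    if (is.null(names(contig_lengths)))
        stop("contig_lengths must be named by contig")
    si <- GenomeInfoDb::Seqinfo(seqnames = names(contig_lengths),
                                seqlengths = as.integer(contig_lengths))
    gr <- GenomicRanges::GRanges(
        seqnames = contig,
        ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end)),
        strand = strand, seqinfo = si)
    S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
    S4Vectors::mcols(gr)$feature_class <- as.character(feature_class)
    methods::new("GenomeAnnotation", genes = gr)
}

#' @describeIn GenomeAnnotation Gene models as a \code{GRanges}.
#' @param x A \code{GenomeAnnotation}.
#' @export
setMethod("geneRanges", "GenomeAnnotation", function(x) x@genes)

#' @describeIn GenomeAnnotation Named contig lengths.
#' @export
setMethod("contigLengths", "GenomeAnnotation",
          function(x) GenomeInfoDb::seqlengths(x@genes))

#' @describeIn GenomeAnnotation Locus tags.
#' @export
setMethod("geneIds", "GenomeAnnotation",
          function(x) S4Vectors::mcols(x@genes)$gene_id)

setMethod("length", "GenomeAnnotation", function(x) length(x@genes))

setMethod("show", "GenomeAnnotation", function(object) {
    cls <- table(factor(S4Vectors::mcols(object@genes)$feature_class,
                        levels = FEATURE_CLASSES))
    cat("GenomeAnnotation:", length(object@genes), "genes on",
        length(contigLengths(object)), "contig(s)\n")
    cat(" ", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
})

#' Construct an InsertionSites table
#'
#' @param contig Character vector of contig names.
#' @param position 1-based site positions (internal convention; the TSV
#'   readers/writers convert from/to 0-based).
#' @param read_count Reads supporting each site (>= 1).
#' @param contig_lengths Optional named contig lengths.
#' @param strand Per-site strand; defaults to "*" (strand-collapsed).
#' @return An \code{InsertionSites}.
#' @export
InsertionSites <- function(contig = character(), position = integer(),
                           read_count = integer(), contig_lengths = NULL,
                           strand = "*") {
    si <- if (is.null(contig_lengths)) NULL else
        GenomeInfoDb::Seqinfo(seqnames = names(contig_lengths),
                              seqlengths = as.integer(contig_lengths))
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(contig),
        ranges = IRanges::IRanges(start = as.integer(position), width = 1L),
        strand = rep(strand, length.out = length(contig)))
    if (!is.null(si)) {
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(si)
        GenomeInfoDb::seqinfo(gr) <- si
    }
    S4Vectors::mcols(gr)$read_count <- as.integer(read_count)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    methods::new("InsertionSites", sites = gr)
}

#' @describeIn InsertionSites Sites as a width-1 \code{GRanges}.
#' @param x An \code{InsertionSites}.
#' @export
setMethod("siteRanges", "InsertionSites", function(x) x@sites)

#' @describeIn InsertionSites Number of unique sites.
#' @export
setMethod("siteCount", "InsertionSites", function(x) length(x@sites))

#' @describeIn InsertionSites Total supporting reads across sites.
#' @export
setMethod("totalReads", "InsertionSites",
          function(x) sum(S4Vectors::mcols(x@sites)$read_count))

setMethod("show", "InsertionSites", function(object) {
    cat("InsertionSites:", siteCount(object), "unique sites,",
        totalReads(object), "reads\n")
})

EssentialityFit <- function(cutoff_low, cutoff_high, exp_rate, gamma_shape,
                            gamma_scale, n_low, n_high, n_between,
                            zero_inflated = FALSE) {
    methods::new("EssentialityFit",
        cutoff_low = cutoff_low, cutoff_high = cutoff_high,
        exp_rate = exp_rate, gamma_shape = gamma_shape,
        gamma_scale = gamma_scale, n_low = as.integer(n_low),
        n_high = as.integer(n_high), n_between = as.integer(n_between),
        zero_inflated = zero_inflated)
}

#' @rdname fitInsertionModes
#' @param x An \code{EssentialityFit}.
#' @export
setMethod("expRate", "EssentialityFit", function(x) x@exp_rate)

#' @rdname fitInsertionModes
#' @export
setMethod("gammaShape", "EssentialityFit", function(x) x@gamma_shape)

#' @rdname fitInsertionModes
#' @export
setMethod("gammaScale", "EssentialityFit", function(x) x@gamma_scale)

#' @rdname fitInsertionModes
#' @export
setMethod("cutoffs", "EssentialityFit",
          function(x) c(low = x@cutoff_low, high = x@cutoff_high))

#' @rdname fitInsertionModes
#' @export
setMethod("sectionCounts", "EssentialityFit",
          function(x) c(low = x@n_low, between = x@n_between, high = x@n_high))

setMethod("show", "EssentialityFit", function(object) {
    cat("EssentialityFit: exponential rate =", format(object@exp_rate),
        if (object@zero_inflated) "(zero-inflation rule)" else "", "\n")
    cat("  gamma shape =", format(object@gamma_shape),
        " scale =", format(object@gamma_scale), "\n")
    cat("  sections (<=", object@cutoff_low, "/ between / >=",
        object@cutoff_high, "):", object@n_low, "/", object@n_between, "/",
        object@n_high, "\n")
})

#' @rdname callGenome
#' @param x A \code{GeneCallSet}.
#' @export
setMethod("geneCalls", "GeneCallSet", function(x) x@calls)

#' @rdname callGenome
#' @export
setMethod("essentialityFit", "GeneCallSet", function(x) x@fit)

setMethod("length", "GeneCallSet", function(x) nrow(x@calls))

setMethod("show", "GeneCallSet", function(object) {
    s <- callSummary(object)
    cat("GeneCallSet:", s$total, "genes classified",
        sprintf("(threshold log2(%g))\n", object@threshold_fold))
    cat(sprintf("  essential %d (%d%%), non-essential %d (%d%%), unclear %d (%d%%)\n",
        s$counts[["essential"]], s$percent[["essential"]],
        s$counts[["non_essential"]], s$percent[["non_essential"]],
        s$counts[["unclear"]], s$percent[["unclear"]]))
    if (any(object@calls$domain_flag))
        cat("  domain-scan flagged:", sum(object@calls$domain_flag), "genes\n")
})

#' @rdname clusterPresence
#' @param x A \code{PresenceMatrix}.
#' @export
setMethod("presenceValues", "PresenceMatrix", function(x) x@values)

#' @rdname clusterPresence
#' @export
setMethod("presenceLinkage", "PresenceMatrix", function(x) x@row_linkage)

#' @rdname clusterPresence
#' @export
setMethod("proteomeClusters", "PresenceMatrix", function(x) x@clusters)

setMethod("show", "PresenceMatrix", function(object) {
    cat("PresenceMatrix:", nrow(object@values), "proteomes x",
        ncol(object@values), "ortholog groups\n")
    if (length(object@clusters))
        cat("  clustered into", length(unique(object@clusters)), "groups\n")
})
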