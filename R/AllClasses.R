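## Central S4 containers. Coordinates inside the package are 1-based closed
## (GRanges convention); file formats keep their native conventions and are
## converted at the read/write boundary only (GFF3 is 1-based already, the
## site TSV is 0-based).

FEATURE_CLASSES <- c("CDS", "tRNA", "rRNA", "other_RNA", "pseudogene")
CALL_LEVELS <- c("essential", "non_essential", "unclear")

#' Genome annotation for an insertion-library analysis
#'
#' Holds gene models (locus tag, contig, 1-based closed coordinates, strand
#' and one of five feature classes: CDS, tRNA, rRNA, other_RNA, pseudogene)
#' as a \code{GRanges}, together with contig lengths carried in its
#' \code{seqinfo}. Every gene must lie within its contig and locus tags must
#' be unique.
#'
#' @slot genes A \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{feature_class}, and \code{seqlengths} set for every contig.
#' @export
setClass("GenomeAnnotation", representation(genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
    g <- object@genes
    msg <- character()
    mc <- S4Vectors::mcols(g)
    if (!all(c("gene_id", "feature_class") %in% colnames(mc)))
        return("genes must carry 'gene_id' and 'feature_class' metadata columns")
    if (anyDuplicated(mc$gene_id))
        msg <- c(msg, "gene_id values must be unique")
    if (!all(mc$feature_class %in% FEATURE_CLASSES))
        msg <- c(msg, sprintf("feature_class must be one of: %s",
                              paste(FEATURE_CLASSES, collapse = ", ")))
    sl <- GenomeInfoDb::seqlengths(g)
    if (anyNA(sl))
        msg <- c(msg, "every contig must have a known length")
    else if (length(g) && any(BiocGenerics::end(g) >
                              sl[as.character(GenomeInfoDb::seqnames(g))]))
        msg <- c(msg, "gene beyond contig end")
    if (length(g) && any(BiocGenerics::start(g) < 1L))
        msg <- c(msg, "gene start below 1")
    if (length(msg)) msg else TRUE
})

#' Table of unique transposon insertion sites
#'
#' One row per unique insertion site: a width-1 \code{GRanges} with a
#' \code{read_count} metadata column (>= 1). Positions are unique per contig
#' and sorted; strand is \code{*} once sites are collapsed across strands
#' (the default on reading), or +/- when strand collapsing is disabled.
#'
#' @slot sites A width-1, sorted \code{GRanges} with metadata column
#'   \code{read_count}.
#' @export
setClass("InsertionSites", representation(sites = "GRanges"))

setValidity("InsertionSites", function(object) {
    s <- object@sites
    msg <- character()
    if (length(s)) {
        if (!all(BiocGenerics::width(s) == 1L))
            msg <- c(msg, "all sites must have width 1")
        mc <- S4Vectors::mcols(s)
        if (!"read_count" %in% colnames(mc))
            return("sites must carry a 'read_count' metadata column")
        if (any(mc$read_count < 1L))
            msg <- c(msg, "read_count must be >= 1")
        key <- paste(GenomeInfoDb::seqnames(s), BiocGenerics::start(s),
                     BiocGenerics::strand(s))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (contig, position, strand) sites")
        by_contig <- split(BiocGenerics::start(s),
                           as.character(GenomeInfoDb::seqnames(s)))
        if (any(vapply(by_contig, is.unsorted, logical(1))))
            msg <- c(msg, "site positions must be non-decreasing per contig")
    }
    if (length(msg)) msg else TRUE
})

#' Fitted two-mode insertion-index model
#'
#' Parameters of the exponential (essential, low) and gamma (non-essential,
#' high) modes fitted to the bimodal per-gene insertion-index distribution,
#' together with the section cut-offs used to split the fitting data and the
#' number of genes falling in each section.
#'
#' @slot cutoff_low,cutoff_high Section cut-offs on the insertion index
#'   (defaults 0.006 and 0.03).
#' @slot exp_rate Exponential rate (lambda) fitted on the low section.
#' @slot gamma_shape,gamma_scale Gamma parameters (k, theta) fitted on the
#'   high section.
#' @slot n_low,n_high,n_between Genes at or below the low cut-off, at or
#'   above the high cut-off, and strictly between (excluded from fitting
#'   but not from classification).
#' @slot zero_inflated TRUE when the low section was all zeros and the
#'   pseudo-insertion rule set the rate.
#' @export
setClass("EssentialityFit", representation(
    cutoff_low = "numeric", cutoff_high = "numeric",
    exp_rate = "numeric", gamma_shape = "numeric", gamma_scale = "numeric",
    n_low = "integer", n_high = "integer", n_between = "integer",
    zero_inflated = "logical"))

setValidity("EssentialityFit", function(object) {
    msg <- character()
    if (object@cutoff_low >= object@cutoff_high)
        msg <- c(msg, "cutoff_low must be < cutoff_high")
    if (object@exp_rate <= 0) msg <- c(msg, "exp_rate must be > 0")
    if (object@gamma_shape <= 0) msg <- c(msg, "gamma_shape must be > 0")
    if (object@gamma_scale <= 0) msg <- c(msg, "gamma_scale must be > 0")
    if (length(msg)) msg else TRUE
})

#' Per-gene essentiality calls
#'
#' One row per classified gene: insertion statistics, log2 likelihood ratio
#' and the trichotomous call, plus the domain-scan flag, together with the
#' fitted model that produced them.
#'
#' @slot calls A \code{DataFrame} with columns gene_id, feature_class,
#'   length_bp, unique_insertions, insertion_index, llr, call, domain_flag.
#' @slot fit The \code{EssentialityFit} behind the calls.
#' @slot threshold_fold Fold threshold on the likelihood ratio (default 12).
#' @export
setClass("GeneCallSet", representation(
    calls = "DataFrame", fit = "EssentialityFit", threshold_fold = "numeric"))

setValidity("GeneCallSet", function(object) {
    d <- object@calls
    need <- c("gene_id", "feature_class", "length_bp", "unique_insertions",
              "insertion_index", "llr", "call", "domain_flag")
    if (!all(need %in% colnames(d)))
        return(sprintf("calls must have columns: %s", paste(need, collapse = ", ")))
    msg <- character()
    if (anyDuplicated(d$gene_id)) msg <- c(msg, "duplicate gene_id")
    if (!all(d$call %in% CALL_LEVELS))
        msg <- c(msg, "call must be essential / non_essential / unclear")
    if (object@threshold_fold <= 1)
        msg <- c(msg, "threshold_fold must be > 1")
    if (length(msg)) msg else TRUE
})

#' Ortholog-group presence/absence matrix with clustering
#'
#' Binary proteome x ortholog-group matrix for phylogenetic profiling,
#' optionally with complete-linkage Euclidean clustering of the rows (and
#' columns) and a k-cut cluster labelling.
#'
#' @slot values Binary matrix, rows = proteomes, columns = ortholog groups.
#' @slot row_linkage,col_linkage \code{hclust} results (empty list before
#'   \code{clusterPresence} is run; column clustering is optional).
#' @slot clusters Named integer vector mapping proteome to cluster id.
#' @export
setClass("PresenceMatrix", representation(
    values = "matrix", row_linkage = "list", col_linkage = "list",
    clusters = "integer"))

setValidity("PresenceMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (length(v) && !all(v %in% c(0, 1)))
        msg <- c(msg, "values must be binary")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must have row (proteome) and column (group) names")
    if (length(object@clusters) &&
        !all(names(object@clusters) %in% rownames(v)))
        msg <- c(msg, "cluster labels must name proteomes in the matrix")
    if (length(msg)) msg else TRUE
})
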