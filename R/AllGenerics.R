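#' @include AllClasses.R
NULL

#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @export
setGeneric("siteCount", function(x) standardGeneric("siteCount"))

#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @export
setGeneric("expRate", function(x) standardGeneric("expRate"))

#' @export
setGeneric("gammaShape", function(x) standardGeneric("gammaShape"))

#' @export
setGeneric("gammaScale", function(x) standardGeneric("gammaScale"))

#' @export
setGeneric("sectionCounts", function(x) standardGeneric("sectionCounts"))

#' @export
setGeneric("cutoffs", function(x) standardGeneric("cutoffs"))

#' @export
setGeneric("geneCalls", function(x) standardGeneric("geneCalls"))

#' @export
setGeneric("essentialityFit", function(x) standardGeneric("essentialityFit"))

#' @export
setGeneric("callSummary", function(x, ...) standardGeneric("callSummary"))

#' @export
setGeneric("presenceValues", function(x) standardGeneric("presenceValues"))

#' @export
setGeneric("presenceLinkage", function(x) standardGeneric("presenceLinkage"))

#' @export
setGeneric("proteomeClusters", function(x) standardGeneric("proteomeClusters"))
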