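#' Default transposon tag
#'
#' Inverted-repeat primer and transposon tail marking the transposon-genome
#' junction in library reads.
#' @export
TN_PRIMER <- "GTTCGAAATGAGATGTGTATAAGAG"

#' @rdname TN_PRIMER
#' @export
TN_TAIL <- "ACAG"

#' Select and trim transposon-tagged reads
#'
#' A read is retained iff it contains the primer immediately followed by the
#' transposon tail (exact match anywhere in the read); the tag and everything
#' 5' of it are removed and the genomic remainder is kept only when strictly
#' longer than \code{min_len} bases. The first tag occurrence is used when a
#' read carries several.
#'
#' @param reads A \code{DNAStringSet} (or character vector) of raw reads.
#' @param primer Primer sequence 5' of the transposon tail.
#' @param tail Transposon tail ending at the genomic junction.
#' @param min_len Minimum genomic remainder, exclusive bound (default 20:
#'   remainders of exactly 20 bases are discarded).
#' @return A list with \code{reads} (trimmed \code{DNAStringSet}) and
#'   \code{report} (input / tagged / selected / discarded counts).
#' @export
selectTransposonReads <- function(reads, primer = TN_PRIMER, tail = TN_TAIL,
                                  min_len = 20L) {
    if (!nzchar(primer)) stop("empty primer")
    if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
    tag <- paste0(primer, tail)
    n_in <- length(reads)
    if (!n_in) {
        return(list(reads = Biostrings::DNAStringSet(),
                    report = list(input = 0L, tagged = 0L, selected = 0L,
                                  discarded_no_tag = 0L,
                                  discarded_short = 0L)))
    }
    m <- Biostrings::vmatchPattern(tag, reads, fixed = TRUE)
    ends <- Biostrings::endIndex(m)
    first_end <- vapply(ends, function(e) if (length(e)) e[[1]] else NA_integer_,
                        integer(1))
    tagged <- !is.na(first_end)
    widths <- Biostrings::width(reads)
    rem_len <- ifelse(tagged, widths - first_end, 0L)
    keep <- tagged & rem_len > min_len
    trimmed <- Biostrings::subseq(reads[keep], start = first_end[keep] + 1L)
    list(reads = trimmed,
         report = list(input = n_in,
                       tagged = sum(tagged),
                       selected = sum(keep),
                       discarded_no_tag = sum(!tagged),
                       discarded_short = sum(tagged & !keep)))
}
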