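#' Exact-match read mapping for synthetic genomes
#'
#' Desk-scale stand-in for a short-read aligner: each trimmed read is placed
#' at its exact occurrence in the genome (forward or reverse complement).
#' The reported insertion position is the forward-strand coordinate of the
#' read's 5'-most genomic base -- the base adjacent to the transposon
#' junction -- so a reverse-strand read maps to the higher end of its
#' alignment. Reads matching at two or more loci (counting both strands) are
#' dropped and counted as multi-mapped; reads matching nowhere are counted
#' as unmapped. Duplicate reads collapse into one site with a summed read
#' count.
#'
#' @param reads A \code{DNAStringSet} of trimmed genomic reads.
#' @param genome A named \code{DNAStringSet} of contigs.
#' @return A list with \code{sites} (an \code{\link{InsertionSites}} with
#'   contig lengths set) and \code{report} (input / mapped / multimapped /
#'   unmapped / dropped_too_long counts).
#' @export
mapReadsExact <- function(reads, genome) {
    if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
    if (is.null(names(genome))) stop("genome contigs must be named")
    clen <- stats::setNames(Biostrings::width(genome), names(genome))
    n_in <- length(reads)
    too_long <- Biostrings::width(reads) > max(clen)
    if (any(too_long))
        warning(sum(too_long), " read(s) longer than any contig dropped")
    reads <- reads[!too_long]

    tot <- integer(length(reads))
    site_contig <- rep(NA_character_, length(reads))
    site_pos <- rep(NA_integer_, length(reads))

    record <- function(idx, n_hits, pos1, contig) {
        # n_hits/pos1 parallel to idx; pos1 is the junction coordinate of the
        # first hit in this (contig, strand) batch
        tot[idx] <<- tot[idx] + n_hits
        fresh <- is.na(site_contig[idx]) & n_hits >= 1L
        site_contig[idx[fresh]] <<- contig
        site_pos[idx[fresh]] <<- pos1[fresh]
    }

    if (length(reads)) {
        widths <- Biostrings::width(reads)
        for (w in unique(widths)) {
            idx <- which(widths == w)
            pd <- Biostrings::PDict(reads[idx])
            for (ci in seq_along(genome)) {
                contig <- names(genome)[ci]
                subj <- genome[[ci]]
                if (w > clen[[ci]]) next
                fwd <- Biostrings::matchPDict(pd, subj)
                st <- Biostrings::startIndex(fwd)
                nf <- vapply(st, length, integer(1))
                p1 <- vapply(st, function(s)
                    if (length(s)) s[[1]] else NA_integer_, integer(1))
                record(idx, nf, p1, contig)
                rev <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj))
                str <- Biostrings::startIndex(rev)
                nr <- vapply(str, length, integer(1))
                # start s on the reverse complement puts the read's 5' base at
                # forward coordinate L - s + 1
                pr <- vapply(str, function(s)
                    if (length(s)) clen[[ci]] - s[[1]] + 1L else NA_integer_,
                    integer(1))
                record(idx, nr, pr, contig)
            }
        }
    }

    ok <- tot == 1L
    report <- list(input = n_in,
                   mapped = sum(ok),
                   multimapped = sum(tot > 1L),
                   unmapped = sum(tot == 0L),
                   dropped_too_long = sum(too_long))
    if (!any(ok)) {
        return(list(sites = InsertionSites(contig_lengths = clen),
                    report = report))
    }
    key <- paste(site_contig[ok], site_pos[ok])
    cnt <- rowsum(rep(1L, sum(ok)), key, reorder = FALSE)
    first <- !duplicated(key)
    sites <- InsertionSites(
        contig = site_contig[ok][first],
        position = site_pos[ok][first],
        read_count = cnt[match(key[first], rownames(cnt)), 1],
        contig_lengths = clen)
    list(sites = sites, report = report)
}
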