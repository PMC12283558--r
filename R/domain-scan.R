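## Sliding-window interrogation of non-essential and unclear genes for
## insertion-free stretches: a tolerant gene hiding an indispensable core
## (tolerant termini, essential domain) shows a window with zero insertions.

.windowOffsets <- function(len, window = 300L, step = 150L,
                           terminal_window = TRUE) {
    if (window <= 0L) stop("window must be > 0")
    if (step <= 0L || step > window) stop("step must satisfy 0 < step <= window")
    if (len < window) {
        if (!terminal_window)  # strict reading: no full window fits
            return(data.frame(offset_bp = integer(), span_bp = integer()))
        return(data.frame(offset_bp = 0L, span_bp = as.integer(len)))
    }
    offs <- seq.int(0L, len - window, by = step)
    if (terminal_window && offs[length(offs)] + window < len)
        offs <- c(offs, len - window)
    data.frame(offset_bp = as.integer(offs),
               span_bp = rep(as.integer(window), length(offs)))
}

.windowCounts <- function(rel_pos, offsets) {
    p <- sort(as.integer(rel_pos))
    below <- function(x) findInterval(x - 0.5, p)
    below(offsets$offset_bp + offsets$span_bp) - below(offsets$offset_bp)
}

#' Sliding-window scan of one gene for insertion-free windows
#'
#' Windows of \code{window} bp are placed at gene-relative offsets 0, step,
#' 2*step, ... while they fit inside the gene; when the gene length is not
#' step-aligned one final window is anchored at the 3' end so the whole gene
#' is covered, and a gene shorter than the window gets a single window
#' spanning it entirely (both behaviours switchable via
#' \code{terminal_window}). A window is essential when it contains no
#' insertion site; the gene is flagged when any window is.
#'
#' @param annotation A \code{\link{GenomeAnnotation}}.
#' @param gene_id Locus tag of the gene to scan.
#' @param sites An \code{\link{InsertionSites}}.
#' @param window Window span in bp (default 300).
#' @param step Stride in bp (default 150).
#' @param terminal_window Place the 3'-anchored terminal window and the
#'   whole-gene window for short genes (default TRUE; FALSE reproduces a
#'   strict full-windows-only scan).
#' @return A list with gene_id, windows (data.frame offset_bp, span_bp,
#'   insertion_count, essential_window) and flagged.
#' @export
scanGene <- function(annotation, gene_id, sites, window = 300L, step = 150L,
                     terminal_window = TRUE) {
    g <- geneRanges(annotation)
    i <- match(gene_id, S4Vectors::mcols(g)$gene_id)
    if (is.na(i)) stop("unknown gene: ", gene_id)
    gene <- g[i]
    s <- siteRanges(sites)
    hit <- s[IRanges::overlapsAny(s, gene, ignore.strand = TRUE)]
    rel <- BiocGenerics::start(hit) - BiocGenerics::start(gene)
    win <- .windowOffsets(BiocGenerics::width(gene), window, step,
                          terminal_window)
    win$insertion_count <- .windowCounts(rel, win)
    win$essential_window <- win$insertion_count == 0L
    list(gene_id = gene_id, windows = win, flagged = any(win$essential_window))
}

#' Essential-domain correction of gene calls
#'
#' Scans every gene currently called non-essential or unclear with the
#' sliding window; genes with at least one insertion-free window get their
#' domain flag set and (by default) their call promoted to essential, since
#' an insertion-free core inside a tolerant gene indicates an indispensable
#' domain missed by the whole-gene index. Genes already called essential
#' are never scanned.
#'
#' @param calls A \code{\link{GeneCallSet}}.
#' @param annotation A \code{\link{GenomeAnnotation}}.
#' @param sites An \code{\link{InsertionSites}}.
#' @param window,step,terminal_window Passed to the window scan.
#' @param promote Promote flagged genes to essential (default TRUE; FALSE
#'   gives a report-only run with calls untouched).
#' @param scope Calls eligible for scanning.
#' @return A list with calls (updated \code{GeneCallSet}) and report (a
#'   data.frame of flagged genes: gene_id, call_before, n_windows,
#'   n_zero_windows, first_zero_offset).
#' @export
domainCorrection <- function(calls, annotation, sites, window = 300L,
                             step = 150L, terminal_window = TRUE,
                             promote = TRUE,
                             scope = c("non_essential", "unclear")) {
    d <- geneCalls(calls)
    g <- geneRanges(annotation)
    idx <- which(d$call %in% scope)
    rep_rows <- list()
    flagged <- logical(nrow(d))
    if (length(idx)) {
        gi <- match(d$gene_id[idx], S4Vectors::mcols(g)$gene_id)
        if (anyNA(gi))
            stop("calls contain genes absent from the annotation")
        s <- siteRanges(sites)
        ov <- GenomicRanges::findOverlaps(g[gi], s, ignore.strand = TRUE)
        rel_by_gene <- split(
            BiocGenerics::start(s)[S4Vectors::subjectHits(ov)] -
                BiocGenerics::start(g[gi])[S4Vectors::queryHits(ov)],
            factor(S4Vectors::queryHits(ov), levels = seq_along(idx)))
        for (k in seq_along(idx)) {
            len <- BiocGenerics::width(g[gi[k]])
            win <- .windowOffsets(len, window, step, terminal_window)
            cnt <- .windowCounts(rel_by_gene[[k]], win)
            if (any(cnt == 0L)) {
                flagged[idx[k]] <- TRUE
                rep_rows[[length(rep_rows) + 1L]] <- data.frame(
                    gene_id = d$gene_id[idx[k]],
                    call_before = d$call[idx[k]],
                    n_windows = nrow(win),
                    n_zero_windows = sum(cnt == 0L),
                    first_zero_offset = win$offset_bp[which(cnt == 0L)[1]],
                    stringsAsFactors = FALSE)
            }
        }
    }
    d$domain_flag <- flagged
    if (promote) d$call[flagged] <- "essential"
    report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
        data.frame(gene_id = character(), call_before = character(),
                   n_windows = integer(), n_zero_windows = integer(),
                   first_zero_offset = integer(), stringsAsFactors = FALSE)
    calls@calls <- d
    list(calls = calls, report = report)
}
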