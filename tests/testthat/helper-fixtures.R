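# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use plain loops / per-base bookkeeping, not the package's vectorised code.

toy_annotation <- function() {
    GenomeAnnotation(
        gene_id = c("gA", "gB", "gC", "gT"),
        contig = "c1",
        start = c(101, 181, 401, 701),   # gA and gB overlap (181..200)
        end = c(200, 300, 600, 760),
        strand = c("+", "-", "+", "+"),
        feature_class = c("CDS", "CDS", "CDS", "tRNA"),
        contig_lengths = c(c1 = 1000L))
}

toy_sites <- function(pos, counts = NULL, contig = "c1", len = 1000L) {
    if (is.null(counts)) counts <- rep(1L, length(pos))
    InsertionSites(contig = rep(contig, length(pos)), position = pos,
                   read_count = counts,
                   contig_lengths = stats::setNames(len, contig))
}

# per-base brute force for the window scan: place windows by explicit loop,
# count insertions through a base-presence vector
bf_window_flag <- function(len, rel_pos, window = 300L, step = 150L,
                           terminal_window = TRUE) {
    present <- logical(len)
    present[rel_pos + 1L] <- TRUE
    offs <- integer()
    o <- 0L
    while (o + window <= len) {
        offs <- c(offs, o)
        o <- o + step
    }
    if (len < window) {
        if (terminal_window) return(sum(present) == 0L)
        return(FALSE)
    }
    if (terminal_window && length(offs) && offs[length(offs)] + window < len)
        offs <- c(offs, len - window)
    for (o in offs) {
        if (sum(present[(o + 1L):(o + window)]) == 0L) return(TRUE)
    }
    FALSE
}

# exhaustive reciprocal-best-hit oracle: filter, pick best and pair by
# explicit row scans with the documented tie-break
bf_filter <- function(h, max_e = 1e-5, min_q = 70, min_s = 70) {
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
        qc <- (h$q_end[i] - h$q_start[i] + 1) / h$q_len[i] * 100
        sc <- (h$s_end[i] - h$s_start[i] + 1) / h$s_len[i] * 100
        keep[i] <- h$evalue[i] <= max_e && qc >= min_q && sc >= min_s &&
            h$query_id[i] != h$subject_id[i]
    }
    h[keep, , drop = FALSE]
}

bf_best <- function(h) {
    out <- list()
    for (q in unique(h$query_id)) {
        rows <- h[h$query_id == q, , drop = FALSE]
        best <- rows[1, ]
        for (i in seq_len(nrow(rows))[-1]) {
            r <- rows[i, ]
            better <- r$bitscore > best$bitscore ||
                (r$bitscore == best$bitscore && r$evalue < best$evalue) ||
                (r$bitscore == best$bitscore && r$evalue == best$evalue &&
                     r$percent_identity > best$percent_identity) ||
                (r$bitscore == best$bitscore && r$evalue == best$evalue &&
                     r$percent_identity == best$percent_identity &&
                     r$subject_id < best$subject_id)
            if (better) best <- r
        }
        out[[q]] <- best$subject_id
    }
    out
}

bf_pairs <- function(best_ab, best_ba) {
    pairs <- character()
    for (a in names(best_ab)) {
        b <- best_ab[[a]]
        if (!is.null(best_ba[[b]]) && best_ba[[b]] == a)
            pairs <- c(pairs, paste(a, b))
    }
    sort(pairs)
}

random_hit_table <- function(n_a = 10L, n_b = 10L, n_hits = 40L) {
    qa <- sprintf("A%02d", sample.int(n_a, n_hits, replace = TRUE))
    sb <- sprintf("B%02d", sample.int(n_b, n_hits, replace = TRUE))
    qlen <- sample(100:500, n_hits, replace = TRUE)
    slen <- sample(100:500, n_hits, replace = TRUE)
    # coarse grids force ties so the tie-break is exercised
    data.frame(query_id = qa, subject_id = sb,
               percent_identity = sample(seq(40, 100, by = 20), n_hits,
                                         replace = TRUE),
               aln_length = qlen, mismatches = 0L, gap_opens = 0L,
               q_start = 1L, q_end = pmax(1L, round(qlen *
                   sample(c(0.5, 0.69, 0.7, 1), n_hits, replace = TRUE))),
               s_start = 1L, s_end = pmax(1L, round(slen *
                   sample(c(0.5, 0.7, 1), n_hits, replace = TRUE))),
               evalue = sample(c(0, 1e-50, 1e-10, 1e-6, 1e-4), n_hits,
                               replace = TRUE),
               bitscore = sample(seq(100, 400, by = 100), n_hits,
                                 replace = TRUE),
               q_len = qlen, s_len = slen, stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
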