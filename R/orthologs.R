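## Reciprocal-best-hit orthology with the comparison's filter chain:
## E-value and two-sided coverage cut-offs, best-hit selection with a
## deterministic tie-break, reciprocity, paralog exclusion, and the join to
## per-species essentiality calls.

#' Filter tabular hits on E-value and coverage
#'
#' Keeps hits with evalue <= max_evalue and both query and subject coverage
#' at least the thresholds (inclusive), where coverage is
#' (end - start + 1) / length x 100 from the single reported HSP.
#' Self-hits (query_id == subject_id) are dropped.
#'
#' @param hits Data.frame from \code{\link{readHits}}.
#' @param max_evalue E-value cut-off (default 1e-5).
#' @param min_qcov,min_scov Minimum query/subject coverage in percent
#'   (default 70).
#' @return The filtered data.frame.
#' @export
filterHits <- function(hits, max_evalue = 1e-5, min_qcov = 70,
                       min_scov = 70) {
    if (!nrow(hits)) return(hits)
    qcov <- (hits$q_end - hits$q_start + 1) / hits$q_len * 100
    scov <- (hits$s_end - hits$s_start + 1) / hits$s_len * 100
    keep <- hits$evalue <= max_evalue & qcov >= min_qcov & scov >= min_scov &
        hits$query_id != hits$subject_id
    hits[keep, , drop = FALSE]
}

#' Best hit per query
#'
#' The subject with the highest bitscore per query; ties broken by lowest
#' E-value, then highest percent identity, then lexicographically smallest
#' subject id, so the choice is deterministic.
#'
#' @param hits Filtered hits of one direction.
#' @return Data.frame with columns query_id, subject_id, bitscore.
#' @export
bestHits <- function(hits) {
    if (!nrow(hits))
        return(data.frame(query_id = character(), subject_id = character(),
                          bitscore = numeric(), stringsAsFactors = FALSE))
    o <- order(hits$query_id, -hits$bitscore, hits$evalue,
               -hits$percent_identity, hits$subject_id)
    h <- hits[o, , drop = FALSE]
    first <- !duplicated(h$query_id)
    data.frame(query_id = h$query_id[first], subject_id = h$subject_id[first],
               bitscore = h$bitscore[first], stringsAsFactors = FALSE)
}

#' Reciprocal best-hit pairs
#'
#' A pair (a, b) is emitted iff a's best hit in the other proteome is b and
#' b's best hit is a, both directions drawn from the same filtered universe.
#'
#' @param best_ab,best_ba Best-hit maps from \code{\link{bestHits}} for the
#'   A->B and B->A directions.
#' @return Data.frame with columns gene_a, gene_b, bitscore_ab, bitscore_ba.
#' @export
reciprocalPairs <- function(best_ab, best_ba) {
    if (!nrow(best_ab) || !nrow(best_ba))
        return(data.frame(gene_a = character(), gene_b = character(),
                          bitscore_ab = numeric(), bitscore_ba = numeric(),
                          stringsAsFactors = FALSE))
    back <- best_ba$subject_id[match(best_ab$subject_id, best_ba$query_id)]
    keep <- !is.na(back) & back == best_ab$query_id
    out <- data.frame(
        gene_a = best_ab$query_id[keep],
        gene_b = best_ab$subject_id[keep],
        bitscore_ab = best_ab$bitscore[keep],
        bitscore_ba = best_ba$bitscore[match(best_ab$subject_id[keep],
                                             best_ba$query_id)],
        stringsAsFactors = FALSE)
    out[order(out$gene_a), , drop = FALSE]
}

#' Remove pairs involving paralogous proteins
#'
#' A protein is paralogous when it appears in any non-self within-proteome
#' hit passing the same E-value/coverage filters (as query or subject, since
#' a within-proteome comparison is nominally symmetric). Any pair touching a
#' paralogous protein is removed: a paralog could complement its disrupted
#' copy and confound the essentiality comparison.
#'
#' @param pairs Data.frame from \code{\link{reciprocalPairs}}.
#' @param self_hits_a,self_hits_b Within-proteome all-vs-all hit tables.
#' @param max_evalue,min_qcov,min_scov Filter thresholds, matching the
#'   cross-proteome filtering.
#' @return The pairs data.frame without pairs touching paralogs.
#' @export
excludeParalogs <- function(pairs, self_hits_a, self_hits_b,
                            max_evalue = 1e-5, min_qcov = 70, min_scov = 70) {
    paralogs <- function(self_hits) {
        f <- filterHits(self_hits, max_evalue, min_qcov, min_scov)
        unique(c(f$query_id, f$subject_id))
    }
    pa <- paralogs(self_hits_a)
    pb <- paralogs(self_hits_b)
    pairs[!(pairs$gene_a %in% pa | pairs$gene_b %in% pb), , drop = FALSE]
}

#' Agreement bookkeeping for an ortholog comparison
#'
#' Assembles the agreement block of the comparison report from the per-pair
#' category counts. Agreement = pairs with the same call in both species;
#' the percentage is rounded to the nearest integer; mismatches are the
#' remainder.
#'
#' @param agree_essential,agree_non_essential,agree_unclear Pairs with the
#'   same call in both species.
#' @param n_pairs Total ortholog pairs compared.
#' @return A list with n_pairs, agree, percent_agree and mismatch.
#' @export
agreementSummary <- function(agree_essential, agree_non_essential,
                             agree_unclear, n_pairs) {
    agree <- agree_essential + agree_non_essential + agree_unclear
    stopifnot(agree <= n_pairs)
    list(n_pairs = as.integer(n_pairs),
         agree = as.integer(agree),
         percent_agree = as.integer(round(agree / n_pairs * 100)),
         mismatch = as.integer(n_pairs - agree))
}

#' Join ortholog pairs to two species' essentiality calls
#'
#' Each pair is assigned an agreement category from its two calls: agreement
#' in essential / non-essential / unclear, or a mismatch (essential vs
#' non-essential in either orientation, or any pair where exactly one side
#' is unclear).
#'
#' @param pairs Data.frame from \code{\link{reciprocalPairs}} (possibly
#'   after \code{\link{excludeParalogs}}).
#' @param calls_a,calls_b Per-species calls: a \code{\link{GeneCallSet}}, a
#'   data.frame with gene_id and call, or a named character vector.
#' @return A list with pairs (the input plus call_a, call_b, category),
#'   counts (named per-category) and summary (from
#'   \code{\link{agreementSummary}}).
#' @export
compareEssentiality <- function(pairs, calls_a, calls_b) {
    as_map <- function(x) {
        if (methods::is(x, "GeneCallSet")) {
            d <- geneCalls(x)
            stats::setNames(as.character(d$call), d$gene_id)
        } else if (is.data.frame(x)) {
            stats::setNames(as.character(x$call), x$gene_id)
        } else x
    }
    ma <- as_map(calls_a)
    mb <- as_map(calls_b)
    call_a <- unname(ma[pairs$gene_a])
    call_b <- unname(mb[pairs$gene_b])
    if (anyNA(call_a))
        stop("no call for gene(s): ",
             paste(utils::head(pairs$gene_a[is.na(call_a)]), collapse = ", "))
    if (anyNA(call_b))
        stop("no call for gene(s): ",
             paste(utils::head(pairs$gene_b[is.na(call_b)]), collapse = ", "))
    category <- ifelse(call_a == call_b,
        paste0("agree_", call_a),
        ifelse(call_a == "unclear" | call_b == "unclear", "mismatch_unclear",
            ifelse(call_a == "essential", "mismatch_ess_a_non_b",
                   "mismatch_non_a_ess_b")))
    levels <- c("agree_essential", "agree_non_essential", "agree_unclear",
                "mismatch_ess_a_non_b", "mismatch_non_a_ess_b",
                "mismatch_unclear")
    counts <- table(factor(category, levels = levels))
    counts <- stats::setNames(as.integer(counts), levels)
    out_pairs <- cbind(pairs,
                       data.frame(call_a = call_a, call_b = call_b,
                                  category = category,
                                  stringsAsFactors = FALSE))
    list(pairs = out_pairs, counts = counts,
         summary = agreementSummary(counts[["agree_essential"]],
                                    counts[["agree_non_essential"]],
                                    counts[["agree_unclear"]],
                                    nrow(pairs)))
}
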