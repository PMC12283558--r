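## Functional profiling: COG-category essentiality distributions and the
## ortholog-group presence/absence matrix with complete-linkage clustering.

#' COG-category essentiality distribution
#'
#' Multi-letter COG labels are split into single letters and each letter
#' counts separately, so a gene with m labels contributes m label counts.
#' Genes with an empty label or no ortholog-group assignment are counted
#' under the pseudo-label "unannotated". Annotation rows for genes absent
#' from the call table are skipped with a warning.
#'
#' @param annotation_rows Data.frame from
#'   \code{\link{readFunctionalAnnotation}}.
#' @param calls A \code{\link{GeneCallSet}}, data.frame with gene_id/call,
#'   or named character vector.
#' @return A data.frame with columns cog_label, call, count; for a given
#'   call the counts sum to the total labels carried by genes with that
#'   call.
#' @export
cogDistribution <- function(annotation_rows, calls) {
    map <- if (methods::is(calls, "GeneCallSet")) {
        d <- geneCalls(calls)
        stats::setNames(as.character(d$call), d$gene_id)
    } else if (is.data.frame(calls)) {
        stats::setNames(as.character(calls$call), calls$gene_id)
    } else calls
    known <- annotation_rows$gene_id %in% names(map)
    if (any(!known)) {
        warning("skipping ", sum(!known),
                " annotation row(s) for genes without a call")
        annotation_rows <- annotation_rows[known, , drop = FALSE]
    }
    if (!nrow(annotation_rows))
        return(data.frame(cog_label = character(), call = character(),
                          count = integer(), stringsAsFactors = FALSE))
    labels <- ifelse(annotation_rows$cog_labels == "" |
                         annotation_rows$og_ids == "",
                     "unannotated", annotation_rows$cog_labels)
    split_labels <- strsplit(labels, "")
    split_labels[labels == "unannotated"] <- list("unannotated")
    gene_rep <- rep(annotation_rows$gene_id, lengths(split_labels))
    lab <- unlist(split_labels, use.names = FALSE)
    tab <- table(cog_label = lab, call = unname(map[gene_rep]))
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out)[3] <- "count"
    out$count <- as.integer(out$count)
    out <- out[out$count > 0L, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build an ortholog-group presence/absence matrix
#'
#' One row per proteome, one column per group of the given universe; a cell
#' is 1 when the group occurs at least once in the proteome's annotation
#' (repeated occurrences still count as presence) and 0 otherwise. Groups
#' absent from every proteome keep their all-zero column.
#'
#' @param annotation_list Named list (one entry per proteome) of data.frames
#'   with an og_ids column (comma-separated group ids per gene).
#' @param group_universe Character vector of ortholog-group ids (columns).
#' @return A \code{\link{PresenceMatrix}} (not yet clustered).
#' @export
buildPresenceMatrix <- function(annotation_list, group_universe) {
    if (length(annotation_list) < 2L)
        stop("need at least 2 proteomes")
    if (!length(group_universe)) stop("empty group universe")
    if (is.null(names(annotation_list)))
        stop("annotation_list must be named by proteome")
    values <- matrix(0, nrow = length(annotation_list),
                     ncol = length(group_universe),
                     dimnames = list(names(annotation_list), group_universe))
    for (p in names(annotation_list)) {
        og <- annotation_list[[p]]$og_ids
        og <- og[!is.na(og) & og != ""]
        present <- unique(unlist(strsplit(og, ",", fixed = TRUE)))
        present <- trimws(present)
        if (!length(present))
            warning("proteome ", p, " has no group annotations; all-zero row")
        values[p, intersect(present, group_universe)] <- 1
    }
    methods::new("PresenceMatrix", values = values, row_linkage = list(),
                 col_linkage = list(), clusters = integer())
}

#' Cluster a presence/absence matrix
#'
#' Complete-linkage agglomeration on Euclidean distances between proteome
#' rows of the raw 0/1 values (no scaling), cut into k clusters. Columns are
#' clustered the same way by default, mirroring a standard clustered
#' heatmap; identical rows merge at height 0 before anything else.
#'
#' @param x A \code{\link{PresenceMatrix}}.
#' @param k Number of row clusters (1 <= k <= number of proteomes), chosen
#'   by inspection of the dendrogram.
#' @param cluster_columns Also cluster columns (default TRUE).
#' @return The \code{PresenceMatrix} with linkage and cluster labels filled.
#' @export
clusterPresence <- function(x, k, cluster_columns = TRUE) {
    v <- presenceValues(x)
    if (k < 1L || k > nrow(v)) stop("k out of range")
    hc <- stats::hclust(stats::dist(v, method = "euclidean"),
                        method = "complete")
    x@row_linkage <- unclass(hc)
    x@clusters <- stats::cutree(hc, k = k)
    if (cluster_columns && ncol(v) > 1L) {
        x@col_linkage <- unclass(stats::hclust(
            stats::dist(t(v), method = "euclidean"), method = "complete"))
    }
    x
}

.as_hclust <- function(lst) structure(lst, class = "hclust")

#' Export a clustered presence matrix
#'
#' Writes the matrix as TSV with rows and columns in dendrogram order
#' (cluster label appended per row) and optionally renders a heatmap through
#' pheatmap when that package is available.
#'
#' @param x A clustered \code{\link{PresenceMatrix}}.
#' @param matrix_path Path for the ordered TSV.
#' @param heatmap_path Optional path for a PNG heatmap.
#' @return \code{matrix_path}, invisibly.
#' @export
exportPresence <- function(x, matrix_path, heatmap_path = NULL) {
    v <- presenceValues(x)
    ro <- if (length(x@row_linkage)) .as_hclust(x@row_linkage)$order
          else seq_len(nrow(v))
    co <- if (length(x@col_linkage)) .as_hclust(x@col_linkage)$order
          else seq_len(ncol(v))
    ord <- v[ro, co, drop = FALSE]
    cl <- if (length(x@clusters)) x@clusters[rownames(ord)] else
        rep(NA_integer_, nrow(ord))
    con <- file(matrix_path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("#proteome\tcluster\t",
                      paste(colnames(ord), collapse = "\t")), con)
    utils::write.table(data.frame(proteome = rownames(ord), cluster = cl,
                                  ord, check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    if (!is.null(heatmap_path) &&
        requireNamespace("pheatmap", quietly = TRUE)) {
        grDevices::png(heatmap_path, width = 1200, height = 800)
        pheatmap::pheatmap(v, clustering_method = "complete",
                           clustering_distance_rows = "euclidean",
                           clustering_distance_cols = "euclidean",
                           cluster_cols = length(x@col_linkage) > 0)
        grDevices::dev.off()
    }
    invisible(matrix_path)
}
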