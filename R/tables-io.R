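## Tab-separated table boundary: insertion-site tables (0-based positions on
## disk, 1-based in memory), 14-column BLAST-style hit tables, emapper-style
## functional annotation, and per-gene call tables. All writers emit UTF-8
## TSV with a single header line prefixed "#".

.read_tsv_hash_header <- function(path, required) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    hdr_i <- which(!startsWith(lines, "##"))[1]
    if (is.na(hdr_i)) stop("no header line in ", path)
    header <- sub("^#", "", lines[hdr_i])
    cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
    body <- lines[-seq_len(hdr_i)]
    body <- body[!startsWith(body, "#")]
    if (!all(required %in% cols))
        stop("missing column(s) in ", path, ": ",
             paste(setdiff(required, cols), collapse = ", "))
    if (!length(body)) {
        df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                            cols))
        return(df)
    }
    df <- utils::read.delim(text = body, header = FALSE, sep = "\t",
                            quote = "", stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) != length(cols))
        stop("column-count mismatch in ", path)
    names(df) <- cols
    df
}

#' Read an insertion-site table
#'
#' Reads a TSV with columns contig, position (0-based), strand, read_count.
#' By default rows at the same (contig, position) are merged across strands
#' by summing read counts, matching a duplicate-removal protocol that
#' collapses by position only; set \code{collapse_strand = FALSE} to keep
#' strands distinct.
#'
#' @param path Path to the TSV (header line may be prefixed "#").
#' @param collapse_strand Merge sites across strands (default TRUE).
#' @param contig_lengths Optional named contig lengths for the result.
#' @return An \code{\link{InsertionSites}}.
#' @export
readSiteTable <- function(path, collapse_strand = TRUE, contig_lengths = NULL) {
    df <- .read_tsv_hash_header(path, c("contig", "position", "strand",
                                        "read_count"))
    pos <- as.integer(df$position)
    cnt <- as.integer(df$read_count)
    if (any(pos < 0L)) stop("negative position in site table")
    if (!nrow(df))
        return(InsertionSites(contig_lengths = contig_lengths))
    if (collapse_strand) {
        key <- paste(df$contig, pos)
        agg <- rowsum(cnt, key, reorder = FALSE)
        first <- !duplicated(key)
        InsertionSites(contig = df$contig[first], position = pos[first] + 1L,
                       read_count = agg[match(key[first], rownames(agg)), 1],
                       contig_lengths = contig_lengths)
    } else {
        InsertionSites(contig = df$contig, position = pos + 1L,
                       read_count = cnt, contig_lengths = contig_lengths,
                       strand = df$strand)
    }
}

#' Write an insertion-site table
#'
#' Positions are written 0-based; strand-collapsed sites are written as "*".
#'
#' @param sites An \code{\link{InsertionSites}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
    s <- siteRanges(sites)
    rows <- sprintf("%s\t%d\t%s\t%d",
        as.character(GenomeInfoDb::seqnames(s)),
        BiocGenerics::start(s) - 1L,
        as.character(BiocGenerics::strand(s)),
        S4Vectors::mcols(s)$read_count)
    writeLines(c("#contig\tposition\tstrand\tread_count", rows), path)
    invisible(path)
}

.HIT_COLS <- c("query_id", "subject_id", "percent_identity", "aln_length",
               "mismatches", "gap_opens", "q_start", "q_end", "s_start",
               "s_end", "evalue", "bitscore", "q_len", "s_len")
.HIT_NUM <- setdiff(.HIT_COLS, c("query_id", "subject_id"))

#' Read a 14-column tabular hit file
#'
#' Standard 12-column BLAST tabular output (outfmt 6) extended with qlen and
#' slen, as produced with \code{-outfmt "6 std qlen slen"}. Lines prefixed
#' "#" are ignored; any data line with a field count other than 14 raises an
#' error naming the offending line.
#'
#' @param path Path to the tabular file.
#' @return A data.frame with columns query_id, subject_id, percent_identity,
#'   aln_length, mismatches, gap_opens, q_start, q_end, s_start, s_end,
#'   evalue, bitscore, q_len, s_len.
#' @export
readHits <- function(path) {
    lines <- readLines(path)
    keep <- nzchar(lines) & !startsWith(lines, "#")
    body <- lines[keep]
    if (!length(body)) {
        df <- as.data.frame(stats::setNames(rep(list(character()), 14), .HIT_COLS))
        for (cn in .HIT_NUM) df[[cn]] <- numeric()
        return(df)
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 14L))
        stop("line ", which(keep)[which(nf != 14L)[1]],
             ": expected 14 tab-separated fields, found ", nf[nf != 14L][1])
    df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
    names(df) <- .HIT_COLS
    for (cn in .HIT_NUM) df[[cn]] <- as.numeric(df[[cn]])
    for (cn in c("aln_length", "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "q_len", "s_len"))
        df[[cn]] <- as.integer(df[[cn]])
    if (any(df$q_len <= 0L) || any(df$s_len <= 0L))
        stop("q_len and s_len must be positive")
    df
}

#' Write a 14-column tabular hit file
#'
#' @param hits A data.frame as returned by \code{\link{readHits}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeHits <- function(hits, path) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("#", paste(.HIT_COLS, collapse = "\t")), con)
    if (nrow(hits)) {
        h <- hits[, .HIT_COLS]
        h$evalue <- format(h$evalue, digits = 15, scientific = TRUE, trim = TRUE)
        utils::write.table(h, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Read an emapper-style functional annotation table
#'
#' Accepts either this package's own three-column format (gene_id,
#' cog_labels, og_ids) or eggNOG-mapper output (columns \code{#query},
#' \code{COG_category}, \code{eggNOG_OGs}); "##" comment lines are skipped
#' and the first remaining line is taken as the header. A "-" in the COG or
#' OG column means no assignment.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns gene_id, cog_labels (string of
#'   single-letter categories, possibly empty) and og_ids (comma-separated,
#'   possibly empty).
#' @export
readFunctionalAnnotation <- function(path) {
    df <- .read_tsv_hash_header(path, character())
    cols <- names(df)
    pick <- function(cands) {
        hit <- intersect(cands, cols)
        if (!length(hit)) stop("cannot find column (tried: ",
                               paste(cands, collapse = ", "), ") in ", path)
        hit[1]
    }
    gene <- pick(c("gene_id", "query", "X.query"))
    cog <- pick(c("cog_labels", "COG_category"))
    og <- pick(c("og_ids", "eggNOG_OGs"))
    out <- data.frame(gene_id = df[[gene]],
                      cog_labels = df[[cog]],
                      og_ids = df[[og]],
                      stringsAsFactors = FALSE)
    out$cog_labels[out$cog_labels %in% c("-", "NA")] <- ""
    out$og_ids[out$og_ids %in% c("-", "NA")] <- ""
    bad <- grepl("[^A-Z]", out$cog_labels)
    if (any(bad))
        stop("cog_labels must contain only letters A-Z: ",
             paste(utils::head(out$cog_labels[bad]), collapse = ", "))
    out
}

#' Write a functional annotation table
#'
#' @param rows A data.frame with columns gene_id, cog_labels, og_ids.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFunctionalAnnotation <- function(rows, path) {
    cl <- ifelse(rows$cog_labels == "", "-", rows$cog_labels)
    og <- ifelse(rows$og_ids == "", "-", rows$og_ids)
    writeLines(c("#gene_id\tcog_labels\tog_ids",
                 sprintf("%s\t%s\t%s", rows$gene_id, cl, og)), path)
    invisible(path)
}

#' Read / write per-gene essentiality call tables
#'
#' The TSV carries gene_id, feature_class, length_bp, unique_insertions,
#' insertion_index, llr, call and domain_flag.
#'
#' @param path Path to the TSV.
#' @return \code{readCallTable}: a data.frame of per-gene calls.
#' @export
readCallTable <- function(path) {
    df <- .read_tsv_hash_header(path, c("gene_id", "call"))
    for (cn in intersect(c("length_bp", "unique_insertions"), names(df)))
        df[[cn]] <- as.integer(df[[cn]])
    for (cn in intersect(c("insertion_index", "llr"), names(df)))
        df[[cn]] <- as.numeric(df[[cn]])
    if ("domain_flag" %in% names(df))
        df$domain_flag <- as.logical(df$domain_flag)
    df
}

#' @rdname readCallTable
#' @param calls A \code{\link{GeneCallSet}} or a data.frame of calls.
#' @export
writeCallTable <- function(calls, path) {
    d <- if (methods::is(calls, "GeneCallSet")) as.data.frame(geneCalls(calls))
         else as.data.frame(calls)
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("#", paste(names(d), collapse = "\t")), con)
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Read / write FASTQ reads
#'
#' Thin wrappers around Biostrings' FASTQ support; qualities are not used by
#' the tag-selection or mapping logic, and \code{writeFastqReads} emits a
#' constant quality.
#'
#' @param path Path to a FASTQ file.
#' @return \code{readFastqReads}: a named \code{DNAStringSet}.
#' @export
readFastqReads <- function(path) {
    Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @rdname readFastqReads
#' @param reads A \code{DNAStringSet}.
#' @export
writeFastqReads <- function(reads, path) {
    if (is.null(names(reads)))
        names(reads) <- sprintf("read_%06d", seq_along(reads))
    quals <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
        function(w) strrep("I", w), character(1)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals)
    invisible(path)
}
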