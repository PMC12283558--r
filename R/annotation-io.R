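## GFF3 / FASTA boundary. GFF3 feature types are mapped onto the five
## internal feature classes; unknown types are skipped with a warning.

.GFF_TYPE_MAP <- c(
    CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
    tmRNA = "other_RNA", ncRNA = "other_RNA", SRP_RNA = "other_RNA",
    RNase_P_RNA = "other_RNA", misc_RNA = "other_RNA",
    pseudogene = "pseudogene")

.CLASS_TO_GFF <- c(
    CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", other_RNA = "ncRNA",
    pseudogene = "pseudogene")

#' Read a GFF3 annotation
#'
#' Parses a GFF3 file into a \code{\link{GenomeAnnotation}}. Contig lengths
#' are taken from \code{##sequence-region} directives or, failing that, from
#' a companion FASTA. Feature types are mapped onto the five feature classes
#' (CDS, tRNA, rRNA, other_RNA, pseudogene); records of any other type are
#' skipped with a warning, and records whose end precedes their start are
#' rejected with a warning.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param fasta Optional path to the genome FASTA, used for contig lengths
#'   when the GFF3 carries no \code{##sequence-region} directives.
#' @return A \code{\link{GenomeAnnotation}}.
#' @export
readAnnotation <- function(path, fasta = NULL) {
    lines <- readLines(path)
    if (!length(lines)) stop("empty GFF3 file: ", path)
    sr <- grep("^##sequence-region", lines, value = TRUE)
    contig_lengths <- NULL
    if (length(sr)) {
        parts <- strsplit(trimws(sr), "[ \t]+")
        contig_lengths <- vapply(parts, function(p) as.integer(p[4]), integer(1))
        names(contig_lengths) <- vapply(parts, `[`, character(1), 2)
    } else if (!is.null(fasta)) {
        genome <- readGenome(fasta)
        contig_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
    } else {
        stop("missing contig lengths: no ##sequence-region directives and no FASTA given")
    }

    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    n_ok <- lengths(fields) == 9L
    if (any(!n_ok))
        warning(sum(!n_ok), " GFF3 record(s) without 9 fields skipped")
    fields <- fields[n_ok]
    bad <- vapply(fields, function(f)
        suppressWarnings(as.integer(f[5]) < as.integer(f[4])), logical(1))
    bad[is.na(bad)] <- TRUE
    if (any(bad))
        warning(sum(bad), " malformed GFF3 record(s) (end < start) rejected")
    fields <- fields[!bad]
    if (!length(fields))
        return(GenomeAnnotation(character(), character(), integer(),
                                integer(), character(), character(),
                                contig_lengths))
    tmp <- tempfile(fileext = ".gff3")
    on.exit(unlink(tmp))
    writeLines(c("##gff-version 3",
                 vapply(fields, paste, character(1), collapse = "\t")), tmp)
    gr <- rtracklayer::import(tmp, format = "gff3")

    type <- as.character(gr$type)
    known <- type %in% names(.GFF_TYPE_MAP)
    if (any(!known))
        warning("skipping ", sum(!known), " record(s) of unmapped type(s): ",
                paste(unique(type[!known]), collapse = ", "))
    gr <- gr[known]
    cls <- unname(.GFF_TYPE_MAP[as.character(gr$type)])
    ids <- if (!is.null(gr$locus_tag) && !anyNA(gr$locus_tag)) gr$locus_tag
           else if (!is.null(gr$ID)) gr$ID
           else stop("GFF3 records carry neither locus_tag nor ID")
    missing_len <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gr))),
                           names(contig_lengths))
    if (length(missing_len))
        stop("missing contig length for: ", paste(missing_len, collapse = ", "))
    GenomeAnnotation(
        gene_id = ids,
        contig = as.character(GenomeInfoDb::seqnames(gr)),
        start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
        strand = as.character(BiocGenerics::strand(gr)),
        feature_class = cls,
        contig_lengths = contig_lengths)
}

#' Write a GenomeAnnotation as GFF3
#'
#' Emits \code{##sequence-region} directives for every contig and one record
#' per gene (1-based inclusive coordinates); feature classes are mapped back
#' to GFF3 types so that \code{\link{readAnnotation}} round-trips the object.
#'
#' @param annotation A \code{\link{GenomeAnnotation}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
    g <- geneRanges(annotation)
    cl <- contigLengths(annotation)
    header <- c("##gff-version 3",
                sprintf("##sequence-region %s 1 %d", names(cl), cl))
    mc <- S4Vectors::mcols(g)
    rows <- sprintf("%s\tTraDISect\t%s\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
        as.character(GenomeInfoDb::seqnames(g)),
        .CLASS_TO_GFF[mc$feature_class],
        BiocGenerics::start(g), BiocGenerics::end(g),
        as.character(BiocGenerics::strand(g)),
        mc$gene_id, mc$gene_id)
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are uppercased and contig names truncated to the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}.
#' @export
readGenome <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    if (!length(x)) stop("empty FASTA file: ", path)
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
    names(x) <- sub("\\s.*$", "", names(x))
    x
}

#' Write a genome FASTA
#'
#' @param genome A \code{DNAStringSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGenome <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path)
    invisible(path)
}
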