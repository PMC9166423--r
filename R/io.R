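## Readers and writers for the on-disk formats the pipeline touches.
## Gene tables are GFF-like TSVs with 1-based inclusive coordinates; hit
## tables are BLAST outfmt-6 compatible with two extra columns (query
## coverage percent, subject taxonomic class); reports are plain TSVs that
## round-trip through readReport().

#' Read a bin from a contig FASTA and a gene coordinate table
#'
#' @param contigFasta path to the contig FASTA.
#' @param geneTable path to a tab-separated gene table with header columns
#'   \code{gene_id}, \code{contig_id}, \code{start}, \code{end},
#'   \code{strand} (1-based inclusive coordinates) and optionally
#'   \code{protein_length}, \code{best_hit_class}, \code{viral}.
#' @param id bin identifier; defaults to the FASTA file name.
#' @param lake,metagenome origin labels.
#' @return a \linkS4class{Bin}. Genes on unknown contigs or with coordinates
#'   outside their contig raise a validation error naming the gene.
#' @export
readBin <- function(contigFasta, geneTable, id = NULL,
                    lake = NA_character_, metagenome = NA_character_) {
    seqs <- tryCatch(Biostrings::readDNAStringSet(contigFasta),
        error = function(e)
            stop("malformed FASTA '", contigFasta, "': ",
                 conditionMessage(e), call. = FALSE))
    ## FASTA descriptions: keep the first word as the contig id
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stop("malformed FASTA '", contigFasta, "': duplicated record name '",
             names(seqs)[duplicated(names(seqs))][1], "'")
    genes <- utils::read.delim(geneTable, stringsAsFactors = FALSE)
    if (is.null(id)) id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                               basename(contigFasta))
    Bin(id, seqs, genes, lake = lake, metagenome = metagenome)
}

#' Write a gene table
#'
#' @param genes gene data.frame (see \code{\link{Bin}}).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
    writeReport(normalizeGeneTable(genes), path)
}

hitTableColumns <- function() {
    c("query", "subject", "similarity", "aln_length", "mismatches",
      "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
      "bitscore", "coverage", "subject_class")
}

#' Read a tabular alignment hit table
#'
#' Tab-separated, one hit per row, BLAST outfmt-6 compatible (12 standard
#' columns) plus a query-coverage-percent column and a subject-class column;
#' no header. Hits are grouped per query with original order preserved.
#'
#' @param path path to the hit table.
#' @return named list: for each query gene id, a data.frame with columns
#'   \code{subject}, \code{evalue}, \code{similarity}, \code{coverage},
#'   \code{bitscore}, \code{subject_class}.
#' @export
readHitTable <- function(path) {
    cols <- hitTableColumns()
    if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
        return(stats::setNames(list(), character()))
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = NULL)
    if (nrow(raw) == 0L) return(stats::setNames(list(), character()))
    if (ncol(raw) < length(cols))
        stop("hit table '", path, "' has ", ncol(raw),
             " columns; expected at least ", length(cols))
    raw <- raw[, seq_along(cols)]
    names(raw) <- cols
    for (numcol in c("evalue", "bitscore", "similarity", "coverage")) {
        val <- suppressWarnings(as.numeric(raw[[numcol]]))
        bad <- which(is.na(val) & !is.na(raw[[numcol]]))
        if (length(bad))
            stop("non-numeric ", numcol, " in '", path, "' at line ", bad[1],
                 ": '", raw[[numcol]][bad[1]], "'")
        raw[[numcol]] <- val
    }
    keep <- c("subject", "evalue", "similarity", "coverage", "bitscore",
              "subject_class")
    split_idx <- split(seq_len(nrow(raw)), raw$query)
    ## preserve first-appearance order of queries
    split_idx <- split_idx[unique(raw$query)]
    lapply(split_idx, function(i) {
        out <- raw[i, keep, drop = FALSE]
        rownames(out) <- NULL
        out
    })
}

#' Write a hit association back to the tabular hit format
#'
#' Inverse of \code{\link{readHitTable}}; columns the association does not
#' carry (alignment coordinates, mismatch counts) are written as 0 so the
#' file stays outfmt-6 shaped. Reading the result back yields the identical
#' association.
#'
#' @param hits named list of per-query hit data.frames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeHitTable <- function(hits, path) {
    rows <- lapply(names(hits), function(q) {
        h <- hits[[q]]
        data.frame(query = q, subject = h$subject,
                   similarity = h$similarity, aln_length = 0L,
                   mismatches = 0L, gap_opens = 0L, qstart = 0L, qend = 0L,
                   sstart = 0L, send = 0L, evalue = h$evalue,
                   bitscore = h$bitscore, coverage = h$coverage,
                   subject_class = h$subject_class,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(tab)) tab <- as.data.frame(
        stats::setNames(rep(list(character(0)), length(hitTableColumns())),
                        hitTableColumns()))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a flat report as TSV
#'
#' Deterministic column order (as given), header line, no quoting or row
#' names; round-trips through \code{\link{readReport}}.
#'
#' @param x data.frame, or a list of S4 result objects coercible with
#'   \code{as.data.frame} (e.g. \linkS4class{QualityReport}).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReport <- function(x, path) {
    if (!is.data.frame(x)) {
        if (!is.list(x))
            stop("writeReport expects a data.frame or a list of objects")
        x <- do.call(rbind, lapply(x, as.data.frame))
        if (is.null(x))
            stop("cannot serialize an empty, type-less list; ",
                 "pass a zero-row data.frame instead")
    }
    con <- tryCatch(file(path, "w"), error = function(e)
        stop("cannot write '", path, "': ", conditionMessage(e),
             call. = FALSE))
    on.exit(close(con))
    utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a TSV report written by writeReport
#' @param path input path.
#' @return data.frame.
#' @export
readReport <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a pairwise ANI table
#'
#' Accepts either a square matrix TSV (row and column genome names) or a
#' three-column long form (\code{query}, \code{reference}, \code{ani}).
#' Missing pairs in the long form are treated as below any threshold (filled
#' with 0); the diagonal is set to 100.
#'
#' @param path input path.
#' @return numeric matrix of percent identities.
#' @export
readAniMatrix <- function(path) {
    first <- readLines(path, n = 1L)
    nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nfield <= 3L && all(c("query", "reference", "ani") %in% names(tab))) {
        ids <- sort(unique(c(tab$query, tab$reference)))
        m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
        m[cbind(tab$query, tab$reference)] <- tab$ani
        m[cbind(tab$reference, tab$query)] <- tab$ani
        diag(m) <- 100
        m
    } else {
        m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                         check.names = FALSE))
        storage.mode(m) <- "double"
        m
    }
}

#' Write a square ANI matrix as TSV
#' @param m numeric matrix with genome names.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAniMatrix <- function(m, path) {
    df <- data.frame(genome = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read rRNA intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted once at this boundary to
#' the 1-based inclusive convention used internally.
#'
#' @param path BED path (first three columns: contig, start, end).
#' @return data.frame with columns \code{contig}, \code{start}, \code{end}
#'   (1-based inclusive).
#' @export
readBed <- function(path) {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 3L) stop("BED file needs at least 3 columns")
    data.frame(contig = as.character(bed[[1]]),
               start = as.integer(bed[[2]]) + 1L,
               end = as.integer(bed[[3]]),
               stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads \link[Biostrings]{DNAStringSet}; a constant maximal quality
#'   is written (the simulator is error-free unless asked otherwise).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFastq <- function(reads, path) {
    quals <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
        function(w) strrep("I", w), character(1)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals)
    invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#' @param path FASTQ path.
#' @return \link[Biostrings]{DNAStringSet}.
#' @export
readFastq <- function(path) {
    Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @export
#' @method as.data.frame QualityReport
as.data.frame.QualityReport <- function(x, ...) {
    data.frame(completeness = x@completeness,
               contamination = x@contamination,
               strain_heterogeneity = x@strainHeterogeneity,
               n_contigs_removed_taxonomy = x@nContigsRemovedTaxonomy,
               n_contigs_removed_viral = x@nContigsRemovedViral,
               passed = x@passed)
}

#' @export
#' @method as.data.frame RecruitmentResult
as.data.frame.RecruitmentResult <- function(x, ...) {
    data.frame(bin_id = x@binId, metagenome_id = x@metagenomeId,
               n_hits = x@nHits, mapped_bases = x@mappedBases,
               effective_genome_len = x@effectiveGenomeLen,
               sampled_bases = x@sampledBases, coverage = x@coverage,
               coverage_per_gbp = x@coveragePerGbp)
}

#' @export
#' @method as.data.frame ReplicationIndex
as.data.frame.ReplicationIndex <- function(x, ...) {
    data.frame(bin_id = x@binId, metagenome_id = x@metagenomeId,
               index = x@index, mean_coverage = x@meanCoverage,
               window_size = x@windowSize)
}

setMethod("as.data.frame", "QualityReport", as.data.frame.QualityReport)
setMethod("as.data.frame", "RecruitmentResult", as.data.frame.RecruitmentResult)
setMethod("as.data.frame", "ReplicationIndex", as.data.frame.ReplicationIndex)
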