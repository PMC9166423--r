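#' Construct a Bin
#'
#' @param id bin identifier.
#' @param contigs either a \link[Biostrings]{DNAStringSet} of contig
#'   sequences, or a named integer vector of contig lengths when sequences
#'   are unavailable.
#' @param genes data.frame of gene coordinates; required columns
#'   \code{gene_id}, \code{contig_id}, \code{start}, \code{end},
#'   \code{strand}; optional \code{protein_length}, \code{best_hit_class},
#'   \code{viral} are filled with NA / FALSE.
#' @param lake,metagenome origin labels.
#' @return a \linkS4class{Bin}.
#' @examples
#' ctg <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTACGT"))
#' b <- Bin("bin1", ctg, data.frame(gene_id = "g1", contig_id = "c1",
#'          start = 1, end = 6, strand = "+"))
#' @export
Bin <- function(id, contigs, genes = emptyGeneTable(),
                lake = NA_character_, metagenome = NA_character_) {
    if (methods::is(contigs, "DNAStringSet")) {
        seqs <- contigs
        lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
    } else {
        seqs <- Biostrings::DNAStringSet()
        lens <- contigs
    }
    methods::new("Bin", id = as.character(id), sequences = seqs,
        contigLens = stats::setNames(as.integer(lens), names(lens)),
        genes = normalizeGeneTable(genes),
        lake = as.character(lake), metagenome = as.character(metagenome))
}

#' An empty gene table with the canonical columns
#' @return zero-row data.frame.
#' @export
emptyGeneTable <- function() {
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               protein_length = integer(), best_hit_class = character(),
               viral = logical(), stringsAsFactors = FALSE)
}

normalizeGeneTable <- function(genes) {
    need <- c("gene_id", "contig_id", "start", "end", "strand")
    miss <- setdiff(need, names(genes))
    if (length(miss))
        stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
    genes$gene_id <- as.character(genes$gene_id)
    genes$contig_id <- as.character(genes$contig_id)
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    genes$strand <- as.character(genes$strand)
    if (is.null(genes$protein_length))
        genes$protein_length <- rep(NA_integer_, nrow(genes))
    if (is.null(genes$best_hit_class))
        genes$best_hit_class <- rep(NA_character_, nrow(genes))
    else genes$best_hit_class <- as.character(genes$best_hit_class)
    if (is.null(genes$viral)) genes$viral <- rep(FALSE, nrow(genes))
    genes$viral <- as.logical(genes$viral)
    rownames(genes) <- NULL
    genes[c("gene_id", "contig_id", "start", "end", "strand",
            "protein_length", "best_hit_class", "viral")]
}

#' @describeIn Bin bin identifier.
#' @param object a \linkS4class{Bin}.
#' @export
setMethod("binId", "Bin", function(object) object@id)

#' @describeIn Bin gene table.
#' @export
setMethod("genes", "Bin", function(object) object@genes)

#' @describeIn Bin contig names.
#' @export
setMethod("contigNames", "Bin", function(object) names(object@contigLens))

#' @describeIn Bin named contig lengths.
#' @export
setMethod("contigLengths", "Bin", function(object) object@contigLens)

#' @describeIn Bin contig sequences (may be empty).
#' @export
setMethod("contigSequences", "Bin", function(object) object@sequences)

setMethod("show", "Bin", function(object) {
    cat("Bin", object@id, "\n")
    cat(" ", length(object@contigLens), "contigs,",
        sum(as.numeric(object@contigLens)), "bp,",
        nrow(object@genes), "genes\n")
    if (!is.na(object@lake))
        cat("  origin:", object@lake, "/", object@metagenome, "\n")
    invisible(NULL)
})

#' Keep a subset of contigs of a bin
#'
#' Drops all other contigs and prunes the gene table consistently.
#'
#' @param bin a \linkS4class{Bin}.
#' @param keep character vector of contig names to keep.
#' @return a \linkS4class{Bin}.
#' @export
subsetContigs <- function(bin, keep) {
    stopifnot(all(keep %in% contigNames(bin)))
    lens <- bin@contigLens[names(bin@contigLens) %in% keep]
    seqs <- bin@sequences
    if (length(seqs)) seqs <- seqs[names(seqs) %in% keep]
    g <- bin@genes[bin@genes$contig_id %in% keep, , drop = FALSE]
    rownames(g) <- NULL
    methods::new("Bin", id = bin@id, sequences = seqs, contigLens = lens,
                 genes = g, lake = bin@lake, metagenome = bin@metagenome)
}
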