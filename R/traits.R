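## Genome streamlining traits, lifestyle-group comparison, KEGG-module
## completeness averaging, and CAZy family tabulation.

#' Compute streamlining traits for one genome
#'
#' GC is the G+C percentage of unmasked (non-N) bases. Coding density is the
#' percentage of the assembly covered by the union of gene spans (overlaps
#' counted once). The estimated genome size extrapolates the assembly length
#' by the completeness estimate: \code{assembly * 100 / completeness}
#' (undefined at completeness 0).
#'
#' @param bin a \linkS4class{Bin} with sequences.
#' @param quality a \linkS4class{QualityReport} (or a completeness percent).
#' @param category lifestyle category label recorded in the row.
#' @return one-row data.frame with columns \code{genome_id},
#'   \code{assembly_length}, \code{estimated_genome_size}, \code{gc},
#'   \code{coding_density}, \code{n_genes}, \code{completeness},
#'   \code{category}.
#' @export
computeTraits <- function(bin, quality, category = NA_character_) {
    comp <- if (methods::is(quality, "QualityReport"))
        completeness(quality) else as.numeric(quality)
    seqs <- contigSequences(bin)
    if (!length(seqs))
        stop("bin '", binId(bin), "' carries no sequences")
    freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
    acgt <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- 100 * sum(acgt[c("C", "G")]) / sum(acgt)
    assembly <- sum(as.numeric(contigLengths(bin)))
    g <- genes(bin)
    coding <- if (nrow(g)) {
        sum(vapply(split(seq_len(nrow(g)), g$contig_id), function(i)
            sum(IRanges::width(IRanges::reduce(
                IRanges::IRanges(g$start[i], g$end[i])))), numeric(1)))
    } else 0
    est <- if (comp > 0) assembly * 100 / comp else NA_real_
    data.frame(genome_id = binId(bin), assembly_length = assembly,
               estimated_genome_size = est, gc = gc,
               coding_density = 100 * coding / assembly,
               n_genes = nrow(g), completeness = comp,
               category = category, stringsAsFactors = FALSE)
}

#' Summarize traits per lifestyle category
#'
#' Median, minimum and maximum of each numeric trait within each category.
#' Categories with no genomes are omitted with a warning.
#'
#' @param traits trait data.frame (rows from \code{\link{computeTraits}} or
#'   \code{\link{makeTraitTable}}); must carry \code{category}.
#' @param traitCols numeric columns to summarize.
#' @return data.frame with columns \code{category}, \code{trait},
#'   \code{median}, \code{min}, \code{max}, \code{n}.
#' @export
summarizeGroups <- function(traits,
                            traitCols = c("assembly_length",
                                          "estimated_genome_size", "gc",
                                          "coding_density", "n_genes")) {
    traitCols <- intersect(traitCols, names(traits))
    if (is.factor(traits$category)) {
        gone <- setdiff(levels(traits$category),
                        unique(as.character(traits$category)))
        if (length(gone))
            warning("omitting empty categor(ies): ",
                    paste(gone, collapse = ", "))
    }
    cats <- sort(unique(as.character(traits$category)))
    rows <- lapply(cats, function(k) {
        sub <- traits[traits$category == k, , drop = FALSE]
        do.call(rbind, lapply(traitCols, function(tc) {
            v <- sub[[tc]]
            v <- v[!is.na(v)]
            data.frame(category = k, trait = tc,
                       median = stats::median(v), min = min(v), max = max(v),
                       n = length(v), stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' KEGG-module completeness per genome and per group
#'
#' A module's completeness in a genome is the fraction of its required KO
#' identifiers the genome encodes. The per-genome value averages over
#' modules, and the group value is the unweighted mean of per-genome
#' averages (average per genome first, then per group).
#'
#' @param koSets named list: genome id -> character vector of KO identifiers.
#' @param modules named list: module id -> character vector of required KOs;
#'   an empty KO set is a configuration error.
#' @param categories optional named character vector genome id -> group
#'   label; when given, group means are returned.
#' @return list with \code{fractions} (genome x module matrix),
#'   \code{perGenome} (named numeric), and \code{groupMeans} (named numeric,
#'   NULL without categories).
#' @export
moduleCompleteness <- function(koSets, modules, categories = NULL) {
    bad <- names(modules)[vapply(modules, length, integer(1)) == 0L]
    if (length(bad))
        stop("module(s) with empty KO set: ", paste(bad, collapse = ", "))
    frac <- vapply(modules, function(req)
        vapply(koSets, function(kos) mean(req %in% kos), numeric(1)),
        numeric(length(koSets)))
    if (length(koSets) == 1L)
        frac <- matrix(frac, nrow = 1,
                       dimnames = list(names(koSets), names(modules)))
    perGenome <- rowMeans(frac)
    groupMeans <- NULL
    if (!is.null(categories)) {
        miss <- setdiff(names(koSets), names(categories))
        if (length(miss))
            stop("no category for genome(s): ", paste(miss, collapse = ", "))
        groupMeans <- tapply(perGenome, categories[names(perGenome)], mean)
        groupMeans <- stats::setNames(as.numeric(groupMeans),
                                      names(groupMeans))
    }
    list(fractions = frac, perGenome = perGenome, groupMeans = groupMeans)
}

#' Summarize carbohydrate-active enzyme (CAZy) annotations
#'
#' @param hits data.frame with columns \code{genome_id}, \code{family} (one
#'   row per annotated gene).
#' @param genomeIds optional character vector of all genomes considered
#'   (genomes with zero hits count toward the mean and prevalence
#'   denominators); defaults to the genomes appearing in \code{hits}.
#' @return list with \code{perGenome} (data.frame \code{genome_id},
#'   \code{n_hits}), \code{meanPerGenome}, and \code{families} (data.frame
#'   \code{family}, \code{n_hits}, \code{share} percent of all hits,
#'   \code{prevalence} percent of genomes with >= 1 hit), families sorted by
#'   descending share.
#' @export
cazySummary <- function(hits, genomeIds = NULL) {
    if (is.null(genomeIds)) genomeIds <- unique(hits$genome_id)
    counts <- table(factor(hits$genome_id, levels = genomeIds))
    perGenome <- data.frame(genome_id = genomeIds,
                            n_hits = as.integer(counts),
                            stringsAsFactors = FALSE)
    total <- nrow(hits)
    fams <- sort(unique(hits$family))
    famrows <- do.call(rbind, lapply(fams, function(f) {
        sub <- hits[hits$family == f, , drop = FALSE]
        data.frame(family = f, n_hits = nrow(sub),
                   share = if (total) 100 * nrow(sub) / total else 0,
                   prevalence = 100 * length(unique(sub$genome_id)) /
                       length(genomeIds),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(famrows))
        famrows <- data.frame(family = character(), n_hits = integer(),
                              share = numeric(), prevalence = numeric())
    famrows <- famrows[order(-famrows$share, famrows$family), , drop = FALSE]
    rownames(famrows) <- NULL
    list(perGenome = perGenome,
         meanPerGenome = if (length(genomeIds)) mean(counts) else NA_real_,
         families = famrows)
}
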