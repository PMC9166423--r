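## Bin decontamination and 43-SCG quality estimation.
##
## A bin's genes are first assigned a taxonomic class from their best
## surviving alignment hit; whole contigs are then removed when fewer than
## 30% of their assigned genes belong to the bin's dominant class, or when
## more than 25% of their genes are of viral origin. Completeness and
## contamination follow from presence/duplication over the 43 single-copy
## markers, and the strict quality gate (>40% completeness, <5%
## contamination) decides whether the bin enters downstream analysis.

#' Assign gene taxonomy from alignment hits
#'
#' Hits failing any of the four acceptance criteria (e-value above the
#' ceiling, similarity, query coverage or bitscore below their floors) are
#' discarded; among the survivors the single best hit (highest bitscore, ties
#' broken by original order) supplies the class. Genes with no surviving hit
#' are unassigned (NA).
#'
#' @param hits named list of per-gene hit data.frames, as returned by
#'   \code{\link{readHitTable}}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return named character vector gene_id -> class label (NA = unassigned);
#'   only genes present in \code{hits} appear.
#' @export
assignGeneTaxonomy <- function(hits, config = pipelineConfig()) {
    out <- vapply(hits, function(h) {
        ok <- h$evalue <= config@hitEvalueMax &
              h$similarity >= config@hitMinSimilarity &
              h$coverage >= config@hitMinCoverage &
              h$bitscore >= config@hitMinBitscore
        if (!any(ok)) return(NA_character_)
        h <- h[ok, , drop = FALSE]
        h$subject_class[which.max(h$bitscore)]
    }, character(1))
    stats::setNames(out, names(hits))
}

#' Dominant taxonomic class of a bin
#'
#' The class with the most assigned genes bin-wide; ties are broken by the
#' lexicographically smallest class label.
#'
#' @param bin a \linkS4class{Bin}.
#' @param taxonomy named character vector gene_id -> class (NA allowed), as
#'   from \code{\link{assignGeneTaxonomy}}; defaults to the bin's own
#'   \code{best_hit_class} column.
#' @return class label (length-1 character).
#' @export
dominantClass <- function(bin, taxonomy = NULL) {
    if (is.null(taxonomy)) {
        g <- genes(bin)
        taxonomy <- stats::setNames(g$best_hit_class, g$gene_id)
    }
    taxonomy <- taxonomy[names(taxonomy) %in% genes(bin)$gene_id]
    cls <- taxonomy[!is.na(taxonomy)]
    if (!length(cls))
        stop("bin '", binId(bin),
             "' has no taxonomically assigned genes; cannot vote")
    tab <- table(cls)
    winners <- names(tab)[tab == max(tab)]
    sort(winners)[1]
}

#' Remove contaminant contigs by taxonomy vote
#'
#' The dominant class is computed once, bin-wide, before any removal. A
#' contig is removed iff it has at least one taxonomically assigned gene and
#' strictly fewer than \code{dominantClassMinFrac} (default 30%) of its
#' assigned genes belong to the dominant class. Contigs with zero assigned
#' genes are retained and flagged: unassigned genes are excluded from the
#' vote denominator because CPR genes frequently lack database hits, and
#' counting them would purge novel sequence.
#'
#' @param bin a \linkS4class{Bin}.
#' @param taxonomy named character vector gene_id -> class (NA = unassigned);
#'   defaults to the bin's \code{best_hit_class} column.
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with elements \code{bin} (filtered \linkS4class{Bin}),
#'   \code{removed} (character contig ids), \code{flagged} (contigs retained
#'   with zero assigned genes), \code{dominant} (the class voted).
#' @export
decontaminate <- function(bin, taxonomy = NULL, config = pipelineConfig()) {
    g <- genes(bin)
    if (is.null(taxonomy))
        taxonomy <- stats::setNames(g$best_hit_class, g$gene_id)
    dom <- dominantClass(bin, taxonomy)
    cls <- taxonomy[g$gene_id]
    assigned <- !is.na(cls)
    n_assigned <- tapply(assigned, g$contig_id, sum)
    n_dom <- tapply(assigned & cls == dom, g$contig_id, sum)
    frac <- ifelse(n_assigned > 0, n_dom / n_assigned, NA)
    voted <- names(n_assigned)
    removed <- voted[!is.na(frac) & frac < config@dominantClassMinFrac]
    flagged <- setdiff(contigNames(bin), voted[n_assigned > 0])
    keep <- setdiff(contigNames(bin), removed)
    list(bin = subsetContigs(bin, keep), removed = sort(removed),
         flagged = sort(flagged), dominant = dom)
}

#' Remove putative viral contigs
#'
#' A contig is removed iff strictly more than \code{viralMaxFrac} (default
#' 25%) of its predicted genes carry a viral flag. Contigs with zero genes
#' are retained (no evidence).
#'
#' @param bin a \linkS4class{Bin}; its gene table must carry \code{viral}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with elements \code{bin} (filtered) and \code{removed}.
#' @export
viralFilter <- function(bin, config = pipelineConfig()) {
    g <- genes(bin)
    frac <- tapply(g$viral, g$contig_id, mean)
    removed <- names(frac)[frac > config@viralMaxFrac]
    keep <- setdiff(contigNames(bin), removed)
    list(bin = subsetContigs(bin, keep), removed = sort(removed))
}

#' Build a single-copy marker profile from marker annotations
#'
#' @param markerTable data.frame with columns \code{gene_id},
#'   \code{marker_id}, and optionally \code{copy_identity} (percent
#'   amino-acid identity of an extra copy to the marker's first copy; NA for
#'   first copies). Marker ids outside the configured 43-set are ignored.
#' @param config a \linkS4class{PipelineConfig}.
#' @return an \linkS4class{SCGProfile}.
#' @export
scgProfile <- function(markerTable, config = pipelineConfig()) {
    markers <- config@scgMarkerIds
    counts <- stats::setNames(integer(length(markers)), markers)
    keep <- markerTable$marker_id %in% markers
    tab <- table(markerTable$marker_id[keep])
    counts[names(tab)] <- as.integer(tab)
    idents <- list()
    if ("copy_identity" %in% names(markerTable)) {
        extra <- markerTable[keep & !is.na(markerTable$copy_identity), ,
                             drop = FALSE]
        if (nrow(extra))
            idents <- split(extra$copy_identity, extra$marker_id)
    }
    methods::new("SCGProfile", counts = counts, identities = idents)
}

#' @describeIn scgProfile marker copy counts of a profile.
#' @param object an \linkS4class{SCGProfile}.
#' @export
setMethod("markerCounts", "SCGProfile", function(object) object@counts)

setMethod("show", "SCGProfile", function(object) {
    cat("SCGProfile:", sum(object@counts > 0L), "of",
        length(object@counts), "markers present;",
        sum(pmax(object@counts - 1L, 0L)), "extra copies\n")
    invisible(NULL)
})

qualityFromCounts <- function(counts, identities, config,
                              nRemovedTax = 0L, nRemovedViral = 0L,
                              shIdentityMin = 90) {
    n <- length(counts)
    comp <- 100 * sum(counts >= 1L) / n
    cont <- 100 * sum(pmax(counts - 1L, 0L)) / n
    multi <- names(counts)[counts > 1L]
    if (length(multi)) {
        hom <- vapply(multi, function(m) {
            idn <- identities[[m]]
            !is.null(idn) && length(idn) && all(idn >= shIdentityMin)
        }, logical(1))
        sh <- 100 * sum(hom) / length(multi)
    } else sh <- 0
    methods::new("QualityReport",
        completeness = comp, contamination = cont, strainHeterogeneity = sh,
        nContigsRemovedTaxonomy = as.integer(nRemovedTax),
        nContigsRemovedViral = as.integer(nRemovedViral),
        passed = comp > config@completenessMin &&
                 cont < config@contaminationMax)
}

#' Estimate bin quality from a 43-marker profile
#'
#' Completeness is the percentage of the 43 markers present at least once;
#' contamination the percentage of extra copies (sum of copies beyond the
#' first over 43); strain heterogeneity the percentage of multi-copy markers
#' whose extra copies are all at least \code{shIdentityMin} percent identical
#' to their first copy (0 when no marker is multi-copy). The gate passes iff
#' completeness strictly exceeds \code{completenessMin} and contamination
#' stays strictly below \code{contaminationMax}.
#'
#' @param object an \linkS4class{SCGProfile}, or a named integer vector of
#'   43 marker copy counts.
#' @param config a \linkS4class{PipelineConfig}.
#' @param nRemovedTax,nRemovedViral decontamination removal counts to record.
#' @param shIdentityMin identity threshold (percent) for a duplicate to count
#'   as strain heterogeneity rather than contamination from another organism.
#' @param ... unused.
#' @return a \linkS4class{QualityReport}.
#' @examples
#' p <- makeScgProfile(1, completeness = 51.16, contamination = 0)
#' estimateQuality(p)
#' @export
setMethod("estimateQuality", "SCGProfile",
    function(object, config = pipelineConfig(), nRemovedTax = 0L,
             nRemovedViral = 0L, shIdentityMin = 90, ...) {
        qualityFromCounts(object@counts, object@identities, config,
                          nRemovedTax, nRemovedViral, shIdentityMin)
    })

#' @rdname estimateQuality-SCGProfile-method
#' @export
setMethod("estimateQuality", "numeric",
    function(object, config = pipelineConfig(), nRemovedTax = 0L,
             nRemovedViral = 0L, shIdentityMin = 90, ...) {
        if (length(object) != 43L)
            stop("a marker profile must have exactly 43 entries, got ",
                 length(object))
        qualityFromCounts(as.integer(object),
                          stats::setNames(list(), character()), config,
                          nRemovedTax, nRemovedViral, shIdentityMin)
    })

#' @describeIn estimateQuality-SCGProfile-method completeness accessor.
#' @export
setMethod("completeness", "QualityReport", function(object) object@completeness)

#' @describeIn estimateQuality-SCGProfile-method contamination accessor.
#' @export
setMethod("contamination", "QualityReport", function(object) object@contamination)

#' @describeIn estimateQuality-SCGProfile-method strain heterogeneity accessor.
#' @export
setMethod("strainHeterogeneity", "QualityReport",
          function(object) object@strainHeterogeneity)

#' @describeIn estimateQuality-SCGProfile-method quality-gate accessor.
#' @export
setMethod("passedQc", "QualityReport", function(object) object@passed)

setMethod("show", "QualityReport", function(object) {
    cat(sprintf(
        "QualityReport: completeness %.2f%%, contamination %.2f%%, SH %.1f%% [%s]\n",
        object@completeness, object@contamination,
        object@strainHeterogeneity,
        if (object@passed) "PASS" else "FAIL"))
    invisible(NULL)
})

#' Run the full QC chain on one bin
#'
#' Taxonomy-vote decontamination, viral filtering, then quality estimation
#' from the marker annotations of the surviving contigs.
#'
#' @param bin a \linkS4class{Bin}.
#' @param hits per-gene hit list (see \code{\link{readHitTable}}); when NULL
#'   the bin's \code{best_hit_class} column is used directly.
#' @param markerTable marker annotation table (see \code{\link{scgProfile}}).
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with \code{bin} (filtered), \code{quality}
#'   (\linkS4class{QualityReport}), \code{removedTaxonomy},
#'   \code{removedViral}, \code{flagged}, \code{dominant}.
#' @export
qcBin <- function(bin, hits = NULL, markerTable = NULL,
                  config = pipelineConfig()) {
    taxonomy <- if (is.null(hits)) NULL else assignGeneTaxonomy(hits, config)
    dec <- decontaminate(bin, taxonomy, config)
    vir <- viralFilter(dec$bin, config)
    clean <- vir$bin
    if (is.null(markerTable))
        markerTable <- data.frame(gene_id = character(),
                                  marker_id = character())
    markerTable <- markerTable[markerTable$gene_id %in% genes(clean)$gene_id, ,
                               drop = FALSE]
    prof <- scgProfile(markerTable, config)
    qual <- estimateQuality(prof, config,
                            nRemovedTax = length(dec$removed),
                            nRemovedViral = length(vir$removed))
    list(bin = clean, quality = qual, removedTaxonomy = dec$removed,
         removedViral = vir$removed, flagged = dec$flagged,
         dominant = dec$dominant)
}
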