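## Central S4 containers for the pipeline. Tabular results (clusters, calls,
## trait tables) are ordinary data.frames; the classes below carry the objects
## whose internal consistency must be enforced by validity methods.

#' Pipeline configuration
#'
#' Holds every threshold the pipeline applies. Defaults are the study
#' conditions: 3 kbp minimum contig length for binning input, the 30%
#' dominant-class vote floor and 25% viral-gene ceiling for contig
#' decontamination, a 43 single-copy marker gene (SCG) set with the
#' >40% completeness / <5% contamination quality gate, the >99% average
#' nucleotide identity (ANI) dereplication threshold, 20 million reads
#' subsampled per metagenome for fragment recruitment, the >150 residue /
#' P < 1e-2 rhodopsin candidate filter with 7 required transmembrane
#' helices, and the alignment-hit acceptance criteria (e-value <= 1e-3,
#' similarity >= 10%, query coverage >= 10%, bitscore >= 50).
#'
#' @slot minContigLen minimum contig length in bases.
#' @slot dominantClassMinFrac fraction of assigned genes on a contig that must
#'   belong to the bin's dominant taxonomic class (strictly below removes).
#' @slot viralMaxFrac fraction of viral genes on a contig (strictly above
#'   removes).
#' @slot scgMarkerIds character vector of exactly 43 distinct marker ids.
#' @slot completenessMin percent completeness a bin must strictly exceed.
#' @slot contaminationMax percent contamination a bin must stay strictly below.
#' @slot aniThreshold percent ANI strictly above which two genomes are linked.
#' @slot readsSubsample number of reads subsampled per metagenome.
#' @slot rhodopsinMinLen residue count a rhodopsin candidate must strictly
#'   exceed.
#' @slot rhodopsinMaxP P-value a candidate must stay strictly below.
#' @slot requiredHelices transmembrane helix count for a canonical rhodopsin.
#' @slot hitEvalueMax,hitMinSimilarity,hitMinCoverage,hitMinBitscore alignment
#'   hit acceptance criteria.
#' @slot rngSeed integer seed from which all randomness is derived.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    slots = c(
        minContigLen = "numeric",
        dominantClassMinFrac = "numeric",
        viralMaxFrac = "numeric",
        scgMarkerIds = "character",
        completenessMin = "numeric",
        contaminationMax = "numeric",
        aniThreshold = "numeric",
        readsSubsample = "numeric",
        rhodopsinMinLen = "numeric",
        rhodopsinMaxP = "numeric",
        requiredHelices = "numeric",
        hitEvalueMax = "numeric",
        hitMinSimilarity = "numeric",
        hitMinCoverage = "numeric",
        hitMinBitscore = "numeric",
        rngSeed = "numeric"
    )
)

setValidity("PipelineConfig", function(object) {
    msg <- character()
    fracs <- c(dominantClassMinFrac = object@dominantClassMinFrac,
               viralMaxFrac = object@viralMaxFrac)
    if (any(fracs < 0 | fracs > 1))
        msg <- c(msg, "fractions must lie in [0, 1]")
    pcts <- c(completenessMin = object@completenessMin,
              contaminationMax = object@contaminationMax,
              aniThreshold = object@aniThreshold,
              hitMinSimilarity = object@hitMinSimilarity,
              hitMinCoverage = object@hitMinCoverage)
    if (any(pcts < 0 | pcts > 100))
        msg <- c(msg, "percent thresholds must lie in [0, 100]")
    ids <- object@scgMarkerIds
    if (length(ids) != 43L || anyDuplicated(ids))
        msg <- c(msg, "scgMarkerIds must contain exactly 43 distinct entries")
    if (object@minContigLen < 1)
        msg <- c(msg, "minContigLen must be >= 1")
    if (object@rhodopsinMaxP <= 0 || object@rhodopsinMaxP > 1)
        msg <- c(msg, "rhodopsinMaxP must lie in (0, 1]")
    if (object@requiredHelices < 1)
        msg <- c(msg, "requiredHelices must be >= 1")
    if (length(msg)) msg else TRUE
})

#' A bin: contigs plus their genes
#'
#' The pipeline's central unit. Contig sequences are optional (some inputs are
#' coordinate tables only); when present, widths must match the declared
#' contig lengths. Gene coordinates are 1-based inclusive.
#'
#' @slot id bin identifier.
#' @slot sequences \link[Biostrings]{DNAStringSet} of contigs (possibly empty
#'   when only coordinates are available).
#' @slot contigLens named integer vector of contig lengths.
#' @slot genes data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{start}, \code{end}, \code{strand}, \code{protein_length},
#'   \code{best_hit_class}, \code{viral}.
#' @slot lake,metagenome origin labels.
#' @exportClass Bin
setClass("Bin",
    slots = c(
        id = "character",
        sequences = "DNAStringSet",
        contigLens = "integer",
        genes = "data.frame",
        lake = "character",
        metagenome = "character"
    )
)

setValidity("Bin", function(object) {
    msg <- character()
    cl <- object@contigLens
    if (is.null(names(cl)) || anyDuplicated(names(cl)))
        msg <- c(msg, "contig lengths must be uniquely named")
    if (any(cl < 1L))
        msg <- c(msg, "contig lengths must be >= 1")
    if (length(object@sequences)) {
        if (!setequal(names(object@sequences), names(cl)))
            msg <- c(msg, "sequence names must match contig names")
        else {
            w <- Biostrings::width(object@sequences)[match(names(cl),
                     names(object@sequences))]
            if (any(w != cl))
                msg <- c(msg, "sequence widths must equal declared contig lengths")
        }
    }
    g <- object@genes
    need <- c("gene_id", "contig_id", "start", "end", "strand",
              "protein_length", "best_hit_class", "viral")
    if (!all(need %in% names(g))) {
        msg <- c(msg, paste("gene table must have columns:",
                            paste(need, collapse = ", ")))
    } else if (nrow(g)) {
        if (anyDuplicated(g$gene_id))
            msg <- c(msg, "gene ids must be unique")
        bad <- !(g$contig_id %in% names(cl))
        if (any(bad))
            msg <- c(msg, paste0("gene(s) on unknown contig: ",
                                 paste(g$gene_id[bad], collapse = ", ")))
        else {
            lens <- cl[g$contig_id]
            off <- g$start < 1L | g$start > g$end | g$end > lens
            if (any(off))
                msg <- c(msg, paste0("gene coordinates outside contig: ",
                                     paste(g$gene_id[off], collapse = ", ")))
        }
        if (!all(g$strand %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-'")
    }
    if (length(msg)) msg else TRUE
})

#' Single-copy marker gene profile
#'
#' Copy counts over the 43-marker set, with optional per-copy amino-acid
#' identities (each duplicated marker's extra copies versus its first copy),
#' used for strain-heterogeneity estimation.
#'
#' @slot counts named integer vector over exactly 43 markers.
#' @slot identities named list; for a duplicated marker, numeric percent
#'   identities of its extra copies to the first copy.
#' @exportClass SCGProfile
setClass("SCGProfile",
    slots = c(counts = "integer", identities = "list"))

setValidity("SCGProfile", function(object) {
    msg <- character()
    if (length(object@counts) != 43L)
        msg <- c(msg, "profile must have exactly 43 markers")
    if (is.null(names(object@counts)) || anyDuplicated(names(object@counts)))
        msg <- c(msg, "marker counts must be uniquely named")
    if (any(object@counts < 0L))
        msg <- c(msg, "copy counts must be >= 0")
    if (length(object@identities) &&
        !all(names(object@identities) %in% names(object@counts)))
        msg <- c(msg, "identity entries must name known markers")
    if (length(msg)) msg else TRUE
})

#' Bin quality report
#'
#' Completeness, contamination and strain heterogeneity estimated from the
#' 43-SCG profile, plus the decontamination removal counts and the strict
#' quality gate (completeness > 40 and contamination < 5 by default).
#'
#' @slot completeness,contamination,strainHeterogeneity percents.
#' @slot nContigsRemovedTaxonomy,nContigsRemovedViral removal counts.
#' @slot passed logical quality gate.
#' @exportClass QualityReport
setClass("QualityReport",
    slots = c(
        completeness = "numeric",
        contamination = "numeric",
        strainHeterogeneity = "numeric",
        nContigsRemovedTaxonomy = "integer",
        nContigsRemovedViral = "integer",
        passed = "logical"
    )
)

setValidity("QualityReport", function(object) {
    msg <- character()
    if (object@completeness < 0 || object@completeness > 100)
        msg <- c(msg, "completeness must lie in [0, 100]")
    if (object@contamination < 0)
        msg <- c(msg, "contamination must be >= 0")
    if (object@strainHeterogeneity < 0 || object@strainHeterogeneity > 100)
        msg <- c(msg, "strain heterogeneity must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' Fragment recruitment result
#'
#' Abundance of one bin in one metagenome: read hits, mapped bases, and fold
#' coverage normalized per gigabase of metagenome sampled.
#'
#' @slot binId,metagenomeId identifiers.
#' @slot nHits recruited reads.
#' @slot mappedBases total bases of recruited reads.
#' @slot effectiveGenomeLen genome length after rRNA masking, bases.
#' @slot sampledBases bases of metagenome sampled.
#' @slot coverage mapped bases / effective genome length.
#' @slot coveragePerGbp coverage / (sampled bases / 1e9).
#' @exportClass RecruitmentResult
setClass("RecruitmentResult",
    slots = c(
        binId = "character",
        metagenomeId = "character",
        nHits = "numeric",
        mappedBases = "numeric",
        effectiveGenomeLen = "numeric",
        sampledBases = "numeric",
        coverage = "numeric",
        coveragePerGbp = "numeric"
    )
)

setValidity("RecruitmentResult", function(object) {
    msg <- character()
    if (object@effectiveGenomeLen <= 0)
        msg <- c(msg, "effective genome length must be > 0")
    if (object@sampledBases <= 0)
        msg <- c(msg, "sampled bases must be > 0")
    if (any(c(object@nHits, object@mappedBases) < 0))
        msg <- c(msg, "hit and base counts must be >= 0")
    if (abs(object@coverage -
            object@mappedBases / object@effectiveGenomeLen) > 1e-8 *
            max(1, object@coverage))
        msg <- c(msg, "coverage must equal mappedBases / effectiveGenomeLen")
    if (abs(object@coveragePerGbp -
            object@coverage / (object@sampledBases / 1e9)) > 1e-8 *
            max(1, object@coveragePerGbp))
        msg <- c(msg, "coveragePerGbp must equal coverage / sampled Gbp")
    if (length(msg)) msg else TRUE
})

#' Replication-skew index
#'
#' Ratio of high- to low-coverage genome windows, an ori/ter-style index of
#' active replication (1 = no skew). Undefined (NA) below the mean-coverage
#' floor.
#'
#' @slot binId,metagenomeId identifiers.
#' @slot index ratio >= 1, or NA when coverage is below the floor.
#' @slot meanCoverage mean window coverage.
#' @slot windowSize window size in bases.
#' @exportClass ReplicationIndex
setClass("ReplicationIndex",
    slots = c(
        binId = "character",
        metagenomeId = "character",
        index = "numeric",
        meanCoverage = "numeric",
        windowSize = "numeric"
    )
)

setValidity("ReplicationIndex", function(object) {
    if (!is.na(object@index) && object@index < 1)
        "a defined replication index is floored at 1.0" else TRUE
})
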