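#' Default 43 single-copy marker identifiers
#'
#' Bacterial single-copy marker gene labels used as the default 43-marker set
#' for completeness and contamination estimation. Marker identifiers are
#' opaque strings throughout the pipeline: any 43 distinct labels matching the
#' ids used in the marker annotation tables work.
#'
#' @return character vector of length 43.
#' @export
defaultScgMarkers <- function() {
    c(paste0("Ribosomal_L", c(1:6, 10, 11, 13:24, 27, 29, 30)),
      paste0("Ribosomal_S", c(2:13, 15:20)),
      "Ribosomal_S14", "Ribosomal_L35")
}

#' Construct a pipeline configuration
#'
#' All thresholds default to the study conditions (see
#' \linkS4class{PipelineConfig}); any can be overridden.
#'
#' @param minContigLen,dominantClassMinFrac,viralMaxFrac,scgMarkerIds,
#'   completenessMin,contaminationMax,aniThreshold,readsSubsample,
#'   rhodopsinMinLen,rhodopsinMaxP,requiredHelices,hitEvalueMax,
#'   hitMinSimilarity,hitMinCoverage,hitMinBitscore,rngSeed see
#'   \linkS4class{PipelineConfig}.
#' @return a \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(aniThreshold = 98)
#' @export
pipelineConfig <- function(minContigLen = 3000,
                           dominantClassMinFrac = 0.30,
                           viralMaxFrac = 0.25,
                           scgMarkerIds = defaultScgMarkers(),
                           completenessMin = 40,
                           contaminationMax = 5,
                           aniThreshold = 99,
                           readsSubsample = 2e7,
                           rhodopsinMinLen = 150,
                           rhodopsinMaxP = 1e-2,
                           requiredHelices = 7,
                           hitEvalueMax = 1e-3,
                           hitMinSimilarity = 10,
                           hitMinCoverage = 10,
                           hitMinBitscore = 50,
                           rngSeed = 1L) {
    methods::new("PipelineConfig",
        minContigLen = minContigLen,
        dominantClassMinFrac = dominantClassMinFrac,
        viralMaxFrac = viralMaxFrac,
        scgMarkerIds = as.character(scgMarkerIds),
        completenessMin = completenessMin,
        contaminationMax = contaminationMax,
        aniThreshold = aniThreshold,
        readsSubsample = readsSubsample,
        rhodopsinMinLen = rhodopsinMinLen,
        rhodopsinMaxP = rhodopsinMaxP,
        requiredHelices = requiredHelices,
        hitEvalueMax = hitEvalueMax,
        hitMinSimilarity = hitMinSimilarity,
        hitMinCoverage = hitMinCoverage,
        hitMinBitscore = hitMinBitscore,
        rngSeed = rngSeed)
}

#' Read a pipeline configuration from a flat key-value file
#'
#' The file holds one \code{key = value} pair per line; \code{#} starts a
#' comment. Keys are the \code{\link{pipelineConfig}} argument names;
#' \code{scgMarkerIds} takes a comma-separated list. Unknown keys are an
#' error. Keys absent from the file keep their defaults.
#'
#' @param path path to the configuration file.
#' @return a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    args <- list()
    numeric_keys <- setdiff(names(formals(pipelineConfig)), "scgMarkerIds")
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2L)
            stop("malformed config line: '", ln, "'")
        key <- trimws(kv[1]); val <- trimws(kv[2])
        if (key == "scgMarkerIds") {
            args[[key]] <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
        } else if (key %in% numeric_keys) {
            num <- suppressWarnings(as.numeric(val))
            if (is.na(num))
                stop("non-numeric value for config key '", key, "': ", val)
            args[[key]] <- num
        } else {
            stop("unknown config key: '", key, "'")
        }
    }
    do.call(pipelineConfig, args)
}

#' Derive a reproducible sub-seed
#'
#' Components of the pipeline draw their randomness from sub-seeds derived
#' from the single configured seed, so each stage is independently
#' reproducible. The derivation keeps seeds inside the 32-bit integer range.
#'
#' @param seed base integer seed.
#' @param offset small integer distinguishing the consumer.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, offset = 0L) {
    as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729 +
                12345) %% 2147483647)
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    cat("  contig floor:", object@minContigLen, "bp;",
        "vote floor:", object@dominantClassMinFrac,
        "; viral ceiling:", object@viralMaxFrac, "\n")
    cat("  quality gate: completeness >", object@completenessMin,
        "%, contamination <", object@contaminationMax, "%\n")
    cat("  ANI threshold: >", object@aniThreshold, "%;",
        length(object@scgMarkerIds), "SCG markers\n")
    cat("  rhodopsin: length >", object@rhodopsinMinLen,
        "aa, P <", object@rhodopsinMaxP, ",",
        object@requiredHelices, "helices\n")
    invisible(NULL)
})
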