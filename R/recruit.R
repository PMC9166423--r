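## Fragment recruitment: rRNA masking, read subsampling, a small ungapped
## matcher for desk-scale data, coverage-per-Gbp normalization and the
## replication-skew (ori/ter) index from window coverages.

#' Mask rRNA intervals in a genome
#'
#' Masked positions are replaced by N and excluded from the effective genome
#' length; overlapping intervals are merged first. Intervals are 1-based
#' inclusive (convert BED input with \code{\link{readBed}}).
#'
#' @param genome \link[Biostrings]{DNAStringSet} of contigs.
#' @param intervals data.frame with columns \code{contig}, \code{start},
#'   \code{end}; an interval outside its contig is an error.
#' @return list with \code{genome} (masked \code{DNAStringSet}) and
#'   \code{effectiveLength} (unmasked bases).
#' @export
maskRrna <- function(genome, intervals) {
    total <- sum(as.numeric(Biostrings::width(genome)))
    if (is.null(intervals) || nrow(intervals) == 0L)
        return(list(genome = genome, effectiveLength = total))
    if (!all(intervals$contig %in% names(genome)))
        stop("interval on unknown contig: ",
             paste(setdiff(intervals$contig, names(genome)), collapse = ", "))
    masked <- 0
    out <- genome
    for (ctg in unique(intervals$contig)) {
        iv <- intervals[intervals$contig == ctg, , drop = FALSE]
        w <- length(genome[[ctg]])
        if (any(iv$start < 1L | iv$end > w | iv$start > iv$end))
            stop("interval out of bounds on contig '", ctg, "'")
        red <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
        masked <- masked + sum(IRanges::width(red))
        repl <- Biostrings::DNAStringSet(strrep("N", IRanges::width(red)))
        out[[ctg]] <- Biostrings::replaceAt(out[[ctg]], red, repl)
    }
    list(genome = out, effectiveLength = total - masked)
}

#' Subsample reads reproducibly
#'
#' Draws exactly \code{min(n, length(reads))} reads without replacement; the
#' selection keeps the original read order and is identical under a fixed
#' seed.
#'
#' @param reads \link[Biostrings]{DNAStringSet}.
#' @param n number of reads to keep.
#' @param seed integer seed.
#' @return \code{DNAStringSet}.
#' @export
subsampleReads <- function(reads, n, seed = 1L) {
    stopifnot(n >= 0)
    if (n >= length(reads)) return(reads)
    set.seed(seed)
    reads[sort(sample.int(length(reads), n))]
}

#' Recruit reads against a masked genome
#'
#' A read is recruited if an ungapped alignment over its full length at
#' identity at least \code{minIdentity} exists anywhere on either strand of
#' the unmasked sequence (N matches nothing, so masked regions recruit no
#' reads, and reads containing ambiguous bases are counted as no-hit). One hit is counted per read, at its first matching location. The
#' matcher is a contract, not an engine: precomputed hit tables from an
#' external mapper can be supplied downstream instead (see
#' \code{\link{coveragePerGbp}}).
#'
#' @param reads \link[Biostrings]{DNAStringSet}.
#' @param genome \link[Biostrings]{DNAStringSet} of (masked) contigs.
#' @param minIdentity minimum identity over the full read, in [0, 1].
#' @return data.frame with one row per read: \code{read_id}, \code{hit}
#'   (logical), \code{contig}, \code{start}, \code{strand}. Reads longer
#'   than the longest contig are counted as no-hit.
#' @export
recruit <- function(reads, genome, minIdentity = 0.95) {
    stopifnot(length(reads) > 0L, length(genome) > 0L)
    rc <- Biostrings::reverseComplement(reads)
    n <- length(reads)
    hit <- logical(n); ctg <- rep(NA_character_, n)
    pos <- rep(NA_integer_, n); strand <- rep(NA_character_, n)
    maxw <- max(Biostrings::width(genome))
    ## vectorized exact phase: dictionary-match all reads of equal width at
    ## once; only reads without a perfect placement fall through to the
    ## per-read mismatch-tolerant scan
    widths <- Biostrings::width(reads)
    ## reads with ambiguous bases have no unambiguous placement: no-hit
    clean <- !grepl("[^ACGT]", as.character(reads))
    for (w in unique(widths)) {
        idx <- which(widths == w & !hit & clean)
        if (!length(idx) || w > maxw) next
        for (str in c("+", "-")) {
            todo <- idx[!hit[idx]]
            if (!length(todo)) break
            pd <- Biostrings::PDict(if (str == "+") reads[todo]
                                    else rc[todo])
            for (j in seq_along(genome)) {
                if (w > Biostrings::width(genome)[j]) next
                mi <- Biostrings::matchPDict(pd, genome[[j]])
                found <- which(S4Vectors::elementNROWS(mi) > 0L)
                if (length(found)) {
                    ri <- todo[found]
                    new <- ri[!hit[ri]]
                    if (length(new)) {
                        hit[new] <- TRUE
                        ctg[new] <- names(genome)[j]
                        pos[new] <- vapply(match(new, todo), function(k)
                            BiocGenerics::start(mi[[k]])[1], integer(1))
                        strand[new] <- str
                    }
                }
            }
        }
    }
    for (i in which(!hit & clean)) {
        w <- widths[i]
        if (w > maxw) next
        mm <- floor((1 - minIdentity) * w)
        if (mm == 0L) next   # exact phase already failed
        for (tol in mm) {
            for (j in seq_along(genome)) {
                if (w > Biostrings::width(genome)[j]) next
                m <- Biostrings::matchPattern(reads[[i]], genome[[j]],
                                              max.mismatch = tol,
                                              fixed = TRUE)
                if (length(m)) {
                    hit[i] <- TRUE; ctg[i] <- names(genome)[j]
                    pos[i] <- BiocGenerics::start(m)[1]; strand[i] <- "+"
                    break
                }
                m <- Biostrings::matchPattern(rc[[i]], genome[[j]],
                                              max.mismatch = tol,
                                              fixed = TRUE)
                if (length(m)) {
                    hit[i] <- TRUE; ctg[i] <- names(genome)[j]
                    pos[i] <- BiocGenerics::start(m)[1]; strand[i] <- "-"
                    break
                }
            }
            if (hit[i]) break
        }
    }
    data.frame(read_id = names(reads) %||% as.character(seq_len(n)),
               hit = hit, contig = ctg, start = pos, strand = strand,
               stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalized abundance: coverage per Gbp of metagenome
#'
#' Fold coverage (mapped bases over effective genome length) divided by the
#' gigabases of metagenome sampled, making abundances comparable across
#' genomes and metagenomes of different sizes.
#'
#' @param nHits recruited read count.
#' @param readLen read length used to derive mapped bases when
#'   \code{mappedBases} is not given.
#' @param effectiveGenomeLen genome length after masking, bases (> 0).
#' @param sampledBases total bases of metagenome sampled (> 0); or supply
#'   \code{sampledReads} and \code{sampledReadLen}.
#' @param mappedBases total recruited bases (defaults to
#'   \code{nHits * readLen}).
#' @param sampledReads,sampledReadLen alternative to \code{sampledBases}.
#' @param binId,metagenomeId identifiers recorded in the result.
#' @return a \linkS4class{RecruitmentResult}.
#' @examples
#' r <- coveragePerGbp(nHits = 2000, readLen = 150,
#'                     effectiveGenomeLen = 1e6,
#'                     sampledReads = 2e7, sampledReadLen = 151)
#' r  # coverage 0.3, coverage per Gbp 0.0993
#' @export
coveragePerGbp <- function(nHits, readLen = NULL, effectiveGenomeLen,
                           sampledBases = NULL, mappedBases = NULL,
                           sampledReads = NULL, sampledReadLen = NULL,
                           binId = NA_character_,
                           metagenomeId = NA_character_) {
    if (effectiveGenomeLen <= 0) stop("effective genome length must be > 0")
    if (is.null(mappedBases)) {
        if (is.null(readLen))
            stop("supply mappedBases or nHits with readLen")
        mappedBases <- nHits * readLen
    }
    if (is.null(sampledBases)) {
        if (is.null(sampledReads) || is.null(sampledReadLen))
            stop("supply sampledBases or sampledReads with sampledReadLen")
        sampledBases <- sampledReads * sampledReadLen
    }
    if (sampledBases <= 0) stop("sampled bases must be > 0")
    cov <- mappedBases / effectiveGenomeLen
    methods::new("RecruitmentResult",
        binId = as.character(binId), metagenomeId = as.character(metagenomeId),
        nHits = as.numeric(nHits), mappedBases = as.numeric(mappedBases),
        effectiveGenomeLen = as.numeric(effectiveGenomeLen),
        sampledBases = as.numeric(sampledBases), coverage = cov,
        coveragePerGbp = cov / (sampledBases / 1e9))
}

setMethod("show", "RecruitmentResult", function(object) {
    cat(sprintf(
        "RecruitmentResult %s vs %s: %d hits, coverage %.4g, %.4g per Gbp\n",
        object@binId, object@metagenomeId, as.integer(object@nHits),
        object@coverage, object@coveragePerGbp))
    invisible(NULL)
})

#' Per-window fold coverage from read start positions
#'
#' Mean per-base coverage in consecutive fixed-size windows, computed from
#' read start positions on a single linearized genome. The trailing partial
#' window is dropped.
#'
#' @param positions integer read start positions (1-based).
#' @param genomeLength genome length in bases.
#' @param readLen read length.
#' @param window window size in bases (default 5 kb).
#' @return numeric vector of window mean coverages.
#' @export
windowCoverage <- function(positions, genomeLength, readLen,
                           window = 5000) {
    nwin <- floor(genomeLength / window)
    if (nwin < 1L) stop("genome shorter than one window")
    cov <- IRanges::coverage(
        IRanges::IRanges(start = positions, width = readLen),
        width = genomeLength)
    v <- IRanges::Views(cov,
        IRanges::IRanges(start = (seq_len(nwin) - 1L) * window + 1L,
                         width = window))
    as.numeric(IRanges::viewMeans(v))
}

runningMean <- function(x, k) {
    ## centered moving average, truncated at the edges
    if (k <= 1L) return(x)
    n <- length(x)
    half <- (k - 1L) %/% 2L
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Replication-skew (ori/ter) index from window coverages
#'
#' Window coverages are smoothed with a centered moving average (to suppress
#' per-window sampling noise), sorted, the extreme \code{trimFrac} of windows
#' on each side discarded, and the index computed as the mean of the top
#' decile over the mean of the bottom decile of the remaining ranks. The
#' index is floored at 1.0 and reported as NA when mean coverage falls below
#' \code{coverageFloor} (too little signal to call replication).
#'
#' @param windowCov numeric vector of window coverages (at least 20 windows).
#' @param coverageFloor minimum mean window coverage for a defined index.
#' @param smoothWindows width (windows) of the moving-average smoother.
#' @param trimFrac fraction of extreme windows discarded per side.
#' @param decileFrac fraction of windows forming each decile.
#' @param window window size recorded in the result, bases.
#' @param binId,metagenomeId identifiers recorded in the result.
#' @return a \linkS4class{ReplicationIndex}.
#' @export
replicationIndex <- function(windowCov, coverageFloor = 0.2,
                             smoothWindows = 9, trimFrac = 0.02,
                             decileFrac = 0.10, window = 5000,
                             binId = NA_character_,
                             metagenomeId = NA_character_) {
    n <- length(windowCov)
    if (n < 20L) stop("replication index needs at least 20 windows, got ", n)
    meanCov <- mean(windowCov)
    if (!is.finite(meanCov) || meanCov < coverageFloor || meanCov == 0) {
        idx <- NA_real_
    } else {
        sm <- sort(runningMean(windowCov, smoothWindows))
        k <- ceiling(trimFrac * n)          # discarded per side
        m <- max(round(decileFrac * n), k + 1L)
        top <- sm[(n - m + 1L):(n - k)]
        bottom <- sm[(k + 1L):m]
        bot_mean <- mean(bottom)
        idx <- if (bot_mean <= 0) NA_real_ else max(1, mean(top) / bot_mean)
    }
    methods::new("ReplicationIndex",
        binId = as.character(binId),
        metagenomeId = as.character(metagenomeId),
        index = idx, meanCoverage = meanCov, windowSize = window)
}

setMethod("show", "ReplicationIndex", function(object) {
    cat(sprintf(
        "ReplicationIndex %s vs %s: index %s (mean coverage %.3g, %g bp windows)\n",
        object@binId, object@metagenomeId,
        if (is.na(object@index)) "NA" else sprintf("%.3f", object@index),
        object@meanCoverage, object@windowSize))
    invisible(NULL)
})
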