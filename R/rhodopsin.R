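## Rhodopsin vs heliorhodopsin classification.
##
## Candidates from an upstream profile search (consumed as a hit table of
## ids, lengths and P values) are filtered (>150 aa, P < 1e-2), their
## membrane topology predicted from Kyte-Doolittle hydropathy plus the
## positive-inside rule, and classified from three signals: 7 transmembrane
## helices, protein orientation (extracellular vs cytoplasmic N-terminus),
## and the retinal-binding motif in helix 7 (DxxxK for Type I ion-pumping
## rhodopsins, SxxxK for heliorhodopsins, whose topology is inverted).

#' Kyte-Doolittle hydropathy scale
#' @return named numeric vector over the 20 standard amino acids.
#' @export
kyteDoolittle <- function() {
    c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
      G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
      H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

#' Filter rhodopsin candidates by length and P value
#'
#' Keeps hits with strictly more than \code{rhodopsinMinLen} residues and
#' P value strictly below \code{rhodopsinMaxP}.
#'
#' @param records data.frame with columns \code{protein_id}, \code{length},
#'   \code{p_value}; a negative length is an error.
#' @param config a \linkS4class{PipelineConfig}.
#' @return character vector of surviving protein ids.
#' @export
filterCandidates <- function(records, config = pipelineConfig()) {
    if (any(records$length < 0))
        stop("negative protein length for: ",
             paste(records$protein_id[records$length < 0], collapse = ", "))
    keep <- records$length > config@rhodopsinMinLen &
            records$p_value < config@rhodopsinMaxP
    as.character(records$protein_id[keep])
}

#' Predict membrane topology from hydropathy
#'
#' Transmembrane helices are maximal stretches (length >= \code{minHelixLen})
#' whose 19-residue sliding-window mean Kyte-Doolittle hydropathy reaches
#' \code{hydropathyMin}; stretches separated by fewer than \code{mergeGap}
#' residues are merged. Orientation follows the positive-inside rule: loops
#' alternate between the N-terminal side and the opposite side, and the side
#' holding more K+R residues is called cytoplasmic. The orientation is
#' ambiguous when the two sides differ by fewer than \code{chargeMargin}
#' residues.
#'
#' @param seq protein sequence (character or \link[Biostrings]{AAString});
#'   non-standard residues are an error listing their positions.
#' @param windowSize hydropathy window (residues).
#' @param hydropathyMin window-mean threshold for a transmembrane call.
#' @param minHelixLen minimum helix span length.
#' @param mergeGap spans closer than this many residues are merged.
#' @param chargeMargin K+R difference below which orientation is ambiguous.
#' @return list with \code{helices} (data.frame \code{start}, \code{end}),
#'   \code{nHelices}, \code{orientation} ("N-in", "N-out" or "ambiguous"),
#'   \code{basicNSide}, \code{basicCSide} (K+R counts of the N-terminal-side
#'   and opposite-side loops).
#' @export
predictTopology <- function(seq, windowSize = 19, hydropathyMin = 1.6,
                            minHelixLen = 19, mergeGap = 5,
                            chargeMargin = 2) {
    s <- as.character(seq)
    res <- strsplit(s, "")[[1]]
    kd <- kyteDoolittle()
    h <- kd[res]
    bad <- which(is.na(h))
    if (length(bad))
        stop("non-standard residue(s) at position(s): ",
             paste(bad, collapse = ", "))
    n <- length(res)
    spans <- data.frame(start = integer(), end = integer())
    if (n >= windowSize) {
        win <- as.numeric(stats::filter(h, rep(1 / windowSize, windowSize),
                                        sides = 2))
        centers <- which(!is.na(win) & win >= hydropathyMin)
        if (length(centers)) {
            half <- (windowSize - 1L) %/% 2L
            brk <- c(0L, which(diff(centers) > 1L), length(centers))
            spans <- do.call(rbind, lapply(seq_len(length(brk) - 1L),
                function(i) {
                    cs <- centers[(brk[i] + 1L):brk[i + 1L]]
                    a <- max(1L, cs[1] - half)
                    b <- min(n, cs[length(cs)] + half)
                    ## trim hydrophilic residues the window expansion
                    ## dragged in from the flanking loops
                    while (a < b && h[a] < 0) a <- a + 1L
                    while (b > a && h[b] < 0) b <- b - 1L
                    data.frame(start = a, end = b)
                }))
            ## merge spans separated by gaps of fewer than mergeGap residues
            if (nrow(spans) > 1L) {
                keep <- list(spans[1, ])
                for (i in 2:nrow(spans)) {
                    last <- keep[[length(keep)]]
                    if (spans$start[i] - last$end - 1L < mergeGap)
                        keep[[length(keep)]]$end <- spans$end[i]
                    else keep[[length(keep) + 1L]] <- spans[i, ]
                }
                spans <- do.call(rbind, keep)
            }
            spans <- spans[spans$end - spans$start + 1L >= minHelixLen, ,
                           drop = FALSE]
            rownames(spans) <- NULL
        }
    }
    ## loops alternate sides starting from the N-terminal tail (side 0)
    nh <- nrow(spans)
    basic <- c(0L, 0L)
    ## loop k (0-based, k = 0 is the N tail) lies on side k %% 2
    loop_starts <- c(1L, if (nh) spans$end + 1L)
    loop_ends <- c(if (nh) spans$start - 1L else integer(), n)
    for (k in seq_along(loop_starts)) {
        a <- loop_starts[k]; b <- loop_ends[k]
        if (a > b) next
        cnt <- sum(res[a:b] %in% c("K", "R"))
        side <- (k - 1L) %% 2L
        basic[side + 1L] <- basic[side + 1L] + cnt
    }
    d <- basic[1] - basic[2]
    orientation <- if (abs(d) < chargeMargin) "ambiguous"
                   else if (d > 0) "N-in" else "N-out"
    list(helices = spans, nHelices = nh, orientation = orientation,
         basicNSide = basic[1], basicCSide = basic[2])
}

#' Classify one protein as rhodopsin type
#'
#' With exactly the required helix count (7), the span of helix 7 (plus a
#' small slack for prediction jitter) is scanned first for the Type I
#' retinal-binding motif D-x(3)-K, then for the heliorhodopsin motif
#' S-x(3)-K. A DxxxK protein is an ion pump when its N-terminus is outside
#' (or orientation is ambiguous); an SxxxK protein is a heliorhodopsin when
#' its N-terminus is inside (or ambiguous). A motif contradicting the
#' orientation yields "ambiguous"; no motif yields
#' "rhodopsin_like_unclassified"; any other helix count is rejected.
#'
#' @param seq protein sequence.
#' @param proteinId identifier recorded in the call.
#' @param topology optional precomputed \code{\link{predictTopology}} result.
#' @param config a \linkS4class{PipelineConfig}.
#' @param motifSlack residues of slack around the helix-7 span scanned for
#'   the motif.
#' @return one-row data.frame: \code{protein_id}, \code{n_helices},
#'   \code{orientation}, \code{tm7_motif} (\code{none}, \code{DxxxK} or
#'   \code{SxxxK}), \code{call} (\code{ion_pump}, \code{heliorhodopsin},
#'   \code{rhodopsin_like_unclassified}, \code{rejected} or
#'   \code{ambiguous}), \code{rejection_reason}.
#' @export
classifyRhodopsin <- function(seq, proteinId = "protein",
                              topology = NULL,
                              config = pipelineConfig(), motifSlack = 3) {
    if (is.null(topology)) topology <- predictTopology(seq)
    s <- as.character(seq)
    call_row <- function(call, motif = "none", reason = NA_character_)
        data.frame(protein_id = proteinId, n_helices = topology$nHelices,
                   orientation = topology$orientation, tm7_motif = motif,
                   call = call, rejection_reason = reason,
                   stringsAsFactors = FALSE)
    if (topology$nHelices != config@requiredHelices)
        return(call_row("rejected", reason = "helix_count"))
    h7 <- topology$helices[config@requiredHelices, ]
    lo <- max(1L, h7$start - motifSlack)
    hi <- min(nchar(s), h7$end + motifSlack)
    region <- substr(s, lo, hi)
    if (grepl("D.{3}K", region)) {
        motif <- "DxxxK"
        if (topology$orientation %in% c("N-out", "ambiguous"))
            return(call_row("ion_pump", motif))
        return(call_row("ambiguous", motif))
    }
    if (grepl("S.{3}K", region)) {
        motif <- "SxxxK"
        if (topology$orientation %in% c("N-in", "ambiguous"))
            return(call_row("heliorhodopsin", motif))
        return(call_row("ambiguous", motif))
    }
    call_row("rhodopsin_like_unclassified")
}

#' Classify a set of candidate proteins
#'
#' Applies the candidate filter when hit records are given (proteins failing
#' it are reported as rejected with reason \code{too_short} or
#' \code{p_value}), then topology prediction and classification.
#'
#' @param proteins \link[Biostrings]{AAStringSet} (or named character
#'   vector).
#' @param hitRecords optional data.frame for \code{\link{filterCandidates}};
#'   defaults to passing every protein with its own length.
#' @param config a \linkS4class{PipelineConfig}.
#' @param ... passed to \code{\link{classifyRhodopsin}}.
#' @return data.frame of calls, one row per protein.
#' @export
classifyRhodopsins <- function(proteins, hitRecords = NULL,
                               config = pipelineConfig(), ...) {
    seqs <- stats::setNames(as.character(proteins),
                            names(proteins) %||%
                                paste0("protein_", seq_along(proteins)))
    rows <- lapply(names(seqs), function(id) {
        if (!is.null(hitRecords)) {
            rec <- hitRecords[hitRecords$protein_id == id, , drop = FALSE]
            if (nrow(rec)) {
                if (any(rec$length < 0))
                    stop("negative protein length for: ", id)
                if (!any(rec$length > config@rhodopsinMinLen))
                    return(data.frame(protein_id = id, n_helices = NA_integer_,
                        orientation = NA_character_, tm7_motif = "none",
                        call = "rejected", rejection_reason = "too_short",
                        stringsAsFactors = FALSE))
                if (!any(rec$length > config@rhodopsinMinLen &
                         rec$p_value < config@rhodopsinMaxP))
                    return(data.frame(protein_id = id, n_helices = NA_integer_,
                        orientation = NA_character_, tm7_motif = "none",
                        call = "rejected", rejection_reason = "p_value",
                        stringsAsFactors = FALSE))
            }
        }
        classifyRhodopsin(seqs[[id]], proteinId = id, config = config, ...)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Tabulate rhodopsin calls per taxonomic class
#'
#' @param calls calls data.frame from \code{\link{classifyRhodopsins}}.
#' @param proteinGenome named character vector protein_id -> genome id; an
#'   unmapped protein is an error.
#' @param genomeClass named character vector genome id -> taxonomy class.
#' @return data.frame with columns \code{class}, \code{ion_pumps},
#'   \code{heliorhodopsins}, one row per class appearing among the calls,
#'   sorted by class.
#' @export
summarizeCalls <- function(calls, proteinGenome, genomeClass) {
    unmapped <- setdiff(calls$protein_id, names(proteinGenome))
    if (length(unmapped))
        stop("protein(s) not mapped to a genome: ",
             paste(unmapped, collapse = ", "))
    gen <- proteinGenome[calls$protein_id]
    unmapped <- setdiff(gen, names(genomeClass))
    if (length(unmapped))
        stop("genome(s) not mapped to a class: ",
             paste(unmapped, collapse = ", "))
    cls <- genomeClass[gen]
    levels <- sort(unique(cls))
    out <- data.frame(
        class = levels,
        ion_pumps = vapply(levels, function(k)
            sum(calls$call == "ion_pump" & cls == k), integer(1)),
        heliorhodopsins = vapply(levels, function(k)
            sum(calls$call == "heliorhodopsin" & cls == k), integer(1)),
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
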