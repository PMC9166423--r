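## Synthetic-data generators. Every input the pipeline consumes can be
## generated here with planted ground truth, so each downstream stage has a
## closed-loop test. All generators are deterministic under a fixed seed.
##
## Construction choices that make the truth recoverable by design:
## transmembrane helices are built from strongly hydrophobic residues
## (I/L/V/F) and loops from polar residues (no S or D, so no spurious
## retinal-binding motif can arise), with K/R placed only on the cytoplasmic
## side to force the intended orientation; read start positions follow an
## exponential ori->ter gradient parameterized directly by the ori:ter
## density ratio; ANI matrices draw intra- and inter-cluster values from
## disjoint ranges straddling the clustering threshold.

#' Generate a synthetic bin with planted contamination
#'
#' Contigs are assigned roles: clean (about 90% of genes in the dominant
#' class), foreign (20% dominant, i.e. below the 30% vote floor and removed
#' by decontamination), viral (40% viral genes, above the 25% ceiling),
#' unassigned (no taxonomy hits; retained and flagged), and, optionally, two
#' exact-boundary contigs sitting at exactly 30% dominant and exactly 25%
#' viral (both retained under the strict inequalities). Every assigned gene
#' also receives a synthetic hit table whose best passing hit carries the
#' planted class, plus a decoy passing hit and a high-bitscore hit failing
#' the e-value criterion.
#'
#' @param seed integer seed.
#' @param nContigs number of contigs (>= 1).
#' @param genesPerContig genes per contig; must make the planted fractions
#'   representable (divisible by 20 when \code{boundary = TRUE}).
#' @param dominantClass label of the planted dominant class.
#' @param foreignFrac,viralFrac fractions of contigs planted as foreign /
#'   viral (each \code{round(frac * nContigs)} contigs).
#' @param unassignedContigs number of contigs with no taxonomy hits.
#' @param boundary plant the two exact-boundary contigs.
#' @param foreignClasses labels used for non-dominant genes.
#' @param geneLen,spacer gene length and intergenic spacer, bases.
#' @param binId bin identifier.
#' @return list with \code{bin} (a \linkS4class{Bin}), \code{hits} (per-gene
#'   hit association as from \code{\link{readHitTable}}), and \code{truth}
#'   (roles per contig: \code{foreign}, \code{viral}, \code{unassigned},
#'   \code{boundary}, \code{clean}, plus \code{dominant}).
#' @export
makeBin <- function(seed, nContigs = 12, genesPerContig = 10,
                    dominantClass = "c__Paceibacteria",
                    foreignFrac = 0, viralFrac = 0,
                    unassignedContigs = 0L, boundary = FALSE,
                    foreignClasses = c("c__Gammaproteobacteria",
                                       "c__Alphaproteobacteria",
                                       "c__Bacteroidia"),
                    geneLen = 900, spacer = 100,
                    binId = sprintf("bin_%05d", seed)) {
    if (nContigs < 1) stop("nContigs must be >= 1")
    stopifnot(foreignFrac >= 0, foreignFrac <= 1,
              viralFrac >= 0, viralFrac <= 1)
    nForeign <- round(foreignFrac * nContigs)
    nViral <- round(viralFrac * nContigs)
    nBoundary <- if (boundary) 2L else 0L
    if (boundary && (genesPerContig %% 20L != 0L))
        stop("boundary contigs need genesPerContig divisible by 20 ",
             "so 30% and 25% are exactly representable")
    nClean <- nContigs - nForeign - nViral - unassignedContigs - nBoundary
    if (nClean < 1)
        stop("planted roles exceed nContigs (need >= 1 clean contig)")
    set.seed(seed)
    roles <- sample(c(rep("foreign", nForeign), rep("viral", nViral),
                      rep("unassigned", unassignedContigs),
                      if (boundary) c("boundary_tax", "boundary_viral"),
                      rep("clean", nClean)))
    ctgLen <- spacer + genesPerContig * (geneLen + spacer)
    ctgIds <- sprintf("%s_c%03d", binId, seq_len(nContigs))
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(nContigs), function(i)
        paste(sample(c("A", "C", "G", "T"), ctgLen, replace = TRUE),
              collapse = ""), character(1)))
    names(seqs) <- ctgIds
    gene_rows <- list(); hits <- list()
    n <- genesPerContig
    for (i in seq_len(nContigs)) {
        ids <- sprintf("%s_g%02d", ctgIds[i], seq_len(n))
        starts <- spacer + (seq_len(n) - 1L) * (geneLen + spacer) + 1L
        cls <- switch(roles[i],
            clean = , viral = , boundary_viral = {
                nd <- ceiling(0.9 * n)
                c(rep(dominantClass, nd),
                  sample(foreignClasses, n - nd, replace = TRUE))
            },
            foreign = {
                nd <- floor(0.2 * n)
                other <- sample(foreignClasses, 1)
                c(rep(dominantClass, nd), rep(other, n - nd))
            },
            boundary_tax = {
                nd <- round(0.3 * n)
                c(rep(dominantClass, nd),
                  sample(foreignClasses, n - nd, replace = TRUE))
            },
            unassigned = rep(NA_character_, n))
        cls <- sample(cls)
        viral_flags <- rep(FALSE, n)
        if (roles[i] == "viral")
            viral_flags[sample.int(n, ceiling(0.4 * n))] <- TRUE
        if (roles[i] == "boundary_viral")
            viral_flags[sample.int(n, round(0.25 * n))] <- TRUE
        gene_rows[[i]] <- data.frame(gene_id = ids, contig_id = ctgIds[i],
            start = starts, end = starts + geneLen - 1L,
            strand = rep_len(c("+", "-"), n),
            protein_length = as.integer(geneLen / 3),
            best_hit_class = cls, viral = viral_flags,
            stringsAsFactors = FALSE)
        for (k in seq_len(n)) {
            if (is.na(cls[k])) next
            decoy <- sample(setdiff(foreignClasses, cls[k]), 1)
            hits[[ids[k]]] <- data.frame(
                subject = paste0("ref_", ids[k], "_", 1:3),
                evalue = c(5e-2, 1e-20, 1e-8),
                similarity = c(80, 60, 35),
                coverage = c(95, 90, 60),
                bitscore = c(300, 120, 70),
                subject_class = c(decoy, cls[k], decoy),
                stringsAsFactors = FALSE)
        }
    }
    bin <- Bin(binId, seqs, do.call(rbind, gene_rows))
    truth <- list(
        foreign = sort(ctgIds[roles == "foreign"]),
        viral = sort(ctgIds[roles == "viral"]),
        unassigned = sort(ctgIds[roles == "unassigned"]),
        boundary = sort(ctgIds[startsWith(roles, "boundary")]),
        clean = sort(ctgIds[roles == "clean"]),
        roles = stats::setNames(roles, ctgIds),
        dominant = dominantClass)
    list(bin = bin, hits = hits, truth = truth)
}

#' Generate a 43-marker profile at target completeness and contamination
#'
#' Targets are snapped to the nearest value representable on the 43-marker
#' grid (\code{round(pct / 100 * 43)} markers); the quality estimator applied
#' to the output recovers them exactly.
#'
#' @param seed integer seed.
#' @param completeness target percent in [0, 100].
#' @param contamination target percent (duplicated markers; must not exceed
#'   the completeness target).
#' @param markers the 43 marker ids.
#' @param dupIdentity percent amino-acid identity planted for duplicate
#'   copies (>= 90 makes duplicates count as strain heterogeneity).
#' @return an \linkS4class{SCGProfile}.
#' @export
makeScgProfile <- function(seed, completeness, contamination = 0,
                           markers = defaultScgMarkers(),
                           dupIdentity = 95) {
    if (completeness > 100 || completeness < 0)
        stop("completeness must lie in [0, 100]")
    if (contamination < 0) stop("contamination must be >= 0")
    nm <- length(markers)
    nPresent <- round(completeness / 100 * nm)
    nDup <- round(contamination / 100 * nm)
    if (nDup > nPresent)
        stop("contamination target exceeds completeness target ",
             "(cannot duplicate an absent marker)")
    set.seed(seed)
    counts <- stats::setNames(integer(nm), markers)
    present <- sample(markers, nPresent)
    counts[present] <- 1L
    dup <- if (nDup) sample(present, nDup) else character()
    counts[dup] <- 2L
    idents <- if (length(dup))
        stats::setNames(lapply(dup, function(m) dupIdentity), dup)
    else list()
    methods::new("SCGProfile", counts = counts, identities = idents)
}

#' Simulate reads with an optional ori->ter coverage gradient
#'
#' Read start positions are drawn from an exponential density along the
#' genome whose ori:ter density ratio equals \code{ptr} (\code{ptr = 1} is
#' uniform); the expected total bases equal \code{depth * genome length}.
#' Reads are error-free and ungapped by default; an optional substitution
#' rate exists for robustness tests.
#'
#' @param seed integer seed.
#' @param genome a \link[Biostrings]{DNAString}, single-sequence
#'   \code{DNAStringSet}, or character string.
#' @param depth target fold coverage (> 0; tiny depths may yield zero
#'   reads, a valid empty result).
#' @param readLen read length, bases; longer than the genome is an error.
#' @param ptr planted ori:ter coverage ratio (>= 1).
#' @param errorRate per-base substitution probability.
#' @param rcFrac fraction of reads reverse-complemented.
#' @param positionsOnly skip sequence extraction and return positions only
#'   (sufficient for window-coverage work).
#' @return list with \code{reads} (\code{DNAStringSet}, NULL when
#'   \code{positionsOnly}), \code{positions} (1-based starts), and
#'   \code{truth} (ptr, depth, readLen, genomeLength, nReads).
#' @export
simulateReads <- function(seed, genome, depth, readLen = 150, ptr = 1,
                          errorRate = 0, rcFrac = 0.5,
                          positionsOnly = FALSE) {
    if (methods::is(genome, "DNAStringSet")) {
        stopifnot(length(genome) == 1L)
        genome <- genome[[1]]
    }
    if (is.character(genome)) genome <- Biostrings::DNAString(genome)
    L <- length(genome)
    if (readLen > L) stop("readLen exceeds genome length")
    if (ptr < 1) stop("ptr must be >= 1")
    if (depth < 0) stop("depth must be >= 0")
    set.seed(seed)
    nReads <- round(depth * L / readLen)
    Lp <- L - readLen + 1L
    if (nReads == 0L) {
        return(list(reads = if (positionsOnly) NULL else
                        Biostrings::DNAStringSet(),
                    positions = integer(),
                    truth = list(ptr = ptr, depth = depth, readLen = readLen,
                                 genomeLength = L, nReads = 0L)))
    }
    u <- stats::runif(nReads)
    if (ptr == 1) {
        pos <- floor(u * Lp) + 1L
    } else {
        lam <- log(ptr) / L
        x <- -log(1 - u * (1 - exp(-lam * Lp))) / lam
        pos <- pmin(floor(x) + 1L, Lp)
    }
    reads <- NULL
    if (!positionsOnly) {
        reads <- Biostrings::extractAt(genome,
            IRanges::IRanges(start = pos, width = readLen))
        names(reads) <- sprintf("read_%06d", seq_len(nReads))
        rc <- stats::runif(nReads) < rcFrac
        if (any(rc))
            reads[rc] <- Biostrings::reverseComplement(reads[rc])
        if (errorRate > 0) {
            chars <- c("A", "C", "G", "T")
            for (i in which(stats::rbinom(nReads, readLen, errorRate) > 0)) {
                nmut <- stats::rbinom(1, readLen, errorRate)
                if (nmut == 0) next
                at <- sample.int(readLen, nmut)
                reads[[i]] <- Biostrings::replaceLetterAt(reads[[i]], at,
                    paste(sample(chars, nmut, replace = TRUE), collapse = ""))
            }
        }
    }
    list(reads = reads, positions = pos,
         truth = list(ptr = ptr, depth = depth, readLen = readLen,
                      genomeLength = L, nReads = nReads))
}

#' Construct a synthetic 7-transmembrane protein
#'
#' Builds a protein the topology predictor and motif scanner solve by
#' construction: helices of strongly hydrophobic residues (I/L/V/F, 21-25
#' residues), loops of clearly hydrophilic residues (N/Q/P, 14-18 residues;
#' tails 10-14) free of serine and aspartate, and two K/R residues per
#' cytoplasmic loop to force the orientation. An ion pump carries DLVAK in helix 7 with
#' an extracellular N-terminus; a heliorhodopsin carries one of the motifs
#' SLVAK, SLIAK or SFVAK with a cytoplasmic N-terminus; a decoy either has a
#' non-7 helix count or lacks the motif.
#'
#' @param seed integer seed.
#' @param kind "pump", "helio" or "decoy".
#' @param nHelices helix count (>= 0; only decoys may deviate from 7).
#' @param decoyMode for decoys: "helix_count" (nHelices defaults to 6) or
#'   "no_motif" (7 helices, motif absent).
#' @return list with \code{seq} (character protein sequence) and
#'   \code{truth} (kind, expected call, motif, orientation, helix count).
#' @export
makeRhodopsinProtein <- function(seed, kind = c("pump", "helio", "decoy"),
                                 nHelices = NULL,
                                 decoyMode = c("helix_count", "no_motif")) {
    kind <- match.arg(kind)
    decoyMode <- match.arg(decoyMode)
    if (!is.null(nHelices) && nHelices < 0) stop("nHelices must be >= 0")
    if (is.null(nHelices))
        nHelices <- if (kind == "decoy" && decoyMode == "helix_count") 6L
                    else 7L
    if (kind != "decoy" && nHelices != 7L)
        stop("pump and helio constructions require 7 helices")
    set.seed(seed)
    ## helix residues are strongly hydrophobic (KD >= 2.8) and loop
    ## residues clearly hydrophilic (KD <= -1.6): a 19-residue window then
    ## reaches the helix threshold iff it lies fully inside a true helix,
    ## so predicted spans neither extend into loops nor merge across them
    hydro <- c("I", "L", "V", "F")
    polar <- c("N", "Q", "P")
    helixLens <- sample(21:25, nHelices, replace = TRUE)
    loopLens <- sample(14:18, max(nHelices - 1L, 0L), replace = TRUE)
    tailLens <- sample(10:14, 2L, replace = TRUE)
    ## cytoplasmic loops: side 0 = N-terminal side (loops 0, 2, 4, ...)
    insideSide <- switch(kind, pump = 1L, helio = 0L,
                         decoy = sample(0:1, 1))
    motif <- switch(kind,
        pump = "DLVAK",
        helio = sample(c("SLVAK", "SLIAK", "SFVAK"), 1),
        decoy = if (decoyMode == "helix_count") "DLVAK" else NULL)
    make_loop <- function(len, side) {
        res <- sample(polar, len, replace = TRUE)
        if (side == insideSide && len >= 10) {
            ## keep charges away from helix edges so hydropathy-span
            ## jitter never swallows them into a predicted helix
            at <- sample.int(len - 8L, 2L) + 4L
            res[at] <- sample(c("K", "R"), 2L, replace = TRUE)
        }
        res
    }
    make_helix <- function(len, with_motif = FALSE) {
        res <- sample(hydro, len, replace = TRUE)
        if (with_motif) {
            at <- sample(6:(len - 9), 1)   # keep motif >= 5 from both ends
            res[at:(at + 4L)] <- strsplit(motif, "")[[1]]
        }
        res
    }
    pieces <- list(make_loop(tailLens[1], 0L))
    for (i in seq_len(nHelices)) {
        motif_here <- !is.null(motif) && i == nHelices
        pieces <- c(pieces, list(make_helix(helixLens[i], motif_here)))
        side <- i %% 2L
        len <- if (i < nHelices) loopLens[i] else tailLens[2]
        pieces <- c(pieces, list(make_loop(len, side)))
    }
    seq <- paste(unlist(pieces), collapse = "")
    expected <- switch(kind,
        pump = "ion_pump",
        helio = "heliorhodopsin",
        decoy = if (decoyMode == "helix_count") "rejected"
                else "rhodopsin_like_unclassified")
    list(seq = seq,
         truth = list(kind = kind, expectedCall = expected,
                      motif = if (is.null(motif)) "none" else motif,
                      orientation = if (insideSide == 0L) "N-in" else "N-out",
                      nHelices = nHelices))
}

#' Generate a symmetric ANI matrix with planted clusters
#'
#' Within-cluster pairs draw from \code{intra}, between-cluster pairs from
#' \code{inter}; the ranges must straddle the threshold disjointly
#' (otherwise the planted truth would be ambiguous), so single-linkage
#' clustering at the threshold recovers \code{clusterSizes} exactly.
#'
#' @param seed integer seed.
#' @param clusterSizes integer vector of planted cluster sizes.
#' @param intra range (min, max) of within-cluster ANI, entirely above the
#'   threshold.
#' @param inter range of between-cluster ANI, entirely at or below the
#'   threshold.
#' @param threshold clustering threshold (strict >).
#' @return list with \code{ani} (matrix, diagonal 100) and \code{truth}
#'   (named membership vector).
#' @export
makeAniMatrix <- function(seed, clusterSizes, intra = c(99.2, 99.8),
                          inter = c(95, 98), threshold = 99) {
    stopifnot(length(intra) == 2L, length(inter) == 2L,
              intra[1] <= intra[2], inter[1] <= inter[2],
              all(clusterSizes >= 1L))
    if (inter[2] >= intra[1])
        stop("intra and inter ANI ranges overlap; planted truth ambiguous")
    if (!(intra[1] > threshold && inter[2] <= threshold))
        stop("ranges must straddle the threshold: intra entirely above, ",
             "inter at or below")
    set.seed(seed)
    n <- sum(clusterSizes)
    ids <- sprintf("g%03d", seq_len(n))
    membership <- rep(seq_along(clusterSizes), clusterSizes)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        rng <- if (membership[i] == membership[j]) intra else inter
        m[i, j] <- m[j, i] <- stats::runif(1, rng[1], rng[2])
    }
    diag(m) <- 100
    list(ani = m, truth = stats::setNames(membership, ids))
}

#' Default lifestyle-group trait parameters
#'
#' Location (median) and scale per trait and category, emulating freshwater
#' CPR genomes (estimated size median 1.02 Mbp, coding density median
#' 89.47%, GC median 42.04%) alongside free-living freshwater bacteria and
#' symbionts/parasites (lower coding density, median near 76%).
#'
#' @return named list of per-category parameter lists, each entry a
#'   \code{c(location, scale)} pair.
#' @export
defaultTraitGroupParams <- function() {
    list(
        CPR = list(estimated_genome_size = c(1.02e6, 3.5e5),
                   gc = c(42.04, 8), coding_density = c(89.47, 3.5)),
        free_living = list(estimated_genome_size = c(3.0e6, 8e5),
                           gc = c(48, 9), coding_density = c(93, 2.5)),
        symbiont = list(estimated_genome_size = c(1.1e6, 4e5),
                        gc = c(35, 7), coding_density = c(76, 8)))
}

#' Generate a trait table for lifestyle-group comparison
#'
#' Traits are drawn from normal distributions at the given location/scale
#' (so sample medians estimate the locations); CPR-like genomes get partial
#' completeness (uniform 40-85%, matching assembly lengths shorter than
#' estimated sizes), reference categories near-complete genomes.
#'
#' @param seed integer seed.
#' @param nPerGroup genomes per category (>= 1).
#' @param groupParams per-category locations and scales, as
#'   \code{\link{defaultTraitGroupParams}}.
#' @return list with \code{traits} (data.frame as \code{\link{computeTraits}}
#'   rows) and \code{truth} (the parameters used).
#' @export
makeTraitTable <- function(seed, nPerGroup = 50,
                           groupParams = defaultTraitGroupParams()) {
    if (nPerGroup < 1) stop("nPerGroup must be >= 1")
    set.seed(seed)
    rows <- lapply(names(groupParams), function(cat) {
        p <- groupParams[[cat]]
        est <- pmax(stats::rnorm(nPerGroup, p$estimated_genome_size[1],
                                 p$estimated_genome_size[2]), 1e5)
        gc <- pmin(pmax(stats::rnorm(nPerGroup, p$gc[1], p$gc[2]), 1), 99)
        cd <- pmin(pmax(stats::rnorm(nPerGroup, p$coding_density[1],
                                     p$coding_density[2]), 1), 100)
        comp <- if (cat == "CPR") stats::runif(nPerGroup, 40, 85)
                else stats::runif(nPerGroup, 90, 100)
        assembly <- est * comp / 100
        data.frame(genome_id = sprintf("%s_%03d", cat, seq_len(nPerGroup)),
                   assembly_length = round(assembly),
                   estimated_genome_size = round(est), gc = gc,
                   coding_density = cd,
                   n_genes = round(assembly * cd / 100 / 1000),
                   completeness = comp, category = cat,
                   stringsAsFactors = FALSE)
    })
    traits <- do.call(rbind, rows)
    rownames(traits) <- NULL
    list(traits = traits, truth = groupParams)
}

#' Generate synthetic CAZy annotations
#'
#' Per-genome gene counts are Poisson around the mean (15 genes per genome
#' by default) and families are drawn from fixed proportions dominated by
#' GT4 (35%) and GT2 (23%), with chitin-, cellulose- and mannose-degradation
#' families in the 1-3% range.
#'
#' @param seed integer seed.
#' @param nGenomes genome count.
#' @param meanPerGenome mean CAZy genes per genome.
#' @param familyProbs named numeric vector of family proportions (summing
#'   to 1).
#' @return data.frame with columns \code{genome_id}, \code{family}.
#' @export
makeCazyTable <- function(seed, nGenomes = 282, meanPerGenome = 15,
                          familyProbs = c(GT4 = 0.35, GT2 = 0.23,
                                          GT28 = 0.08, GH23 = 0.08,
                                          GT51 = 0.06, GH3 = 0.05,
                                          GH73 = 0.05, CBM50 = 0.041,
                                          GH18 = 0.028, GH5 = 0.02,
                                          GH38 = 0.011)) {
    set.seed(seed)
    counts <- stats::rpois(nGenomes, meanPerGenome)
    ids <- sprintf("mag_%03d", seq_len(nGenomes))
    data.frame(
        genome_id = rep(ids, counts),
        family = sample(names(familyProbs), sum(counts), replace = TRUE,
                        prob = familyProbs),
        stringsAsFactors = FALSE)
}
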