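test_that("makeBin plants contamination at the requested granularity", {
    ## no foreign contigs: every contig holds >= 30% dominant-class genes
    mb0 <- makeBin(1, nContigs = 10, genesPerContig = 10, foreignFrac = 0)
    g <- genes(mb0$bin)
    frac <- tapply(g$best_hit_class == mb0$truth$dominant, g$contig_id, mean)
    expect_true(all(frac >= 0.30))

    ## half foreign: exactly 5 of 10 contigs sit below the vote floor
    mb5 <- makeBin(2, nContigs = 10, genesPerContig = 10, foreignFrac = 0.5)
    g <- genes(mb5$bin)
    frac <- tapply(g$best_hit_class == mb5$truth$dominant, g$contig_id, mean)
    expect_equal(sum(frac < 0.30), 5)
    expect_length(mb5$truth$foreign, 5)

    expect_error(makeBin(1, nContigs = 0), "nContigs")
    expect_error(makeBin(1, nContigs = 10, genesPerContig = 10,
                         boundary = TRUE), "divisible by 20")
})

test_that("generators are byte-deterministic under a fixed seed", {
    f1 <- withr::local_tempfile(fileext = ".fa")
    f2 <- withr::local_tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(contigSequences(makeBin(9)$bin), f1)
    Biostrings::writeXStringSet(contigSequences(makeBin(9)$bin), f2)
    expect_identical(base::readBin(f1, n = file.size(f1), what = "raw"),
                     base::readBin(f2, n = file.size(f2), what = "raw"))

    g <- paste(rep("ACGT", 500), collapse = "")
    q1 <- withr::local_tempfile(fileext = ".fq")
    q2 <- withr::local_tempfile(fileext = ".fq")
    writeFastq(simulateReads(3, g, depth = 2, readLen = 50)$reads, q1)
    writeFastq(simulateReads(3, g, depth = 2, readLen = 50)$reads, q2)
    expect_identical(readLines(q1), readLines(q2))

    expect_identical(makeAniMatrix(4, c(3, 2))$ani,
                     makeAniMatrix(4, c(3, 2))$ani)
})

test_that("makeScgProfile snaps targets onto the 43-marker grid", {
    p <- makeScgProfile(1, 100, 0)
    expect_true(all(markerCounts(p) == 1L))

    p22 <- makeScgProfile(1, 51.16, 0)
    expect_equal(sum(markerCounts(p22) >= 1), 22)

    pdup <- makeScgProfile(1, 100, 4.65)
    expect_equal(sum(markerCounts(pdup) == 2), 2)
    expect_true(all(markerCounts(pdup) >= 1))

    expect_error(makeScgProfile(1, 101, 0), "completeness")
    expect_error(makeScgProfile(1, 10, 50), "exceeds")

    ## estimator recovers the nearest representable targets exactly
    set.seed(11)
    for (i in 1:25) {
        comp <- runif(1, 0, 100)
        cont <- runif(1, 0, comp / 2)
        q <- estimateQuality(makeScgProfile(100 + i, comp, cont))
        expect_equal(completeness(q), 100 * round(comp / 100 * 43) / 43)
        expect_equal(contamination(q), 100 * round(cont / 100 * 43) / 43)
    }
})

test_that("simulated reads follow the planted coverage gradient", {
    gen <- paste(sample(c("A", "C", "G", "T"), 2e5, replace = TRUE),
                 collapse = "")
    ## uniform: window coverages stay within Poisson-like noise of the mean
    sim <- simulateReads(5, gen, depth = 20, ptr = 1, positionsOnly = TRUE)
    wc <- windowCoverage(sim$positions, 2e5, 150)
    expect_equal(mean(wc), 20, tolerance = 0.05)
    expect_lt(stats::sd(wc) / mean(wc), 0.15)

    ## ptr 2: top/bottom decile window density ratio near 2
    sim2 <- simulateReads(5, gen, depth = 50, ptr = 2, positionsOnly = TRUE)
    wc2 <- windowCoverage(sim2$positions, 2e5, 5000)
    srt <- sort(wc2)
    ratio <- mean(srt[37:40]) / mean(srt[1:4])
    expect_gt(ratio, 1.5)
    expect_lt(ratio, 2.6)

    ## expected total bases = depth * genome length
    expect_equal(sim$truth$nReads * 150, 20 * 2e5, tolerance = 0.01)

    ## degenerate depth: possibly zero reads is a valid empty result
    tiny <- simulateReads(1, gen, depth = 1e-6)
    expect_length(tiny$positions, 0)
    expect_s4_class(tiny$reads, "DNAStringSet")

    expect_error(simulateReads(1, "ACGT", depth = 1, readLen = 10),
                 "exceeds")
    expect_error(simulateReads(1, gen, depth = 1, ptr = 0.5), "ptr")
})

test_that("synthetic proteins honor their construction guarantees", {
    for (s in 1:5) {
        pump <- makeRhodopsinProtein(s, "pump")
        expect_gt(nchar(pump$seq), 150)
        topo <- predictTopology(pump$seq)
        expect_equal(topo$nHelices, 7)
        expect_equal(topo$orientation, "N-out")

        helio <- makeRhodopsinProtein(s, "helio")
        topo2 <- predictTopology(helio$seq)
        expect_equal(topo2$nHelices, 7)
        expect_equal(topo2$orientation, "N-in")
        expect_true(helio$truth$motif %in% c("SLVAK", "SLIAK", "SFVAK"))
    }
    expect_error(makeRhodopsinProtein(1, "pump", nHelices = -1), "nHelices")
    expect_identical(makeRhodopsinProtein(2, "helio")$seq,
                     makeRhodopsinProtein(2, "helio")$seq)
})

test_that("planted ANI clusters are recoverable by construction", {
    mk <- makeAniMatrix(1, c(2, 1), intra = c(99.2, 99.8),
                        inter = c(95, 98))
    expect_equal(canon_clusters(clusterByAni(mk$ani, 99)),
                 list(c("g001", "g002"), "g003"))

    singles <- makeAniMatrix(2, c(1, 1, 1))
    expect_length(clusterByAni(singles$ani, 99), 3)

    expect_error(makeAniMatrix(1, c(2, 1), intra = c(97, 99.5),
                               inter = c(95, 98)), "overlap")
    expect_error(makeAniMatrix(1, c(2, 1), intra = c(99.2, 99.8),
                               inter = c(95, 99.5)), "overlap")
})

test_that("trait tables center on the requested group locations", {
    tt <- makeTraitTable(1, nPerGroup = 200)
    cpr <- tt$traits[tt$traits$category == "CPR", ]
    ## median within 3 standard errors (se of median ~ 1.25 sd / sqrt(n))
    se <- 1.25 * 3.5 / sqrt(200)
    expect_lt(abs(median(cpr$coding_density) - 89.47), 3 * se)
    se_gc <- 1.25 * 8 / sqrt(200)
    expect_lt(abs(median(cpr$gc) - 42.04), 3 * se_gc)
    expect_true(all(tt$traits$assembly_length <=
                    tt$traits$estimated_genome_size + 1))

    one <- makeTraitTable(2, nPerGroup = 1)
    expect_equal(nrow(one$traits), 3)

    degen <- makeTraitTable(3, nPerGroup = 10, groupParams = list(
        CPR = list(estimated_genome_size = c(1e6, 0), gc = c(42, 0),
                   coding_density = c(89.47, 0))))
    expect_true(all(degen$traits$coding_density == 89.47))
    expect_true(all(degen$traits$gc == 42))
    expect_error(makeTraitTable(1, nPerGroup = 0), "nPerGroup")
})
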