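mini_bin <- function(classes_by_contig, viral_by_contig = NULL) {
    ## build a bin from a list contig -> vector of gene classes (NA allowed)
    rows <- list()
    lens <- integer(0)
    for (ctg in names(classes_by_contig)) {
        cls <- classes_by_contig[[ctg]]
        n <- length(cls)
        viral <- if (is.null(viral_by_contig[[ctg]])) rep(FALSE, n)
                 else viral_by_contig[[ctg]]
        starts <- seq(1, by = 100, length.out = n)
        rows[[ctg]] <- data.frame(
            gene_id = sprintf("%s_g%02d", ctg, seq_len(n)),
            contig_id = ctg, start = starts, end = starts + 89,
            strand = "+", best_hit_class = cls, viral = viral,
            stringsAsFactors = FALSE)
        lens[ctg] <- max(starts) + 100
    }
    Bin("mini", lens, do.call(rbind, rows))
}

test_that("gene taxonomy keeps the best hit passing all four criteria", {
    cfg <- pipelineConfig()
    base_hit <- function(evalue = 1e-10, sim = 50, cov = 80, bits = 100,
                         cls = "ClassA")
        data.frame(subject = "s", evalue = evalue, similarity = sim,
                   coverage = cov, bitscore = bits, subject_class = cls)

    two <- rbind(base_hit(bits = 80, cls = "ClassA"),
                 base_hit(bits = 60, cls = "ClassB"))
    expect_equal(unname(assignGeneTaxonomy(list(g = two), cfg)), "ClassA")

    ## each criterion is a strict gate on its own
    expect_true(is.na(assignGeneTaxonomy(list(g = base_hit(bits = 49)), cfg)))
    expect_false(is.na(assignGeneTaxonomy(list(g = base_hit(bits = 50)), cfg)))
    expect_true(is.na(assignGeneTaxonomy(list(g = base_hit(evalue = 1e-2)), cfg)))
    expect_true(is.na(assignGeneTaxonomy(list(g = base_hit(sim = 9)), cfg)))
    expect_true(is.na(assignGeneTaxonomy(list(g = base_hit(cov = 9)), cfg)))

    ## a failing hit never outvotes a weaker passing one
    mixed <- rbind(base_hit(evalue = 5e-2, bits = 300, cls = "Wrong"),
                   base_hit(bits = 90, cls = "Right"))
    expect_equal(unname(assignGeneTaxonomy(list(g = mixed), cfg)), "Right")

    expect_length(assignGeneTaxonomy(list(), cfg), 0)
})

test_that("dominant class vote counts genes bin-wide with lexicographic ties", {
    b <- mini_bin(list(c1 = rep("ClassA", 6), c2 = rep("ClassB", 4)))
    expect_equal(dominantClass(b), "ClassA")

    tie <- mini_bin(list(c1 = rep("Beta", 5), c2 = rep("Alpha", 5)))
    expect_equal(dominantClass(tie), "Alpha")

    none <- mini_bin(list(c1 = rep(NA_character_, 3)))
    expect_error(dominantClass(none), "no taxonomically assigned")
})

test_that("decontamination removes contigs strictly below the 30% vote floor", {
    b <- mini_bin(list(
        keep_hi = rep("Dom", 10),
        drop_20 = c(rep("Dom", 2), rep("Other", 8)),
        keep_30 = c(rep("Dom", 3), rep("Other", 7)),
        flag_un = rep(NA_character_, 4)))
    out <- decontaminate(b)
    expect_equal(out$dominant, "Dom")
    expect_equal(out$removed, "drop_20")
    expect_equal(out$flagged, "flag_un")
    expect_setequal(contigNames(out$bin), c("keep_hi", "keep_30", "flag_un"))
    ## gene association pruned consistently
    expect_false(any(genes(out$bin)$contig_id == "drop_20"))

    ## idempotence: a second pass removes nothing
    again <- decontaminate(out$bin)
    expect_length(again$removed, 0)
})

test_that("the vote is computed once, before any removal", {
    ## Removing drop_a (all ClassB) would flip the majority if re-voted;
    ## single-pass semantics keep the original dominant class for every
    ## decision.
    b <- mini_bin(list(
        drop_a = c(rep("ClassA", 1), rep("ClassB", 9)),
        c2 = rep("ClassB", 3),
        c3 = rep("ClassA", 10)))
    ## bin-wide: ClassB 12, ClassA 11 -> dominant ClassB
    out <- decontaminate(b)
    expect_equal(out$dominant, "ClassB")
    ## c3 is 0% ClassB -> removed under the pre-removal vote
    expect_true("c3" %in% out$removed)
    expect_false("drop_a" %in% out$removed)
})

test_that("viral filter removes contigs strictly above 25% viral genes", {
    b <- mini_bin(
        list(v26 = rep("Dom", 100), v25 = rep("Dom", 100),
             clean = rep("Dom", 10)),
        list(v26 = c(rep(TRUE, 26), rep(FALSE, 74)),
             v25 = c(rep(TRUE, 25), rep(FALSE, 75))))
    out <- viralFilter(b)
    expect_equal(out$removed, "v26")
    expect_setequal(contigNames(out$bin), c("v25", "clean"))
})

test_that("SCG profiles count copies over the 43-marker set only", {
    cfg <- pipelineConfig()
    mk <- cfg@scgMarkerIds
    tab <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      marker_id = c(mk[1], mk[2], mk[2], "not_a_marker"))
    p <- scgProfile(tab, cfg)
    counts <- markerCounts(p)
    expect_equal(unname(counts[mk[1]]), 1L)
    expect_equal(unname(counts[mk[2]]), 2L)
    expect_equal(sum(counts), 3L)  # foreign marker ignored
    expect_true(all(markerCounts(scgProfile(tab[0, ], cfg)) == 0L))
})

test_that("quality estimation matches the spec formulas and strict gate", {
    cfg <- pipelineConfig()
    all43 <- setNames(rep(1L, 43), cfg@scgMarkerIds)
    q <- estimateQuality(all43, cfg)
    expect_equal(completeness(q), 100)
    expect_equal(contamination(q), 0)
    expect_true(passedQc(q))

    part <- all43; part[23:43] <- 0L
    q22 <- estimateQuality(part, cfg)
    expect_equal(completeness(q22), 100 * 22 / 43, tolerance = 1e-12)
    expect_true(passedQc(q22))

    dup3 <- all43; dup3[1:3] <- 2L
    q3 <- estimateQuality(dup3, cfg)
    expect_equal(contamination(q3), 100 * 3 / 43, tolerance = 1e-12)
    expect_false(passedQc(q3))  # 6.98 >= 5

    expect_error(estimateQuality(all43[1:40], cfg), "43")
})

test_that("strain heterogeneity counts near-identical duplicates only", {
    cfg <- pipelineConfig()
    mk <- cfg@scgMarkerIds
    tab <- data.frame(
        gene_id = paste0("g", 1:6),
        marker_id = c(mk[1], mk[1], mk[2], mk[2], mk[3], mk[3]),
        copy_identity = c(NA, 95, NA, 50, NA, 92))
    q <- estimateQuality(scgProfile(tab, cfg), cfg)
    ## 3 multi-copy markers, 2 with >= 90% identical extra copies
    expect_equal(strainHeterogeneity(q), 100 * 2 / 3, tolerance = 1e-12)
    ## no multi-copy markers -> 0
    q0 <- estimateQuality(makeScgProfile(1, 100, 0))
    expect_equal(strainHeterogeneity(q0), 0)
})

test_that("quality estimator equals the brute-force recount oracle", {
    set.seed(17)
    cfg <- pipelineConfig()
    for (i in 1:500) {
        counts <- sample(0:3, 43, replace = TRUE,
                         prob = c(0.3, 0.5, 0.15, 0.05))
        q <- estimateQuality(counts, cfg)
        o <- oracle_scg(counts)
        expect_equal(completeness(q), o$completeness)
        expect_equal(contamination(q), o$contamination)
        expect_identical(passedQc(q),
                         o$completeness > 40 && o$contamination < 5)
    }
})

test_that("completeness and contamination are monotone in profile edits", {
    set.seed(23)
    counts <- sample(0:2, 43, replace = TRUE)
    q <- estimateQuality(counts)
    absent <- which(counts == 0)
    if (length(absent)) {
        more <- counts; more[absent[1]] <- 1L
        expect_gte(completeness(estimateQuality(more)), completeness(q))
    }
    dup <- counts; dup[which(counts >= 1)[1]] <- dup[which(counts >= 1)[1]] + 1L
    expect_gte(contamination(estimateQuality(dup)), contamination(q))
})

test_that("qcBin chains decontamination, viral filter and quality gating", {
    mb <- makeBin(31, nContigs = 10, genesPerContig = 20,
                  foreignFrac = 0.2, viralFrac = 0.1)
    mk <- pipelineConfig()@scgMarkerIds
    surviving <- genes(mb$bin)
    surviving <- surviving[!(surviving$contig_id %in%
        c(mb$truth$foreign, mb$truth$viral)), ]
    markerTab <- data.frame(gene_id = surviving$gene_id[seq_len(30)],
                            marker_id = mk[c(1:30)])
    out <- qcBin(mb$bin, hits = mb$hits, markerTable = markerTab)
    expect_equal(out$removedTaxonomy, mb$truth$foreign)
    expect_equal(out$removedViral, mb$truth$viral)
    expect_equal(completeness(out$quality), 100 * 30 / 43, tolerance = 1e-12)
    expect_true(passedQc(out$quality))
    rep <- as.data.frame(out$quality)
    expect_equal(rep$n_contigs_removed_taxonomy, 2L)
    expect_equal(rep$n_contigs_removed_viral, 1L)
})
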