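test_that("readBin assembles a consistent bin from FASTA plus gene table", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">c1 some description", "ACGTACGTACGTACGTACGT",
                 ">c2", "GGGGCCCCAAAATTTT"), fa)
    gt <- withr::local_tempfile(fileext = ".tsv")
    genes <- data.frame(gene_id = paste0("g", 1:5),
                        contig_id = c("c1", "c1", "c1", "c2", "c2"),
                        start = c(1, 5, 11, 1, 9),
                        end = c(4, 10, 20, 8, 16),
                        strand = c("+", "-", "+", "+", "-"))
    write.table(genes, gt, sep = "\t", quote = FALSE, row.names = FALSE)
    b <- readBin(fa, gt, id = "bin1")
    expect_s4_class(b, "Bin")
    expect_length(contigNames(b), 2)
    expect_equal(nrow(genes(b)), 5)
    expect_equal(unname(contigLengths(b)), c(20L, 16L))

    ## gene beyond its contig end is a validation error naming the gene
    genes$end[4] <- 99
    write.table(genes, gt, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readBin(fa, gt), "g4")

    ## empty gene table: contigs intact, zero genes
    write.table(genes[0, ], gt, sep = "\t", quote = FALSE, row.names = FALSE)
    b0 <- readBin(fa, gt)
    expect_equal(nrow(genes(b0)), 0)
    expect_length(contigNames(b0), 2)
})

test_that("readBin rejects genes on unknown contigs and malformed FASTA", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">c1", "ACGT"), fa)
    gt <- withr::local_tempfile(fileext = ".tsv")
    write.table(data.frame(gene_id = "gX", contig_id = "nope", start = 1,
                           end = 2, strand = "+"),
                gt, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readBin(fa, gt), "gX")

    bad <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">c1", "ACGT", ">c1", "GGGG"), bad)
    write.table(data.frame(gene_id = "g1", contig_id = "c1", start = 1,
                           end = 2, strand = "+"),
                gt, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readBin(bad, gt), "c1")
})

test_that("hit tables parse grouped per query, keep order, and round-trip", {
    path <- withr::local_tempfile(fileext = ".tsv")
    rows <- c("geneA\ts1\t85.0\t100\t2\t0\t1\t100\t5\t104\t1e-30\t200\t95\tClassA",
              "geneA\ts2\t70.0\t100\t5\t0\t1\t100\t9\t108\t1e-10\t120\t90\tClassB",
              "geneA\ts3\t40.0\t80\t9\t0\t1\t80\t2\t81\t1e-05\t80\t60\tClassA")
    writeLines(rows, path)
    h <- readHitTable(path)
    expect_named(h, "geneA")
    expect_equal(nrow(h$geneA), 3)
    expect_equal(h$geneA$subject, c("s1", "s2", "s3"))
    expect_equal(h$geneA$bitscore, c(200, 120, 80))

    ## no row silently dropped: parsed hits equal input rows
    expect_equal(sum(vapply(h, nrow, integer(1))), length(rows))

    ## writer/reader round-trip is exact
    out <- withr::local_tempfile(fileext = ".tsv")
    writeHitTable(h, out)
    expect_identical(readHitTable(out), h)

    writeLines(character(), path)
    expect_length(readHitTable(path), 0)

    writeLines(sub("\t120\t", "\tNA\t", rows), path)
    expect_error(readHitTable(path), "line 2")
})

test_that("reports round-trip through writeReport/readReport", {
    q <- list(estimateQuality(makeScgProfile(1, 100, 0)),
              estimateQuality(makeScgProfile(2, 51.16, 0)))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeReport(q, path)
    back <- readReport(path)
    expect_equal(back$completeness, c(100, 100 * 22 / 43))
    expect_equal(back$passed, c(TRUE, TRUE))

    ## empty report: header-only file
    writeReport(as.data.frame(q[[1]])[0, ], path)
    expect_length(readLines(path), 1)
    expect_equal(nrow(readReport(path)), 0)

    ## data.frame round-trip is value-identical
    df <- data.frame(a = c(1.25, 2.5), b = c("x", "y"))
    writeReport(df, path)
    expect_identical(readReport(path), df)
})

test_that("configuration enforces its invariants and reads from file", {
    cfg <- pipelineConfig()
    expect_length(cfg@scgMarkerIds, 43)
    expect_identical(cfg@dominantClassMinFrac, 0.30)
    expect_identical(cfg@hitMinBitscore, 50)
    expect_error(pipelineConfig(viralMaxFrac = 1.5), "fraction")
    expect_error(pipelineConfig(scgMarkerIds = letters), "43")
    expect_error(pipelineConfig(completenessMin = 400), "percent")

    path <- withr::local_tempfile(fileext = ".cfg")
    writeLines(c("# study overrides", "aniThreshold = 98.5",
                 "readsSubsample = 1000000"), path)
    cfg2 <- readPipelineConfig(path)
    expect_equal(cfg2@aniThreshold, 98.5)
    expect_equal(cfg2@readsSubsample, 1e6)
    expect_equal(cfg2@completenessMin, 40)  # untouched default
    writeLines("noSuchKey = 1", path)
    expect_error(readPipelineConfig(path), "unknown config key")
})

test_that("ANI matrices read from square and long form equivalently", {
    mk <- makeAniMatrix(5, c(2, 2), intra = c(99.3, 99.7),
                        inter = c(96, 98))
    sq <- withr::local_tempfile(fileext = ".tsv")
    writeAniMatrix(mk$ani, sq)
    m1 <- readAniMatrix(sq)
    expect_equal(m1, mk$ani)

    lg <- withr::local_tempfile(fileext = ".tsv")
    ids <- rownames(mk$ani)
    pairs <- which(upper.tri(mk$ani), arr.ind = TRUE)
    write.table(data.frame(query = ids[pairs[, 1]],
                           reference = ids[pairs[, 2]],
                           ani = mk$ani[pairs]),
                lg, sep = "\t", quote = FALSE, row.names = FALSE)
    m2 <- readAniMatrix(lg)
    expect_equal(m2, mk$ani)
})

test_that("BED intervals convert to 1-based inclusive at the boundary", {
    path <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("c1\t0\t100", "c1\t4999\t6000"), path)
    iv <- readBed(path)
    expect_equal(iv$start, c(1, 5000))
    expect_equal(iv$end, c(100, 6000))
})

test_that("sub-seeds stay in the 32-bit integer range", {
    seeds <- vapply(c(1, 42, 2^28, 2^31 - 1),
                    function(s) deriveSeed(s, 7L), numeric(1))
    expect_true(all(seeds >= 0 & seeds < 2^31))
    expect_identical(deriveSeed(10, 3), deriveSeed(10, 3))
    expect_false(deriveSeed(10, 3) == deriveSeed(10, 4))
})
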