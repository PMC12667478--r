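test_that("readBed parses records, skips headers, reports bad lines", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("track name=demo", "# a comment",
                 "chr1\t100\t200\tpk1\t7", "chr1\t50\t80"), bed)
    gr <- readBed(bed)
    expect_length(gr, 2L)
    expect_equal(start(gr), c(51L, 101L))   # 1-based internally
    expect_equal(end(gr), c(80L, 200L))
    expect_equal(mcols(gr)$name[2], "pk1")

    writeLines("chr1\t200\t100", bed)
    expect_error(readBed(bed), "line 1")
    writeLines(c("chr1\t1\t10", "chr1\txx\t10"), bed)
    expect_error(readBed(bed), "line 2")
})

test_that("BED files round-trip bit-exactly through read/write", {
    set.seed(42)
    gr <- sort(randomIntervals(40))
    bed <- withr::local_tempfile(fileext = ".bed")
    writeBed(gr, bed)
    back <- readBed(bed)
    expect_identical(start(back), start(gr))
    expect_identical(end(back), end(gr))
    bed2 <- withr::local_tempfile(fileext = ".bed")
    writeBed(back, bed2)
    expect_identical(readLines(bed), readLines(bed2))
})

test_that("merge coalesces overlaps but keeps abutting intervals apart", {
    m <- mergeIntervals(gr0("chr1", c(100, 150), c(200, 300)))
    expect_length(m, 1L)
    expect_equal(c(start(m) - 1L, end(m)), c(100L, 300L))

    ab <- mergeIntervals(gr0("chr1", c(100, 200), c(200, 300)))
    expect_length(ab, 2L)   # half-open: no shared base

    set.seed(7)
    for (i in 1:25) {
        gr <- randomIntervals(500)
        m <- mergeIntervals(gr)
        expect_identical(mergeIntervals(m), m)        # idempotent
        # union of bases preserved, outputs disjoint (abutting allowed)
        expect_true(mergeMatchesOracle(gr, m, 10000L))
        # base count equals the boolean-union oracle's
        expect_identical(sum(width(m)), sum(perBaseMask(gr, 10000L)))
    }
})

test_that("filterOverlapping matches the per-base oracle and validates input", {
    a <- gr0("chr1", 100, 200)
    expect_length(filterOverlapping(a, gr0("chr1", 150, 160), 1), 1L)
    expect_length(filterOverlapping(a, gr0("chr1", 200, 300), 1), 0L)
    expect_error(filterOverlapping(a, a, 0), "min_overlap_bp")

    set.seed(11)
    for (i in 1:20) {
        anchor <- randomIntervals(30)
        other <- randomIntervals(30)
        ov <- perBaseOverlap(anchor, other, 10000L)
        for (k in c(1L, 5L, 50L)) {
            got <- filterOverlapping(anchor, other, k)
            expect_identical(sort(got), sort(anchor[ov >= k]))
        }
        expect_equal(overlapBases(anchor, other), as.integer(ov))
    }
})

test_that("distance to TSS points uses occupied bases and chrom identity", {
    gr <- gr0("chr1", 100000, 100800)
    # last occupied base is 100799, so the distance is 103000 - 100799
    expect_equal(distanceToPoints(gr, data.frame(chrom = "chr1",
                                                 pos = 103000)), 2201)
    expect_equal(distanceToPoints(gr, data.frame(chrom = "chr1",
                                                 pos = 100500)), 0)
    expect_equal(distanceToPoints(gr, data.frame(chrom = "chr2",
                                                 pos = 100500)), Inf)
    # upstream side measured from start
    expect_equal(distanceToPoints(gr, data.frame(chrom = "chr1",
                                                 pos = 99000)), 1000)
    # multiple points: minimum wins; boundary base at end-1 is distance 1
    pts <- data.frame(chrom = "chr1", pos = c(90000, 100800))
    expect_equal(distanceToPoints(gr, pts), 1)
})

test_that("gene linking window is half-open at the downstream edge", {
    loci <- gr0("chr1", 40000, 45000)
    mcols(loci)$region_id <- "L1"
    gene <- function(tss) data.frame(gene_id = "g1", chrom = "chr1",
                                     tss = tss, biotype = "protein_coding")
    expect_equal(nrow(linkGenesWithin(loci, gene(245100), 200000)), 0L)
    expect_equal(nrow(linkGenesWithin(loci, gene(244999), 200000)), 1L)
    expect_equal(nrow(linkGenesWithin(loci, gene(42000), 200000)), 1L)
    # exact window upstream of the start links (left edge closed) ...
    expect_equal(nrow(linkGenesWithin(loci, gene(0), 40000)), 1L)
    # ... but exact window past the end does not (right edge open)
    expect_equal(nrow(linkGenesWithin(loci, gene(85000), 40000)), 0L)
    expect_equal(nrow(linkGenesWithin(loci, gene(84999), 40000)), 1L)
    # biotype filter
    g <- gene(42000); g$biotype <- "lncRNA"
    expect_equal(nrow(linkGenesWithin(loci, g, 200000, "protein_coding")), 0L)
})

test_that("linking equals expand-then-contain, both ways", {
    set.seed(13)
    for (i in 1:10) {
        loci <- randomIntervals(10)
        mcols(loci)$region_id <- sprintf("L%02d", seq_along(loci))
        genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                            chrom = "toy",
                            tss = sample.int(10000L, 60) - 1L,
                            biotype = "protein_coding")
        w <- 500L
        links <- linkGenesWithin(loci, genes, w)
        for (j in seq_along(loci)) {
            s0 <- start(loci)[j] - 1L; e0 <- end(loci)[j]
            contained <- genes$gene_id[genes$tss >= s0 - w &
                                       genes$tss < e0 + w]
            got <- links$gene_id[links$locus_id ==
                                 mcols(loci)$region_id[j]]
            expect_setequal(got, contained)
        }
    }
})

test_that("gene table readers convert coordinates strand-correctly", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
      paste0("chr1\tsrc\tgene\t1001\t5000\t.\t+\t.\t",
             "gene_id \"gA\"; gene_name \"ALPHA\"; gene_biotype \"protein_coding\";"),
      paste0("chr1\tsrc\tgene\t2001\t7000\t.\t-\t.\t",
             "gene_id \"gB\"; gene_name \"BETA\"; gene_biotype \"lncRNA\";")),
      gtf)
    g <- readGtfGenes(gtf)
    expect_equal(g$tss, c(1000L, 6999L))    # +: start-1; -: end-1
    expect_equal(g$biotype, c("protein_coding", "lncRNA"))

    tsv <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(g[c("gene_id", "gene_name", "chrom", "strand",
                           "tss", "biotype")],
                       tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_equal(readGeneTable(tsv)$tss, g$tss)
})
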