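test_that("cell-type overlap stage keeps SOE coordinates, per-base exact", {
    expect_length(celltypeOverlapStage(GRanges(), randomIntervals(5)), 0L)
    soe <- gr0("chr1", 100, 200)
    kept <- celltypeOverlapStage(soe, gr0("chr1", 150, 250))
    expect_equal(c(start(kept) - 1L, end(kept)), c(100L, 200L))
    set.seed(21)
    for (i in 1:15) {
        soes <- randomIntervals(25)
        peaks <- randomIntervals(25)
        ov <- perBaseOverlap(soes, peaks, 10000L)
        expect_identical(sort(celltypeOverlapStage(soes, peaks)),
                         sort(soes[ov >= 1]))
    }
})

test_that("bulk DE filter applies signed-rank + BH with strict cutoffs", {
    set.seed(31)
    n <- 8
    des <- PairedDesign(paste0("P", 1:n), paste0("P", 1:n, "_T"),
                        paste0("P", 1:n, "_N"))
    base <- matrix(2^rnorm(3 * n, 4, 0.2), 3, n)
    expr <- cbind(base * matrix(c(6, 2, 1), 3, n), base)
    rownames(expr) <- c("up6x", "up2x_exact", "flat")
    colnames(expr) <- c(tumorSamples(des), normalSamples(des))
    # make the 2x gene land exactly at log2fc = 1 (pseudocount 0)
    cfg <- thresholdConfig(pseudocount = 0)
    res <- bulkDeFilter(expr, des, cfg)
    expect_true(res$pass[res$gene_id == "up6x"])
    expect_equal(res$log2fc[res$gene_id == "up2x_exact"], 1,
                 tolerance = 1e-12)
    expect_false(res$pass[res$gene_id == "up2x_exact"])  # strict > 1
    expect_false(res$pass[res$gene_id == "flat"])
    expect_equal(res$p[res$gene_id == "flat"], 1)        # all-zero diffs
})

test_that("cluster DE filter matches an independent rank-sum recomputation", {
    set.seed(41)
    ncell <- 200
    labels <- rep(c("squamous", "other"), c(60, 140))
    cells <- matrix(2^rnorm(20 * ncell, 3, 0.5), 20, ncell,
                    dimnames = list(sprintf("g%02d", 1:20),
                                    sprintf("c%03d", 1:ncell)))
    cells[1:4, labels == "squamous"] <- cells[1:4, labels == "squamous"] * 4
    res <- clusterDeFilter(cells = cells, labels = labels,
                           target = "squamous")
    expect_setequal(res$gene_id[res$pass], sprintf("g%02d", 1:4))
    # oracle: stats::wilcox.test + bonferroni, gene by gene
    for (g in c("g01", "g10")) {
        ref <- suppressWarnings(wilcox.test(cells[g, labels == "squamous"],
                                            cells[g, labels == "other"]))
        expect_equal(res$p[res$gene_id == g], ref$p.value, tolerance = 1e-6)
    }
    expect_equal(res$p_adjusted, pmin(1, res$p * 20), tolerance = 1e-12)
    expect_error(clusterDeFilter(cells = cells, labels = labels,
                                 target = "missing"), "unknown cluster")
    # precomputed-table route honours the same strict thresholds
    tab <- data.frame(gene_id = c("a", "b"), log2fc = c(1.2, 1.2),
                      p_adjusted = c(0.01, 0.2))
    expect_equal(clusterDeFilter(tab)$pass, c(TRUE, FALSE))
})

test_that("co-expression requires all TFs to pass jointly", {
    set.seed(51)
    n <- 12
    z <- rnorm(n)
    mk <- function(rho) sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
    expr <- rbind(tf1 = mk(0.95), tf2 = mk(0.95), tf3 = mk(0.95),
                  tf4 = mk(0.95),
                  good = mk(0.95), anti = -z, noise = rnorm(n),
                  konst = rep(2, n)) + 10
    colnames(expr) <- sprintf("s%02d", 1:n)
    got <- coexpressionFilter(expr, paste0("tf", 1:4),
                              c("good", "anti", "noise", "konst"))
    expect_identical(got$kept, "good")
    tab <- got$table
    expect_true(all(tab$r[tab$gene_id == "anti"] < 0))
    expect_true(all(is.na(tab$r[tab$gene_id == "konst"])))
    expect_false(any(tab$pass[tab$gene_id == "konst"]))
    # candidate identical to a TF: r = 1 against it
    got2 <- coexpressionFilter(rbind(expr, dup = expr["tf1", ]),
                               paste0("tf", 1:4), "dup")
    expect_equal(got2$table$r[got2$table$tf == "tf1"], 1)
})

test_that("the funnel recovers the planted oncogene and only it", {
    fx <- funnelFixture()
    co <- fx$co; tr <- fx$tr
    fr <- runFunnel(fx$parts$soes, co@clusterPeaks, co@genes,
                    co@expression, co@design, tr$tf_ids,
                    cells = co@clusterCells$matrix,
                    labels = co@clusterCells$labels,
                    target = tr$target_cluster)
    expect_identical(candidates(fr), tr$oncogene_id)
    # nesting of the gene stages
    expect_true(all(fr@stage4Genes %in% fr@stage3Genes))
    expect_true(all(fr@stage3Genes %in% fr@stage2Genes))
    # each decoy dies at exactly its designed stage
    aud <- auditTable(fr)
    dec <- fx$tr$decoys
    stage_of <- c(not_bulk_de = "bulk_de", not_cluster_de = "cluster_de",
                  not_coexpressed = "coexpression")
    for (i in seq_len(nrow(dec))) {
        if (dec$type[i] == "no_overlap") {
            expect_false(dec$gene_id[i] %in% fr@stage2Genes)
        } else {
            expect_equal(aud$failed_stage[aud$gene_id == dec$gene_id[i]],
                         unname(stage_of[[dec$type[i]]]))
        }
    }
    # ablation: removing the oncogene SOE/peak overlap empties stage 4
    onco_soe <- celltypeOverlapStage(fx$parts$soes, co@clusterPeaks)
    keep_peaks <- co@clusterPeaks[overlapBases(co@clusterPeaks,
        fx$parts$soes[mcols(fx$parts$soes)$region_id %in%
            mcols(onco_soe)$region_id[1]]) == 0]
    fr2 <- runFunnel(fx$parts$soes, keep_peaks, co@genes, co@expression,
                     co@design, tr$tf_ids,
                     cells = co@clusterCells$matrix,
                     labels = co@clusterCells$labels,
                     target = tr$target_cluster)
    expect_lt(length(fr2@loci), length(fr@loci))
})

test_that("the funnel is invariant to input permutations", {
    fx <- funnelFixture()
    co <- fx$co; tr <- fx$tr
    run <- function(expr, genes, cells, labels) {
        runFunnel(fx$parts$soes, co@clusterPeaks, genes, expr, co@design,
                  tr$tf_ids, cells = cells, labels = labels,
                  target = tr$target_cluster)
    }
    base <- run(co@expression, co@genes, co@clusterCells$matrix,
                co@clusterCells$labels)
    set.seed(61)
    gperm <- sample(nrow(co@expression))
    sperm <- sample(ncol(co@expression))
    cperm <- sample(ncol(co@clusterCells$matrix))
    perm <- run(co@expression[gperm, sperm],
                co@genes[sample(nrow(co@genes)), ],
                co@clusterCells$matrix[gperm, cperm],
                co@clusterCells$labels[cperm])
    expect_identical(candidates(perm), candidates(base))
    expect_identical(stageCounts(perm), stageCounts(base))
})

test_that("relaxed thresholds collapse the funnel stages", {
    fx <- funnelFixture()
    co <- fx$co; tr <- fx$tr
    cfg <- thresholdConfig()
    cfg$deg_log2fc <- -Inf; cfg$cluster_log2fc <- -Inf
    cfg$deg_padj <- 1 + 1e-9
    cfg$coexpr_r <- -Inf; cfg$coexpr_padj <- 1 + 1e-9
    fr <- runFunnel(fx$parts$soes, co@clusterPeaks, co@genes,
                    co@expression, co@design, tr$tf_ids,
                    cells = co@clusterCells$matrix,
                    labels = co@clusterCells$labels,
                    target = tr$target_cluster, cfg = cfg)
    expect_setequal(fr@stage3Genes, fr@stage2Genes)
    defined_r <- fr@audit$gene_id[!is.na(fr@audit[[paste0("r_",
                                                  tr$tf_ids[1])]])]
    expect_setequal(fr@stage4Genes, intersect(fr@stage3Genes, defined_r))
})
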