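#' Simulation configuration
#'
#' Parameters of the synthetic paired tumor/normal cohort. Defaults encode
#' the study conditions the pipeline is built for: 18 matched pairs, 500
#' enhancer-sized regions on one 10 Mb toy chromosome, 10% planted
#' cancer-gained and 10% cancer-depleted regions with log2 fold changes
#' drawn from N(1.5, 0.3) / N(-1.5, 0.3), negative-binomial counts with a
#' shared lognormal patient effect (what makes the paired test the right
#' analysis), per-sample stochastic peak detection, four master-TF
#' expression vectors plus a planted oncogene correlated with all four,
#' and cluster-specific accessible peaks over a positional subset of the
#' planted gained regions.
#'
#' @param seed integer seed; a fixed seed gives byte-identical fixtures.
#' @param n_patients number of tumor/normal pairs.
#' @param n_regions number of candidate enhancer regions.
#' @param frac_soe,frac_cde fractions of regions with planted gain/loss.
#' @param soe_log2fc_mean,soe_log2fc_sd planted gain effect distribution.
#' @param cde_log2fc_mean,cde_log2fc_sd planted loss effect distribution.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param detection_prob per-sample, per-mark peak detection probability.
#' @param peak_jitter_bp max peak boundary jitter (bp, each side).
#' @param chrom,chrom_length toy genome geometry (single chromosome).
#' @param region_width,region_spacing,region_start region grid (0-based).
#' @param n_genes genes on the TSS grid (midway between regions, so
#'   ordinary regions sit ~7.8 kb from the nearest TSS).
#' @param n_proximal_regions stable regions given an internal (lncRNA) TSS
#'   to exercise the TSS exclusion filter.
#' @param baseline_log2_rpkm_mean,baseline_log2_rpkm_sd region baseline
#'   signal distribution (log2 RPKM).
#' @param patient_effect_sd sd of the shared lognormal patient factor.
#' @param library_size_meanlog,library_size_sdlog lognormal library sizes.
#' @param tf_target_corr latent correlation among the master TFs and the
#'   planted oncogene across tumor samples. The default is high enough
#'   that, with 18 tumor samples, the planted co-expression is reliably
#'   detectable at r > 0.5 with BH-adjusted p < 0.05 inside a short
#'   candidate list -- the property the planted oncogene must satisfy by
#'   construction.
#' @param expr_base_log2_mean,expr_base_log2_sd gene baseline expression.
#' @param expr_noise_sd residual expression noise (log2).
#' @param expr_signal_sd scale (log2) of the shared-latent signal in the
#'   co-regulated genes; kept below `expr_noise_sd` so the raw-scale
#'   Pearson correlation stays close to the planted latent correlation.
#' @param planted_deg_log2fc tumor upshift of planted up-genes (log2).
#' @param n_bulk_de_only,n_cluster_de_only,n_both_de_background background
#'   genes that are bulk-DE only, cluster-DE only, or both (the both-DE
#'   background is what the co-expression stage must reject).
#' @param n_target_cells,n_other_cells cluster cell-matrix geometry.
#' @param cluster_cell_log2fc target-cluster upshift of cluster-DE genes.
#' @param cluster_cell_noise_sd per-cell noise (log2).
#' @param n_cluster_peaks_extra cluster peaks placed in region gaps (they
#'   overlap no enhancer and must not create funnel loci).
#' @return Named list of validated parameters (class `"simConfig"`).
#' @export
simConfig <- function(seed = 1L,
                      n_patients = 18L,
                      n_regions = 500L,
                      frac_soe = 0.10,
                      frac_cde = 0.10,
                      soe_log2fc_mean = 1.5, soe_log2fc_sd = 0.3,
                      cde_log2fc_mean = -1.5, cde_log2fc_sd = 0.3,
                      nb_dispersion = 0.05,
                      detection_prob = 0.9,
                      peak_jitter_bp = 50L,
                      chrom = "chrS",
                      chrom_length = 1e7,
                      region_width = 1200L,
                      region_spacing = 18000L,
                      region_start = 10000L,
                      n_genes = 300L,
                      n_proximal_regions = 10L,
                      baseline_log2_rpkm_mean = 2.3,
                      baseline_log2_rpkm_sd = 0.8,
                      patient_effect_sd = 0.3,
                      library_size_meanlog = log(2e7),
                      library_size_sdlog = 0.2,
                      tf_target_corr = 0.95,
                      expr_base_log2_mean = 3,
                      expr_base_log2_sd = 1,
                      expr_noise_sd = 1,
                      expr_signal_sd = 0.5,
                      planted_deg_log2fc = 2.0,
                      n_bulk_de_only = 30L,
                      n_cluster_de_only = 20L,
                      n_both_de_background = 10L,
                      n_target_cells = 100L,
                      n_other_cells = 300L,
                      cluster_cell_log2fc = 1.5,
                      cluster_cell_noise_sd = 0.8,
                      n_cluster_peaks_extra = 35L) {
    cfg <- as.list(environment())
    if (cfg$frac_soe + cfg$frac_cde > 1)
        stop("frac_soe + frac_cde must be <= 1")
    if (cfg$detection_prob < 0 || cfg$detection_prob > 1)
        stop("detection_prob must lie in [0, 1]")
    if (cfg$tf_target_corr < 0 || cfg$tf_target_corr > 1)
        stop("tf_target_corr must lie in [0, 1]")
    span <- cfg$region_start + (cfg$n_regions - 1) * cfg$region_spacing +
        cfg$region_width
    if (span > cfg$chrom_length)
        stop("infeasible geometry: ", cfg$n_regions,
             " regions need ", span, " bp but the chromosome has ",
             cfg$chrom_length)
    class(cfg) <- "simConfig"
    cfg
}

## deterministic, evenly spread index subsets (no RNG involvement)
.spreadIdx <- function(pool, k) {
    if (k == 0L) return(integer(0))
    pool[unique(round(seq(1, length(pool), length.out = k)))]
}

#' Simulate a paired tumor/normal cohort
#'
#' Builds the full multi-omic fixture the pipeline consumes, entirely in
#' memory, together with its ground truth: per-sample dual-mark peak sets
#' (each true region emits a peak per mark with probability
#' `detection_prob`, boundaries jittered), negative-binomial region counts
#' with shared patient effects and planted log2 fold changes, a bulk
#' expression matrix in which four master TFs and a planted oncogene load
#' on a common latent factor across tumor samples, decoy genes violating
#' exactly one funnel criterion each, cluster-specific accessible peaks
#' over the left-positioned planted gains (always including the oncogene's
#' region, never the no-overlap decoy's), and a cluster cell matrix.
#'
#' @param cfg a [simConfig()].
#' @return A [SyntheticCohort-class].
#' @export
simulateCohort <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "simConfig"))
    set.seed(cfg$seed)
    n <- cfg$n_regions
    npat <- cfg$n_patients

    ## --- region grid (0-based starts) and planted classes -------------
    start0 <- cfg$region_start + (seq_len(n) - 1L) * cfg$region_spacing
    region_ids <- sprintf("region_%04d", seq_len(n))
    regions <- GRanges(cfg$chrom,
                       IRanges(start0 + 1L, width = cfg$region_width))
    names(regions) <- region_ids

    nSoe <- round(cfg$frac_soe * n)
    nCde <- round(cfg$frac_cde * n)
    soe_idx <- .spreadIdx(seq_len(n), nSoe)
    cde_idx <- .spreadIdx(setdiff(seq_len(n), soe_idx), nCde)
    stable_idx <- setdiff(seq_len(n), c(soe_idx, cde_idx))
    prox_idx <- .spreadIdx(stable_idx, min(cfg$n_proximal_regions,
                                           length(stable_idx)))

    true_lfc <- stats::setNames(numeric(n), region_ids)
    if (nSoe > 0)
        true_lfc[soe_idx] <- stats::rnorm(nSoe, cfg$soe_log2fc_mean,
                                          cfg$soe_log2fc_sd)
    if (nCde > 0)
        true_lfc[cde_idx] <- stats::rnorm(nCde, cfg$cde_log2fc_mean,
                                          cfg$cde_log2fc_sd)

    ## --- design and samples -------------------------------------------
    pats <- sprintf("P%02d", seq_len(npat))
    tum <- paste0(pats, "_T")
    nor <- paste0(pats, "_N")
    design <- PairedDesign(pats, tum, nor)
    samples <- c(tum, nor)
    grp <- rep(c("tumor", "normal"), each = npat)
    pat_of <- rep(pats, 2L)

    lib <- stats::rlnorm(2L * npat, cfg$library_size_meanlog,
                         cfg$library_size_sdlog)
    names(lib) <- samples
    pat_fac <- stats::rlnorm(npat, 0, cfg$patient_effect_sd)
    names(pat_fac) <- pats

    ## --- counts: NB around RPKM-scale means ---------------------------
    base_rpkm <- 2^stats::rnorm(n, cfg$baseline_log2_rpkm_mean,
                                cfg$baseline_log2_rpkm_sd)
    fc <- outer(true_lfc, as.numeric(grp == "tumor")) # log2 effect if tumor
    mu <- base_rpkm * (cfg$region_width / 1e3) *
        outer(rep(1, n), lib / 1e6) *
        outer(rep(1, n), pat_fac[pat_of]) * 2^fc
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / cfg$nb_dispersion),
                     nrow = n, dimnames = list(region_ids, samples))
    storage.mode(counts) <- "integer"

    ## --- gene grid and special genes ----------------------------------
    ngen <- cfg$n_genes
    gene_slot <- pmin(n, ceiling(seq_len(ngen) * n / ngen))
    gene_tss <- start0[gene_slot] + cfg$region_spacing %/% 2L
    gene_ids <- sprintf("g%04d", seq_len(ngen))
    gene_names <- sprintf("GENE%04d", seq_len(ngen))

    geneNear <- function(slot)
        max(1L, min(ngen, as.integer(round(slot * ngen / n))))
    reserve <- integer(0)
    claim <- function(slot) {
        g <- geneNear(slot)
        while (g %in% reserve) {
            g <- g + 1L
            if (g > ngen) g <- 1L
        }
        reserve <<- c(reserve, g)
        g
    }
    overlapped_soe <- soe_idx[start0[soe_idx] < 0.5 * cfg$chrom_length]
    decoy1_soe <- if (length(soe_idx)) soe_idx[length(soe_idx)] else NA
    overlapped_soe <- setdiff(overlapped_soe, decoy1_soe)
    ## with enough planted gains the oncogene/decoy layout is set up;
    ## otherwise (e.g. a null cohort) the funnel actors are omitted
    full_layout <- length(overlapped_soe) >= 4L

    tf_slots <- pmax(1L, as.integer(round(c(0.30, 0.42, 0.58, 0.70) * n)))
    if (full_layout) {
        onco_soe <- overlapped_soe[1L]
        g_onco <- claim(onco_soe)
        g_dec1 <- claim(decoy1_soe)
        g_dec2 <- claim(overlapped_soe[2L])
        g_dec3 <- claim(overlapped_soe[3L])
        g_dec4 <- claim(overlapped_soe[4L])
    } else {
        onco_soe <- NA_integer_
        g_onco <- g_dec1 <- g_dec2 <- g_dec3 <- g_dec4 <- integer(0)
        overlapped_soe <- integer(0)
    }
    g_tfs <- vapply(tf_slots, claim, integer(1))
    gene_names[g_tfs] <- c("TP63", "SOX2", "KLF5", "GRHL2")
    if (full_layout) {
        gene_names[g_onco] <- "SQONC1"
        gene_names[c(g_dec1, g_dec2, g_dec3, g_dec4)] <-
            sprintf("DECOY%d", 1:4)
    }

    genes <- data.frame(gene_id = gene_ids,
                        gene_name = gene_names,
                        chrom = cfg$chrom,
                        strand = rep(c("+", "-"), length.out = ngen),
                        tss = gene_tss,
                        biotype = "protein_coding",
                        stringsAsFactors = FALSE)
    if (length(prox_idx)) {   # lncRNA TSSs inside stable regions
        genes <- rbind(genes, data.frame(
            gene_id = sprintf("gx%02d", seq_along(prox_idx)),
            gene_name = sprintf("LNC%02d", seq_along(prox_idx)),
            chrom = cfg$chrom,
            strand = "+",
            tss = start0[prox_idx] + cfg$region_width %/% 2L,
            biotype = "lncRNA",
            stringsAsFactors = FALSE))
    }
    tss_pts <- geneTssPoints(genes)

    ## --- per-sample peaks ----------------------------------------------
    jit <- function(k) sample.int(2L * cfg$peak_jitter_bp + 1L, k,
                                  replace = TRUE) - cfg$peak_jitter_bp - 1L
    samplePeaks <- vector("list", length(samples))
    names(samplePeaks) <- samples
    for (si in seq_along(samples)) {
        marks <- list()
        for (mk in c("k4me1", "k27ac")) {
            det <- which(stats::runif(n) < cfg$detection_prob)
            k <- length(det)
            s <- pmax(0L, start0[det] + jit(k))
            e <- pmax(s + 1L, start0[det] + cfg$region_width + jit(k))
            marks[[mk]] <- sort(GRanges(cfg$chrom, IRanges(s + 1L, e)))
        }
        samplePeaks[[si]] <- list(group = grp[si], patient_id = pat_of[si],
                                  k4me1 = marks$k4me1, k27ac = marks$k27ac)
    }

    ## --- bulk expression ------------------------------------------------
    allg <- nrow(genes)
    pool <- setdiff(seq_len(ngen), reserve)
    bulk_only <- .spreadIdx(pool, min(cfg$n_bulk_de_only, length(pool)))
    pool <- setdiff(pool, bulk_only)
    clus_only <- .spreadIdx(pool, min(cfg$n_cluster_de_only, length(pool)))
    pool <- setdiff(pool, clus_only)
    both_bg <- .spreadIdx(pool, min(cfg$n_both_de_background, length(pool)))

    coexpr_set <- c(g_tfs, g_onco, g_dec1, g_dec2, g_dec3)
    bulk_up <- c(g_onco, g_dec1, g_dec3, g_dec4, g_tfs, bulk_only, both_bg)
    cluster_up <- c(g_onco, g_dec1, g_dec2, g_dec4, clus_only, both_bg)

    rho <- cfg$tf_target_corr
    base_e <- stats::rnorm(allg, cfg$expr_base_log2_mean,
                           cfg$expr_base_log2_sd)
    pi_p <- stats::rnorm(npat, 0, cfg$patient_effect_sd)
    z <- stats::rnorm(npat)                  # latent squamous activity
    lx <- matrix(stats::rnorm(allg * 2L * npat, 0, cfg$expr_noise_sd),
                 allg, 2L * npat, dimnames = list(genes$gene_id, samples))
    lx <- lx + base_e                        # per-gene baseline (row-wise)
    lx <- sweep(lx, 2L, pi_p[match(pat_of, pats)], "+")
    tumor_cols <- seq_len(npat)
    for (g in coexpr_set) {
        sig <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(npat)
        lx[g, tumor_cols] <- base_e[g] + pi_p + cfg$expr_signal_sd * sig
    }
    lx[bulk_up, tumor_cols] <- lx[bulk_up, tumor_cols, drop = FALSE] +
        cfg$planted_deg_log2fc
    expr <- round(2^lx, 6)

    ## --- cluster-specific peaks and cluster cell matrix -----------------
    ov_s <- pmax(0L, start0[overlapped_soe] - 100L)
    ov_e <- start0[overlapped_soe] + cfg$region_width + 100L
    gaps <- .spreadIdx(stable_idx[start0[stable_idx] >
                                  0.55 * cfg$chrom_length],
                       cfg$n_cluster_peaks_extra)
    gap_s <- start0[gaps] - 6000L
    clusterPeaks <- sort(GRanges(cfg$chrom,
        IRanges(c(ov_s, gap_s) + 1L,
                c(ov_e, gap_s + 500L))))

    ncell <- cfg$n_target_cells + cfg$n_other_cells
    labels <- c(rep("squamous", cfg$n_target_cells),
                rep("other", cfg$n_other_cells))
    cell_ids <- sprintf("cell_%04d", seq_len(ncell))
    cbase <- stats::rnorm(allg, cfg$expr_base_log2_mean,
                          cfg$expr_base_log2_sd)
    cl <- matrix(stats::rnorm(allg * ncell, 0, cfg$cluster_cell_noise_sd),
                 allg, ncell, dimnames = list(genes$gene_id, cell_ids))
    cl <- cl + cbase
    cl[cluster_up, labels == "squamous"] <-
        cl[cluster_up, labels == "squamous", drop = FALSE] +
        cfg$cluster_cell_log2fc
    cells <- round(2^cl, 6)

    truth <- list(planted_soe_ids = region_ids[soe_idx],
                  planted_cde_ids = region_ids[cde_idx],
                  stable_ids = region_ids[stable_idx],
                  proximal_ids = region_ids[prox_idx],
                  true_log2fc = true_lfc,
                  overlapped_soe_ids = if (full_layout)
                      region_ids[c(onco_soe,
                                   setdiff(overlapped_soe, onco_soe))]
                      else character(0),
                  oncogene_id = if (full_layout) gene_ids[g_onco]
                      else NA_character_,
                  tf_ids = gene_ids[g_tfs],
                  decoys = if (full_layout) data.frame(
                      gene_id = gene_ids[c(g_dec1, g_dec2, g_dec3, g_dec4)],
                      type = c("no_overlap", "not_bulk_de",
                               "not_cluster_de", "not_coexpressed"),
                      stringsAsFactors = FALSE)
                      else data.frame(gene_id = character(0),
                                      type = character(0),
                                      stringsAsFactors = FALSE),
                  bulk_de_up_ids = gene_ids[sort(unique(bulk_up))],
                  cluster_de_up_ids = gene_ids[sort(unique(cluster_up))],
                  target_cluster = "squamous")

    se <- regionCounts(counts,
                       region_lengths = rep(cfg$region_width, n),
                       library_sizes = lib,
                       row_ranges = regions,
                       col_data = data.frame(group = grp,
                                             patient_id = pat_of,
                                             row.names = samples))
    new("SyntheticCohort",
        samplePeaks = samplePeaks, counts = se, design = design,
        genes = genes, expression = expr, clusterPeaks = clusterPeaks,
        clusterCells = list(matrix = cells, labels = labels),
        truth = truth, config = unclass(cfg))
}

fmtNum <- function(x) sprintf("%.6f", x)

writeTsv <- function(df, path, num_cols = character(0)) {
    for (cc in num_cols) df[[cc]] <- fmtNum(df[[cc]])
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = "\t"), con)
    if (nrow(df))
        writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
    invisible(path)
}

writeMatrixTsv <- function(m, path, id_col) {
    df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
    colnames(df) <- id_col
    body <- apply(m, 2L, fmtNum)
    if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
    colnames(body) <- colnames(m)
    writeTsv(cbind(df, as.data.frame(body, stringsAsFactors = FALSE)), path)
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the plain-text formats the pipeline readers consume:
#' per-sample BED peak files (two marks), a cohort manifest, region
#' coordinates, counts / region-length / library-size TSVs, the design
#' TSV, the gene table, the bulk expression TSV, the cluster peak BED,
#' the cluster cell matrix with labels, a ready-to-run pipeline config
#' (`run.yaml`), and the ground-truth JSON. Counts
#' are written as integers and all reals at fixed 6-decimal formatting,
#' so identical configurations yield byte-identical files.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest of emitted files (`kind`, `path`),
#'   invisibly.
#' @export
writeFixtures <- function(cohort, out_dir) {
    dir.create(file.path(out_dir, "peaks"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(out_dir))
        stop("cannot create output directory: ", out_dir)
    emitted <- list()
    note <- function(kind, path)
        emitted[[length(emitted) + 1L]] <<- data.frame(
            kind = kind, path = path, stringsAsFactors = FALSE)

    sp <- cohort@samplePeaks
    man <- data.frame(sample_id = names(sp),
                      patient_id = vapply(sp, `[[`, character(1), "patient_id"),
                      group = vapply(sp, `[[`, character(1), "group"),
                      k4me1_path = file.path("peaks",
                          paste0(names(sp), "_k4me1.bed")),
                      k27ac_path = file.path("peaks",
                          paste0(names(sp), "_k27ac.bed")),
                      stringsAsFactors = FALSE)
    for (i in seq_along(sp)) {
        writeBed(sp[[i]]$k4me1, file.path(out_dir, man$k4me1_path[i]))
        writeBed(sp[[i]]$k27ac, file.path(out_dir, man$k27ac_path[i]))
        note("peaks", man$k4me1_path[i]); note("peaks", man$k27ac_path[i])
    }
    writeTsv(man, file.path(out_dir, "manifest.tsv"))
    note("table", "manifest.tsv")

    se <- cohort@counts
    rr <- SummarizedExperiment::rowRanges(se)
    mcols(rr)$name <- rownames(se)
    writeBed(rr, file.path(out_dir, "regions.bed"))
    note("bed", "regions.bed")
    cnt <- as.data.frame(SummarizedExperiment::assay(se, "counts"))
    cnt <- cbind(data.frame(region_id = rownames(se),
                            stringsAsFactors = FALSE), cnt)
    writeTsv(cnt, file.path(out_dir, "counts.tsv"))
    note("table", "counts.tsv")
    writeTsv(data.frame(region_id = rownames(se),
                        length = as.integer(
                            SummarizedExperiment::rowData(se)$region_length)),
             file.path(out_dir, "region_lengths.tsv"))
    note("table", "region_lengths.tsv")
    writeTsv(data.frame(sample_id = colnames(se),
                        library_size =
                            SummarizedExperiment::colData(se)$library_size),
             file.path(out_dir, "library_sizes.tsv"),
             num_cols = "library_size")
    note("table", "library_sizes.tsv")
    writeTsv(data.frame(patient_id = patients(cohort@design),
                        tumor_sample = tumorSamples(cohort@design),
                        normal_sample = normalSamples(cohort@design)),
             file.path(out_dir, "design.tsv"))
    note("table", "design.tsv")
    writeTsv(cohort@genes, file.path(out_dir, "genes.tsv"))
    note("table", "genes.tsv")
    writeMatrixTsv(cohort@expression, file.path(out_dir, "expression.tsv"),
                   "gene_id")
    note("table", "expression.tsv")
    writeBed(cohort@clusterPeaks, file.path(out_dir, "cluster_peaks.bed"))
    note("bed", "cluster_peaks.bed")
    writeMatrixTsv(cohort@clusterCells$matrix,
                   file.path(out_dir, "cluster_cells.tsv"), "gene_id")
    note("table", "cluster_cells.tsv")
    writeTsv(data.frame(cell_id = colnames(cohort@clusterCells$matrix),
                        cluster = cohort@clusterCells$labels),
             file.path(out_dir, "cluster_labels.tsv"))
    note("table", "cluster_labels.tsv")

    run_cfg <- list(manifest = "manifest.tsv", counts = "counts.tsv",
                    region_lengths = "region_lengths.tsv",
                    library_sizes = "library_sizes.tsv",
                    regions_bed = "regions.bed", design = "design.tsv",
                    genes = "genes.tsv", expression = "expression.tsv",
                    cluster_peaks = "cluster_peaks.bed",
                    cluster_cells = "cluster_cells.tsv",
                    cluster_labels = "cluster_labels.tsv",
                    target_cluster = cohort@truth$target_cluster,
                    seed = cohort@config$seed)
    yaml::write_yaml(run_cfg, file.path(out_dir, "run.yaml"))
    note("config", "run.yaml")

    truth <- cohort@truth
    truth$true_log2fc <- stats::setNames(
        as.numeric(fmtNum(truth$true_log2fc)), names(truth$true_log2fc))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("truth", "truth.json")

    invisible(do.call(rbind, emitted))
}
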