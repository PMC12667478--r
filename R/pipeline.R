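#' Immunohistochemistry score
#'
#' Product of the positive-cell-proportion score (1-4) and the
#' staining-intensity score (0-3), giving a score in 0-12. Proportion
#' bins: up to 25% scores 1; up to 50% scores 2; up to 75% scores 3;
#' above 75% scores 4. (The published bins leave 25-26% unassigned; the
#' boundary rule used here — `<= 25` scores 1 — is this package's
#' documented choice.)
#'
#' @param proportion_pct percentage of positive cells, in `[0, 100]`.
#' @param intensity staining intensity, one of 0, 1, 2, 3.
#' @return list with `proportion_pct`, `intensity`, `proportion_score`,
#'   `score`.
#' @examples
#' ihcScore(80, 3)$score  # 12
#' ihcScore(40, 2)$score  # 4
#' @export
ihcScore <- function(proportion_pct, intensity) {
    if (length(proportion_pct) != 1L || is.na(proportion_pct) ||
        proportion_pct < 0 || proportion_pct > 100)
        stop("proportion_pct must be a single value in [0, 100]")
    if (length(intensity) != 1L || !intensity %in% 0:3)
        stop("intensity must be one of 0, 1, 2, 3")
    prop_score <- if (proportion_pct <= 25) 1L
        else if (proportion_pct <= 50) 2L
        else if (proportion_pct <= 75) 3L
        else 4L
    list(proportion_pct = proportion_pct,
         intensity = as.integer(intensity),
         proportion_score = prop_score,
         score = prop_score * as.integer(intensity))
}

#' Read a pipeline run configuration
#'
#' A single plain-text YAML file holding input paths, threshold overrides
#' and run options. Recognized keys: `manifest`, `counts`,
#' `region_lengths`, `library_sizes`, `regions_bed`, `design`, `genes`,
#' `expression`, `cluster_peaks`, `cluster_cells`, `cluster_labels`,
#' `target_cluster`, `tf_names`, `seed`, `out_dir`, `saturation`
#' (logical), `saturation_k`, `saturation_replicates`, and a `thresholds`
#' block of [thresholdConfig()] overrides. Relative input paths are
#' resolved against the config file's directory. Explicit arguments to
#' [runPipeline()] override config values, which override defaults.
#'
#' @param path path to the YAML config.
#' @return Named list (class `"runConfig"`).
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    base <- dirname(path)
    pathkeys <- c("manifest", "counts", "region_lengths", "library_sizes",
                  "regions_bed", "design", "genes", "expression",
                  "cluster_peaks", "cluster_cells", "cluster_labels")
    for (k in intersect(pathkeys, names(cfg)))
        if (!grepl("^(/|[A-Za-z]:)", cfg[[k]]))
            cfg[[k]] <- file.path(base, cfg[[k]])
    class(cfg) <- "runConfig"
    cfg
}

#' Validate pipeline inputs
#'
#' Checks file existence, table schemas, id cross-references
#' (design vs counts vs expression) and BED coordinate sanity, without
#' running any stage. Findings are returned, not thrown; `level` is
#' `"error"` or `"warning"`.
#'
#' @param config a list/`runConfig` of input paths (see
#'   [readRunConfig()]).
#' @return data.frame with columns `level` and `message` (zero rows when
#'   everything is well-formed).
#' @export
validateInputs <- function(config) {
    findings <- list()
    add <- function(level, msg)
        findings[[length(findings) + 1L]] <<- data.frame(
            level = level, message = msg, stringsAsFactors = FALSE)
    need <- c("manifest", "counts", "region_lengths", "library_sizes",
              "design", "genes", "expression")
    for (k in need)
        if (is.null(config[[k]]))
            add("error", paste0("missing config key: ", k))
        else if (!file.exists(config[[k]]))
            add("error", paste0(k, " file not found: ", config[[k]]))
    asdf <- function() do.call(rbind, c(findings, list(data.frame(
        level = character(0), message = character(0)))))
    if (any(vapply(findings, function(f) f$level == "error", logical(1))))
        return(asdf())

    man <- tryCatch(readSampleManifest(config$manifest),
                    error = function(e) { add("error", conditionMessage(e)); NULL })
    if (!is.null(man)) {
        for (p in c(man$k4me1_path, man$k27ac_path))
            if (!file.exists(p))
                add("error", paste0("peak file not found: ", p))
            else {
                bad <- tryCatch({ readBed(p); NULL },
                                error = function(e) conditionMessage(e))
                if (!is.null(bad)) add("error", paste0(p, ": ", bad))
            }
    }
    des <- tryCatch(readPairedDesign(config$design),
                    error = function(e) { add("error", conditionMessage(e)); NULL })
    cnt <- tryCatch(readCounts(config$counts, config$region_lengths,
                               config$library_sizes, config$regions_bed),
                    error = function(e) { add("error", conditionMessage(e)); NULL })
    expr <- tryCatch(readExpression(config$expression),
                     error = function(e) { add("error", conditionMessage(e)); NULL })
    tryCatch(readGeneTable(config$genes),
             error = function(e) add("error", conditionMessage(e)))
    if (!is.null(des)) {
        ds <- c(tumorSamples(des), normalSamples(des))
        if (!is.null(cnt)) {
            miss <- setdiff(ds, colnames(cnt))
            if (length(miss))
                add("error", paste0("design samples absent from counts: ",
                                    paste(miss, collapse = ", ")))
        }
        if (!is.null(expr)) {
            miss <- setdiff(ds, colnames(expr))
            if (length(miss))
                add("error", paste0("design samples absent from expression: ",
                                    paste(miss, collapse = ", ")))
        }
        if (!is.null(man)) {
            miss <- setdiff(ds, man$sample_id)
            if (length(miss))
                add("warning", paste0("design samples absent from manifest: ",
                                      paste(miss, collapse = ", ")))
        }
    }
    asdf()
}

outputHeader <- function(cfg, seed, stage) {
    thr <- cfg[!vapply(cfg, is.character, logical(1)) |
               names(cfg) %in% c("cluster_adjust", "anchor", "log2fc_mode",
                                 "link_to", "coexpr_method")]
    c(sprintf("# EnhancerFunnel %s stage=%s",
              as.character(utils::packageVersion("EnhancerFunnel")), stage),
      sprintf("# seed=%s", as.character(seed)),
      paste0("# thresholds: ",
             paste(sprintf("%s=%s", names(thr),
                           vapply(thr, as.character, character(1))),
                   collapse = " ")))
}

#' Run the full pipeline
#'
#' Orchestrates catalog construction, differential enhancer calling,
#' optional saturation analysis, and the candidate-gene funnel from files
#' on disk, writing per-stage BED/TSV outputs (each with a header block
#' recording version, thresholds and seed) and a machine-readable summary
#' JSON. Reruns with identical inputs and seed reproduce identical
#' outputs byte-for-byte.
#'
#' @param config a `runConfig` list or path to a YAML config file (see
#'   [readRunConfig()]).
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @param seed seed for the saturation subsampling; overrides the
#'   config's.
#' @param cfg a [thresholdConfig()]; overrides the config's `thresholds`
#'   block when supplied.
#' @param saturation logical; run the saturation analysis (default from
#'   config, else FALSE).
#' @return Invisibly, a list: `summary` (stage counts and options),
#'   `differential`, `funnel`, `saturation` (or NULL), and the output
#'   paths. Validation failures abort before any stage runs; a stage
#'   failure aborts with the stage name.
#' @export
runPipeline <- function(config, out_dir = NULL, seed = NULL, cfg = NULL,
                        saturation = NULL) {
    if (is.character(config))
        config <- readRunConfig(config)
    if (is.null(out_dir)) out_dir <- config$out_dir
    if (is.null(out_dir))
        stop("an output directory is required (out_dir)")
    if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
    if (is.null(cfg))
        cfg <- do.call(thresholdConfig,
                       if (is.null(config$thresholds)) list()
                       else config$thresholds)
    if (is.null(saturation))
        saturation <- isTRUE(config$saturation)

    val <- validateInputs(config)
    if (any(val$level == "error"))
        stop("input validation failed:\n  ",
             paste(val$message[val$level == "error"], collapse = "\n  "))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- function(stage) outputHeader(cfg, seed, stage)

    ## stage: catalogs ---------------------------------------------------
    man <- readSampleManifest(config$manifest)
    genes <- readGeneTable(config$genes)
    tss <- geneTssPoints(genes)
    enh <- lapply(seq_len(nrow(man)), function(i)
        callSampleEnhancers(readBed(man$k27ac_path[i]),
                            readBed(man$k4me1_path[i]),
                            tss, cfg$tss_min_dist_bp, cfg$anchor))
    names(enh) <- man$sample_id
    catalogs <- lapply(c(tumor = "tumor", normal = "normal"), function(g)
        buildConsensus(enh[man$group == g], g, cfg$min_support))
    writeCatalogBed(catalogs$tumor,
                    file.path(out_dir, "catalog_tumor.bed"), hdr("catalog"))
    writeCatalogBed(catalogs$normal,
                    file.path(out_dir, "catalog_normal.bed"), hdr("catalog"))

    ## stage: differential ----------------------------------------------
    universe <- mergeIntervals(c(granges(regions(catalogs$tumor)),
                                 granges(regions(catalogs$normal))))
    mcols(universe)$region_id <- sprintf("univ_%04d", seq_along(universe))
    design <- readPairedDesign(config$design)
    counts <- readCounts(config$counts, config$region_lengths,
                         config$library_sizes, config$regions_bed)
    if (is.null(config$regions_bed))
        stop("stage differential: a regions_bed mapping count regions to ",
             "coordinates is required")
    mapped <- mapCountsToRegions(counts, universe)
    diff <- callDifferentialEnhancers(mapped, design, cfg = cfg)
    writeDifferentialTsv(diff, file.path(out_dir, "differential.tsv"),
                         hdr("differential"))
    soe_ids <- differentialRegions(diff, "SOE")
    soes <- universe[match(soe_ids, mcols(universe)$region_id)]
    writeBed(`mcols<-`(soes, value = S4Vectors::DataFrame(
                 name = soe_ids)),
             file.path(out_dir, "soe.bed"), header = hdr("differential"))
    cde_ids <- differentialRegions(diff, "CDE")
    writeBed(`mcols<-`(universe[match(cde_ids, mcols(universe)$region_id)],
                       value = S4Vectors::DataFrame(name = cde_ids)),
             file.path(out_dir, "cde.bed"), header = hdr("differential"))

    ## stage: saturation (optional) ---------------------------------------
    sat <- NULL
    if (saturation) {
        kv <- if (!is.null(config$saturation_k))
            as.integer(config$saturation_k)
        else seq(2L, nPairs(design), by = 2L)
        nr <- if (!is.null(config$saturation_replicates))
            as.integer(config$saturation_replicates) else 25L
        sat <- saturationAnalysis(mapped, design, cfg = cfg, k_values = kv,
                                  n_replicates = nr, seed = seed)
        writeSaturationTsv(sat, file.path(out_dir, "saturation.tsv"),
                           file.path(out_dir, "saturation_summary.tsv"),
                           hdr("saturation"))
    }

    ## stage: funnel ------------------------------------------------------
    expr <- readExpression(config$expression)
    cluster_peaks <- readBed(config$cluster_peaks)
    cells <- readExpression(config$cluster_cells)  # same layout as bulk
    labels <- utils::read.delim(config$cluster_labels, sep = "\t",
                                comment.char = "#",
                                stringsAsFactors = FALSE)
    labels <- stats::setNames(labels$cluster, labels$cell_id)[colnames(cells)]
    tf_names <- if (!is.null(config$tf_names)) config$tf_names
        else c("TP63", "SOX2", "KLF5", "GRHL2")
    tf_ids <- genes$gene_id[match(tf_names, genes$gene_name)]
    if (any(is.na(tf_ids)))
        stop("stage funnel: TF gene names not found in the gene table: ",
             paste(tf_names[is.na(tf_ids)], collapse = ", "))
    target <- if (!is.null(config$target_cluster)) config$target_cluster
        else "squamous"
    funnel <- runFunnel(soes, cluster_peaks, genes, expr, design, tf_ids,
                        cells = cells, labels = labels, target = target,
                        cfg = cfg)
    writeBed(funnel@loci, file.path(out_dir, "funnel_loci.bed"),
             name_col = "region_id", header = hdr("funnel"))
    audit <- auditTable(funnel)
    writeTsvWithHeader(audit, file.path(out_dir, "funnel_audit.tsv"),
                       hdr("funnel"))

    sc <- stageCounts(funnel)
    summary <- list(
        n_samples = nrow(man),
        n_pairs = nPairs(design),
        catalog_tumor_regions = length(regions(catalogs$tumor)),
        catalog_normal_regions = length(regions(catalogs$normal)),
        universe_regions = length(universe),
        n_soe = length(soe_ids),
        n_cde = length(cde_ids),
        funnel = as.list(sc),
        candidates = candidates(funnel),
        thresholds = unclass(cfg),
        seed = seed,
        version = as.character(utils::packageVersion("EnhancerFunnel")))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(summary = summary, differential = diff, funnel = funnel,
                   saturation = sat, catalogs = catalogs,
                   out_dir = out_dir))
}

writeTsvWithHeader <- function(df, path, header) {
    num <- vapply(df, is.numeric, logical(1))
    for (cc in names(df)[num]) df[[cc]] <- fmtNum(df[[cc]])
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    if (nrow(df))
        writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
    invisible(path)
}

writeDifferentialTsv <- function(diff, path, header) {
    writeTsvWithHeader(as.data.frame(diff), path, header)
}

writeSaturationTsv <- function(sat, path, summary_path, header) {
    writeTsvWithHeader(sat, path, header)
    writeTsvWithHeader(attr(sat, "summary"), summary_path, header)
    invisible(path)
}
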