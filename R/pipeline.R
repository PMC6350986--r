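#' Pipeline configuration
#'
#' Bundles all inputs and parameters of [runPipeline()]. Defaults are the
#' analysis constants of the emulated study: per-library minimum coverage 15,
#' BH FDR alpha 0.01, gene-score cutoff 4.0, top fraction 5%, extreme
#' fraction 10%, MIT+ReDox category merge.
#'
#' @param counts Named list of counts-TSV paths, one per collection (names =
#'   collection ids), or a single path.
#' @param genes Path to the gene annotation (GFF3 or BED).
#' @param categories Path to the gene->category TSV (optional; enrichment is
#'   skipped without it).
#' @param manifest Optional library manifest path.
#' @param outDir Output directory.
#' @param minCoverage,alpha,cutoff,topFraction,extremeFraction,neglog10Cap
#'   Analysis parameters (see the stage functions).
#' @param dfRule `"observed"` or `"alternate"` (see [testSites()]).
#' @param fdrLevel `"site"` or `"gene"` (see [scoreGenes()]).
#' @param merges Category merge spec (see [mergeCategories()]).
#' @param focal Optional focal interval as `list(chrom, start, end)` for the
#'   positional summary (e.g. the VGSC locus).
#' @param seed Optional integer seed recorded in the log (the analysis
#'   itself is deterministic; the seed matters when the inputs come from the
#'   simulator).
#' @return A `PipelineConfig` list (class `"PipelineConfig"`).
#' @export
pipelineConfig <- function(counts, genes, categories = NULL,
                           manifest = NULL, outDir = "poolassoc_out",
                           minCoverage = 15L, alpha = 0.01, cutoff = 4.0,
                           topFraction = 0.05, extremeFraction = 0.10,
                           neglog10Cap = 320, dfRule = "observed",
                           fdrLevel = "site",
                           merges = list("MIT/ReDox" = c("MIT", "ReDox")),
                           focal = NULL, seed = NULL) {
    stopifnot(alpha > 0, alpha < 1, topFraction > 0, topFraction < 1,
              extremeFraction > 0, extremeFraction < 1)
    if (!is.list(counts)) counts <- list(C1 = counts)
    structure(list(counts = counts, genes = genes, categories = categories,
                   manifest = manifest, outDir = outDir,
                   minCoverage = as.integer(minCoverage), alpha = alpha,
                   cutoff = cutoff, topFraction = topFraction,
                   extremeFraction = extremeFraction,
                   neglog10Cap = neglog10Cap, dfRule = dfRule,
                   fdrLevel = fdrLevel, merges = merges, focal = focal,
                   seed = seed),
              class = "PipelineConfig")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()] (`counts` as a mapping of
#' collection id to path; `merges` as a mapping of merged code to source
#' codes; `focal` as a mapping with `chrom`, `start`, `end`).
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
pipelineConfigFromYaml <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(pipelineConfig, y)
}

#' Run the full association-mapping pipeline
#'
#' Per collection: read counts, apply the per-library coverage filter,
#' exclude monomorphic sites, run the contingency chi-square at every
#' polymorphic site, and score genes. Across collections (when >= 2):
#' intersect the high-association sets (Venn region counts; non-coding genes
#' removed from the common set), extract the extreme top-decile subset, run
#' the positional summary, and test functional-category over-representation
#' of the common set against the coding background. All tables are written
#' as TSV, a Manhattan-style plot per collection as PNG, and a plain-text
#' log records every parameter, input checksums and per-stage counts.
#' Outputs are deterministic given the config (and the seed that produced
#' simulated inputs); a single-collection run stops after gene scoring.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results (`site_results`,
#'   `gene_scores`, `high_sets`, `common`, `extreme`, `positional`,
#'   `enrichment`, `filter_reports`) and `paths` of the written artifacts.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    logpath <- file.path(config$outDir, "run_log.txt")
    logcon <- file(logpath, "w")
    on.exit(close(logcon))
    logln <- function(...) writeLines(paste0(...), logcon)
    logln("poolAssoc pipeline log")
    logln("parameters: minCoverage=", config$minCoverage,
          " alpha=", config$alpha, " cutoff=", config$cutoff,
          " topFraction=", config$topFraction,
          " extremeFraction=", config$extremeFraction,
          " dfRule=", config$dfRule, " fdrLevel=", config$fdrLevel,
          " neglog10Cap=", config$neglog10Cap,
          if (!is.null(config$seed)) paste0(" seed=", config$seed) else "")
    for (p in c(unlist(config$counts), config$genes, config$categories,
                config$manifest))
        logln("input ", p, " md5=", unname(tools::md5sum(p)))

    fail <- function(stage, e) stop("stage '", stage, "' failed: ",
                                    conditionMessage(e), call. = FALSE)
    genes <- tryCatch(readGeneModels(config$genes),
                      error = function(e) fail("read_genes", e))
    categories <- if (!is.null(config$categories))
        tryCatch(readCategoryMap(config$categories),
                 error = function(e) fail("read_categories", e)) else NULL
    manifest <- if (!is.null(config$manifest))
        readLibraryManifest(config$manifest) else NULL

    site_results <- list(); gene_scores <- list(); high_sets <- list()
    filter_reports <- list(); paths <- list()
    for (cid in names(config$counts)) {
        pc <- tryCatch(readPoolCounts(config$counts[[cid]],
                                      manifest = if (is.null(manifest)) NULL
                                      else manifest[manifest$collection_id ==
                                                    cid, , drop = FALSE]),
                       error = function(e) fail(paste0("read_counts[", cid, "]"), e))
        flt <- filterSites(pc, config$minCoverage)
        mono <- flagMonomorphic(flt$counts)
        logln(sprintf(
            "[%s] sites=%d low_coverage_removed=%d monomorphic=%d no_data=%d tested_pool=%d",
            cid, flt$report$n_input, flt$report$n_removed_low_coverage,
            mono$n_monomorphic, mono$n_no_data, nrow(mono$counts)))
        res <- tryCatch(testSites(mono$counts, dfRule = config$dfRule,
                                  neglog10Cap = config$neglog10Cap),
                        error = function(e) fail(paste0("test[", cid, "]"), e))
        gs <- scoreGenes(res, genes, categories = categories,
                         topFraction = config$topFraction,
                         alpha = config$alpha, cutoff = config$cutoff,
                         fdrLevel = config$fdrLevel)
        site_results[[cid]] <- res
        gene_scores[[cid]] <- gs
        high_sets[[cid]] <- highAssociationSet(gs)
        filter_reports[[cid]] <- c(flt$report,
                                   n_monomorphic = mono$n_monomorphic,
                                   n_no_data = mono$n_no_data)
        paths[[paste0("sites_", cid)]] <-
            writeSiteResults(res, file.path(config$outDir,
                                            paste0("site_results_", cid,
                                                   ".tsv")))
        paths[[paste0("genes_", cid)]] <-
            writeGeneScores(gs, file.path(config$outDir,
                                          paste0("gene_scores_", cid,
                                                 ".tsv")))
        logln(sprintf("[%s] high_association_genes=%d", cid,
                      length(high_sets[[cid]])))
        pl <- file.path(config$outDir, paste0("manhattan_", cid, ".png"))
        grDevices::png(pl, width = 1200, height = 400)
        print(plotGeneScores(gs, cutoff = config$cutoff,
                             focal = config$focal))
        grDevices::dev.off()
        paths[[paste0("plot_", cid)]] <- pl
    }

    common <- extreme <- positional <- enrichment <- NULL
    if (length(config$counts) >= 2L) {
        coding <- mcols(genes)$gene_id[mcols(genes)$biotype %in%
                                       c("protein_coding", NA)]
        common <- intersectCollections(high_sets, coding = coding)
        logln("common high-association genes (coding)=",
              length(common$common), " removed_noncoding=",
              length(common$removed_noncoding))
        venn <- data.frame(region = names(common$regions),
                           n_genes = as.integer(common$regions))
        paths$venn <- file.path(config$outDir, "venn_regions.tsv")
        utils::write.table(venn, paths$venn, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        if (length(common$common)) {
            scores <- vapply(gene_scores, function(gs)
                gs$score[match(common$common, gs$gene_id)],
                numeric(length(common$common)))
            if (length(common$common) == 1L)
                scores <- matrix(scores, nrow = 1L,
                                 dimnames = list(NULL, names(gene_scores)))
            rownames(scores) <- common$common
            extreme <- extremeSubset(scores, config$extremeFraction)
            logln("extreme subset: thresholds=",
                  paste(sprintf("%s=%.3f", names(extreme$thresholds),
                                extreme$thresholds), collapse = " "),
                  " members=", length(extreme$members))
            ext <- data.frame(gene_id = rownames(scores), scores,
                              extreme = rownames(scores) %in%
                                  extreme$members, check.names = FALSE)
            paths$extreme <- file.path(config$outDir, "extreme_set.tsv")
            utils::write.table(ext, paths$extreme, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            focal <- if (!is.null(config$focal))
                GRanges(config$focal$chrom,
                        IRanges(config$focal$start, config$focal$end))
            else NULL
            positional <- positionalSummary(common$common, genes,
                                            focal = focal)
            paths$positional <- file.path(config$outDir,
                                          "positional_summary.tsv")
            utils::write.table(positional$distances, paths$positional,
                               sep = "\t", quote = FALSE, row.names = FALSE)
            if (!is.null(categories)) {
                bg <- categories[categories$gene_id %in% coding, ,
                                 drop = FALSE]
                enrichment <- enrichAll(common$common, bg,
                                        merges = config$merges)
                paths$enrichment <- file.path(config$outDir,
                                              "enrichment.tsv")
                utils::write.table(enrichment, paths$enrichment, sep = "\t",
                                   quote = FALSE, row.names = FALSE)
                logln("enrichment: top category=",
                      enrichment$category_code[1], " p=",
                      format(enrichment$p_upper[1]))
            }
        }
    }
    logln("pipeline complete")
    invisible(list(site_results = site_results, gene_scores = gene_scores,
                   high_sets = high_sets, common = common,
                   extreme = extreme, positional = positional,
                   enrichment = enrichment,
                   filter_reports = filter_reports, paths = paths,
                   log = logpath))
}

#' Manhattan-style plot of gene scores
#'
#' Gene midpoints against gene-wise scores, one panel per chromosome, with
#' the score cutoff drawn as a horizontal line and an optional focal
#' interval (e.g. the VGSC locus) shaded.
#'
#' @param geneScores `DataFrame` from [scoreGenes()].
#' @param cutoff Horizontal reference line (default 4.0).
#' @param focal Optional `list(chrom, start, end)`.
#' @return A `ggplot` object.
#' @export
plotGeneScores <- function(geneScores, cutoff = 4.0, focal = NULL) {
    df <- as.data.frame(geneScores)
    df <- df[!is.na(df$score), , drop = FALSE]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position_midpoint / 1e6,
                                          y = .data$score)) +
        ggplot2::geom_point(ggplot2::aes(colour = .data$high_association),
                            size = 0.8, show.legend = FALSE) +
        ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                                `TRUE` = "firebrick")) +
        ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
        ggplot2::facet_wrap(~chromosome, nrow = 1, scales = "free_x") +
        ggplot2::labs(x = "position (Mb)",
                      y = expression("gene-wise mean top 5% " *
                                     -log[10](italic(p)))) +
        ggplot2::theme_bw()
    if (!is.null(focal))
        p <- p + ggplot2::geom_vline(
            data = data.frame(chromosome = focal$chrom,
                              x = (focal$start + focal$end) / 2e6),
            ggplot2::aes(xintercept = .data$x), colour = "red",
            linetype = "dotted")
    p
}
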