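#' Assign tested sites to gene intervals
#'
#' A site maps to every gene whose `[start, end]` interval (1-based,
#' inclusive; expected to span UTRs, exons and introns) contains its
#' position. Intergenic sites map nowhere and are counted; sites inside
#' overlapping genes map to all of them.
#'
#' @param sites `GRanges` of sites (e.g. from [testSites()]).
#' @param genes `GRanges` of gene models with a `gene_id` metadata column.
#' @return List with `hits` (a `Hits` object sites -> genes),
#'   `n_intergenic`, and `n_multi_gene` (sites in > 1 gene).
#' @export
assignSitesToGenes <- function(sites, genes) {
    hits <- findOverlaps(sites, genes, ignore.strand = TRUE)
    per_site <- tabulate(S4Vectors::queryHits(hits), length(sites))
    list(hits = hits,
         n_intergenic = sum(per_site == 0L),
         n_multi_gene = sum(per_site > 1L))
}

#' Gene-wise weighted average: mean of the top fraction of site scores
#'
#' The gene score is the arithmetic mean of the `m_top` largest -log10(p)
#' values among the gene's tested sites, with
#' `m_top = max(1, ceiling(topFraction * n))`. Averaging only the top sites
#' highlights genes whose association signal is localized to a few SNPs
#' along an otherwise unremarkable interval. Selection is by value with a
#' deterministic order (value descending, then position ascending), so ties
#' at the `m_top` boundary are stable; as the selected values are averaged,
#' the score itself does not depend on which of several tied values enter.
#'
#' @param values Numeric vector of per-site -log10(p) values (non-empty).
#' @param topFraction Fraction of sites averaged (default 0.05).
#' @param positions Optional integer vector of site positions used as the
#'   tie-break order.
#' @return List with `score` and `m_top`.
#' @export
#' @examples
#' geneScore(seq(0, 3.9, by = 0.1))  # 40 sites -> mean of the 2 largest
geneScore <- function(values, topFraction = 0.05, positions = NULL) {
    n <- length(values)
    if (!n) stop("geneScore requires at least one site value")
    m_top <- max(1L, as.integer(ceiling(topFraction * n)))
    ord <- if (is.null(positions)) order(-values)
           else order(-values, positions)
    list(score = mean(values[ord[seq_len(m_top)]]), m_top = m_top)
}

#' Benjamini-Hochberg step-up rejection at level alpha
#'
#' Standard step-up FDR procedure: with sorted p-values p(1) <= ... <= p(m),
#' all hypotheses up to the largest i with `p(i) <= alpha * i / m` are
#' rejected.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.01).
#' @return Logical rejection flags, same length as `p` (empty input gives an
#'   empty vector).
#' @export
bhFdr <- function(p, alpha = 0.01) {
    if (!length(p)) return(logical(0))
    stopifnot(all(p > 0 & p <= 1))
    stats::p.adjust(p, method = "BH") <= alpha
}

#' Score genes from per-site association results
#'
#' Maps tested sites to genes, computes each gene's top-fraction score and
#' per-phenotype average expected heterozygosity, applies BH FDR and the
#' score cutoff, and returns one row per gene. FDR is applied at the site
#' level across all tested sites of the collection (default): a gene
#' `passes_fdr` when at least one of its sites is rejected. With
#' `fdrLevel = "gene"`, BH is instead applied across genes to each gene's
#' minimum site p-value (sensitivity analysis). `high_association` is the
#' conjunction `passes_fdr & passes_cutoff`; the cutoff comparison is
#' inclusive (`score >= cutoff`).
#'
#' @param siteResults `GRanges` from [testSites()].
#' @param genes `GRanges` of gene models (`gene_id`, optionally `biotype`,
#'   `description`).
#' @param categories Optional `data.frame` (`gene_id`, `category_code`).
#' @param topFraction Fraction of top site scores averaged (default 0.05).
#' @param alpha BH FDR level (default 0.01).
#' @param cutoff Gene-score threshold (default 4.0).
#' @param fdrLevel `"site"` (default) or `"gene"`.
#' @return A `DataFrame` with one row per gene: `gene_id`, `chromosome`,
#'   `start`, `end`, `position_midpoint`, `category_code`, `description`,
#'   `n_sites_tested`, `m_top`, `score`, `avg_hexp_resistant`,
#'   `avg_hexp_susceptible`, `passes_fdr`, `passes_cutoff`,
#'   `high_association`. Genes with no tested site have `n_sites_tested = 0`
#'   and NA score. The assignment report of [assignSitesToGenes()] is
#'   attached in `metadata(x)$assignment`.
#' @export
scoreGenes <- function(siteResults, genes, categories = NULL,
                       topFraction = 0.05, alpha = 0.01, cutoff = 4.0,
                       fdrLevel = c("site", "gene")) {
    fdrLevel <- match.arg(fdrLevel)
    tested <- mcols(siteResults)$flag == "tested"
    ts <- siteResults[tested]
    asg <- assignSitesToGenes(ts, genes)
    q <- S4Vectors::queryHits(asg$hits)
    g <- S4Vectors::subjectHits(asg$hits)

    ng <- length(genes)
    n_sites <- tabulate(g, ng)
    score <- rep(NA_real_, ng); m_top <- rep(NA_integer_, ng)
    hr <- rep(NA_real_, ng); hs <- rep(NA_real_, ng)
    min_p <- rep(NA_real_, ng)
    any_fdr <- rep(FALSE, ng)

    fdr_site <- if (fdrLevel == "site" && length(ts))
        bhFdr(mcols(ts)$p_value, alpha) else logical(length(ts))

    nl <- mcols(ts)$neglog10p
    pos <- start(ts)
    pv <- mcols(ts)$p_value
    hexp_r <- mcols(ts)$hexp_resistant
    hexp_s <- mcols(ts)$hexp_susceptible
    idx <- split(q, factor(g, levels = seq_len(ng)))
    for (j in which(n_sites > 0L)) {
        i <- idx[[j]]
        gs <- geneScore(nl[i], topFraction, positions = pos[i])
        score[j] <- gs$score; m_top[j] <- gs$m_top
        hr[j] <- if (all(is.na(hexp_r[i]))) NA_real_
                 else mean(hexp_r[i], na.rm = TRUE)
        hs[j] <- if (all(is.na(hexp_s[i]))) NA_real_
                 else mean(hexp_s[i], na.rm = TRUE)
        min_p[j] <- min(pv[i])
        if (fdrLevel == "site") any_fdr[j] <- any(fdr_site[i])
    }
    if (fdrLevel == "gene") {
        has <- n_sites > 0L
        any_fdr[has] <- bhFdr(min_p[has], alpha)
    }
    passes_cutoff <- !is.na(score) & score >= cutoff
    cat_code <- rep(NA_character_, ng)
    if (!is.null(categories)) {
        m <- match(mcols(genes)$gene_id, categories$gene_id)
        cat_code <- categories$category_code[m]
    }
    out <- DataFrame(
        gene_id = mcols(genes)$gene_id,
        chromosome = as.character(seqnames(genes)),
        start = start(genes), end = end(genes),
        position_midpoint = as.integer(floor((start(genes) + end(genes)) / 2)),
        category_code = cat_code,
        description = if ("description" %in% colnames(mcols(genes)))
            mcols(genes)$description else NA_character_,
        n_sites_tested = n_sites, m_top = m_top, score = score,
        avg_hexp_resistant = hr, avg_hexp_susceptible = hs,
        passes_fdr = any_fdr, passes_cutoff = passes_cutoff,
        high_association = any_fdr & passes_cutoff)
    metadata(out)$assignment <- asg[c("n_intergenic", "n_multi_gene")]
    metadata(out)$params <- list(topFraction = topFraction, alpha = alpha,
                                 cutoff = cutoff, fdrLevel = fdrLevel)
    out
}

#' Gene ids of the high-association set
#'
#' Genes whose score passes the cutoff *and* that carry at least one
#' FDR-rejected site (both flags as computed by [scoreGenes()]).
#'
#' @param geneScores `DataFrame` from [scoreGenes()].
#' @return Character vector of gene ids.
#' @export
highAssociationSet <- function(geneScores) {
    geneScores$gene_id[geneScores$high_association]
}

#' Write per-gene scores as TSV
#'
#' @param geneScores `DataFrame` from [scoreGenes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneScores <- function(geneScores, path) {
    utils::write.table(as.data.frame(geneScores), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
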