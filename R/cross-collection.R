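#' Intersect high-association gene sets across collections
#'
#' Computes the genes common to every collection's high-association set plus
#' all Venn region counts (one count per nonempty subset of collections,
#' counting genes present in exactly those collections). Non-coding genes
#' can be removed from the common set by supplying the coding universe.
#'
#' @param sets Named list (>= 2) of character vectors of gene ids.
#' @param coding Optional character vector of coding gene ids; when given,
#'   common genes outside it are removed and counted.
#' @return List with `common` (gene ids in every set, coding-filtered when
#'   requested), `regions` (named integer vector of exclusive Venn region
#'   counts, names like `"C1&C2"`), `n_union`, `removed_noncoding`
#'   (character vector, possibly empty).
#' @export
#' @examples
#' intersectCollections(list(a = c("A","B","C"), b = c("B","C","D"),
#'                           c = c("B","C")))$common
intersectCollections <- function(sets, coding = NULL) {
    if (length(sets) < 2L) stop("need at least two collections to intersect")
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        names(sets) <- paste0("S", seq_along(sets))
    sets <- lapply(sets, unique)
    universe <- Reduce(union, sets)
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L)
        member <- matrix(member, nrow = 1L, dimnames = list(NULL, names(sets)))
    pattern <- apply(member, 1L, function(row)
        paste(names(sets)[row], collapse = "&"))
    all_patterns <- unlist(lapply(seq_along(sets), function(k)
        utils::combn(names(sets), k, paste, collapse = "&")))
    regions <- stats::setNames(integer(length(all_patterns)), all_patterns)
    tab <- table(pattern)
    regions[names(tab)] <- as.integer(tab)
    common <- universe[rowSums(member) == length(sets)]
    removed <- character(0)
    if (!is.null(coding)) {
        removed <- setdiff(common, coding)
        common <- intersect(common, coding)
    }
    list(common = sort(common), regions = regions,
         n_union = length(universe), removed_noncoding = sort(removed))
}

#' Extreme top-decile subset of the common gene set
#'
#' Per collection, the threshold is the empirical `1 - extremeFraction`
#' quantile (nearest-rank convention) of the common-set scores; a gene is
#' extreme iff its score strictly exceeds the threshold in *every*
#' collection. With the default fraction, members rank among the top 10% in
#' all collections and all their scores exceed the per-collection floors
#' reported alongside.
#'
#' @param scores Numeric matrix or data.frame of gene scores: rows = common
#'   genes (rownames = gene ids), columns = collections.
#' @param extremeFraction Upper tail fraction (default 0.10).
#' @return List with `thresholds` (named per collection) and `members`
#'   (character vector of gene ids).
#' @export
extremeSubset <- function(scores, extremeFraction = 0.10) {
    scores <- as.matrix(scores)
    if (!nrow(scores)) stop("common set is empty")
    if (is.null(rownames(scores)))
        stop("scores must carry gene ids as rownames")
    thresholds <- apply(scores, 2L, nearestRankQuantile,
                        prob = 1 - extremeFraction)
    ok <- rowSums(sweep(scores, 2L, thresholds, ">")) == ncol(scores)
    list(thresholds = thresholds, members = rownames(scores)[ok])
}

#' Nearest-rank empirical quantile
#'
#' The `prob` quantile of `x` under the nearest-rank convention: the value at
#' rank `ceiling(prob * n)` of the ascending sort.
#'
#' @param x Numeric vector.
#' @param prob Probability in (0, 1].
#' @return The quantile.
#' @export
nearestRankQuantile <- function(x, prob) {
    stopifnot(length(x) > 0, prob > 0, prob <= 1)
    sort(x)[max(1L, ceiling(prob * length(x)))]
}

#' Positional summary of a gene set
#'
#' Counts genes per chromosome (and per arm, when arm intervals are
#' supplied) and reports each gene's signed distance from its midpoint to a
#' focal interval (0 when the gene overlaps it; negative upstream of the
#' interval start, positive downstream of its end). The focal interval
#' defaults to none; for pyrethroid-resistance work it is typically the
#' voltage-gated sodium channel (VGSC) locus.
#'
#' @param geneIds Character vector of gene ids to summarise.
#' @param genes `GRanges` gene models with `gene_id`.
#' @param focal Optional `GRanges` of length 1.
#' @param arms Optional named `GRanges` of chromosome arm intervals (names =
#'   arm labels).
#' @return List with `per_chromosome` (named integer), `per_arm` (or NULL),
#'   `distances` (`data.frame` gene_id, chromosome, midpoint,
#'   distance_to_focal — NA for genes on other chromosomes) and `missing`
#'   (ids without coordinates, excluded from counts).
#' @export
positionalSummary <- function(geneIds, genes, focal = NULL, arms = NULL) {
    m <- match(geneIds, mcols(genes)$gene_id)
    missing <- geneIds[is.na(m)]
    gr <- genes[m[!is.na(m)]]
    per_chrom <- table(factor(as.character(seqnames(gr))))
    per_arm <- NULL
    if (!is.null(arms)) {
        mid <- GRanges(seqnames(gr),
                       IRanges(floor((start(gr) + end(gr)) / 2), width = 1L))
        ov <- findOverlaps(mid, arms, ignore.strand = TRUE)
        lab <- rep(NA_character_, length(gr))
        lab[S4Vectors::queryHits(ov)] <- names(arms)[S4Vectors::subjectHits(ov)]
        per_arm <- table(factor(lab, levels = names(arms)))
    }
    dist <- NULL
    mid_pos <- floor((start(gr) + end(gr)) / 2)
    if (!is.null(focal)) {
        stopifnot(length(focal) == 1L)
        d <- rep(NA_real_, length(gr))
        same <- as.character(seqnames(gr)) == as.character(seqnames(focal))
        ov <- start(gr) <= end(focal) & end(gr) >= start(focal) & same
        d[same & ov] <- 0
        before <- same & !ov & mid_pos < start(focal)
        after <- same & !ov & mid_pos > end(focal)
        d[before] <- mid_pos[before] - start(focal)
        d[after] <- mid_pos[after] - end(focal)
        dist <- d
    }
    list(per_chromosome = c(per_chrom), per_arm = if (is.null(per_arm)) NULL
         else c(per_arm),
         distances = data.frame(gene_id = mcols(gr)$gene_id,
                                chromosome = as.character(seqnames(gr)),
                                midpoint = mid_pos,
                                distance_to_focal = if (is.null(dist))
                                    NA_real_ else dist),
         missing = missing)
}
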