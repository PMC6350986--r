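#' Per-site contingency chi-square between resistant and susceptible pools
#'
#' For each site, read counts are summed across replicate libraries within
#' each phenotype, giving a 2 x k contingency table over the k nucleotides
#' with nonzero total count. The Pearson chi-square statistic against
#' independence is computed with df = k - 1 (default) and the upper-tail
#' p-value of the chi-square law gives the per-SNP association score
#' -log10(p), capped to avoid infinities from underflow. Sites with k < 2
#' are flagged `monomorphic` and sites where one phenotype has zero reads are
#' flagged `low_coverage`; neither receives a statistic.
#'
#' Expected per-phenotype heterozygosity `1 - sum(p_i^2)` is computed from
#' the phenotype-pooled read frequencies at each tested site (NA when the
#' phenotype has zero depth).
#'
#' The `dfRule = "alternate"` convention sets df to the number of alternate
#' (non-reference-maximal) nucleotides minus 1, i.e. `k - 2`, for sites with
#' k >= 3; biallelic sites fall back to df = 1 since df = 0 is untestable.
#'
#' @param x A [PoolCounts-class] object for a single collection, normally
#'   after [filterSites()] and [flagMonomorphic()]. Sites failing either rule
#'   are still handled and flagged.
#' @param dfRule `"observed"` (df = observed alleles - 1, default) or
#'   `"alternate"`.
#' @param neglog10Cap Cap on -log10(p) (default 320, the double-precision
#'   underflow bound).
#' @return A `GRanges` mirroring the input sites with metadata columns
#'   `alleles`, `chi2`, `df`, `p_value`, `neglog10p`, `hexp_resistant`,
#'   `hexp_susceptible` and `flag` (one of `tested`, `monomorphic`,
#'   `low_coverage`).
#' @seealso [replicateHeterogeneityChisq()] for the within-phenotype
#'   replicate diagnostic.
#' @export
testSites <- function(x, dfRule = c("observed", "alternate"),
                      neglog10Cap = 320) {
    stopifnot(is(x, "PoolCounts"))
    dfRule <- match.arg(dfRule)
    if (length(unique(collectionId(x))) > 1L)
        stop("testSites expects libraries from a single collection")
    n <- nrow(x)
    R <- phenotypeCounts(x, "resistant")
    S <- phenotypeCounts(x, "susceptible")
    st <- chisqCounts2xk(R, S, dfRule = dfRule, neglog10Cap = neglog10Cap)

    out <- GRanges(seqnames(rowRanges(x)),
                   IRanges(start(rowRanges(x)), width = 1L))
    present <- st$present
    alleles <- vapply(seq_len(n), function(i)
        paste(NUCLEOTIDES[present[i, ]], collapse = "/"), "")
    mcols(out) <- DataFrame(
        ref = refAllele(x), alleles = alleles,
        chi2 = st$chi2, df = st$df, p_value = st$p_value,
        neglog10p = st$neglog10p,
        hexp_resistant = .hexpRows(R),
        hexp_susceptible = .hexpRows(S),
        flag = st$flag)
    out
}

#' Pearson chi-square on paired rows of nucleotide counts
#'
#' Vectorised core of [testSites()]: given two matrices of per-nucleotide
#' counts (one row per site, columns A/C/G/T) for the two phenotypes, builds
#' the per-site 2 x k table over nucleotides with nonzero total count and
#' returns the Pearson statistic, df, p-value and capped -log10(p).
#'
#' @param res,sus Numeric matrices, sites x 4 nucleotide counts.
#' @param dfRule,neglog10Cap See [testSites()].
#' @return List of vectors `chi2`, `df`, `p_value`, `neglog10p`, `k`,
#'   `flag`, and the logical `present` matrix of nucleotides in the table.
#' @export
chisqCounts2xk <- function(res, sus, dfRule = c("observed", "alternate"),
                           neglog10Cap = 320) {
    dfRule <- match.arg(dfRule)
    res <- .as4col(res); sus <- .as4col(sus)
    tot <- res + sus
    present <- tot > 0
    k <- rowSums(present)
    r <- rowSums(res); s <- rowSums(sus); N <- r + s
    flag <- rep("tested", nrow(res))
    flag[k < 2L] <- "monomorphic"
    flag[k >= 2L & (r == 0 | s == 0)] <- "low_coverage"
    tested <- flag == "tested"

    # E[i,j] = rowtotal_i * coltotal_j / N over the k present nucleotides
    chi2 <- rep(NA_real_, nrow(res))
    eR <- r * tot / N
    eS <- s * tot / N
    contrib <- (res - eR)^2 / eR + (sus - eS)^2 / eS
    contrib[!present | is.nan(contrib)] <- 0
    chi2[tested] <- rowSums(contrib)[tested]

    df <- rep(NA_integer_, nrow(res))
    df[tested] <- as.integer(if (dfRule == "observed") k[tested] - 1L
                             else pmax(k[tested] - 2L, 1L))
    p <- rep(NA_real_, nrow(res))
    nl <- rep(NA_real_, nrow(res))
    logp <- stats::pchisq(chi2[tested], df[tested], lower.tail = FALSE,
                          log.p = TRUE)
    nl[tested] <- pmin(-logp / log(10), neglog10Cap)
    p[tested] <- pmax(exp(logp), .Machine$double.xmin)
    list(chi2 = chi2, df = df, p_value = p, neglog10p = nl, k = k,
         flag = flag, present = present)
}

.as4col <- function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 4L)
    m
}

.hexpRows <- function(m) {
    d <- rowSums(m)
    h <- 1 - rowSums((m / d)^2)
    h[d == 0] <- NA_real_
    h
}

#' Expected heterozygosity of one phenotype at one or more sites
#'
#' `1 - sum(p_i^2)` with `p_i` the read frequency of nucleotide i summed over
#' the phenotype's libraries. For k observed alleles the value lies in
#' `[0, 1 - 1/k]` (at most 0.75 for four nucleotides).
#'
#' @param x A [PoolCounts-class] object.
#' @param phenotype `"resistant"` or `"susceptible"`.
#' @return Numeric vector, one value per site; NA where the phenotype has
#'   zero depth.
#' @export
siteHexp <- function(x, phenotype = c("resistant", "susceptible")) {
    .hexpRows(phenotypeCounts(x, match.arg(phenotype)))
}

#' Replicate-heterogeneity chi-square diagnostic
#'
#' Within one phenotype, tests the replicates x alleles contingency table at
#' each site: large values indicate that replicate pools of the same
#' phenotype disagree beyond read-sampling noise (e.g. strong finite-pool
#' drift or library artifacts). Diagnostic only; it does not gate the
#' association results.
#'
#' @param x A [PoolCounts-class] object.
#' @param phenotype `"resistant"` or `"susceptible"`.
#' @return `data.frame` with `chi2`, `df`, `p_value` per site (NA where the
#'   table is degenerate).
#' @export
replicateHeterogeneityChisq <- function(x,
                                        phenotype = c("resistant",
                                                      "susceptible")) {
    phenotype <- match.arg(phenotype)
    sel <- which(poolPhenotype(x) == phenotype)
    if (length(sel) < 2L)
        stop("need >= 2 replicate libraries for phenotype '", phenotype, "'")
    n <- nrow(x)
    chi2 <- rep(NA_real_, n); df <- rep(NA_integer_, n)
    arr <- vapply(NUCLEOTIDES, function(nt)
        assay(x, nt)[, sel, drop = FALSE], matrix(0L, n, length(sel)))
    for (i in seq_len(n)) {
        tab <- matrix(arr[i, , ], nrow = length(sel))  # replicates x 4
        tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
        if (nrow(tab) < 2L || ncol(tab) < 2L) next
        E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        chi2[i] <- sum((tab - E)^2 / E)
        df[i] <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
    }
    data.frame(chi2 = chi2, df = df,
               p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Write per-site association results
#'
#' @param results `GRanges` from [testSites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeSiteResults <- function(results, path) {
    df <- data.frame(chrom = as.character(seqnames(results)),
                     pos = start(results),
                     as.data.frame(mcols(results)), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
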