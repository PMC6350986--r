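suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
    library(GenomicRanges)
})

# Independent Pearson chi-square oracle: explicit expectation loop over the
# cells of a 2 x k table (columns with zero total dropped), upper-tail
# probability evaluated through the gamma distribution.
pearsonOracle <- function(tab) {
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    k <- ncol(tab)
    E <- matrix(0, nrow(tab), k)
    chi2 <- 0
    for (i in seq_len(nrow(tab)))
        for (j in seq_len(k)) {
            E[i, j] <- sum(tab[i, ]) * sum(tab[, j]) / sum(tab)
            chi2 <- chi2 + (tab[i, j] - E[i, j])^2 / E[i, j]
        }
    df <- (nrow(tab) - 1) * (k - 1)
    p <- stats::pgamma(chi2 / 2, shape = df / 2, lower.tail = FALSE)
    list(chi2 = chi2, df = df, p = p)
}

# Textbook BH step-up: largest i with p_(i) <= alpha * i / m; reject all
# hypotheses whose p-value is at most p_(i*).
bhOracle <- function(p, alpha) {
    m <- length(p)
    if (!m) return(logical(0))
    o <- order(p)
    ok <- which(p[o] <= alpha * seq_len(m) / m)
    if (!length(ok)) return(rep(FALSE, m))
    p <= p[o][max(ok)]
}

# Exhaustive hypergeometric upper tail by direct summation of the pmf.
hyperOracleUpper <- function(N, K, n, k) {
    j <- k:min(K, n)
    if (k > min(K, n)) return(0)
    sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Build a small PoolCounts from a named list of sites x 4 (A,C,G,T) count
# matrices, one per library; library ids follow <collection>_<R|S><rep>.
makePoolCounts <- function(lib_counts, chrom = "chr1", pos = NULL,
                           ref = NULL) {
    n <- nrow(lib_counts[[1]])
    if (is.null(pos)) pos <- seq_len(n) * 10L
    if (is.null(ref)) ref <- rep("A", n)
    libs <- names(lib_counts)
    counts <- lapply(setNames(nm = c("A", "C", "G", "T")), function(nt) {
        j <- match(nt, c("A", "C", "G", "T"))
        m <- vapply(lib_counts, function(x) as.integer(x[, j]), integer(n))
        if (n == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, libs))
        m
    })
    sites <- GRanges(chrom, IRanges(pos, width = 1L), ref = ref)
    pheno <- ifelse(grepl("_R[0-9]+$", libs), "resistant", "susceptible")
    repl <- as.integer(sub(".*_(R|S)([0-9]+)$", "\\2", libs))
    coll <- sub("_(R|S)[0-9]+$", "", libs)
    PoolCounts(counts, sites,
               data.frame(library_id = libs, collection_id = coll,
                          phenotype = pheno, replicate = repl))
}

# Random 2 x k contingency table with nonzero row sums.
randomTable <- function(k) {
    repeat {
        tab <- matrix(rpois(2 * k, lambda = sample(c(2, 20, 80), 1)), 2, k)
        if (all(rowSums(tab) > 0) && sum(colSums(tab) > 0) >= 2) return(tab)
    }
}

# Wrap a 2-row table (resistant, susceptible) as 4-column count matrices for
# chisqCounts2xk, padding unused nucleotides with zeros.
tableToCounts <- function(tab) {
    res <- sus <- matrix(0L, 1, 4)
    res[1, seq_len(ncol(tab))] <- tab[1, ]
    sus[1, seq_len(ncol(tab))] <- tab[2, ]
    list(res = res, sus = sus)
}
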