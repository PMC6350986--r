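# minimal site-result GRanges for scoreGenes, bypassing the chi-square stage
makeSiteResults <- function(pos, neglog10p, p_value = 10^(-neglog10p),
                            chrom = "chr1") {
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    mcols(gr) <- DataFrame(ref = "A", alleles = "A/C", chi2 = NA_real_,
                           df = 1L, p_value = p_value,
                           neglog10p = neglog10p,
                           hexp_resistant = 0.5, hexp_susceptible = 0.4,
                           flag = "tested")
    gr
}

test_that("gene score is the mean of the ceiling(5%) largest site values", {
    expect_equal(geneScore(5.0), list(score = 5.0, m_top = 1L))
    gs <- geneScore(seq(0, 3.9, by = 0.1))
    expect_identical(gs$m_top, 2L)
    expect_equal(gs$score, (3.9 + 3.8) / 2)
    gs21 <- geneScore(rep(2.5, 21))
    expect_identical(gs21$m_top, 2L)
    expect_equal(gs21$score, 2.5)
    expect_identical(geneScore(rep(1, 20))$m_top, 1L)
    expect_error(geneScore(numeric(0)), "at least one")
})

test_that("gene score is permutation invariant and monotone in site values", {
    set.seed(17)
    for (i in 1:25) {
        v <- rexp(sample(1:60, 1), 1)
        s0 <- geneScore(v)$score
        expect_equal(geneScore(sample(v))$score, s0)
        v2 <- v
        j <- sample(length(v), 1)
        v2[j] <- v2[j] + rexp(1)
        expect_gte(geneScore(v2)$score, s0)
    }
})

test_that("BH step-up matches hand-worked and degenerate cases", {
    expect_identical(bhFdr(c(0.001, 0.008, 0.039, 0.041), alpha = 0.01),
                     c(TRUE, FALSE, FALSE, FALSE))
    expect_identical(bhFdr(rep(1, 5), alpha = 0.01), rep(FALSE, 5))
    expect_identical(bhFdr(0.005, alpha = 0.01), TRUE)
    expect_identical(bhFdr(numeric(0)), logical(0))
})

test_that("site-to-gene assignment uses inclusive 1-based intervals", {
    genes <- GRanges("chr1", IRanges(c(100, 250), c(300, 400)),
                     gene_id = c("GA", "GB"))
    sites <- makeSiteResults(pos = c(100, 300, 301, 401, 50, 275),
                             neglog10p = rep(1, 6))
    asg <- assignSitesToGenes(sites, genes)
    hits <- as.data.frame(asg$hits)
    expect_setequal(hits$queryHits[hits$subjectHits == 1], c(1, 2, 6))
    expect_setequal(hits$queryHits[hits$subjectHits == 2], c(2, 3, 6))
    expect_identical(asg$n_intergenic, 2L)  # positions 401 and 50
    expect_identical(asg$n_multi_gene, 2L)  # positions 275 and 300 in both
})

test_that("high-association requires both an FDR-rejected site and the inclusive cutoff", {
    genes <- GRanges("chr1", IRanges(c(1, 1000), c(500, 1500)),
                     gene_id = c("GA", "GB"))
    sites <- makeSiteResults(pos = c(100, 1100), neglog10p = c(4.0, 12))
    # alpha = 0.01: both sites are BH-rejected; both genes pass the cutoff
    gs <- scoreGenes(sites, genes, alpha = 0.01)
    expect_identical(highAssociationSet(gs), c("GA", "GB"))
    expect_equal(gs$score, c(4.0, 12))
    # an FDR level no site reaches: score 12 alone is not enough
    gs2 <- scoreGenes(sites, genes, alpha = 1e-15)
    expect_identical(gs2$passes_cutoff, c(TRUE, TRUE))
    expect_identical(gs2$passes_fdr, c(FALSE, FALSE))
    expect_length(highAssociationSet(gs2), 0)
    # below the cutoff with a rejected site is equally excluded
    sites3 <- makeSiteResults(pos = 100, neglog10p = 3.9)
    gs3 <- scoreGenes(sites3, genes, alpha = 0.01)
    expect_identical(gs3$passes_fdr[1], TRUE)
    expect_false(gs3$high_association[1])
})

test_that("per-gene expected heterozygosity averages defined sites only", {
    genes <- GRanges("chr1", IRanges(1, 500), gene_id = "GA")
    sites <- makeSiteResults(pos = c(10, 20), neglog10p = c(1, 2))
    mcols(sites)$hexp_resistant <- c(0.18, 0.5)
    mcols(sites)$hexp_susceptible <- c(NA_real_, 0.3)
    gs <- scoreGenes(sites, genes)
    expect_equal(gs$avg_hexp_resistant[1], 0.34)
    expect_equal(gs$avg_hexp_susceptible[1], 0.3)
    mcols(sites)$hexp_susceptible <- NA_real_
    expect_true(is.na(scoreGenes(sites, genes)$avg_hexp_susceptible[1]))
    # a phenotype fixed at every site gives 0, not NA
    mcols(sites)$hexp_susceptible <- 0
    expect_equal(scoreGenes(sites, genes)$avg_hexp_susceptible[1], 0)
})

test_that("genes without tested sites are reported without a score", {
    genes <- GRanges("chr1", IRanges(c(1, 1000), c(500, 1500)),
                     gene_id = c("GA", "GB"))
    sites <- makeSiteResults(pos = 100, neglog10p = 5)
    gs <- scoreGenes(sites, genes)
    expect_identical(gs$n_sites_tested, c(1L, 0L))
    expect_true(is.na(gs$score[2]))
    expect_false(gs$high_association[2])
})

test_that("a null ideal-mode run yields an essentially empty high-association set", {
    cfg <- simulationConfig(seed = 23L, n_genes = 120L, delta = 0,
                            mode = "ideal", seq_error = 0,
                            triallelic_fraction = 0, n_collections = 1L)
    sim <- simulateCollection(cfg)
    pc <- flagMonomorphic(filterSites(sim$counts)$counts)$counts
    gs <- scoreGenes(testSites(pc), sim$genes, categories = sim$categories)
    hits <- highAssociationSet(gs)
    expect_lte(length(hits), 2)
    if (length(hits))
        expect_true(all(gs$passes_fdr[gs$gene_id %in% hits]))
})
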