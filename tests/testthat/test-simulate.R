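test_that("identical config and seed reproduce byte-identical artifact files", {
    cfg <- simulationConfig(seed = 7L, n_genes = 30L, n_causal_genes = 6L,
                            n_collections = 2L)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    s1 <- simulateStudy(cfg, dir = d1)
    s2 <- simulateStudy(cfg, dir = d2)
    f1 <- sort(list.files(d1, recursive = TRUE))
    expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
    for (f in f1)
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         info = f)
    expect_identical(sum(s1$truth_genes$is_causal), 6L)
})

test_that("truth table covers every gene once and flags exactly the causal count", {
    cfg <- simulationConfig(seed = 7L, n_genes = 100L, n_causal_genes = 20L,
                            delta = 0.35, n_collections = 1L)
    sim <- simulateCollection(cfg)
    expect_identical(sort(sim$truth_genes$gene_id),
                     sort(unique(mcols(sim$genes)$gene_id)))
    expect_identical(anyDuplicated(sim$truth_genes$gene_id), 0L)
    expect_identical(sum(sim$truth_genes$is_causal), 20L)
    expect_setequal(unique(sim$truth_sites$gene_id), sim$truth_genes$gene_id)
    # causal sites only in causal genes, and every causal gene has >= 1
    causal_ids <- sim$truth_genes$gene_id[sim$truth_genes$is_causal]
    with_causal <- unique(sim$truth_sites$gene_id[sim$truth_sites$is_causal_site])
    expect_setequal(with_causal, causal_ids)
    # gene intervals do not overlap within a chromosome
    expect_identical(sum(GenomicRanges::countOverlaps(sim$genes, sim$genes) > 1), 0L)
})

test_that("a null configuration marks no gene causal and phenotypes are exchangeable", {
    cfg <- simulationConfig(seed = 3L, n_genes = 150L, delta = 0,
                            mode = "ideal", seq_error = 0,
                            triallelic_fraction = 0, n_collections = 1L)
    sim <- simulateCollection(cfg)
    expect_identical(sum(sim$truth_genes$is_causal), 0L)
    # distribution of alternate-allele read frequencies matches across
    # phenotypes over many independent sites
    pc <- flagMonomorphic(filterSites(sim$counts)$counts)$counts
    alt <- sim$truth_sites$alt[match(start(rowRanges(pc)),
                                     sim$truth_sites$pos)]
    fr <- function(pheno) {
        m <- phenotypeCounts(pc, pheno)
        m[cbind(seq_len(nrow(m)), match(alt, c("A", "C", "G", "T")))] /
            rowSums(m)
    }
    ks <- suppressWarnings(stats::ks.test(fr("resistant"),
                                          fr("susceptible")))
    expect_gt(ks$p.value, 1e-3)
})

test_that("read frequencies recover the configured population frequency", {
    cfg <- simulationConfig(seed = 5L, n_genes = 200L, n_causal_genes = 0L,
                            delta = 0, seq_error = 0,
                            triallelic_fraction = 0, n_collections = 1L,
                            mode = "pooled")
    sim <- simulateCollection(cfg)
    pc <- sim$counts
    alt_idx <- match(sim$truth_sites$alt, c("A", "C", "G", "T"))
    m <- phenotypeCounts(pc, "resistant") + phenotypeCounts(pc, "susceptible")
    d <- rowSums(m)
    keep <- d > 0
    obs <- m[cbind(seq_len(nrow(m)), alt_idx)][keep] / d[keep]
    err <- obs - sim$truth_sites$freq_alt_susceptible[keep]
    se <- stats::sd(err) / sqrt(length(err))
    expect_lt(abs(mean(err)), 3 * se)
})

test_that("finite-pool sampling adds the p(1-p)/2N variance on top of read noise", {
    # pools of 25 diploids at baseline 0.5 and depth 1e4: the variance of the
    # realized read frequency approaches p(1-p)/50, far above p(1-p)/1e4
    cfg <- simulationConfig(seed = 9L, n_genes = 4L, snps_per_gene = 250,
                            n_causal_genes = 0L, delta = 0,
                            baseline_freq_min = 0.5, baseline_freq_max = 0.5,
                            pool_individuals = 25L, coverage_mean = 1e4,
                            coverage_dispersion = Inf, seq_error = 0,
                            triallelic_fraction = 0, n_collections = 1L,
                            mode = "pooled")
    sim <- simulateCollection(cfg)
    alt_idx <- match(sim$truth_sites$alt, c("A", "C", "G", "T"))
    freqs <- unlist(lapply(c("A", "C", "G", "T"), function(nt) {
        a <- SummarizedExperiment::assay(sim$counts, nt)
        sel <- alt_idx == match(nt, c("A", "C", "G", "T"))
        a[sel, ] / 1e4
    }))
    v <- stats::var(as.numeric(freqs))
    pool_bound <- 0.5 * 0.5 / 50
    read_only <- 0.5 * 0.5 / 1e4
    expect_gt(v, 3 * read_only)
    mc_se <- sqrt(2) * (pool_bound + read_only) / sqrt(length(freqs))
    expect_lt(abs(v - (pool_bound + read_only)), 4 * mc_se)
})

test_that("an infeasible delta is a hard error naming the site", {
    cfg <- simulationConfig(seed = 2L, n_genes = 10L, n_causal_genes = 5L,
                            delta = 0.6, baseline_freq_min = 0.45,
                            baseline_freq_max = 0.5, n_collections = 1L)
    expect_error(simulateCollection(cfg), "above 1 at chr[0-9]+:[0-9]+")
})

test_that("triallelic sites appear and zero-depth libraries are recorded", {
    cfg <- simulationConfig(seed = 13L, n_genes = 60L,
                            triallelic_fraction = 0.3, coverage_mean = 5,
                            n_collections = 1L)
    sim <- simulateCollection(cfg)
    expect_gt(sum(!is.na(sim$truth_sites$alt2)), 0)
    expect_gt(S4Vectors::metadata(sim$counts)$n_zero_depth, 0)
})
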