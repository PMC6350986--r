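test_that("counts TSV writer and reader are mutually inverse", {
    set.seed(42)
    pc <- makePoolCounts(list(
        X_R1 = matrix(rpois(12, 20), 3, 4),
        X_R2 = matrix(rpois(12, 20), 3, 4),
        X_S1 = matrix(rpois(12, 20), 3, 4),
        X_S2 = matrix(rpois(12, 20), 3, 4)),
        ref = c("A", "C", "G"))
    path <- withr::local_tempfile(fileext = ".tsv")
    writePoolCounts(pc, path)
    back <- readPoolCounts(path)
    for (nt in c("A", "C", "G", "T"))
        expect_identical(SummarizedExperiment::assay(back, nt),
                         SummarizedExperiment::assay(pc, nt))
    expect_identical(start(rowRanges(back)), start(rowRanges(pc)))
    expect_identical(refAllele(back), refAllele(pc))
    expect_identical(poolPhenotype(back), poolPhenotype(pc))
})

test_that("a valid header with an empty body parses to zero sites", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste(c("chrom", "pos", "ref",
                       paste0("X_R1:", c("A", "C", "G", "T", "depth")),
                       paste0("X_S1:", c("A", "C", "G", "T", "depth"))),
                     collapse = "\t"), path)
    pc <- readPoolCounts(path)
    expect_s4_class(pc, "PoolCounts")
    expect_identical(nrow(pc), 0L)
})

test_that("inconsistent depth, duplicate sites and bad nucleotides are rejected with locations", {
    pc <- makePoolCounts(list(X_R1 = matrix(5L, 2, 4),
                              X_S1 = matrix(5L, 2, 4)))
    path <- withr::local_tempfile(fileext = ".tsv")
    writePoolCounts(pc, path)
    lines <- readLines(path)
    bad <- sub("20$", "19", lines[2])  # corrupt first site's last depth field
    writeLines(c(lines[1], bad, lines[3]), path)
    expect_error(readPoolCounts(path), "chr1:10.*line 2")

    writeLines(c(lines[1], lines[2], lines[2]), path)
    expect_error(readPoolCounts(path), "duplicated site")

    writeLines(c(lines[1], sub("\tA\t", "\tN\t", lines[2])), path)
    expect_error(readPoolCounts(path), "unknown reference nucleotide")
})

test_that("coverage filter is per library with an inclusive boundary", {
    # site 1: one library at 14 -> removed; site 2: all at exactly 15 -> kept
    lib <- function(d1, d2) cbind(c(d1, d2), 0L, 0L, 0L)
    pc <- makePoolCounts(list(X_R1 = lib(14L, 15L), X_R2 = lib(50L, 15L),
                              X_S1 = lib(50L, 15L), X_S2 = lib(50L, 15L)))
    out <- filterSites(pc, minCoverage = 15L)
    expect_identical(out$report$n_removed_low_coverage, 1L)
    expect_identical(start(rowRanges(out$counts)), 20L)
    expect_true(all(rowSums(depthMatrix(out$counts)) >= 60))
})

test_that("monomorphic and no-data sites are separated from polymorphic ones", {
    set.seed(7)
    mono <- cbind(30L, 0L, 0L, 0L)
    poly <- cbind(25L, 5L, 0L, 0L)
    none <- cbind(0L, 0L, 0L, 0L)
    build <- function(rows) do.call(rbind, rows)
    rows <- list(mono, poly, mono, poly, mono, poly, mono, none, poly, poly)
    pc <- makePoolCounts(list(X_R1 = build(rows), X_S1 = build(rows)))
    out <- flagMonomorphic(pc)
    expect_identical(out$n_monomorphic, 4L)
    expect_identical(out$n_no_data, 1L)
    expect_identical(nrow(out$counts), 5L)

    # minimal polymorphism: 99 ref + 1 alt in total is retained
    pc2 <- makePoolCounts(list(X_R1 = cbind(99L, 1L, 0L, 0L),
                               X_S1 = cbind(0L, 0L, 0L, 0L)))
    expect_identical(nrow(flagMonomorphic(pc2)$counts), 1L)
})

test_that("coverage filtering and monomorphic exclusion commute", {
    set.seed(11)
    for (rep in 1:20) {
        n <- 30
        mats <- lapply(setNames(nm = c("Y_R1", "Y_R2", "Y_S1", "Y_S2")),
                       function(i) {
            m <- matrix(rpois(n * 4, 6), n, 4)
            m[sample(n, 8), sample(4, 1)] <- 0L
            zero <- sample(n, 5)
            m[zero, 2:4] <- 0L  # force some monomorphic candidates
            m
        })
        pc <- makePoolCounts(mats)
        a <- flagMonomorphic(filterSites(pc)$counts)$counts
        b <- filterSites(flagMonomorphic(pc)$counts)$counts
        expect_identical(start(rowRanges(a)), start(rowRanges(b)))
    }
})

test_that("coverage summary uses total depth across libraries with midpoint median", {
    mk <- function(totals) {
        q <- as.integer(totals / 4)
        makePoolCounts(list(X_R1 = cbind(q, 0L, 0L, 0L),
                            X_R2 = cbind(q, 0L, 0L, 0L),
                            X_S1 = cbind(q, 0L, 0L, 0L),
                            X_S2 = cbind(totals - 3L * q, 0L, 0L, 0L)))
    }
    s1 <- coverageSummary(mk(60L))
    expect_equal(unlist(s1), c(min = 60, max = 60, mean = 60, median = 60))
    s2 <- coverageSummary(mk(c(60L, 100L, 140L)))
    expect_equal(s2$mean, 100); expect_equal(s2$median, 100)
    s3 <- coverageSummary(mk(c(60L, 80L, 100L, 1000L)))
    expect_equal(s3$median, 90); expect_equal(s3$mean, 310)
    expect_error(coverageSummary(mk(60L)[0, ]), "empty")
})

test_that("variant-sites-per-aligned-nucleotide ratio matches its definition", {
    expect_equal(sitesPerAlignedNtRatio(0, 1e4, 100), 0)
    expect_equal(sitesPerAlignedNtRatio(5000, 10000, 100), 5)
    expect_equal(sitesPerAlignedNtRatio(5000, 20000, 100),
                 sitesPerAlignedNtRatio(5000, 10000, 100) / 2)
    expect_error(sitesPerAlignedNtRatio(5, 0, 100), "positive")
})

test_that("gene models round-trip through GFF3 and categories validate", {
    genes <- GRanges("chr2", IRanges(c(100, 900), c(500, 1500)),
                     gene_id = c("G1", "G2"),
                     biotype = c("protein_coding", "ncRNA"),
                     description = c("a", "b"))
    gff <- withr::local_tempfile(fileext = ".gff3")
    poolAssoc:::.writeGff3(genes, gff)
    back <- readGeneModels(gff)
    expect_identical(mcols(back)$gene_id, c("G1", "G2"))
    expect_identical(start(back), c(100L, 900L))
    expect_identical(mcols(back)$biotype, c("protein_coding", "ncRNA"))

    cat_path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tcategory_code", "G1\tTRP", "G2\tBOGUS"), cat_path)
    expect_error(readCategoryMap(cat_path), "BOGUS")
})
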