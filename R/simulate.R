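#' Configuration of the synthetic pool-seq generator
#'
#' Holds the design of a simulated pooled-resequencing study: gene landscape,
#' allele-frequency model, pooling design and sequencing-depth law. Defaults
#' reproduce the emulated study design at reduced scale: 3 collections, each
#' with 2 resistant + 2 susceptible replicate pools of 25 diploid females,
#' 100 genes on 3 chromosomes of which 20 (shared across collections) carry
#' resistance-associated allele-frequency differentials of `delta = 0.35`,
#' and a mean total coverage of 150 across each collection's four libraries
#' (per-library mean 37.5, marginally negative binomial).
#'
#' @slot seed Integer RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @slot n_chromosomes,n_genes,n_causal_genes,n_collections Design sizes.
#' @slot gene_length_meanlog,gene_length_sdlog Log-normal gene length (bp).
#' @slot snps_per_gene Poisson mean number of variant sites per gene
#'   (minimum 1 enforced).
#' @slot causal_site_fraction Fraction of a causal gene's sites that carry
#'   the differential (at least one site always does).
#' @slot delta Allele-frequency differential in [0,1] added to the alternate
#'   allele of causal sites in the resistant population. A frequency pushed
#'   outside [0,1] is a hard error naming the site, never silently clipped.
#' @slot baseline_freq_min,baseline_freq_max Uniform law for the population
#'   alternate-allele frequency shared by both phenotypes at non-causal
#'   sites (and by the susceptible phenotype everywhere).
#' @slot pool_individuals Diploid individuals per pool (default 25).
#' @slot replicates_per_phenotype Replicate pools per phenotype (default 2).
#' @slot coverage_mean,coverage_dispersion Per-library depth law: each site
#'   carries a capture efficiency drawn once per landscape from
#'   Gamma(shape = `coverage_dispersion`, rate = `coverage_dispersion`)
#'   (mean 1) and shared by every library and collection, as a common capture
#'   probe set implies; library depth at a site is Poisson(`coverage_mean` x
#'   efficiency), i.e. marginally negative binomial with mean
#'   `coverage_mean` and size `coverage_dispersion`.
#'   `coverage_dispersion = Inf` gives fixed depth `coverage_mean`. The
#'   default per-library mean 37.5 corresponds to a mean total coverage of
#'   150 across the four libraries of a collection.
#' @slot seq_error Per-read miscall probability; errors are redistributed
#'   uniformly over the other three nucleotides.
#' @slot mode `"pooled"` draws 2 x pool_individuals chromosomes per pool from
#'   the population frequency and then reads from the realized pool
#'   frequency (finite-pool resampling); `"ideal"` draws reads directly from
#'   the population frequency (calibration mode for the read-level test).
#' @slot triallelic_fraction Fraction of sites given a third segregating
#'   allele, exercising the multi-allele df rule.
#' @slot noncoding_fraction Fraction of genes marked non-coding (excluded
#'   from the enrichment background and never causal).
#' @slot category_enrichment Named numeric: realized causal-gene
#'   over-representation per category code. Each named category contributes
#'   `min(K, round(fold * K/N * n_causal))` causal genes (K = category size,
#'   N = coding genes); the default `c(TRP = 5)` plants a transport category
#'   over-represented about 5-fold among causal genes. With `delta = 0` no
#'   gene is flagged causal (a null configuration has no differentiated
#'   locus).
#' @slot collection_ids Labels; empty means `C1..Cn`.
#' @export
setClass("SimulationConfig", representation(
    seed = "integer",
    n_chromosomes = "integer",
    n_genes = "integer",
    gene_length_meanlog = "numeric",
    gene_length_sdlog = "numeric",
    snps_per_gene = "numeric",
    n_causal_genes = "integer",
    causal_site_fraction = "numeric",
    delta = "numeric",
    baseline_freq_min = "numeric",
    baseline_freq_max = "numeric",
    pool_individuals = "integer",
    replicates_per_phenotype = "integer",
    coverage_mean = "numeric",
    coverage_dispersion = "numeric",
    seq_error = "numeric",
    mode = "character",
    triallelic_fraction = "numeric",
    noncoding_fraction = "numeric",
    category_enrichment = "numeric",
    n_collections = "integer",
    collection_ids = "character"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@delta < 0 || object@delta > 1)
        msg <- c(msg, "delta must be in [0, 1]")
    if (object@n_causal_genes > object@n_genes)
        msg <- c(msg, "n_causal_genes must be <= n_genes")
    if (object@pool_individuals < 1L)
        msg <- c(msg, "pool_individuals must be positive")
    if (object@coverage_mean <= 0)
        msg <- c(msg, "coverage_mean must be positive")
    if (!object@mode %in% c("pooled", "ideal"))
        msg <- c(msg, "mode must be 'pooled' or 'ideal'")
    if (object@baseline_freq_min <= 0 ||
        object@baseline_freq_max >= 1 ||
        object@baseline_freq_min > object@baseline_freq_max)
        msg <- c(msg, "baseline frequency range must satisfy 0 < min <= max < 1")
    if (object@seq_error < 0 || object@seq_error >= 0.25)
        msg <- c(msg, "seq_error must be in [0, 0.25)")
    for (f in c("causal_site_fraction", "triallelic_fraction",
                "noncoding_fraction"))
        if (slot(object, f) < 0 || slot(object, f) > 1)
            msg <- c(msg, paste(f, "must be in [0, 1]"))
    if (length(object@collection_ids) &&
        length(object@collection_ids) != object@n_collections)
        msg <- c(msg, "collection_ids length must equal n_collections")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig Constructor with the study-design defaults.
#' @param seed Integer RNG seed.
#' @param n_chromosomes,n_genes,n_causal_genes,n_collections,pool_individuals,replicates_per_phenotype
#'   Integer design sizes.
#' @param gene_length_meanlog,gene_length_sdlog,snps_per_gene,causal_site_fraction,delta,baseline_freq_min,baseline_freq_max,coverage_mean,coverage_dispersion,seq_error,triallelic_fraction,noncoding_fraction
#'   Numeric model parameters (see slots).
#' @param mode `"pooled"` or `"ideal"`.
#' @param category_enrichment Named numeric causal-weight multipliers.
#' @param collection_ids Optional labels.
#' @export
simulationConfig <- function(seed = 1L,
                             n_chromosomes = 3L,
                             n_genes = 100L,
                             gene_length_meanlog = log(2000),
                             gene_length_sdlog = 0.4,
                             snps_per_gene = 40,
                             n_causal_genes = 20L,
                             causal_site_fraction = 0.25,
                             delta = 0.35,
                             baseline_freq_min = 0.05,
                             baseline_freq_max = 0.5,
                             pool_individuals = 25L,
                             replicates_per_phenotype = 2L,
                             coverage_mean = 37.5,
                             coverage_dispersion = 2,
                             seq_error = 0.001,
                             mode = "pooled",
                             triallelic_fraction = 0.02,
                             noncoding_fraction = 0.19,
                             category_enrichment = c(TRP = 5),
                             n_collections = 3L,
                             collection_ids = character(0)) {
    new("SimulationConfig", seed = as.integer(seed),
        n_chromosomes = as.integer(n_chromosomes),
        n_genes = as.integer(n_genes),
        gene_length_meanlog = gene_length_meanlog,
        gene_length_sdlog = gene_length_sdlog,
        snps_per_gene = snps_per_gene,
        n_causal_genes = as.integer(n_causal_genes),
        causal_site_fraction = causal_site_fraction,
        delta = delta,
        baseline_freq_min = baseline_freq_min,
        baseline_freq_max = baseline_freq_max,
        pool_individuals = as.integer(pool_individuals),
        replicates_per_phenotype = as.integer(replicates_per_phenotype),
        coverage_mean = coverage_mean,
        coverage_dispersion = coverage_dispersion,
        seq_error = seq_error,
        mode = mode,
        triallelic_fraction = triallelic_fraction,
        noncoding_fraction = noncoding_fraction,
        category_enrichment = category_enrichment,
        n_collections = as.integer(n_collections),
        collection_ids = as.character(collection_ids))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@n_collections, "collection(s),",
        object@n_genes, "genes (", object@n_causal_genes, "causal ) on",
        object@n_chromosomes, "chromosomes\n")
    cat(sprintf(
        "  pools: %d x %d individuals per phenotype | delta = %.2f | %s mode\n",
        object@replicates_per_phenotype, object@pool_individuals,
        object@delta, object@mode))
    cat(sprintf("  coverage: NB(mean %.0f, size %s) | seq_error %.4g | seed %d\n",
                object@coverage_mean, format(object@coverage_dispersion),
                object@seq_error, object@seed))
})

.collectionIds <- function(config) {
    if (length(config@collection_ids)) config@collection_ids
    else paste0("C", seq_len(config@n_collections))
}

# Vectorised multinomial draws: one draw per row of the 4-column probability
# matrix P, with row-specific sizes, via sequential conditional binomials.
.rmultinomRows <- function(size, P) {
    n <- length(size)
    out <- matrix(0L, n, 4L, dimnames = list(NULL, NUCLEOTIDES))
    rem <- as.integer(size)
    cum <- rep(0, n)
    for (j in 1:3) {
        pj <- P[, j] / pmax(1 - cum, .Machine$double.eps)
        pj <- pmin(pmax(pj, 0), 1)
        x <- stats::rbinom(n, rem, pj)
        out[, j] <- x
        rem <- rem - x
        cum <- cum + P[, j]
    }
    out[, 4L] <- rem
    out
}

# Apply a symmetric per-read miscall probability e to a frequency matrix:
# each true-nucleotide read is observed as one of the other three with
# probability e/3 each.
.errorFreq <- function(P, e) {
    if (e <= 0) return(P)
    P * (1 - 4 * e / 3) + e / 3
}

#' Draw the shared gene landscape and population frequencies
#'
#' Internal stage of [simulateStudy()]/[simulateCollection()], exposed for
#' testing: gene intervals (non-overlapping within each chromosome),
#' functional categories, causal-gene choice and per-site population allele
#' frequencies for the two phenotype classes. Consumes the current RNG
#' stream.
#'
#' @param config A [SimulationConfig-class].
#' @return List with `genes` (GRanges), `categories` (data.frame over coding
#'   genes), `truth_genes`, `truth_sites` (data.frames) and the per-site
#'   frequency matrices `freq_resistant`, `freq_susceptible` (sites x 4).
#' @keywords internal
#' @export
simulateLandscape <- function(config) {
    ng <- config@n_genes
    gene_id <- sprintf("G%04d", seq_len(ng))
    chrom <- paste0("chr", rep_len(seq_len(config@n_chromosomes), ng))
    len <- pmax(200L, as.integer(round(stats::rlnorm(
        ng, config@gene_length_meanlog, config@gene_length_sdlog))))
    start <- integer(ng)
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        gaps <- as.integer(round(stats::runif(length(i), 1000, 10000)))
        start[i] <- cumsum(gaps) + c(0L, cumsum(len[i])[-length(i)]) + 1L
    }
    end <- start + len - 1L

    n_noncoding <- round(config@noncoding_fraction * ng)
    noncoding <- sample(ng, n_noncoding)
    biotype <- rep("protein_coding", ng)
    biotype[noncoding] <- "ncRNA"
    coding <- which(biotype == "protein_coding")

    cat_code <- rep(NA_character_, ng)
    cat_code[coding] <- sample(categoryCodes(), length(coding),
                               replace = TRUE)
    if (config@n_causal_genes > length(coding))
        stop("n_causal_genes exceeds the number of coding genes")
    n_causal <- if (config@delta == 0) 0L else config@n_causal_genes
    # Deterministic planting: each enriched category contributes a realized
    # causal count equal to fold x its background share of the causal set
    # (capped at the category size); remaining causal genes are drawn
    # uniformly from the other coding genes.
    causal_genes <- integer(0)
    enr <- config@category_enrichment
    n_left <- n_causal
    for (cc in names(enr)) {
        members <- coding[cat_code[coding] == cc]
        n_cc <- min(length(members), n_left,
                    round(enr[[cc]] * length(members) / length(coding) *
                          n_causal))
        causal_genes <- c(causal_genes,
                          if (n_cc) sample(members, n_cc) else integer(0))
        n_left <- n_left - n_cc
    }
    rest <- setdiff(coding, c(causal_genes,
                              coding[cat_code[coding] %in% names(enr)]))
    causal_genes <- sort(c(causal_genes, sample(rest, n_left)))
    is_causal <- seq_len(ng) %in% causal_genes

    genes <- GRanges(chrom, IRanges(start, end), gene_id = gene_id,
                     biotype = biotype,
                     description = paste("synthetic gene", gene_id))
    names(genes) <- gene_id

    # sites
    m <- pmax(1L, stats::rpois(ng, config@snps_per_gene))
    site_gene <- rep(seq_len(ng), m)
    pos <- unlist(lapply(seq_len(ng), function(j)
        sort(sample(seq(start[j], end[j]), m[j]))), use.names = FALSE)
    ns <- length(pos)
    ref <- sample(NUCLEOTIDES, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(NUCLEOTIDES, r), 1L), "")
    tri <- stats::runif(ns) < config@triallelic_fraction
    alt2 <- rep(NA_character_, ns)
    alt2[tri] <- mapply(function(r, a)
        sample(setdiff(NUCLEOTIDES, c(r, a)), 1L), ref[tri], alt[tri])

    f <- stats::runif(ns, config@baseline_freq_min, config@baseline_freq_max)
    f2 <- ifelse(tri, stats::runif(ns, 0.02, 0.10), 0)

    causal_site <- rep(FALSE, ns)
    in_causal <- site_gene %in% causal_genes
    causal_site[in_causal] <- stats::runif(sum(in_causal)) <
        config@causal_site_fraction
    for (j in causal_genes) {      # every causal gene carries >= 1 causal site
        i <- which(site_gene == j)
        if (!any(causal_site[i])) causal_site[sample(i, 1L)] <- TRUE
    }

    freq_s <- matrix(0, ns, 4L, dimnames = list(NULL, NUCLEOTIDES))
    rows <- seq_len(ns)
    freq_s[cbind(rows, match(alt, NUCLEOTIDES))] <- f
    freq_s[cbind(rows[tri], match(alt2[tri], NUCLEOTIDES))] <- f2[tri]
    freq_s[cbind(rows, match(ref, NUCLEOTIDES))] <-
        1 - f - f2
    freq_r <- freq_s
    f_res <- f + ifelse(causal_site, config@delta, 0)
    bad <- which(f_res + f2 > 1 + 1e-12)
    if (length(bad))
        stop(sprintf(
            "delta pushes the alternate-allele frequency above 1 at %s:%d",
            chrom[site_gene[bad[1]]], pos[bad[1]]))
    freq_r[cbind(rows, match(alt, NUCLEOTIDES))] <- f_res
    freq_r[cbind(rows, match(ref, NUCLEOTIDES))] <- 1 - f_res - f2

    # per-site capture efficiency, shared by all libraries and collections
    eff <- if (is.finite(config@coverage_dispersion))
        stats::rgamma(ns, shape = config@coverage_dispersion,
                      rate = config@coverage_dispersion)
    else rep(1, ns)

    list(genes = genes,
         categories = data.frame(gene_id = gene_id[coding],
                                 category_code = cat_code[coding]),
         truth_genes = data.frame(gene_id = gene_id, is_causal = is_causal,
                                  biotype = biotype,
                                  category_code = cat_code),
         truth_sites = data.frame(gene_id = gene_id[site_gene],
                                  chrom = chrom[site_gene], pos = pos,
                                  ref = ref, alt = alt, alt2 = alt2,
                                  freq_alt_resistant = f_res,
                                  freq_alt_susceptible = f,
                                  is_causal_site = causal_site),
         freq_resistant = freq_r, freq_susceptible = freq_s,
         site_efficiency = eff)
}

.simulateCounts <- function(config, landscape, collection_id) {
    ns <- nrow(landscape$freq_resistant)
    reps <- config@replicates_per_phenotype
    pheno <- rep(c("resistant", "susceptible"), each = reps)
    repl <- rep(seq_len(reps), 2L)
    lib_id <- paste0(collection_id, "_",
                     ifelse(pheno == "resistant", "R", "S"), repl)
    nlib <- length(lib_id)
    assays <- lapply(stats::setNames(nm = NUCLEOTIDES), function(nt)
        matrix(0L, ns, nlib, dimnames = list(NULL, lib_id)))
    n_zero_depth <- 0L
    chroms_per_pool <- 2L * config@pool_individuals
    for (l in seq_len(nlib)) {
        P <- if (pheno[l] == "resistant") landscape$freq_resistant
             else landscape$freq_susceptible
        depth <- if (is.infinite(config@coverage_dispersion))
            rep(as.integer(round(config@coverage_mean)), ns)
        else stats::rpois(ns, config@coverage_mean *
                              landscape$site_efficiency)
        n_zero_depth <- n_zero_depth + sum(depth == 0L)
        poolfreq <- if (config@mode == "pooled")
            .rmultinomRows(rep(chroms_per_pool, ns), P) / chroms_per_pool
        else P
        reads <- .rmultinomRows(depth, .errorFreq(poolfreq,
                                                  config@seq_error))
        for (nt in NUCLEOTIDES) assays[[nt]][, l] <- reads[, nt]
    }
    rl <- 100L
    total_nt <- vapply(lib_id, function(l)
        sum(assays$A[, l] + assays$C[, l] + assays$G[, l] + assays$T[, l]),
        0)
    libs <- DataFrame(library_id = lib_id, collection_id = collection_id,
                      phenotype = pheno, replicate = repl,
                      aligned_reads = as.numeric(ceiling(total_nt / rl)),
                      read_length = rl)
    ts <- landscape$truth_sites
    sites <- GRanges(ts$chrom, IRanges(ts$pos, width = 1L), ref = ts$ref)
    pc <- PoolCounts(assays, sites, libs)
    metadata(pc)$n_zero_depth <- n_zero_depth
    pc
}

#' Simulate one collection of pooled read counts
#'
#' Draws a gene landscape (unless one is supplied) and the read counts of
#' one collection's libraries, and optionally writes the four artifact files
#' (counts TSV, GFF3 gene annotation, category map TSV, truth TSV) to a
#' directory. Seeds the RNG from `config@seed` when drawing its own
#' landscape, so identical config + seed reproduces identical files.
#'
#' @param config A [SimulationConfig-class].
#' @param collection_id Collection label (default `"C1"`).
#' @param landscape Optional landscape from [simulateLandscape()] (used by
#'   [simulateStudy()] to share causal genes across collections). When
#'   supplied, the caller controls the RNG state.
#' @param dir Optional output directory; created if needed.
#' @return List with `counts` ([PoolCounts-class]), `genes` (GRanges),
#'   `categories`, `truth_genes`, `truth_sites` and, when `dir` is given,
#'   `paths`.
#' @export
simulateCollection <- function(config, collection_id = "C1",
                               landscape = NULL, dir = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (is.null(landscape)) {
        set.seed(config@seed)
        landscape <- simulateLandscape(config)
    }
    counts <- .simulateCounts(config, landscape, collection_id)
    out <- list(counts = counts, genes = landscape$genes,
                categories = landscape$categories,
                truth_genes = landscape$truth_genes,
                truth_sites = landscape$truth_sites)
    if (!is.null(dir)) out$paths <- .writeCollection(out, collection_id, dir)
    out
}

#' Simulate a multi-collection study
#'
#' One shared gene landscape (identical gene models, categories, causal
#' genes and population frequencies) with independently sampled pools and
#' read counts for each collection — the design of a replicated
#' resistant/susceptible pool-seq comparison across field collections.
#'
#' @param config A [SimulationConfig-class].
#' @param dir Optional output directory for the artifact files.
#' @return List with `collections` (named list of [PoolCounts-class]),
#'   `genes`, `categories`, `truth_genes`, `truth_sites` and optionally
#'   `paths`.
#' @export
simulateStudy <- function(config, dir = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    landscape <- simulateLandscape(config)
    ids <- .collectionIds(config)
    collections <- lapply(ids, function(cid)
        .simulateCounts(config, landscape, cid))
    names(collections) <- ids
    out <- list(collections = collections, genes = landscape$genes,
                categories = landscape$categories,
                truth_genes = landscape$truth_genes,
                truth_sites = landscape$truth_sites)
    if (!is.null(dir)) out$paths <- .writeStudy(out, dir)
    out
}

.writeGff3 <- function(genes, path) {
    gr <- genes
    mcols(gr) <- DataFrame(source = "poolAssoc", type = "gene",
                           ID = mcols(genes)$gene_id,
                           biotype = mcols(genes)$biotype,
                           description = mcols(genes)$description)
    rtracklayer::export(gr, path, format = "gff3")
    path
}

.writeCollection <- function(sim, collection_id, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
        counts = file.path(dir, paste0("counts_", collection_id, ".tsv")),
        genes = file.path(dir, "genes.gff3"),
        categories = file.path(dir, "categories.tsv"),
        truth_genes = file.path(dir, "truth_genes.tsv"),
        truth_sites = file.path(dir, "truth_sites.tsv"),
        manifest = file.path(dir, "manifest.tsv"))
    writePoolCounts(sim$counts, paths$counts)
    .writeGff3(sim$genes, paths$genes)
    utils::write.table(sim$categories, paths$categories, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth_genes, paths$truth_genes, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth_sites, paths$truth_sites, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(colData(sim$counts))
    manifest <- data.frame(library_id = cd$library_id,
                           collection = cd$collection_id,
                           phenotype = cd$phenotype,
                           replicate = cd$replicate,
                           aligned_reads = cd$aligned_reads,
                           read_length = cd$read_length)
    utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths
}

.writeStudy <- function(study, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(counts = list())
    for (cid in names(study$collections)) {
        p <- file.path(dir, paste0("counts_", cid, ".tsv"))
        writePoolCounts(study$collections[[cid]], p)
        paths$counts[[cid]] <- p
    }
    paths$genes <- .writeGff3(study$genes, file.path(dir, "genes.gff3"))
    paths$categories <- file.path(dir, "categories.tsv")
    utils::write.table(study$categories, paths$categories, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$truth_genes <- file.path(dir, "truth_genes.tsv")
    utils::write.table(study$truth_genes, paths$truth_genes, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$truth_sites <- file.path(dir, "truth_sites.tsv")
    utils::write.table(study$truth_sites, paths$truth_sites, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cd <- do.call(rbind, lapply(study$collections, function(x)
        as.data.frame(colData(x))))
    paths$manifest <- file.path(dir, "manifest.tsv")
    utils::write.table(
        data.frame(library_id = cd$library_id, collection = cd$collection_id,
                   phenotype = cd$phenotype, replicate = cd$replicate,
                   aligned_reads = cd$aligned_reads,
                   read_length = cd$read_length),
        paths$manifest, sep = "\t", quote = FALSE, row.names = FALSE)
    paths
}
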