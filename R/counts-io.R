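#' Read a per-site per-pool nucleotide count table
#'
#' Reads the tab-separated counts dialect written by [writePoolCounts()] and
#' by the synthetic generator: columns `chrom`, `pos`, `ref`, then one block
#' per library `<lib>:A, <lib>:C, <lib>:G, <lib>:T, <lib>:depth`. The format
#' models the post-alignment read-count tables produced downstream of an
#' mpileup/readcounts step. Each library's depth column must equal the sum of
#' its four nucleotide columns; violations are rejected with the offending
#' line number.
#'
#' The library roster is inferred from the column names. Without a manifest,
#' library ids must follow `<collection>_<R|S><replicate>` (e.g. `C1_R2` =
#' collection C1, resistant, replicate 2). A manifest (see
#' [readLibraryManifest()]) overrides the inferred roster and may add
#' `aligned_reads` metadata; its library ids must match the file's columns.
#'
#' @param path Path to the counts TSV.
#' @param manifest Optional library manifest `data.frame` as returned by
#'   [readLibraryManifest()].
#' @return A [PoolCounts-class] object (possibly with zero rows).
#' @seealso [writePoolCounts()], [filterSites()], [flagMonomorphic()]
#' @export
readPoolCounts <- function(path, manifest = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos", "ref") %in% colnames(tab)))
        stop("counts header must start with chrom, pos, ref")
    libcols <- grep(":(A|C|G|T|depth)$", colnames(tab), value = TRUE)
    libs <- unique(sub(":(A|C|G|T|depth)$", "", libcols))
    if (!length(libs)) stop("no library count columns found in header")
    for (lib in libs) {
        need <- paste0(lib, ":", c(NUCLEOTIDES, "depth"))
        if (!all(need %in% colnames(tab)))
            stop("incomplete column block for library ", lib)
    }
    roster <- if (is.null(manifest)) .inferRoster(libs) else {
        if (!setequal(manifest$library_id, libs))
            stop("manifest libraries do not match counts columns: ",
                 paste(symdiff <- union(setdiff(manifest$library_id, libs),
                                        setdiff(libs, manifest$library_id)),
                       collapse = ", "))
        manifest[match(libs, manifest$library_id), , drop = FALSE]
    }

    n <- nrow(tab)
    lineno <- function(i) i + 1L  # header is line 1
    if (n) {
        if (anyNA(tab$pos) || any(tab$pos < 1) || any(tab$pos != round(tab$pos)))
            stop("malformed position at line ",
                 lineno(which(is.na(tab$pos) | tab$pos < 1 |
                              tab$pos != round(tab$pos))[1]))
        bad <- !tab$ref %in% NUCLEOTIDES
        if (any(bad))
            stop("unknown reference nucleotide '", tab$ref[which(bad)[1]],
                 "' at line ", lineno(which(bad)[1]))
        key <- paste(tab$chrom, tab$pos)
        if (anyDuplicated(key))
            stop("duplicated site ", key[anyDuplicated(key)],
                 " at line ", lineno(anyDuplicated(key)))
    }
    counts <- lapply(stats::setNames(nm = NUCLEOTIDES), function(nt) {
        m <- as.matrix(tab[, paste0(libs, ":", nt), drop = FALSE])
        if (n && (anyNA(m) || any(m < 0) || any(m != round(m))))
            stop("malformed count at line ",
                 lineno(which(rowSums(is.na(m) | m < 0 | m != round(m)) > 0)[1]))
        colnames(m) <- libs
        storage.mode(m) <- "integer"
        m
    })
    if (n) {
        depth <- as.matrix(tab[, paste0(libs, ":depth"), drop = FALSE])
        calc <- counts$A + counts$C + counts$G + counts$T
        bad <- which(rowSums(depth != calc) > 0)
        if (length(bad))
            stop(sprintf(
                "depth column inconsistent with nucleotide sums at %s:%d (line %d)",
                tab$chrom[bad[1]], tab$pos[bad[1]], lineno(bad[1])))
    }
    sites <- GRanges(tab$chrom, IRanges(tab$pos, width = 1L), ref = tab$ref)
    PoolCounts(counts, sites, roster)
}

.inferRoster <- function(libs) {
    m <- regmatches(libs, regexec("^(.*)_(R|S)([0-9]+)$", libs))
    ok <- lengths(m) == 4L
    if (!all(ok))
        stop("cannot infer phenotype for library id(s) ",
             paste(libs[!ok], collapse = ", "),
             "; supply a manifest or use <collection>_<R|S><replicate> ids")
    DataFrame(
        library_id = libs,
        collection_id = vapply(m, `[`, "", 2L),
        phenotype = ifelse(vapply(m, `[`, "", 3L) == "R",
                           "resistant", "susceptible"),
        replicate = as.integer(vapply(m, `[`, "", 4L)))
}

#' Write a PoolCounts object in the counts TSV dialect
#'
#' Inverse of [readPoolCounts()]: stable column order (`chrom`, `pos`, `ref`,
#' then per-library `A,C,G,T,depth` blocks), one header line, tab-separated.
#'
#' @param x A [PoolCounts-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePoolCounts <- function(x, path) {
    stopifnot(is(x, "PoolCounts"))
    rr <- rowRanges(x)
    out <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                      ref = mcols(rr)$ref, check.names = FALSE)
    depth <- depthMatrix(x)
    for (lib in colnames(x)) {
        for (nt in NUCLEOTIDES)
            out[[paste0(lib, ":", nt)]] <- assay(x, nt)[, lib]
        out[[paste0(lib, ":depth")]] <- depth[, lib]
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a library manifest
#'
#' TSV with columns `library_id`, `collection`, `phenotype`, `replicate` and
#' optionally `aligned_reads`, `read_length`.
#'
#' @param path Path to the manifest TSV.
#' @return A `DataFrame` with standardised column names.
#' @export
readLibraryManifest <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("library_id", "collection", "phenotype", "replicate")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
    out <- DataFrame(library_id = tab$library_id,
                     collection_id = tab$collection,
                     phenotype = tolower(tab$phenotype),
                     replicate = as.integer(tab$replicate))
    if (!all(out$phenotype %in% c("resistant", "susceptible")))
        stop("manifest phenotype must be 'resistant' or 'susceptible'")
    if ("aligned_reads" %in% colnames(tab))
        out$aligned_reads <- as.numeric(tab$aligned_reads)
    if ("read_length" %in% colnames(tab))
        out$read_length <- as.integer(tab$read_length)
    out
}

#' Read gene models from GFF3 or BED
#'
#' Gene intervals are taken as-is (a gene's interval is expected to span its
#' 5'UTR, exons, introns and 3'UTR). GFF3 files are subset to `type == "gene"`
#' features and the `ID` attribute becomes `gene_id`; BED intervals are
#' converted to 1-based inclusive coordinates on import and the name field
#' becomes `gene_id`. A `biotype` column is kept when present (used to
#' separate coding from non-coding genes); otherwise all genes are assumed
#' coding.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @return `GRanges` with metadata columns `gene_id`, `biotype` and, when
#'   present in the source, `description`.
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path)
    mc <- mcols(gr)
    if ("type" %in% colnames(mc))
        gr <- gr[as.character(mc$type) == "gene"]
    mc <- mcols(gr)
    gene_id <- if ("ID" %in% colnames(mc)) as.character(mc$ID)
               else if ("name" %in% colnames(mc)) as.character(mc$name)
               else stop("gene identifiers not found (need GFF3 ID or BED name)")
    biotype <- if ("biotype" %in% colnames(mc)) as.character(mc$biotype)
               else rep("protein_coding", length(gr))
    description <- if ("description" %in% colnames(mc))
        as.character(mc$description) else NA_character_
    mcols(gr) <- DataFrame(gene_id = gene_id, biotype = biotype,
                           description = description)
    names(gr) <- gene_id
    gr
}

#' Read a gene-to-functional-category map
#'
#' Two-column TSV (`gene_id`, `category_code`); codes must belong to the
#' controlled vocabulary ([categoryCodes()]) or be a merged code such as
#' `MIT/ReDox`.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `gene_id`, `category_code`.
#' @export
readCategoryMap <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "category_code") %in% colnames(tab)))
        stop("category map needs columns gene_id, category_code")
    ok <- tab$category_code %in% c(categoryCodes(), "MIT/ReDox")
    if (!all(ok))
        stop("unknown category code(s): ",
             paste(unique(tab$category_code[!ok]), collapse = ", "))
    tab[, c("gene_id", "category_code")]
}

#' Filter sites on per-library coverage
#'
#' A site is kept only if *every* library has depth at or above
#' `minCoverage`. The rule is per library, not on the summed depth, matching
#' an mpileup-to-readcounts conversion run per sample with a minimum-coverage
#' option; with four libraries at the default threshold every kept site has
#' total depth >= 60.
#'
#' @param x A [PoolCounts-class] object.
#' @param minCoverage Minimum per-library depth (default 15).
#' @return `list(counts, report)` where `counts` is the filtered
#'   [PoolCounts-class] and `report` records `n_input`,
#'   `n_removed_low_coverage`, `n_kept` and the threshold.
#' @export
filterSites <- function(x, minCoverage = 15L) {
    stopifnot(is(x, "PoolCounts"))
    d <- depthMatrix(x)
    keep <- if (nrow(x)) rowSums(d >= minCoverage) == ncol(x) else logical(0)
    list(counts = x[keep, ],
         report = list(n_input = nrow(x),
                       n_removed_low_coverage = sum(!keep),
                       n_kept = sum(keep),
                       min_coverage = as.integer(minCoverage)))
}

#' Separate monomorphic and no-data sites from testable polymorphic sites
#'
#' A site is monomorphic when exactly one nucleotide has a nonzero count
#' summed over all libraries; such sites are excluded from association
#' testing and counted. Sites with zero reads in every library are classed
#' `no_data`, never monomorphic, so the accounting is unambiguous.
#'
#' @param x A [PoolCounts-class] object.
#' @return `list(counts, n_monomorphic, n_no_data)` with `counts` holding the
#'   retained polymorphic sites.
#' @export
flagMonomorphic <- function(x) {
    stopifnot(is(x, "PoolCounts"))
    tot <- vapply(NUCLEOTIDES, function(nt) rowSums(assay(x, nt)),
                  numeric(nrow(x)))
    if (nrow(x) == 1L) tot <- matrix(tot, nrow = 1L)
    k <- rowSums(tot > 0)
    list(counts = x[k >= 2L, ],
         n_monomorphic = sum(k == 1L),
         n_no_data = sum(k == 0L))
}

#' Coverage summary across libraries
#'
#' Descriptive statistics of the per-site depth summed over all libraries of
#' the collection (total coverage across replicates). The median uses the
#' midpoint convention for even counts.
#'
#' @param x A [PoolCounts-class] object with at least one site.
#' @return Named list `min`, `max`, `mean`, `median`.
#' @export
coverageSummary <- function(x) {
    stopifnot(is(x, "PoolCounts"))
    if (!nrow(x)) stop("coverage summary undefined for an empty site set")
    tot <- rowSums(depthMatrix(x))
    list(min = min(tot), max = max(tot), mean = mean(tot),
         median = stats::median(tot))
}

#' Variant sites per aligned nucleotide, per mille
#'
#' `n_variant_sites * 1000 / (aligned_reads * read_length)`: the number of
#' variant sites divided by the total aligned nucleotides, multiplied by
#' 1000.
#'
#' @param nVariantSites Number of variant sites.
#' @param alignedReads Number of aligned reads.
#' @param readLength Read length in nucleotides (default 100).
#' @return The ratio.
#' @export
#' @examples
#' sitesPerAlignedNtRatio(5000, 10000, 100)  # 5
sitesPerAlignedNtRatio <- function(nVariantSites, alignedReads,
                                   readLength = 100) {
    if (alignedReads * readLength <= 0)
        stop("total aligned nucleotides must be positive")
    nVariantSites * 1000 / (alignedReads * readLength)
}
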