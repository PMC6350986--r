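#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays assayNames
NULL

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Controlled vocabulary of functional category codes
#'
#' Functional categories used to annotate gene models: apoptosis (APOP),
#' chemosensory response (CSR), cytoskeletal/structural (CYT/STR), diverse
#' (DIV), mitochondrial (MIT), lipid processing (LIPID), oxidation/reduction
#' (ReDox), proteolysis (PROT), replication/repair/transcription/translation
#' (RRTT), signal transduction (SigT), metabolism (MET), unknown (UNK) and
#' transport (TRP). Enrichment analyses conventionally merge MIT and ReDox
#' into a single MIT/ReDox category (see [mergeCategories()]).
#'
#' @return Character vector of the thirteen category codes.
#' @export
#' @examples
#' categoryCodes()
categoryCodes <- function() {
    c("APOP", "CSR", "CYT/STR", "DIV", "MIT", "LIPID", "ReDox",
      "PROT", "RRTT", "SigT", "MET", "UNK", "TRP")
}

#' PoolCounts: per-site nucleotide read counts for a set of pool libraries
#'
#' `PoolCounts` extends `RangedSummarizedExperiment` with four integer assays
#' (`"A"`, `"C"`, `"G"`, `"T"`) holding the read count of each nucleotide at
#' each genomic site (rows) in each pooled sequencing library (columns).
#' `rowRanges` are width-1 `GRanges` with a `ref` metadata column (reference
#' nucleotide); `colData` describes the libraries: `library_id`,
#' `collection_id`, `phenotype` (`"resistant"` or `"susceptible"`),
#' `replicate` and optionally `aligned_reads` and `read_length`.
#'
#' @export
setClass("PoolCounts", contains = "RangedSummarizedExperiment")

setValidity("PoolCounts", function(object) {
    msg <- character()
    if (!all(NUCLEOTIDES %in% assayNames(object)))
        msg <- c(msg, "assays must include 'A', 'C', 'G', 'T'")
    cd <- colData(object)
    need <- c("library_id", "collection_id", "phenotype", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) return(msg)
    for (nt in NUCLEOTIDES) {
        a <- assay(object, nt)
        if (any(a < 0, na.rm = TRUE))
            msg <- c(msg, sprintf("negative counts in assay '%s'", nt))
    }
    if (!all(cd$phenotype %in% c("resistant", "susceptible")))
        msg <- c(msg, "phenotype must be 'resistant' or 'susceptible'")
    key <- paste(cd$collection_id, cd$phenotype, cd$replicate)
    if (anyDuplicated(key))
        msg <- c(msg, "(collection_id, phenotype, replicate) must be unique")
    rr <- rowRanges(object)
    if (length(rr)) {
        if (any(width(rr) != 1L))
            msg <- c(msg, "sites must have width 1")
        if (any(start(rr) < 1L))
            msg <- c(msg, "positions must be >= 1")
        sk <- paste(as.character(seqnames(rr)), start(rr))
        if (anyDuplicated(sk))
            msg <- c(msg, "at most one record per (chromosome, position)")
        if (!"ref" %in% colnames(mcols(rr)) ||
            !all(mcols(rr)$ref %in% NUCLEOTIDES))
            msg <- c(msg, "rowRanges must carry a 'ref' column in {A,C,G,T}")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PoolCounts object
#'
#' @param counts Named list of four integer matrices (`A`, `C`, `G`, `T`),
#'   sites in rows and libraries in columns.
#' @param sites `GRanges` of width 1 with a `ref` metadata column, one range
#'   per row of the count matrices.
#' @param libraries `data.frame` or `DataFrame` with one row per column of
#'   the count matrices and columns `library_id`, `collection_id`,
#'   `phenotype`, `replicate` (optionally `aligned_reads`, `read_length`).
#'
#' @return A [PoolCounts-class] object.
#' @export
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1),
#'                                 ref = c("A", "C"))
#' libs <- data.frame(library_id = c("X_R1", "X_S1"), collection_id = "X",
#'                    phenotype = c("resistant", "susceptible"), replicate = 1L)
#' cnt <- lapply(setNames(nm = c("A", "C", "G", "T")),
#'               function(n) matrix(5L, 2, 2))
#' PoolCounts(cnt, sites, libs)
PoolCounts <- function(counts, sites, libraries) {
    counts <- lapply(counts[NUCLEOTIDES], function(m) {
        m <- as.matrix(m)
        storage.mode(m) <- "integer"
        m
    })
    libraries <- as(libraries, "DataFrame")
    if (is.null(libraries$read_length)) libraries$read_length <- 100L
    se <- SummarizedExperiment(assays = counts, rowRanges = sites,
                               colData = libraries)
    colnames(se) <- libraries$library_id
    new("PoolCounts", se)
}

#' @describeIn PoolCounts Per-library sequencing depth at each site
#'   (sum of the four nucleotide counts), as a sites x libraries matrix.
#' @param x A `PoolCounts` object.
#' @export
depthMatrix <- function(x) {
    stopifnot(is(x, "PoolCounts"))
    assay(x, "A") + assay(x, "C") + assay(x, "G") + assay(x, "T")
}

#' @describeIn PoolCounts Reference nucleotide of each site.
#' @export
refAllele <- function(x) mcols(rowRanges(x))$ref

#' @describeIn PoolCounts Phenotype label of each library.
#' @export
poolPhenotype <- function(x) as.character(colData(x)$phenotype)

#' @describeIn PoolCounts Collection label(s) of the libraries.
#' @export
collectionId <- function(x) as.character(colData(x)$collection_id)

#' Sum nucleotide counts across the libraries of one phenotype
#'
#' @param x A `PoolCounts` object.
#' @param phenotype `"resistant"` or `"susceptible"`.
#' @return Integer matrix, sites x 4 nucleotides.
#' @export
phenotypeCounts <- function(x, phenotype = c("resistant", "susceptible")) {
    phenotype <- match.arg(phenotype)
    sel <- poolPhenotype(x) == phenotype
    if (!any(sel))
        stop("no libraries with phenotype '", phenotype, "'")
    out <- vapply(NUCLEOTIDES, function(nt) {
        m <- assay(x, nt)[, sel, drop = FALSE]
        as.integer(rowSums(m))
    }, integer(nrow(x)))
    if (nrow(x) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(NULL, NUCLEOTIDES))
    out
}

setMethod("show", "PoolCounts", function(object) {
    cd <- colData(object)
    cat("PoolCounts with", nrow(object), "sites and", ncol(object),
        "pool libraries\n")
    cat("collections:", paste(unique(cd$collection_id), collapse = ", "), "\n")
    cat("libraries:", paste(sprintf("%s[%s]", cd$library_id,
                                    substr(cd$phenotype, 1, 1)),
                            collapse = " "), "\n")
    if (nrow(object)) {
        d <- depthMatrix(object)
        cat(sprintf("median per-library depth: %.0f\n", stats::median(d)))
    }
})
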