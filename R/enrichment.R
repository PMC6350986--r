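#' Merge functional categories
#'
#' Replaces the listed source codes with a merged code in a gene-category
#' table. By default the mitochondrial and redox categories are combined
#' (`MIT`, `ReDox` -> `MIT/ReDox`), as key redox activities are carried by
#' mitochondrially localized proteins; the merge is applied to both the
#' background and the test set before enrichment.
#'
#' @param categories `data.frame` with `gene_id`, `category_code`.
#' @param merges Named list: merged code -> character vector of source
#'   codes. `NULL` leaves labels unchanged.
#' @return The table with merged codes.
#' @export
mergeCategories <- function(categories,
                            merges = list("MIT/ReDox" = c("MIT", "ReDox"))) {
    if (is.null(merges)) return(categories)
    for (target in names(merges)) {
        src <- merges[[target]]
        unknown <- setdiff(src, c(categoryCodes(), target))
        if (length(unknown))
            stop("unknown category code(s) in merge spec: ",
                 paste(unknown, collapse = ", "))
        categories$category_code[categories$category_code %in% src] <- target
    }
    categories
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability that a category with `K` members in a background of `N` genes
#' is represented at least `k` times in a draw of `n` genes without
#' replacement. Computed in log space via the hypergeometric distribution
#' function, so it is stable for genome-scale `N`.
#'
#' @param N Background size (all coding genes).
#' @param K Category size within the background.
#' @param n Size of the drawn (high-association) set.
#' @param k Observed category count within the drawn set.
#'   All four arguments are recycled to a common length.
#' @return `P(X >= k)` in (0, 1].
#' @export
#' @examples
#' hypergeomUpper(10, 4, 5, 4)  # 6/252
hypergeomUpper <- function(N, K, n, k) {
    stopifnot(all(K >= 0), all(K <= N), all(n >= 0), all(n <= N),
              all(k >= 0), all(k <= pmin(K, n)))
    p <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
    p[k == 0] <- 1
    p
}

#' Hypergeometric over-representation of every category in a gene set
#'
#' One upper-tail hypergeometric test per (merged) category: is the category
#' represented in the high-association set more often than expected from a
#' uniform draw out of the coding-gene background? No multiple-testing
#' correction is applied across categories by default (raw p-values are
#' reported); set `adjust = TRUE` to add a BH-adjusted column.
#'
#' @param highSet Character vector of gene ids (must all be in the
#'   background).
#' @param background `data.frame` (`gene_id`, `category_code`) covering the
#'   full coding-gene universe.
#' @param merges Merge spec passed to [mergeCategories()]; default combines
#'   MIT and ReDox.
#' @param adjust Add a `p_adjusted` BH column (default `FALSE`).
#' @return `data.frame` sorted by `p_upper`: `category_code`, `k`, `n`, `K`,
#'   `N`, `fold` (= (k/n)/(K/N)), `p_upper`. High-set genes missing from the
#'   background's category map are assigned `UNK`; a `warning` reports how
#'   many.
#' @export
enrichAll <- function(highSet, background,
                      merges = list("MIT/ReDox" = c("MIT", "ReDox")),
                      adjust = FALSE) {
    if (!all(highSet %in% background$gene_id))
        stop("background must include every high-association gene")
    background <- mergeCategories(background, merges)
    nas <- is.na(background$category_code)
    if (any(nas)) {
        background$category_code[nas] <- "UNK"
        if (any(background$gene_id[nas] %in% highSet))
            warning(sum(background$gene_id[nas] %in% highSet),
                    " high-set gene(s) without a category assigned UNK")
    }
    N <- length(unique(background$gene_id))
    n <- length(unique(highSet))
    cats <- sort(unique(background$category_code))
    inset <- background$gene_id %in% highSet
    K <- vapply(cats, function(cc)
        sum(background$category_code == cc), 0L)
    k <- vapply(cats, function(cc)
        sum(inset & background$category_code == cc), 0L)
    p <- mapply(hypergeomUpper, N = N, K = K, n = n, k = k)
    out <- data.frame(category_code = cats, k = k, n = n, K = K, N = N,
                      fold = ifelse(K > 0 & n > 0, (k / n) / (K / N), NA_real_),
                      p_upper = p, row.names = NULL)
    if (adjust) out$p_adjusted <- stats::p.adjust(out$p_upper, "BH")
    out[order(out$p_upper, out$category_code), , drop = FALSE]
}
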