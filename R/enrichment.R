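#' Dual-set GO term enrichment
#'
#' One-tailed over-representation tests of GO terms in a test set of
#' clusters against a reference universe, with Benjamini-Hochberg FDR
#' control, plus the dual-set exclusion rule: a term enriched both among
#' selected and among unselected clusters is flagged as a possible
#' ascertainment bias and excluded from interpretation.
#'
#' @name enrichment
NULL

#' Fisher over-representation test per GO term
#'
#' For every GO term annotated to at least one test-set member, computes
#' the one-tailed hypergeometric p-value of observing `k` or more
#' term-carrying clusters among the `n` drawn from a universe of `N`
#' reference clusters of which `K` carry the term, then adjusts across
#' terms by Benjamini-Hochberg.
#'
#' @param testSet character vector of cluster ids (must be contained in
#'   the reference set).
#' @param referenceSet character vector of cluster ids (the universe).
#' @param annotations named list: cluster id -> GO ids.
#' @param alpha FDR threshold for the `enriched` flag (default 0.05).
#' @param goNames optional named character: GO id -> readable name.
#' @return data.frame: go_id, go_name, k, n, K, N, p, q, enriched;
#'   ordered by p.
#' @export
fisherEnrich <- function(testSet, referenceSet, annotations, alpha = 0.05,
                         goNames = NULL) {
  testSet <- unique(testSet)
  referenceSet <- unique(referenceSet)
  stopifnot(length(referenceSet) > 0)
  extra <- setdiff(testSet, referenceSet)
  if (length(extra))
    stop("test set not contained in reference set: ",
         paste(head(extra, 3), collapse = ", "))
  n <- length(testSet)
  N <- length(referenceSet)
  termsOf <- function(id) unique(annotations[[id]] %||% character())
  testTerms <- lapply(testSet, termsOf)
  terms <- sort(unique(unlist(testTerms)))
  if (!length(terms))
    return(data.frame(go_id = character(), go_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      enriched = logical()))
  refCount <- table(factor(unlist(lapply(referenceSet, termsOf)),
                           levels = terms))
  k <- table(factor(unlist(testTerms), levels = terms))
  K <- as.integer(refCount)
  k <- as.integer(k)
  low <- K < k
  if (any(low)) {
    warning(sum(low), " terms less frequent in the reference than in the ",
            "test set; reference count raised to the test count")
    K[low] <- k[low]
  }
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  res <- data.frame(
    go_id = terms,
    go_name = if (is.null(goNames)) NA_character_
              else unname(goNames[terms]),
    k = k, n = n, K = K, N = N, p = p, q = q,
    enriched = q < alpha, row.names = NULL)
  res[order(res$p, res$go_id), ]
}

#' Dual-set exclusion of shared enriched terms
#'
#' Terms enriched in both the selected and the unselected cluster set may
#' reflect a systematic bias of the reference rather than selection; they
#' are separated out so only set-exclusive terms are interpreted.
#'
#' @param enrichedSelected GO ids enriched among selected clusters.
#' @param enrichedUnselected GO ids enriched among unselected clusters.
#' @return list with `exclusive_selected`, `exclusive_unselected` and
#'   `shared` (flagged as possible systematic bias).
#' @export
dualSetFilter <- function(enrichedSelected, enrichedUnselected) {
  list(exclusive_selected = sort(setdiff(enrichedSelected, enrichedUnselected)),
       exclusive_unselected = sort(setdiff(enrichedUnselected, enrichedSelected)),
       shared = sort(intersect(enrichedSelected, enrichedUnselected)))
}

#' Dual-set enrichment analysis
#'
#' Runs [fisherEnrich()] for the selected set and its complement within
#' the reference, and applies the exclusion rule.
#'
#' @param selected cluster ids with signatures of selection.
#' @param referenceSet the universe of cluster ids.
#' @param annotations named list: cluster id -> GO ids.
#' @param alpha FDR threshold (default 0.05).
#' @param goNames optional GO id -> name map.
#' @return list with `selected` and `unselected` enrichment tables and
#'   `filter` (the [dualSetFilter()] result).
#' @export
dualSetEnrichment <- function(selected, referenceSet, annotations,
                              alpha = 0.05, goNames = NULL) {
  selected <- intersect(unique(selected), referenceSet)
  unselected <- setdiff(referenceSet, selected)
  enrSel <- fisherEnrich(selected, referenceSet, annotations, alpha, goNames)
  enrUns <- fisherEnrich(unselected, referenceSet, annotations, alpha, goNames)
  list(selected = enrSel, unselected = enrUns,
       filter = dualSetFilter(enrSel$go_id[enrSel$enriched],
                              enrUns$go_id[enrUns$enriched]))
}
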