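#' Consensus across selection methods
#'
#' Merges the per-cluster, per-branch verdicts of the three selection
#' tests into Venn-style summary counts and tests whether a functional
#' category's positive clusters are spread homogeneously across branches.
#'
#' @name consensus
NULL

#' Merge selection calls across methods
#'
#' Deduplicates (cluster, method, branch) rows with a warning, then
#' summarizes per cluster which methods called it positive anywhere, and
#' per branch how many clusters each method flagged.
#'
#' @param calls data.frame with columns `cluster_id`, `method`
#'   (`"paml"`, `"treesaap"` or `"mk"`), `branch` (branch label, or the
#'   species-pair tag for MK) and `positive` (logical).
#' @return list with `perCluster` (cluster_id, methods
#'   (comma-separated), n_methods), `summary` (n_any, n_exactly1,
#'   n_exactly2, n_all3), and `perBranch` (method, branch, n_positive).
#' @export
mergeCalls <- function(calls) {
  need <- c("cluster_id", "method", "branch", "positive")
  stopifnot(all(need %in% names(calls)))
  key <- paste(calls$cluster_id, calls$method, calls$branch, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate (cluster, method, branch) calls dropped")
    calls <- calls[!dup, ]
  }
  pos <- calls[calls$positive, , drop = FALSE]
  ids <- sort(unique(pos$cluster_id))
  methods <- lapply(ids, function(i)
    sort(unique(pos$method[pos$cluster_id == i])))
  perCluster <- data.frame(
    cluster_id = ids,
    methods = vapply(methods, paste, character(1), collapse = ","),
    n_methods = vapply(methods, length, integer(1)),
    row.names = NULL)
  nm <- perCluster$n_methods
  summary <- list(n_any = length(ids),
                  n_exactly1 = sum(nm == 1L),
                  n_exactly2 = sum(nm == 2L),
                  n_all3 = sum(nm == 3L))
  if (nrow(pos)) {
    agg <- aggregate(list(n_positive = pos$positive),
                     by = list(method = pos$method, branch = pos$branch),
                     FUN = length)
  } else {
    agg <- data.frame(method = character(), branch = character(),
                      n_positive = integer())
  }
  list(perCluster = perCluster, summary = summary, perBranch = agg)
}

#' Homogeneity of a category's positive calls across branches
#'
#' Chi-squared test of equal frequency of a functional category's
#' positively selected clusters across branch classes (expected counts
#' uniform over branches, scaled to the observed total); df is
#' branches - 1.
#'
#' @param counts named numeric: positive-cluster count per branch class
#'   (>= 2 classes).
#' @return list with `chi2`, `df`, `p` (all NA when the total is 0).
#' @export
categoryHomogeneityTest <- function(counts) {
  stopifnot(length(counts) >= 2L)
  df <- length(counts) - 1L
  total <- sum(counts)
  if (total == 0)
    return(list(chi2 = NA_real_, df = df, p = NA_real_))
  expected <- rep(total / length(counts), length(counts))
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Homogeneity tests for a set of GO categories
#'
#' Counts, per branch class and category, the clusters called positive
#' (by the branch-resolved methods) that are annotated with the category,
#' and applies [categoryHomogeneityTest()] to each category. MK calls are
#' tagged with a species-pair rather than a branch and are excluded.
#'
#' @param calls merged call table (columns as in [mergeCalls()]).
#' @param annotations named list: cluster id -> GO ids.
#' @param categories GO ids to test.
#' @param branchClasses branch labels forming the classes; defaults to the
#'   branches present among non-MK positive calls.
#' @return data.frame: go_id, total, chi2, df, p.
#' @export
categoryHomogeneityAcrossBranches <- function(calls, annotations, categories,
                                              branchClasses = NULL) {
  pos <- calls[calls$positive & calls$method != "mk", , drop = FALSE]
  if (is.null(branchClasses)) branchClasses <- sort(unique(pos$branch))
  rows <- lapply(categories, function(g) {
    inCat <- vapply(pos$cluster_id, function(i)
      g %in% (annotations[[i]] %||% character()), logical(1))
    cnt <- vapply(branchClasses, function(b)
      length(unique(pos$cluster_id[inCat & pos$branch == b])), numeric(1))
    ht <- categoryHomogeneityTest(cnt)
    data.frame(go_id = g, total = sum(cnt), chi2 = ht$chi2, df = ht$df,
               p = ht$p, row.names = NULL)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
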