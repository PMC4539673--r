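#' Codon-level McDonald-Kreitman test
#'
#' Compares fixed inter-species differences (D) against within-species
#' polymorphisms (P), each split into non-synonymous (n) and synonymous
#' (s) classes, iterating codon by codon over a two-species alignment.
#' Polymorphisms are called from read depth and allele counts; positive
#' selection is inferred from `Dn/Ds > Pn/Ps`.
#'
#' @name mk-test
NULL

#' Call the SNP status of one position
#'
#' A position is `no_data` when read depth is below `minDepth`;
#' `polymorphic` when at least two alleles are observed and the minor
#' allele frequency (second-most-frequent count over the total allele
#' count) is at least `minMaf`; otherwise `monomorphic`.
#'
#' @param depth integer read depth.
#' @param alleleCounts named numeric of per-nucleotide counts.
#' @param minDepth minimum depth (default 10).
#' @param minMaf minimum minor allele frequency (default 0.2, inclusive).
#' @return one of `"polymorphic"`, `"monomorphic"`, `"no_data"`.
#' @export
callSNP <- function(depth, alleleCounts, minDepth = 10, minMaf = 0.2) {
  stopifnot(all(alleleCounts >= 0))
  if (depth < minDepth) return("no_data")
  alleleCounts <- alleleCounts[alleleCounts > 0]
  if (length(alleleCounts) == 0L) {
    warning("no allele counts at a position with depth >= ", minDepth)
    return("no_data")
  }
  if (length(alleleCounts) < 2L) return("monomorphic")
  srt <- sort(alleleCounts, decreasing = TRUE)
  maf <- srt[2] / sum(alleleCounts)
  if (maf >= minMaf) "polymorphic" else "monomorphic"
}

# Alternate allele of a polymorphic position: the most frequent allele
# different from the consensus base (ties broken alphabetically). Taking
# the raw second-most-frequent allele instead can return the consensus
# itself when counts tie, which would turn the event into a meaningless
# self-substitution.
.minorAllele <- function(alleleCounts, ref = NA_character_) {
  ac <- alleleCounts[alleleCounts > 0]
  if (length(ac) < 2L) return(NA_character_)
  if (!is.na(ref)) ac <- ac[names(ac) != ref]
  if (!length(ac)) return(NA_character_)
  ac <- ac[order(-ac, names(ac))]
  names(ac)[1]
}

#' Classify one aligned codon pair into MK cells
#'
#' Positions polymorphic in either species contribute to P (one event per
#' polymorphic species and position, classified by applying the
#' major-to-minor allele change on that species' codon background).
#' Positions whose letters differ between the species and are monomorphic
#' in both contribute to D, with synonymous/non-synonymous labels averaged
#' over the minimal mutational pathways through the differing positions
#' (pathways through stop codons excluded). A position that is both
#' polymorphic and divergent counts as P only.
#'
#' @param codon_a,codon_b aligned codons (gap- and N-free).
#' @param status_a,status_b character(3): SNP status per position
#'   (`"polymorphic"`, `"monomorphic"`, `"no_data"`); `no_data` positions
#'   are treated as monomorphic for D-calling.
#' @param minor_a,minor_b character(3): minor allele per position (NA when
#'   not polymorphic).
#' @param code see [resolveGeneticCode()].
#' @return numeric `c(dn, ds, pn, ps)` increments (fractional for
#'   averaged multi-hit codons); zero vector with a warning when the codon
#'   must be skipped (stop codon, or all pathways blocked).
#' @export
classifyCodon <- function(codon_a, codon_b,
                          status_a = rep("monomorphic", 3),
                          status_b = rep("monomorphic", 3),
                          minor_a = rep(NA_character_, 3),
                          minor_b = rep(NA_character_, 3),
                          code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  out <- c(dn = 0, ds = 0, pn = 0, ps = 0)
  if (is.na(code[codon_a]) || is.na(code[codon_b]) ||
      code[[codon_a]] == "*" || code[[codon_b]] == "*") {
    warning("codon skipped (stop or unrecognized): ", codon_a, "/", codon_b)
    return(out)
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]

  polyPos <- status_a == "polymorphic" | status_b == "polymorphic"

  # polymorphic events: single-site change on the carrying species' codon
  for (pos in 1:3) {
    for (side in c("a", "b")) {
      status <- if (side == "a") status_a else status_b
      if (status[pos] != "polymorphic") next
      minor <- if (side == "a") minor_a[pos] else minor_b[pos]
      if (is.na(minor)) next
      cod <- if (side == "a") codon_a else codon_b
      alt <- cod
      substr(alt, pos, pos) <- minor
      syn <- !is.na(code[alt]) && code[[alt]] != "*" &&
        code[[alt]] == code[[cod]]
      if (syn) out["ps"] <- out["ps"] + 1 else out["pn"] <- out["pn"] + 1
    }
  }

  # fixed differences at positions monomorphic in both species
  dPos <- which(a != b & !polyPos)
  if (length(dPos)) {
    target <- codon_a
    for (pos in dPos) substr(target, pos, pos) <- b[pos]
    cnt <- codonPathwayCounts(codon_a, target, positions = dPos, code = code)
    if (is.null(cnt)) {
      warning("all mutational pathways blocked by stops for ",
              codon_a, " -> ", target, "; fixed differences skipped")
    } else {
      out["dn"] <- out["dn"] + cnt[["n"]]
      out["ds"] <- out["ds"] + cnt[["s"]]
    }
  }
  out
}

#' MK counts for a two-species codon alignment
#'
#' Iterates over every complete codon (no gap or N in either row), calls
#' the SNP status of each position from the polymorphism table (positions
#' absent from the table are monomorphic with unknown depth) and sums the
#' [classifyCodon()] increments.
#'
#' @param aln a [CodonAlignment] restricted to exactly 2 species.
#' @param poly a [PolymorphismTable] (may be empty).
#' @param code see [resolveGeneticCode()].
#' @param minDepth,minMaf SNP-calling thresholds, see [callSNP()].
#' @return an [MKCounts].
#' @export
mkCounts <- function(aln, poly = NULL, code = resolveGeneticCode(),
                     minDepth = 10, minMaf = 0.2) {
  code <- resolveGeneticCode(code)
  m <- .alnCharMatrix(aln)
  stopifnot(nrow(m) == 2L)
  sp <- rownames(m)
  cid <- clusterId(aln)
  ncod <- ncol(m) %/% 3L
  tot <- c(dn = 0, ds = 0, pn = 0, ps = 0)
  nCodons <- 0L; nPos <- 0L; nNoData <- 0L

  # per-cluster hash of polymorphism rows for O(1) position lookups
  polyIdx <- new.env(parent = emptyenv())
  if (!is.null(poly)) {
    d <- poly@data
    sel <- which(d$cluster_id == cid)
    for (i in sel)
      assign(paste0(d$species[i], "\r", d$column_index[i]),
             list(depth = d$depth[i],
                  counts = c(A = d$count_A[i], C = d$count_C[i],
                             G = d$count_G[i], T = d$count_T[i])),
             envir = polyIdx)
  }
  statusOf <- function(species, col, ref) {
    rec <- get0(paste0(species, "\r", col), envir = polyIdx)
    if (is.null(rec)) return(list(status = "monomorphic", minor = NA_character_))
    st <- callSNP(rec$depth, rec$counts, minDepth, minMaf)
    list(status = st,
         minor = if (st == "polymorphic") .minorAllele(rec$counts, ref)
                 else NA_character_)
  }

  for (k in seq_len(ncod)) {
    cols <- (3 * k - 2):(3 * k)
    ca <- paste(m[1, cols], collapse = "")
    cb <- paste(m[2, cols], collapse = "")
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    sa <- sb <- character(3); mina <- minb <- rep(NA_character_, 3)
    for (p in 1:3) {
      col0 <- cols[p] - 1L   # 0-based alignment column
      ra <- statusOf(sp[1], col0, m[1, cols[p]])
      rb <- statusOf(sp[2], col0, m[2, cols[p]])
      sa[p] <- ra$status; sb[p] <- rb$status
      mina[p] <- ra$minor; minb[p] <- rb$minor
      nPos <- nPos + 2L
      nNoData <- nNoData + (ra$status == "no_data") + (rb$status == "no_data")
    }
    # no_data positions are treated as monomorphic for D-calling
    saD <- ifelse(sa == "no_data", "monomorphic", sa)
    sbD <- ifelse(sb == "no_data", "monomorphic", sb)
    inc <- classifyCodon(ca, cb, saD, sbD, mina, minb, code)
    tot <- tot + inc
    nCodons <- nCodons + 1L
  }
  new("MKCounts", dn = tot[["dn"]], ds = tot[["ds"]],
      pn = tot[["pn"]], ps = tot[["ps"]],
      nCodons = as.numeric(nCodons),
      noDataFrac = if (nPos > 0) nNoData / nPos else 0)
}

#' MK verdict from the four count cells
#'
#' Positive selection is called when `Dn/Ds > Pn/Ps` in the cross-product
#' form `Dn * Ps > Pn * Ds`, additionally requiring at least one
#' synonymous observation (`Ds > 0` or `Ps > 0`) and `Dn > 0` so the
#' degenerate all-zero table is never called. The classical 2x2 Fisher
#' test p-value is reported alongside (on counts rounded to integers) but
#' plays no part in the verdict.
#'
#' @param counts an [MKCounts].
#' @return list with `counts`, `dRatio` (NA when Ds = 0), `pRatio` (NA
#'   when Ps = 0), `positive`, `fisherP`.
#' @export
mkVerdict <- function(counts) {
  stopifnot(is(counts, "MKCounts"))
  dn <- counts@dn; ds <- counts@ds; pn <- counts@pn; ps <- counts@ps
  positive <- (dn * ps > pn * ds) && (ds > 0 || ps > 0) && dn > 0
  tab <- matrix(round(c(dn, ds, pn, ps)), 2, 2, byrow = TRUE)
  fisherP <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    fisher.test(tab)$p.value else 1
  list(counts = counts,
       dRatio = if (ds > 0) dn / ds else NA_real_,
       pRatio = if (ps > 0) pn / ps else NA_real_,
       positive = positive,
       fisherP = fisherP)
}

#' Run the MK test over a set of clusters
#'
#' @param alignments list of two-species [CodonAlignment] objects.
#' @param poly a [PolymorphismTable].
#' @param speciesPair character(2); used to tag the calls.
#' @param code see [resolveGeneticCode()].
#' @param minDepth,minMaf SNP-calling thresholds.
#' @return data.frame: cluster_id, Dn, Ds, Pn, Ps, d_ratio, p_ratio,
#'   no_data_frac, positive, fisher_p, and the `method`/`branch` columns
#'   consumed by [mergeCalls()].
#' @export
mkTestClusters <- function(alignments, poly = NULL,
                           speciesPair = NULL,
                           code = resolveGeneticCode(),
                           minDepth = 10, minMaf = 0.2) {
  rows <- lapply(alignments, function(aln) {
    cnt <- mkCounts(aln, poly, code, minDepth, minMaf)
    v <- mkVerdict(cnt)
    pairTag <- if (is.null(speciesPair))
      paste(sort(speciesNames(aln)), collapse = "~")
    else paste(sort(speciesPair), collapse = "~")
    data.frame(cluster_id = clusterId(aln),
               Dn = cnt@dn, Ds = cnt@ds, Pn = cnt@pn, Ps = cnt@ps,
               d_ratio = v$dRatio, p_ratio = v$pRatio,
               no_data_frac = cnt@noDataFrac,
               method = "mk", branch = pairTag,
               positive = v$positive, fisher_p = v$fisherP,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
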