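#' Codon-aware alignment and divergence filtering
#'
#' Translation of coding sequences, protein-guided progressive alignment,
#' back-translation to an in-frame codon alignment, and the mean pairwise
#' nucleotide divergence filter applied before any selection test.
#'
#' @name codon-align
NULL

#' Translate a coding sequence
#'
#' Standard-table translation with the conventions used throughout the
#' pipeline: a trailing partial codon is truncated with a warning, codons
#' containing N (or any non-ACGT character) translate to `X`, a terminal
#' stop codon is dropped, and an internal stop translates to `*` and sets
#' the `internalStop` attribute so the cluster can be flagged.
#'
#' @param cds coding nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @param code see [resolveGeneticCode()].
#' @return amino-acid string with attribute `internalStop` (logical).
#' @export
translateCDS <- function(cds, code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  cds <- toupper(as.character(cds))
  if (!nzchar(cds)) stop("cannot translate an empty sequence")
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    warning("trailing partial codon (", n %% 3L, " nt) truncated")
    cds <- substr(cds, 1L, n - n %% 3L)
    n <- nchar(cds)
  }
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  out <- paste(aa, collapse = "")
  attr(out, "internalStop") <- any(aa == "*")
  out
}

# BLOSUM62 amino-acid substitution scores (the standard matrix as shipped
# with Biostrings), cached.
.blosum62 <- function() {
  if (is.null(.osCache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .osCache$blosum62 <- e$BLOSUM62
  }
  .osCache$blosum62
}

# Column composition matrix of a profile (rows = alignment columns,
# cols = BLOSUM alphabet); gaps excluded.
.profileComposition <- function(profile, alphabet) {
  counts <- matrix(0, ncol(profile), length(alphabet),
                   dimnames = list(NULL, alphabet))
  for (r in seq_len(nrow(profile))) {
    res <- profile[r, ]
    keep <- res != "-"
    res[!(res %in% alphabet)] <- "X"
    idx <- cbind(which(keep), match(res[keep], alphabet))
    counts[idx] <- counts[idx] + 1
  }
  counts
}

# Align two profiles (character matrices); returns the merged profile.
.mergeProfiles <- function(a, b, gapOpen, gapExtend) {
  blo <- .blosum62()
  alpha <- rownames(blo)
  ca <- .profileComposition(a, alpha)
  cb <- .profileComposition(b, alpha)
  raw <- ca %*% blo %*% t(cb)
  denom <- outer(rowSums(ca), rowSums(cb))
  score <- ifelse(denom > 0, raw / denom, 0)
  moves <- .profileAlignCpp(score, gapOpen, gapExtend)
  na <- nrow(a); nb <- nrow(b)
  out <- matrix("-", na + nb, length(moves))
  ia <- 0L; ib <- 0L
  for (k in seq_along(moves)) {
    mv <- moves[k]
    if (mv != 3L) { ia <- ia + 1L; out[seq_len(na), k] <- a[, ia] }
    if (mv != 2L) { ib <- ib + 1L; out[na + seq_len(nb), k] <- b[, ib] }
  }
  rownames(out) <- c(rownames(a), rownames(b))
  out
}

#' Progressive protein multiple alignment
#'
#' Deterministic progressive alignment: a UPGMA guide tree built from
#' pairwise alignment identities, profile-profile Needleman-Wunsch merges
#' with affine gap costs and mean-BLOSUM62 column scores, and lexicographic
#' species order as the tie-break so permuting the input never changes the
#' result.
#'
#' @param proteins named character vector (>= 2) of amino-acid sequences.
#' @param gapOpen,gapExtend affine gap penalties (negative).
#' @return named character vector of gapped rows, in lexicographic species
#'   order.
#' @export
alignProteins <- function(proteins, gapOpen = -10, gapExtend = -1) {
  stopifnot(length(proteins) >= 2L, !is.null(names(proteins)))
  proteins <- unlist(lapply(proteins, as.character))
  ord <- order(names(proteins))
  proteins <- proteins[ord]
  nm <- names(proteins)
  n <- length(proteins)
  profs <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(proteins[i], "")[[1]], nrow = 1)
    rownames(m) <- nm[i]
    m
  })

  if (n == 2L) {
    merged <- .mergeProfiles(profs[[1]], profs[[2]], gapOpen, gapExtend)
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ab <- .mergeProfiles(profs[[i]], profs[[j]], gapOpen, gapExtend)
      id <- mean(ab[1, ] == ab[2, ] & ab[1, ] != "-")
      D[i, j] <- D[j, i] <- 1 - id
    }
    hc <- hclust(as.dist(D), method = "average")
    nodes <- vector("list", n - 1)
    for (k in seq_len(n - 1)) {
      pick <- function(idx) if (idx < 0) profs[[-idx]] else nodes[[idx]]
      nodes[[k]] <- .mergeProfiles(pick(hc$merge[k, 1]), pick(hc$merge[k, 2]),
                                   gapOpen, gapExtend)
    }
    merged <- nodes[[n - 1]]
  }
  merged <- merged[nm, , drop = FALSE]
  setNames(apply(merged, 1, paste, collapse = ""), nm)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Expands every amino-acid column to its source codon (protein gap ->
#' `---`), verifying first that each ungapped protein row equals the
#' translation of its coding sequence.
#'
#' @param proteinAlignment named character vector of gapped amino-acid
#'   rows.
#' @param cdsMap named character vector (or `DNAStringSet`) of the source
#'   coding sequences.
#' @param clusterId cluster identifier for the resulting alignment.
#' @param code see [resolveGeneticCode()].
#' @return a [CodonAlignment].
#' @export
backtranslate <- function(proteinAlignment, cdsMap, clusterId = "cluster",
                          code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  species <- names(proteinAlignment)
  stopifnot(!is.null(species), all(species %in% names(cdsMap)))
  rows <- character(length(species))
  for (k in seq_along(species)) {
    sp <- species[k]
    cds <- toupper(as.character(cdsMap[[sp]]))
    protRow <- strsplit(proteinAlignment[[sp]], "")[[1]]
    ungapped <- protRow[protRow != "-"]
    trans <- suppressWarnings(translateCDS(cds, code))
    transCh <- strsplit(as.character(trans), "")[[1]]
    if (length(ungapped) != length(transCh))
      stop("protein/CDS length mismatch for species ", sp, ": ",
           length(ungapped), " aa vs translated ", length(transCh))
    mism <- which(ungapped != transCh)
    if (length(mism))
      stop("protein/CDS mismatch for species ", sp,
           " at amino-acid position ", mism[1])
    usable <- nchar(cds) - nchar(cds) %% 3L
    codons <- substring(cds, seq(1L, usable, 3L), seq(3L, usable, 3L))
    out <- character(length(protRow))
    ci <- 0L
    for (i in seq_along(protRow)) {
      if (protRow[i] == "-") out[i] <- "---"
      else { ci <- ci + 1L; out[i] <- codons[ci] }
    }
    rows[k] <- paste(out, collapse = "")
  }
  new("CodonAlignment", clusterId = clusterId,
      rows = Biostrings::DNAStringSet(setNames(rows, species)))
}

#' Codon-align an ortholog cluster
#'
#' Convenience wrapper: translate every sequence, align the proteins,
#' back-translate. Clusters whose translation contains an internal stop
#' are rejected with an error (callers run clusters in isolation and
#' record such failures).
#'
#' @param cluster an [OrthologCluster].
#' @param code see [resolveGeneticCode()].
#' @return a [CodonAlignment].
#' @export
alignCluster <- function(cluster, code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  seqs <- alignmentRows(cluster)
  prots <- lapply(as.character(seqs), translateCDS, code = code)
  stops <- vapply(prots, function(p) isTRUE(attr(p, "internalStop")), logical(1))
  if (any(stops))
    stop("internal stop codon in species: ",
         paste(names(prots)[stops], collapse = ", "))
  aln <- alignProteins(vapply(prots, as.character, character(1)))
  backtranslate(aln, setNames(as.character(seqs), names(seqs)),
                clusterId = clusterId(cluster), code = code)
}

#' Mean pairwise nucleotide divergence of a codon alignment
#'
#' Mean over all unordered species pairs of the per-pair p-distance
#' (mismatching nucleotide columns / compared columns). Columns with a gap
#' or N in either row of a pair are excluded for that pair
#' (pairwise deletion); pairs with no comparable column are dropped.
#'
#' @param aln a [CodonAlignment].
#' @return proportion in `[0, 1]`.
#' @export
meanDivergence <- function(aln) {
  m <- .alnCharMatrix(aln)
  n <- nrow(m)
  stopifnot(n >= 2L)
  valid <- matrix(m %in% .NUCS, nrow = n)
  dists <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- valid[i, ] & valid[j, ]
    if (!any(both)) next
    dists <- c(dists, mean(m[i, both] != m[j, both]))
  }
  if (!length(dists))
    stop("divergence undefined: no species pair has comparable columns")
  mean(dists)
}

#' Restrict a codon alignment to a subset of species
#'
#' @param aln a [CodonAlignment].
#' @param species species names to keep (>= 2).
#' @return a [CodonAlignment] with the selected rows; columns are kept
#'   as-is (codons gapped in the remaining rows are ignored downstream).
#' @export
restrictAlignment <- function(aln, species) {
  rows <- alignmentRows(aln)
  miss <- setdiff(species, names(rows))
  if (length(miss)) stop("species not in alignment: ",
                         paste(miss, collapse = ", "))
  new("CodonAlignment", clusterId = clusterId(aln),
      rows = rows[sort(species)])
}

#' Filter codon alignments by mean divergence
#'
#' Keeps alignments whose mean pairwise nucleotide divergence is strictly
#' below the threshold (default 10%); a discard report records the rest.
#'
#' @param alignments list of [CodonAlignment] objects.
#' @param threshold maximum divergence (exclusive; default 0.10).
#' @return list with `kept` (list of alignments) and `discarded`
#'   (data.frame of cluster_id, divergence).
#' @export
filterClusters <- function(alignments, threshold = 0.10) {
  div <- vapply(alignments, meanDivergence, numeric(1))
  keep <- div < threshold
  list(kept = alignments[keep],
       discarded = data.frame(
         cluster_id = vapply(alignments[!keep], clusterId, character(1)),
         divergence = div[!keep], row.names = NULL))
}
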