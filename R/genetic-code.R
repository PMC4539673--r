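#' Genetic-code utilities
#'
#' Helpers shared by the counting, modelling and simulation stages: sense
#' codon enumeration, single-nucleotide neighbourhoods, and Nei-Gojobori
#' style pathway-averaged synonymous/non-synonymous step counts.
#'
#' @name genetic-code
NULL

.NUCS <- c("A", "C", "G", "T")

#' Resolve a genetic code specification
#'
#' @param code either a single NCBI genetic-code table id (e.g. "1" for the
#'   standard code) or a full named character vector of 64 codon -> amino
#'   acid mappings as returned by [Biostrings::getGeneticCode()].
#' @return named character vector of 64 translations.
#' @export
resolveGeneticCode <- function(code = "1") {
  if (is.character(code) && length(code) == 1L)
    return(Biostrings::getGeneticCode(code))
  stopifnot(is.character(code), length(code) == 64L, !is.null(names(code)))
  code
}

.codeKey <- function(code) paste(names(code), code, sep = "", collapse = "")

#' Sense codons of a genetic code
#'
#' @param code see [resolveGeneticCode()].
#' @return sorted character vector of non-stop codons (61 for the standard
#'   code).
#' @export
senseCodons <- function(code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  sort(names(code)[code != "*"])
}

.isTransition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Single-nucleotide neighbour structure among sense codons, cached per code:
# data.frame of (i, j, pos, transition, synonymous) for ordered pairs.
.codonNeighbors <- function(code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  key <- paste0("nbr_", .codeKey(code))
  if (!is.null(.osCache[[key]])) return(.osCache[[key]])
  sc <- senseCodons(code)
  n <- length(sc)
  chars <- do.call(rbind, strsplit(sc, "", fixed = TRUE))
  ii <- jj <- pp <- integer(0); tr <- sy <- logical(0)
  for (i in seq_len(n)) {
    for (pos in 1:3) {
      for (nt in setdiff(.NUCS, chars[i, pos])) {
        cod <- sc[i]
        substr(cod, pos, pos) <- nt
        j <- match(cod, sc)
        if (is.na(j)) next    # stop codon
        ii <- c(ii, i); jj <- c(jj, j); pp <- c(pp, pos)
        tr <- c(tr, .isTransition(chars[i, pos], nt))
        sy <- c(sy, code[[sc[i]]] == code[[cod]])
      }
    }
  }
  res <- data.frame(i = ii, j = jj, pos = pp, transition = tr, synonymous = sy)
  .osCache[[key]] <- res
  res
}

.permutations <- function(x) {
  # all orderings of a short vector (k <= 3 in practice)
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in .permutations(x[-k])) out <- c(out, list(c(x[k], rest)))
  }
  out
}

#' Pathway-averaged substitution step counts between two codons
#'
#' Counts how many of the single-nucleotide steps separating `codon_a`
#' from `codon_b` (at the given positions) are non-synonymous vs
#' synonymous, averaged over all minimal mutational pathways (orderings of
#' the differing positions). Pathways passing through a stop codon are
#' excluded; if every pathway is blocked the function returns `NULL`.
#'
#' @param codon_a,codon_b codon strings (sense codons).
#' @param positions integer positions (1-3) to traverse; defaults to all
#'   differing positions.
#' @param code see [resolveGeneticCode()].
#' @return numeric `c(n = , s = )` mean non-synonymous and synonymous step
#'   counts, or `NULL` when all pathways pass through a stop.
#' @export
codonPathwayCounts <- function(codon_a, codon_b, positions = NULL,
                               code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  if (is.null(positions)) {
    a <- strsplit(codon_a, "")[[1]]; b <- strsplit(codon_b, "")[[1]]
    positions <- which(a != b)
  }
  if (length(positions) == 0L) return(c(n = 0, s = 0))
  tot <- c(n = 0, s = 0); npath <- 0L
  for (ord in .permutations(positions)) {
    cur <- codon_a; steps <- c(n = 0, s = 0); ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[cur]] == code[[nxt]]) steps["s"] <- steps["s"] + 1
      else steps["n"] <- steps["n"] + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + steps; npath <- npath + 1L }
  }
  if (npath == 0L) return(NULL)
  tot / npath
}

# Cached pathway-averaged (n, s) for every ordered sense-codon pair.
# Entries are NA where all pathways are blocked by stop codons.
.pathwayTables <- function(code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  key <- paste0("path_", .codeKey(code))
  if (!is.null(.osCache[[key]])) return(.osCache[[key]])
  sc <- senseCodons(code)
  n <- length(sc)
  N <- S <- matrix(NA_real_, n, n, dimnames = list(sc, sc))
  for (i in seq_len(n)) {
    N[i, i] <- S[i, i] <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      cnt <- codonPathwayCounts(sc[i], sc[j], code = code)
      if (!is.null(cnt)) { N[i, j] <- cnt["n"]; S[i, j] <- cnt["s"] }
    }
  }
  .osCache[[key]] <- list(n = N, s = S)
  .osCache[[key]]
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies (codon positions 1-3) are
#' multiplied to give codon frequencies, restricted to sense codons and
#' renormalized. A pseudocount of 0.5 per nucleotide per position keeps
#' all frequencies strictly positive on short alignments.
#'
#' @param aln a [CodonAlignment] or character matrix of aligned rows.
#' @param code see [resolveGeneticCode()].
#' @return named numeric vector over the sense codons, summing to 1.
#' @export
f3x4Frequencies <- function(aln, code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  m <- if (is.matrix(aln)) aln else .alnCharMatrix(aln)
  stopifnot(ncol(m) %% 3L == 0L)
  posFreq <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, .NUCS))
  for (p in 1:3) {
    nts <- as.vector(m[, seq(p, ncol(m), by = 3L)])
    cnt <- table(factor(nts, levels = .NUCS)) + 0.5
    posFreq[p, ] <- cnt / sum(cnt)
  }
  sc <- senseCodons(code)
  chars <- do.call(rbind, strsplit(sc, "", fixed = TRUE))
  f <- posFreq[1, chars[, 1]] * posFreq[2, chars[, 2]] * posFreq[3, chars[, 3]]
  f <- f / sum(f)
  names(f) <- sc
  f
}
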