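# Shared fixtures and independent oracles, all built in code.

uniformFreqs <- function() {
  sc <- senseCodons()
  setNames(rep(1 / length(sc), length(sc)), sc)
}

makeAln <- function(rows, clusterId = "toy") {
  new("CodonAlignment", clusterId = clusterId,
      rows = Biostrings::DNAStringSet(rows))
}

fourTaxonTree <- function(text = "((A:0.10,B:0.15)n1:0.05,(C:0.08,D:0.12)n2:0.07)r;") {
  speciesTreeFromPhylo(ape::read.tree(text = text))
}

# A one-ratio fit object carrying known (true) parameters, for stages that
# consume a fit without needing estimation.
truthFit <- function(tree, kappa, omega, codonFreqs = uniformFreqs()) {
  ur <- ape::reorder.phylo(ape::unroot(treePhylo(tree)), "postorder")
  labs <- phyloBranchLabels(ur)
  new("CodonModelFit", mode = "one_ratio", kappa = kappa,
      omega = setNames(rep(omega, length(labs)), labs),
      branchLengths = setNames(ur$edge.length, labs),
      codonFreqs = codonFreqs, lnL = NA_real_, converged = TRUE,
      nSites = 0)
}

# Independent oracle for pathway-averaged MK step counts: depth-first
# enumeration of every minimal pathway through the single-step codon graph,
# pruning at stop codons.
oraclePathwayCounts <- function(a, b, code = resolveGeneticCode()) {
  ach <- strsplit(a, "")[[1]]; bch <- strsplit(b, "")[[1]]
  rec <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(n = 0, s = 0)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (code[[nxt]] == "*") next
      step <- if (code[[cur]] == code[[nxt]]) c(n = 0, s = 1) else c(n = 1, s = 0)
      for (rest in rec(nxt, setdiff(remaining, pos)))
        out <- c(out, list(step + rest))
    }
    out
  }
  paths <- rec(a, which(ach != bch))
  if (!length(paths)) return(NULL)
  Reduce(`+`, paths) / length(paths)
}

# Brute-force neutral impact-class distribution: triple loop over every
# codon, position and substituted nucleotide.
bruteForceNeutral <- function(property, code = resolveGeneticCode()) {
  sc <- senseCodons(code)
  nucs <- c("A", "C", "G", "T")
  deltas <- c()
  for (cod in sc) for (pos in 1:3) for (nt in nucs) {
    if (substr(cod, pos, pos) == nt) next
    alt <- cod
    substr(alt, pos, pos) <- nt
    if (code[[alt]] == "*") next
    if (code[[cod]] == code[[alt]]) next
    deltas <- c(deltas, abs(property[code[[alt]]] - property[code[[cod]]]))
  }
  maxd <- max(deltas)
  cls <- pmin(8L, pmax(1L, ceiling(deltas / (maxd / 8))))
  tabulate(cls, 8L) / length(cls)
}

# Independent hypergeometric upper-tail oracle from binomial coefficients.
oracleHyperTail <- function(k, K, N, n) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exhaustive codon-model likelihood oracles: direct summation over all
# internal-node codon states.
oracleLogLik2 <- function(states, t1, t2, kappa, omega, pi) {
  P1 <- codonTransitionMatrix(kappa, omega, pi, t1)
  P2 <- codonTransitionMatrix(kappa, omega, pi, t2)
  sum(apply(states, 2, function(s)
    log(sum(pi * P1[, s[1]] * P2[, s[2]]))))
}

# rooted ((A,B)v,C)r: internal nodes v and r enumerated exhaustively
oracleLogLik3 <- function(states, bl, kappa, omega, pi) {
  # bl: c(r->v, v->A, v->B, r->C)
  P <- lapply(bl, function(t) codonTransitionMatrix(kappa, omega, pi, t))
  ns <- length(pi)
  sum(apply(states, 2, function(s) {
    tot <- 0
    for (x in seq_len(ns)) for (y in seq_len(ns))
      tot <- tot + pi[x] * P[[1]][x, y] * P[[2]][y, s[1]] *
        P[[3]][y, s[2]] * P[[4]][x, s[3]]
    log(tot)
  }))
}

# rooted ((A,B)v,(C,D)w)r with per-edge omega support
oracleLogLik4 <- function(states, bl, kappa, omega, pi) {
  # bl and omega: named c("r->v","v->A","v->B","r->w","w->C","w->D")
  P <- lapply(names(bl), function(e)
    codonTransitionMatrix(kappa, omega[[e]], pi, bl[[e]]))
  names(P) <- names(bl)
  ns <- length(pi)
  sum(apply(states, 2, function(s) {
    tot <- 0
    for (x in seq_len(ns)) for (y in seq_len(ns)) {
      innerW <- 0
      for (z in seq_len(ns))
        innerW <- innerW + P[["r->w"]][x, z] * P[["w->C"]][z, s[3]] *
          P[["w->D"]][z, s[4]]
      tot <- tot + pi[x] * P[["r->v"]][x, y] * P[["v->A"]][y, s[1]] *
        P[["v->B"]][y, s[2]] * innerW
    }
    log(tot)
  }))
}

# Brute-force optimal global pairwise alignment score with affine gaps,
# by exhaustive enumeration of all monotone alignments (short sequences).
oraclePairScore <- function(s1, s2, gapOpen = -10, gapExtend = -1) {
  blo <- orthoselect:::.blosum62()
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  best <- -Inf
  # enumerate alignments as move sequences via recursion
  rec <- function(i, j, prev, score) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, 1L, score + blo[a[i], b[j]])
    if (i <= length(a))
      rec(i + 1, j, 2L,
          score + if (identical(prev, 2L)) gapExtend else gapOpen)
    if (j <= length(b))
      rec(i, j + 1, 3L,
          score + if (identical(prev, 3L)) gapExtend else gapOpen)
  }
  rec(1L, 1L, 0L, 0)
  best
}

# score an alignment (two gapped rows) under the same affine scheme
scorePairAlignment <- function(r1, r2, gapOpen = -10, gapExtend = -1) {
  blo <- orthoselect:::.blosum62()
  a <- strsplit(r1, "")[[1]]; b <- strsplit(r2, "")[[1]]
  sc <- 0; prev <- 0L
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-") { sc <- sc + blo[a[k], b[k]]; prev <- 0L }
    else if (a[k] == "-") { sc <- sc + if (prev == 1L) gapExtend else gapOpen; prev <- 1L }
    else { sc <- sc + if (prev == 2L) gapExtend else gapOpen; prev <- 2L }
  }
  sc
}
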