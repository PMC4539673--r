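#' Branch codon-model inference (dN/dS)
#'
#' GY94-style codon substitution model over the sense codons: rate matrix
#' construction, Felsenstein-pruning log-likelihood, maximum-likelihood
#' one-ratio and free-ratio fits on a fixed tree, likelihood-ratio tests
#' with FDR control, and per-branch positive-selection calls.
#'
#' @name codon-model
NULL

#' Build a GY94-style codon rate matrix
#'
#' Off-diagonal rate i->j is zero unless the codons differ at exactly one
#' position and j is a sense codon; otherwise it is
#' `pi_j * kappa^[transition] * omega^[non-synonymous]`. Rows sum to zero
#' and, when `scale = TRUE`, the matrix is scaled so the expected
#' substitution rate at stationarity is 1 per codon per unit branch length.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param codonFreqs named stationary frequencies over the sense codons.
#' @param code see [resolveGeneticCode()].
#' @param scale rescale to one expected substitution per unit time.
#' @return square generator matrix over the sense codons.
#' @export
buildRateMatrix <- function(kappa, omega, codonFreqs,
                            code = resolveGeneticCode(), scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0)
  code <- resolveGeneticCode(code)
  sc <- senseCodons(code)
  stopifnot(setequal(names(codonFreqs), sc))
  pi <- codonFreqs[sc]
  nb <- .codonNeighbors(code)
  Q <- matrix(0, length(sc), length(sc), dimnames = list(sc, sc))
  rate <- pi[nb$j] * ifelse(nb$transition, kappa, 1) *
    ifelse(nb$synonymous, 1, omega)
  Q[cbind(nb$i, nb$j)] <- rate
  diag(Q) <- -rowSums(Q)
  if (scale) {
    r <- -sum(pi * diag(Q))
    if (r > 0) Q <- Q / r
  }
  Q
}

# Eigen system of the reversible generator, for fast exp(Qt):
# Q = D^{-1/2} B D^{1/2} with B symmetric. Rebuilds the generator from the
# cached neighbour arrays directly (hot path of the optimizer).
.eigenSystem <- function(kappa, omega, pi, code) {
  nb <- .codonNeighbors(code)
  ns <- length(pi)
  r <- unname(pi[nb$j])
  r[nb$transition] <- r[nb$transition] * kappa
  r[!nb$synonymous] <- r[!nb$synonymous] * omega
  Q <- matrix(0, ns, ns)
  Q[cbind(nb$i, nb$j)] <- r
  diag(Q) <- -rowSums(Q)
  sc <- -sum(pi * diag(Q))
  if (sc > 0) Q <- Q / sc
  d <- sqrt(pi)
  B <- Q * outer(d, 1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(V = e$vectors, lambda = e$values)
}

#' Codon transition probability matrix
#'
#' `exp(Q t)` for the generator of [buildRateMatrix()], computed through
#' the symmetric eigen decomposition of the reversible model.
#'
#' @inheritParams buildRateMatrix
#' @param t branch length (expected substitutions per codon).
#' @return stochastic matrix over the sense codons.
#' @export
codonTransitionMatrix <- function(kappa, omega, codonFreqs, t,
                                  code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  sc <- senseCodons(code)
  pi <- codonFreqs[sc]
  es <- .eigenSystem(kappa, omega, pi, code)
  d <- sqrt(pi)
  P <- es$V %*% (exp(es$lambda * t) * t(es$V))
  P <- P * outer(1 / d, d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(sc, sc)
  P
}

#' Codon state matrix of an alignment
#'
#' Maps every codon of every row to its index among the sense codons;
#' codons containing a gap, N or stop map to `NA`.
#'
#' @param aln a [CodonAlignment].
#' @param code see [resolveGeneticCode()].
#' @return integer matrix, species x codon sites.
#' @export
codonStateMatrix <- function(aln, code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  m <- .alnCharMatrix(aln)
  sc <- senseCodons(code)
  ncod <- ncol(m) %/% 3L
  out <- matrix(NA_integer_, nrow(m), ncod,
                dimnames = list(rownames(m), NULL))
  for (k in seq_len(ncod)) {
    cods <- paste0(m[, 3 * k - 2], m[, 3 * k - 1], m[, 3 * k])
    out[, k] <- match(cods, sc)
  }
  out
}

# Postorder tree preparation shared by likelihood, fitting and
# reconstruction. `unroot` collapses a bifurcating root (reversible model:
# root placement is inestimable).
.prepTree <- function(tree, unroot = FALSE) {
  tr <- if (is(tree, "SpeciesTree")) treePhylo(tree) else tree
  stopifnot(inherits(tr, "phylo"))
  if (unroot && length(tr$tip.label) > 2L) tr <- ape::unroot(tr)
  tr <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(tr$tip.label)
  list(phylo = tr, edge = tr$edge, edgeLen = tr$edge.length,
       labels = phyloBranchLabels(tr), ntip = ntip,
       nNode = ntip + tr$Nnode, root = ntip + 1L)
}

# Complete-case codon patterns for a set of species in tree tip order.
.sitePatterns <- function(aln, tipOrder, code) {
  st <- codonStateMatrix(aln, code)
  miss <- setdiff(tipOrder, rownames(st))
  if (length(miss))
    stop("alignment lacks rows for tree leaves: ", paste(miss, collapse = ", "))
  st <- st[tipOrder, , drop = FALSE]
  usable <- colSums(is.na(st)) == 0L
  st <- st[, usable, drop = FALSE]
  if (ncol(st) == 0L) stop("no usable codon columns (all contain gaps, N or stops)")
  key <- apply(st, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(states = st[, first, drop = FALSE], weights = as.numeric(tab),
       nSites = ncol(st), usable = usable, siteKey = key)
}

# Shared likelihood-evaluation plumbing. Eigen systems depend only on
# (kappa, omega); a per-fit cache lets branch-length moves (the majority of
# finite-difference evaluations) skip the decompositions entirely.
.loglikEngine <- function(pat, prep, kappa, omegaPerEdge, edgeLen, pi, code,
                          cache = NULL) {
  uo <- sort(unique(omegaPerEdge))
  K <- length(uo)
  ns <- length(pi)
  V <- array(0, c(ns, ns, K)); lam <- matrix(0, ns, K)
  for (k in seq_len(K)) {
    es <- NULL
    if (!is.null(cache)) {
      keyk <- sprintf("%.17g|%.17g", kappa, uo[k])
      es <- cache[[keyk]]
    }
    if (is.null(es)) {
      es <- .eigenSystem(kappa, uo[k], pi, code)
      if (!is.null(cache)) cache[[keyk]] <- es
    }
    V[, , k] <- es$V; lam[, k] <- es$lambda
  }
  eigIdx <- match(omegaPerEdge, uo)
  .codonPruningCpp(pat$states, pat$weights, prep$edge, edgeLen,
                   as.integer(eigIdx), V, lam, unname(pi),
                   prep$nNode, prep$root)
}

#' Codon-model log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over the sense-codon states; codon columns with a
#' gap, N or stop in any row are excluded.
#'
#' @param aln a [CodonAlignment] whose species match the tree leaves.
#' @param tree a [SpeciesTree] or [ape::phylo] with branch lengths; used as
#'   given (not unrooted).
#' @param params list with `kappa`, `omega` (single value, or named by
#'   branch label), `branchLengths` (named by branch label; defaults to the
#'   tree's own `edge.length`), and optional `codonFreqs` (defaults to
#'   F3x4 from the alignment).
#' @param code see [resolveGeneticCode()].
#' @return log-likelihood (single numeric).
#' @export
codonLogLikelihood <- function(aln, tree, params, code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  prep <- .prepTree(tree, unroot = FALSE)
  pat <- .sitePatterns(aln, prep$phylo$tip.label, code)
  pi <- params$codonFreqs
  if (is.null(pi)) pi <- f3x4Frequencies(aln, code)
  pi <- pi[senseCodons(code)]
  om <- params$omega
  omegaPerEdge <- if (length(om) == 1L) rep(unname(om), nrow(prep$edge))
                  else unname(om[prep$labels])
  if (anyNA(omegaPerEdge)) stop("omega missing for some branch labels")
  el <- params$branchLengths
  edgeLen <- if (is.null(el)) prep$edgeLen else unname(el[prep$labels])
  if (is.null(edgeLen) || anyNA(edgeLen)) stop("branch lengths missing")
  .loglikEngine(pat, prep, params$kappa, omegaPerEdge, edgeLen, pi, code)
}

# Optimizer bounds; chosen to keep parameters away from pathological
# boundaries while covering all realistic values.
.fitBounds <- list(kappa = c(0.1, 50), omega = c(1e-4, 20), bl = c(1e-6, 5))

#' Fit a branch codon model by maximum likelihood
#'
#' Maximizes the pruning likelihood over kappa, branch lengths and either a
#' single shared omega (`one_ratio`) or one omega per branch
#' (`free_ratio`). Codon frequencies are fixed at their F3x4 estimates.
#' Trees with more than two leaves are unrooted before fitting; branch
#' labels refer to the unrooted topology. Three deterministic starts
#' (a data-driven initialization plus two jittered copies) guard against
#' local optima.
#'
#' @param aln a [CodonAlignment].
#' @param tree a [SpeciesTree] or [ape::phylo] over the alignment species.
#' @param mode `"one_ratio"` or `"free_ratio"`.
#' @param code see [resolveGeneticCode()].
#' @param starts number of optimizer starts (>= 1).
#' @param init optional [CodonModelFit] (e.g. a one-ratio fit) used to
#'   initialize the search.
#' @return a [CodonModelFit].
#' @export
fitCodonModel <- function(aln, tree, mode = c("one_ratio", "free_ratio"),
                          code = resolveGeneticCode(), starts = 3L,
                          init = NULL) {
  mode <- match.arg(mode)
  code <- resolveGeneticCode(code)
  prep <- .prepTree(tree, unroot = TRUE)
  pat <- .sitePatterns(aln, prep$phylo$tip.label, code)
  pi <- f3x4Frequencies(aln, code)[senseCodons(code)]
  E <- nrow(prep$edge)
  nOm <- if (mode == "one_ratio") 1L else E

  # data-driven initialization
  if (!is.null(init) && is(init, "CodonModelFit")) {
    k0 <- init@kappa
    o0 <- rep(mean(init@omega), nOm)
    b0 <- pmax(.fitBounds$bl[1], pmin(.fitBounds$bl[2],
            unname(init@branchLengths[prep$labels])))
    if (anyNA(b0)) b0 <- rep(0.05, E)
  } else {
    d <- tryCatch(meanDivergence(.asCodonAlignment(aln)), error = function(e) 0.02)
    k0 <- 2; o0 <- rep(0.3, nOm)
    b0 <- rep(max(0.005, 3 * d / 2), E)
  }

  lower <- c(.fitBounds$kappa[1], rep(.fitBounds$omega[1], nOm),
             rep(.fitBounds$bl[1], E))
  upper <- c(.fitBounds$kappa[2], rep(.fitBounds$omega[2], nOm),
             rep(.fitBounds$bl[2], E))
  clamp <- function(p) pmax(lower, pmin(upper, p))

  cache <- new.env(parent = emptyenv())
  negll <- function(par) {
    kap <- par[1]
    om <- par[2:(1 + nOm)]
    bl <- par[(2 + nOm):(1 + nOm + E)]
    omEdge <- if (nOm == 1L) rep(om, E) else om
    v <- tryCatch(.loglikEngine(pat, prep, kap, omEdge, bl, pi, code, cache),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else -v
  }

  jit <- c(1, exp(0.7), exp(-0.7))
  best <- NULL
  for (s in seq_len(max(1L, starts))) {
    f <- jit[((s - 1L) %% 3L) + 1L]
    p0 <- clamp(c(k0 * f, o0 * f, b0 * if (f > 1) 1.5 else if (f < 1) 0.6 else 1))
    opt <- tryCatch(
      optim(p0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300, factr = 1e9,
                           parscale = c(1, rep(0.3, nOm), rep(0.05, E)))),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("codon model optimization failed on all starts")

  kap <- best$par[1]
  om <- best$par[2:(1 + nOm)]
  bl <- best$par[(2 + nOm):(1 + nOm + E)]
  omega <- if (nOm == 1L) setNames(rep(om, E), prep$labels)
           else setNames(om, prep$labels)
  new("CodonModelFit", mode = mode, kappa = kap, omega = omega,
      branchLengths = setNames(bl, prep$labels),
      codonFreqs = pi, lnL = -best$value,
      converged = best$convergence == 0L, nSites = pat$nSites)
}

.asCodonAlignment <- function(aln) {
  if (is(aln, "CodonAlignment")) aln
  else stop("expected a CodonAlignment")
}

#' Likelihood-ratio test between nested branch-model fits
#'
#' Free-ratio vs one-ratio comparison: `stat = 2 (lnL1 - lnL0)`, clamped at
#' zero; degrees of freedom are `branches - 1` (the free model adds one
#' omega per branch and removes the shared one).
#'
#' @param one one-ratio [CodonModelFit].
#' @param free free-ratio [CodonModelFit] on the same cluster.
#' @return list with `stat`, `df`, `p` and `converged` (both fits).
#' @export
branchTest <- function(one, free) {
  stopifnot(is(one, "CodonModelFit"), is(free, "CodonModelFit"),
            one@mode == "one_ratio", free@mode == "free_ratio")
  nb <- length(free@omega)
  stat <- max(0, 2 * (free@lnL - one@lnL))
  df <- nb - 1L
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       converged = one@converged && free@converged)
}

#' Per-branch positive-selection calls from branch-model fits
#'
#' Applies Benjamini-Hochberg FDR correction to the per-cluster
#' likelihood-ratio p-values and flags a branch as positively selected
#' when its free-ratio omega exceeds 1 and the cluster-level test passes
#' the FDR threshold.
#'
#' @param fits named list (by cluster id) of lists with elements `one` and
#'   `free` ([CodonModelFit] pairs).
#' @param alpha FDR threshold (default 0.05).
#' @return list with `tests` (one row per cluster: lnL0, lnL1, stat, df,
#'   p, q, converged) and `calls` (one row per cluster x branch: omega,
#'   positive).
#' @export
callPamlPositive <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) > 0)
  ids <- names(fits)
  lrt <- lapply(fits, function(f) branchTest(f$one, f$free))
  tests <- data.frame(
    cluster_id = ids,
    lnL0 = vapply(fits, function(f) f$one@lnL, numeric(1)),
    lnL1 = vapply(fits, function(f) f$free@lnL, numeric(1)),
    stat = vapply(lrt, `[[`, numeric(1), "stat"),
    df = vapply(lrt, `[[`, numeric(1), "df"),
    p = vapply(lrt, `[[`, numeric(1), "p"),
    converged = vapply(lrt, `[[`, logical(1), "converged"),
    row.names = NULL)
  tests$q <- p.adjust(tests$p, method = "BH")
  calls <- do.call(rbind, lapply(seq_along(fits), function(i) {
    om <- fits[[i]]$free@omega
    data.frame(cluster_id = ids[i], method = "paml", branch = names(om),
               omega = unname(om),
               positive = unname(om) > 1 & tests$q[i] < alpha,
               row.names = NULL)
  }))
  list(tests = tests, calls = calls)
}

#' Marginal ML ancestral codon reconstruction
#'
#' Marginal posterior codon states at the internal nodes of the fitted
#' (unrooted) tree under a one-ratio codon model fit, by the standard
#' up-down message-passing algorithm. The MAP codon is reported per node
#' and site; ties are broken towards the codon with higher stationary
#' frequency and states with maximum posterior below `minPosterior` are
#' returned as `NA`.
#'
#' @param aln a [CodonAlignment].
#' @param tree the [SpeciesTree] used for fitting.
#' @param fit a [CodonModelFit] (its kappa/omega/branch lengths are used).
#' @param code see [resolveGeneticCode()].
#' @param minPosterior resolution threshold (default 0.5).
#' @return list with `states`: integer matrix (rows = all node labels,
#'   tips included, columns = all codon sites; `NA` at excluded or
#'   unresolved sites), `prep`: the internal tree representation, and
#'   `codons`: the sense-codon alphabet.
#' @export
ancestralCodons <- function(aln, tree, fit, code = resolveGeneticCode(),
                            minPosterior = 0.5) {
  code <- resolveGeneticCode(code)
  prep <- .prepTree(tree, unroot = TRUE)
  pat <- .sitePatterns(aln, prep$phylo$tip.label, code)
  sc <- senseCodons(code)
  pi <- fit@codonFreqs[sc]
  om <- fit@omega[prep$labels]
  if (anyNA(om)) stop("fit branch labels do not match the tree")
  uo <- sort(unique(unname(om)))
  ns <- length(sc)
  V <- array(0, c(ns, ns, length(uo))); lam <- matrix(0, ns, length(uo))
  for (k in seq_along(uo)) {
    es <- .eigenSystem(fit@kappa, uo[k], pi, code)
    V[, , k] <- es$V; lam[, k] <- es$lambda
  }
  eigIdx <- match(unname(om), uo)
  edgeLen <- unname(fit@branchLengths[prep$labels])
  parts <- .codonPartialsCpp(pat$states, prep$edge, edgeLen,
                             as.integer(eigIdx), V, lam, unname(pi),
                             prep$nNode)
  Pmats <- parts$P
  L <- parts$partials
  npat <- ncol(pat$states)
  ntip <- prep$ntip

  # per-edge upward messages
  msg <- vector("list", nrow(prep$edge))
  for (e in seq_len(nrow(prep$edge))) {
    ch <- prep$edge[e, 2]
    P <- Pmats[[e]]
    msg[[e]] <- if (ch <= ntip) P[, pat$states[ch, ], drop = FALSE]
                else P %*% L[[ch + 1L]]
  }

  # downward messages: process edges parent-first (reverse postorder)
  above <- vector("list", prep$nNode)
  above[[prep$root]] <- matrix(pi, ns, npat)
  post <- vector("list", prep$nNode)
  post[[prep$root]] <- above[[prep$root]] * L[[prep$root + 1L]]
  for (e in rev(seq_len(nrow(prep$edge)))) {
    par <- prep$edge[e, 1]; ch <- prep$edge[e, 2]
    if (ch <= ntip) next
    sibs <- setdiff(which(prep$edge[, 1] == par), e)
    acc <- above[[par]]
    for (s in sibs) acc <- acc * msg[[s]]
    above[[ch]] <- crossprod(Pmats[[e]], acc)
    post[[ch]] <- above[[ch]] * L[[ch + 1L]]
  }

  labs <- c(prep$phylo$tip.label, prep$phylo$node.label)
  nAllSites <- length(pat$usable)
  states <- matrix(NA_integer_, length(labs), nAllSites,
                   dimnames = list(labs, NULL))
  patOfSite <- match(pat$siteKey, apply(pat$states, 2, paste, collapse = ","))
  usableIdx <- which(pat$usable)
  for (t in seq_len(ntip))
    states[t, usableIdx] <- pat$states[t, patOfSite]
  tieBreak <- order(pi, decreasing = TRUE)
  for (v in (ntip + 1L):prep$nNode) {
    pm <- post[[v]]
    if (is.null(pm)) next
    pm <- sweep(pm, 2, colSums(pm), "/")
    mapIdx <- apply(pm[tieBreak, , drop = FALSE], 2, which.max)
    mapState <- tieBreak[mapIdx]
    mapState[pm[cbind(mapState, seq_len(npat))] < minPosterior] <- NA_integer_
    states[v, usableIdx] <- mapState[patOfSite]
  }
  list(states = states, prep = prep, codons = sc)
}
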