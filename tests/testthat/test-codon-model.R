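test_that("the rate matrix has GY94 structure, reversibility and unit scaling", {
  pi <- uniformFreqs()
  Q <- buildRateMatrix(2, 0.5, pi)
  sc <- senseCodons()
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  # expected substitution rate 1 at stationarity
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance pi_i q_ij = pi_j q_ji
  M <- diag(pi) %*% Q
  expect_equal(max(abs(M - t(M))), 0, tolerance = 1e-14)
  # multi-step entries are zero
  expect_equal(Q["AAA", "ACC"], 0)
  expect_equal(Q["AAA", "CCC"], 0)

  # omega = 0 kills all non-synonymous rates
  Q0 <- buildRateMatrix(2, 0, pi, scale = FALSE)
  code <- resolveGeneticCode()
  for (i in c("AAA", "TTT", "GGG")) {
    js <- sc[Q0[i, ] > 0 & sc != i]
    expect_true(all(code[js] == code[[i]]))
  }

  # kappa = 1, omega = 1, uniform frequencies: all single-step rates equal
  Q1 <- buildRateMatrix(1, 1, pi, scale = FALSE)
  off <- Q1[Q1 > 0]
  expect_equal(max(off), min(off))
})

test_that("transition matrices are stochastic for fitted branch lengths", {
  pi <- uniformFreqs()
  for (t in c(1e-6, 0.05, 0.5, 3)) {
    P <- codonTransitionMatrix(2.5, 0.3, pi, t)
    expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-8)
    expect_true(all(P >= 0))
  }
})

test_that("pruning equals closed forms in degenerate cases", {
  pi <- uniformFreqs()
  st <- fourTaxonTree()
  aln <- makeAln(c(A = "ATGAAA", B = "ATGAAA", C = "ATGAAA", D = "ATGAAA"))
  labs <- branchLabels(st)
  bl <- setNames(rep(1e-9, length(labs)), labs)
  ll <- codonLogLikelihood(aln, st, list(kappa = 2, omega = 0.5,
                                         branchLengths = bl, codonFreqs = pi))
  # zero branch lengths, identical rows: lnL = sum log pi(observed)
  expect_equal(ll, sum(log(pi[c("ATG", "AAA")])), tolerance = 1e-5)
})

test_that("likelihood is invariant to re-rooting of the reversible model", {
  pi <- uniformFreqs()
  set.seed(3)
  cfg <- simulationConfig(nClusters = 1, codonsPerCluster = 40, seed = NULL,
                          selectedFraction = 0)
  sim <- simulateCluster(cfg, 1, FALSE)
  aln <- alignCluster(sim$cluster)
  tr <- treePhylo(cfg$speciesTree)
  ur <- ape::unroot(tr)
  params <- function(phy) {
    labs <- phyloBranchLabels(ape::reorder.phylo(phy, "postorder"))
    list(kappa = 2, omega = 0.4, codonFreqs = pi)
  }
  ll1 <- codonLogLikelihood(aln, ur, list(kappa = 2, omega = 0.4,
                                          codonFreqs = pi))
  r2 <- ape::root(ur, outgroup = "sp3", resolve.root = TRUE)
  ll2 <- codonLogLikelihood(aln, r2, list(kappa = 2, omega = 0.4,
                                          codonFreqs = pi))
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("free-ratio fits nest the one-ratio fit and the LRT uses branches - 1 df", {
  set.seed(11)
  cfg <- simulationConfig(nClusters = 1, codonsPerCluster = 120,
                          selectedFraction = 0, seed = NULL)
  sim <- simulateCluster(cfg, 1, FALSE)
  aln <- alignCluster(sim$cluster)
  one <- fitCodonModel(aln, cfg$speciesTree, "one_ratio")
  free <- fitCodonModel(aln, cfg$speciesTree, "free_ratio", init = one)
  expect_true(one@converged)
  expect_gte(free@lnL, one@lnL - 1e-6)
  lrt <- branchTest(one, free)
  expect_equal(lrt$df, 4L)            # unrooted 4-taxon tree: 5 branches
  expect_gte(lrt$stat, 0)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
  # one-ratio omega is shared across branches
  expect_equal(length(unique(one@omega)), 1L)
  expect_length(free@omega, 5L)
})

test_that("per-branch calls require both omega > 1 and FDR-significant LRT", {
  mkFit <- function(mode, lnl, om) {
    labs <- paste0("b", seq_along(om))
    new("CodonModelFit", mode = mode, kappa = 2,
        omega = setNames(om, labs),
        branchLengths = setNames(rep(0.1, length(om)), labs),
        codonFreqs = uniformFreqs(), lnL = lnl, converged = TRUE,
        nSites = 100)
  }
  fits <- list(
    hit    = list(one = mkFit("one_ratio", -1000, rep(0.4, 5)),
                  free = mkFit("free_ratio", -980, c(3.0, 0.2, 0.2, 0.2, 0.2))),
    lowq   = list(one = mkFit("one_ratio", -1000, rep(0.4, 5)),
                  free = mkFit("free_ratio", -999.5, c(3.0, 0.2, 0.2, 0.2, 0.2))),
    purify = list(one = mkFit("one_ratio", -1000, rep(0.4, 5)),
                  free = mkFit("free_ratio", -980, c(0.5, 0.2, 0.2, 0.2, 0.2))))
  out <- callPamlPositive(fits, alpha = 0.05)
  calls <- out$calls
  expect_true(calls$positive[calls$cluster_id == "hit" & calls$branch == "b1"])
  # significant LRT but omega < 1: never positive
  expect_false(any(calls$positive[calls$cluster_id == "purify"]))
  # omega > 1 but LRT q above threshold: not positive
  expect_false(any(calls$positive[calls$cluster_id == "lowq"]))
  expect_equal(out$tests$q, p.adjust(out$tests$p, "BH"))
})

test_that("ancestral reconstruction recovers internal states on clean data", {
  set.seed(21)
  cfg <- simulationConfig(nClusters = 1, codonsPerCluster = 50,
                          selectedFraction = 0, theta = 0, seed = NULL)
  sim <- simulateCluster(cfg, 1, FALSE)
  aln <- alignCluster(sim$cluster)
  fit <- truthFit(cfg$speciesTree, cfg$kappa, cfg$omegaBackground)
  anc <- ancestralCodons(aln, cfg$speciesTree, fit)
  st <- anc$states
  # tips reproduce the observed codons
  obs <- codonStateMatrix(aln)
  for (sp in rownames(obs))
    expect_equal(unname(st[sp, ]), unname(obs[sp, ]))
  # internal rows exist and are mostly resolved at these divergences
  internal <- setdiff(rownames(st), rownames(obs))
  expect_gte(length(internal), 1L)
  expect_gt(mean(!is.na(st[internal[1], ])), 0.8)
})
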