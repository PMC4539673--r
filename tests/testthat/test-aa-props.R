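test_that("the default property table has 31 complete scales", {
  tab <- defaultPropertyTable()
  expect_equal(dim(tab), c(20L, 31L))
  expect_true(all(is.finite(tab)))
  expect_setequal(rownames(tab),
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_length(attr(tab, "descriptions"), 31L)
})

test_that("neutral magnitude distributions match a brute-force enumeration", {
  code <- resolveGeneticCode()
  tab <- defaultPropertyTable()
  for (k in sample(seq_len(ncol(tab)), 8)) {
    nd <- neutralMagnitudeDistribution(tab[, k])
    expect_equal(sum(nd), 1, tolerance = 1e-12)
    expect_equal(as.numeric(nd), bruteForceNeutral(tab[, k], code),
                 tolerance = 1e-12, info = colnames(tab)[k])
  }
})

test_that("degenerate properties are rejected and two-valued ones load classes 1 and 8", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  const <- setNames(rep(1, 20), aas)
  expect_error(neutralMagnitudeDistribution(const), "constant")
  twoval <- setNames(rep(0, 20), aas)
  twoval["W"] <- 5
  nd <- neutralMagnitudeDistribution(twoval)
  expect_true(all(nd[2:7] == 0))
  expect_gt(nd[1], 0); expect_gt(nd[8], 0)
})

test_that("branch events appear only for amino-acid-changing codons, one per property", {
  set.seed(5)
  cfg <- simulationConfig(nClusters = 1, codonsPerCluster = 40,
                          tree = "((a:0.3,b:0.3)n1:0.2,(c:0.3,d:0.3)n2:0.2)r;",
                          omegaBackground = 1, kappa = 1,
                          selectedFraction = 0, theta = 0, seed = NULL)
  sim <- simulateCluster(cfg, 1, FALSE)
  aln <- alignCluster(sim$cluster)
  fit <- truthFit(cfg$speciesTree, 1, 1)
  props <- defaultPropertyTable()
  ev <- branchEvents(aln, cfg$speciesTree, fit, props)
  if (nrow(ev)) {
    # total events = (changed codons per branch) x (number of properties)
    perBranch <- table(ev$branch)
    chg <- table(unique(ev[, c("branch", "codon_index")])$branch)
    expect_equal(as.numeric(perBranch), as.numeric(chg) * ncol(props))
    expect_true(all(ev$aa_from != ev$aa_to))
    expect_true(all(ev$magnitude_class %in% 1:8))
  }
  # purifying to zero: no non-synonymous events at all
  cfg0 <- simulationConfig(nClusters = 1, codonsPerCluster = 40,
                           omegaBackground = 0, selectedFraction = 0,
                           theta = 0, seed = NULL)
  sim0 <- simulateCluster(cfg0, 1, FALSE)
  aln0 <- alignCluster(sim0$cluster)
  fit0 <- truthFit(cfg0$speciesTree, cfg0$kappa, 1)
  ev0 <- branchEvents(aln0, cfg0$speciesTree, fit0, props)
  expect_equal(nrow(ev0), 0L)
})

test_that("window goodness-of-fit behaves at its extremes", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prop <- defaultPropertyTable()[, 1]
  nd <- neutralMagnitudeDistribution(prop)

  # observed counts exactly proportional to expectation: chi2 = 0, p = 1
  g <- orthoselect:::.gofChisq(round(nd * 800), as.numeric(nd))
  expect_lt(g$chi2, 1.5)   # rounding noise only
  g2 <- orthoselect:::.gofChisq(as.numeric(nd) * 800, as.numeric(nd))
  expect_equal(g2$chi2, 0)
  expect_equal(g2$p, 1)

  # everything radical when expectation is spread: large chi2, tiny p
  obs <- c(0, 0, 0, 0, 0, 0, 0, 12)
  g3 <- orthoselect:::.gofChisq(obs, as.numeric(nd))
  expect_lt(g3$p, 0.001)
})

test_that("window scanning skips sparse windows and respects the step", {
  ev <- data.frame(branch = "b", codon_index = c(2L, 3L, 5L, 30L),
                   aa_from = "K", aa_to = "E",
                   property = "P1", delta = 1,
                   magnitude_class = c(8L, 8L, 8L, 1L))
  nd <- rep(1 / 8, 8)
  w <- windowScan(ev, "P1", "b", nCodons = 60, neutral = nd,
                  window = 20L, step = 20L)
  # window [0,20) has 3 events; window [20,40) has 1 (< 2, skipped)
  expect_equal(w$window_start, 0L)
  expect_equal(w$n_events, 3L)
})

test_that("the positive call needs >= 2 radical codons inside a significant window", {
  mkev <- function(codons, cls) data.frame(
    branch = "b", codon_index = codons, aa_from = "K", aa_to = "E",
    property = "P1", delta = 1, magnitude_class = cls)
  mkwin <- function(p) data.frame(branch = "b", property = "P1",
                                  window_start = 0L, n_events = 3L,
                                  chi2 = 30, df = 5L, p = p)
  # p < 0.001 and two class >= 6 codons: positive
  out <- callTreesaapPositive(mkwin(5e-4), mkev(c(1L, 4L), c(7L, 6L)))
  expect_true(out$positive)
  # only one radical codon (even class 8): not positive
  out <- callTreesaapPositive(mkwin(5e-4), mkev(c(1L, 4L), c(8L, 5L)))
  expect_false(out$positive)
  # two radical codons but p = 0.01: not positive
  out <- callTreesaapPositive(mkwin(0.01), mkev(c(1L, 4L, 9L), c(8L, 8L, 8L)))
  expect_false(out$positive)
  # p exactly 0.001 is not below the threshold
  out <- callTreesaapPositive(mkwin(0.001), mkev(c(1L, 4L), c(8L, 8L)))
  expect_false(out$positive)
})
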