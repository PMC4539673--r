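test_that("simulation is deterministic given the seed", {
  cfg <- simulationConfig(nClusters = 3, codonsPerCluster = 30, seed = 77)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(lapply(s1$clusters, function(c) as.character(alignmentRows(c))),
                   lapply(s2$clusters, function(c) as.character(alignmentRows(c))))
  expect_identical(polyData(s1$poly), polyData(s2$poly))
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$truth, s2$truth)
})

test_that("omega = 0 forbids non-synonymous divergence", {
  set.seed(13)
  cfg <- simulationConfig(nClusters = 1, codonsPerCluster = 80,
                          omegaBackground = 0, selectedFraction = 0,
                          theta = 0, seed = NULL)
  code <- resolveGeneticCode()
  for (r in 1:3) {
    sim <- simulateCluster(cfg, r, FALSE)
    seqs <- as.character(alignmentRows(sim$cluster))
    prots <- unique(vapply(seqs, function(s)
      as.character(translateCDS(s)), character(1)))
    expect_length(prots, 1L)
  }
})

test_that("zero branch lengths and theta give identical sequences and no polymorphism", {
  cfg <- simulationConfig(nClusters = 1, codonsPerCluster = 25,
    tree = "(((x1:0,x2:0)a:0,x3:0)b:0,x4:0)r;", theta = 0,
    selectedFraction = 0, seed = 5)
  set.seed(5)
  sim <- simulateCluster(cfg, 1, FALSE)
  seqs <- as.character(alignmentRows(sim$cluster))
  expect_length(unique(seqs), 1L)
  expect_equal(nrow(sim$polyRows), 0L)
})

test_that("truth bookkeeping matches the emitted study", {
  cfg <- simulationConfig(nClusters = 12, codonsPerCluster = 20,
                          selectedFraction = 0.25, seed = 8)
  st <- simulateStudy(cfg)
  expect_equal(nrow(st$truth), 12L)
  expect_equal(sum(st$truth$selected), 3L)
  expect_setequal(st$truth$cluster_id, names(st$clusters))
  expect_setequal(names(st$annotations), st$truth$cluster_id)
  # polymorphism rows reference simulated clusters and in-range columns
  pd <- polyData(st$poly)
  if (nrow(pd)) {
    expect_true(all(pd$cluster_id %in% st$truth$cluster_id))
    expect_true(all(pd$column_index >= 0 &
                      pd$column_index < 3 * cfg$codonsPerCluster))
    expect_true(all(pd$count_A + pd$count_C + pd$count_G + pd$count_T
                    <= pd$depth))
  }
})

test_that("study files round-trip through the on-disk formats", {
  dir <- withr::local_tempdir()
  cfg <- simulationConfig(nClusters = 2, codonsPerCluster = 15, seed = 3)
  st <- simulateStudy(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "poly.tsv")))
  cl <- readClusterFasta(st$paths$clusters[[1]],
                         setNames(speciesNames(st$tree), speciesNames(st$tree)))
  expect_identical(as.character(alignmentRows(cl)),
                   as.character(alignmentRows(st$clusters[[1]])))
  pt <- readPolymorphismTable(file.path(dir, "poly.tsv"))
  expect_equal(nrow(polyData(pt)), nrow(polyData(st$poly)))
  tr <- readSpeciesTree(file.path(dir, "tree.nwk"))
  expect_setequal(speciesNames(tr), speciesNames(st$tree))
  ann <- readGoAnnotations(file.path(dir, "go_map.tsv"))
  expect_identical(ann, st$annotations)
})

test_that("substitution counts scale with branch length and omega raises the non-synonymous fraction", {
  set.seed(17)
  count_subs <- function(bl, omega, reps = 12, ncod = 60) {
    tot <- 0; nons <- 0
    cfg <- simulationConfig(nClusters = 1, codonsPerCluster = ncod,
      tree = sprintf("(a:%g,b:%g)r;", bl / 2, bl / 2),
      omegaBackground = omega, selectedFraction = 0, theta = 0, seed = NULL)
    code <- resolveGeneticCode()
    for (r in seq_len(reps)) {
      sim <- simulateCluster(cfg, r, FALSE)
      seqs <- as.character(alignmentRows(sim$cluster))
      m <- do.call(rbind, strsplit(seqs, ""))
      ndiff <- sum(m[1, ] != m[2, ])
      tot <- tot + ndiff
      p1 <- strsplit(as.character(translateCDS(seqs[1])), "")[[1]]
      p2 <- strsplit(as.character(translateCDS(seqs[2])), "")[[1]]
      nons <- nons + sum(p1 != p2)
    }
    c(tot = tot, nons = nons)
  }
  lo <- count_subs(0.05, 1)
  hi <- count_subs(0.20, 1)
  # observed differences roughly quadruple with branch length
  expect_gt(hi["tot"] / max(lo["tot"], 1), 2.2)
  expect_lt(hi["tot"] / max(lo["tot"], 1), 7)
  # non-synonymous fraction increases monotonically with omega
  fr <- vapply(c(0.2, 1, 4), function(om) {
    x <- count_subs(0.15, om, reps = 10)
    x["nons"] / max(x["tot"], 1)
  }, numeric(1))
  expect_true(fr[1] < fr[2] && fr[2] < fr[3])
})

test_that("planted GO terms appear preferentially among selected clusters", {
  set.seed(23)
  ids <- sprintf("c%03d", 1:300)
  sel <- ids[1:50]
  ann <- simulateGoAnnotations(ids, sel, plantedBaseRate = 0.08,
                               plantedOdds = 10)
  has <- vapply(ann, function(x) "GO:0000001" %in% x, logical(1))
  rateSel <- mean(has[ids %in% sel])
  rateUns <- mean(has[!ids %in% sel])
  expect_gt(rateSel, 0.6)
  expect_lt(rateUns, 0.2)
})
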