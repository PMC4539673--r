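test_that("SNP calling applies the depth and MAF thresholds at their boundaries", {
  expect_equal(callSNP(12, c(A = 9, C = 3)), "polymorphic")   # MAF 0.25
  expect_equal(callSNP(9, c(A = 6, C = 3)), "no_data")        # depth < 10
  expect_equal(callSNP(10, c(A = 8, C = 2)), "polymorphic")   # MAF exactly 0.2
  expect_equal(callSNP(20, c(A = 18, C = 2)), "monomorphic")  # MAF 0.10
  expect_equal(callSNP(20, c(A = 20)), "monomorphic")
  expect_warning(s <- callSNP(15, c(A = 0, C = 0)), "no allele counts")
  expect_equal(s, "no_data")
})

test_that("codon classification handles fixed, polymorphic and multi-hit cases", {
  x <- classifyCodon("TTT", "TTC")                 # F -> F
  expect_equal(unname(x), c(0, 1, 0, 0))
  x <- classifyCodon("AAA", "GAA")                 # K -> E
  expect_equal(unname(x), c(1, 0, 0, 0))
  # both minimal pathways TTA->CTA->CTG and TTA->TTG->CTG are L -> L
  x <- classifyCodon("TTA", "CTG")
  expect_equal(unname(x), c(0, 2, 0, 0))
  # polymorphism at position 3 of AAA (A/G): K <-> K, synonymous P
  x <- classifyCodon("AAA", "AAA",
                     status_a = c("monomorphic", "monomorphic", "polymorphic"),
                     minor_a = c(NA, NA, "G"))
  expect_equal(unname(x), c(0, 0, 0, 1))
  # a site both polymorphic and divergent counts as P only
  x <- classifyCodon("AAA", "AAG",
                     status_a = c("monomorphic", "monomorphic", "polymorphic"),
                     minor_a = c(NA, NA, "G"))
  expect_equal(unname(x["ds"] + x["dn"]), 0)
  expect_equal(unname(x["ps"]), 1)
  # stop codon input is skipped with a warning
  expect_warning(x <- classifyCodon("TAA", "AAA"), "skipped")
  expect_equal(unname(sum(x)), 0)
})

test_that("pathway averaging matches the exhaustive minimal-pathway oracle on sampled pairs", {
  set.seed(1)
  sc <- senseCodons()
  pairs <- cbind(sample(sc, 120, replace = TRUE), sample(sc, 120, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    got <- codonPathwayCounts(a, b)
    want <- oraclePathwayCounts(a, b)
    if (is.null(want)) expect_null(got, info = paste(a, b))
    else expect_equal(got, want, tolerance = 1e-12, info = paste(a, b))
  }
})

test_that("MK counting is symmetric and bounded by 3 counts per codon", {
  set.seed(7)
  sc <- senseCodons()
  for (r in 1:10) {
    n <- 20
    rowA <- paste(sample(sc, n, replace = TRUE), collapse = "")
    rowB <- paste(sample(sc, n, replace = TRUE), collapse = "")
    cab <- mkCounts(makeAln(c(a = rowA, b = rowB)))
    cba <- mkCounts(makeAln(c(a = rowB, b = rowA)))
    expect_equal(mkCells(cab), mkCells(cba))
    expect_lte(sum(mkCells(cab)), 3 * cab@nCodons)
  }
  # identical monomorphic sequences give the zero table
  z <- mkCells(mkCounts(makeAln(c(a = "ATGAAACCC", b = "ATGAAACCC"))))
  expect_equal(unname(z), c(0, 0, 0, 0))
})

test_that("a hand-enumerated toy cluster yields the exact MK cells", {
  # codon 1 TTT/TTC: fixed synonymous; codon 2 AAA/GAA: fixed
  # non-synonymous; codon 4: CCC with a synonymous polymorphism in a;
  # codons with gaps are ignored
  aln <- makeAln(c(a = "TTTAAAGGGCCC---", b = "TTCGAAGGGCCCTTA"), "toy")
  poly <- polymorphismTable(data.frame(
    species = "a", cluster_id = "toy", column_index = 11L, depth = 20L,
    count_A = 14L, count_C = 0L, count_G = 6L, count_T = 0L))
  cnt <- mkCounts(aln, poly)
  expect_equal(unname(mkCells(cnt)), c(1, 1, 0, 1))
  expect_equal(cnt@nCodons, 4)  # gapped codon 5 skipped
})

test_that("sub-threshold depth makes positions no_data and divergent sites count as D", {
  aln <- makeAln(c(a = "TTT", b = "TTC"), "nd")
  poly <- polymorphismTable(data.frame(
    species = "a", cluster_id = "nd", column_index = 2L, depth = 5L,
    count_A = 0L, count_C = 2L, count_G = 0L, count_T = 3L))
  cnt <- mkCounts(aln, poly)
  expect_equal(unname(mkCells(cnt)), c(0, 1, 0, 0))
  expect_gt(cnt@noDataFrac, 0)
})

test_that("the MK verdict implements the cross-product rule with guards", {
  v <- function(dn, ds, pn, ps)
    mkVerdict(new("MKCounts", dn = dn, ds = ds, pn = pn, ps = ps))
  expect_true(v(4, 1, 1, 4)$positive)
  expect_false(v(2, 2, 2, 2)$positive)
  expect_false(v(0, 0, 0, 0)$positive)
  expect_false(v(3, 0, 0, 0)$positive)   # no synonymous observation at all
  expect_false(v(0, 1, 0, 4)$positive)   # Dn = 0
  expect_true(v(2, 0, 1, 5)$positive)    # Ds = 0 but Ps > 0
  out <- v(4, 1, 1, 4)
  expect_equal(out$dRatio, 4)
  expect_equal(out$pRatio, 0.25)
  expect_true(is.na(v(2, 0, 1, 5)$dRatio))
})
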