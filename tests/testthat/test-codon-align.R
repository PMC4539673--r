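test_that("translation follows the stated conventions", {
  x <- translateCDS("ATGAAATAG")
  expect_equal(as.character(x), "MK")
  expect_false(attr(x, "internalStop"))
  expect_equal(as.character(translateCDS("ATGNNAAAA")), "MXK")
  y <- translateCDS("ATGTAAAAA")
  expect_equal(as.character(y), "M*K")
  expect_true(attr(y, "internalStop"))
  expect_warning(z <- translateCDS("ATGAAAT"), "partial codon")
  expect_equal(as.character(z), "MK")
  expect_error(translateCDS(""), "empty")
})

test_that("protein alignment is optimal for short pairs and order-invariant", {
  # {"MKV","MV"}: one gapped column, three columns total
  a <- alignProteins(c(s1 = "MKV", s2 = "MV"))
  expect_equal(unname(nchar(a)), c(3L, 3L))
  expect_equal(sum(strsplit(a[["s2"]], "")[[1]] == "-"), 1L)
  # achieved score equals the brute-force optimum
  expect_equal(scorePairAlignment(a[["s1"]], a[["s2"]]),
               oraclePairScore("MKV", "MV"))

  # random short pairs: returned score equals exhaustive optimum
  set.seed(42)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  for (r in 1:5) {
    s1 <- paste(sample(aas, sample(4:6, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(aas, sample(3:5, 1), replace = TRUE), collapse = "")
    al <- alignProteins(c(x = s1, y = s2))
    expect_equal(scorePairAlignment(al[["x"]], al[["y"]]),
                 oraclePairScore(s1, s2), info = paste(s1, s2))
  }

  # permuting the input never changes the result
  p3 <- c(a = "MKVLLD", b = "MKLLD", c = "MRVLLD")
  expect_identical(alignProteins(p3), alignProteins(p3[c(3, 1, 2)]))
  # identical proteins align gapless
  g <- alignProteins(c(a = "MKV", b = "MKV"))
  expect_false(any(grepl("-", g, fixed = TRUE)))
})

test_that("backtranslation expands codons, turns protein gaps into codon gaps, and validates", {
  aln <- backtranslate(c(a = "MK", b = "MK"),
                       c(a = "ATGAAA", b = "ATGAAG"), "c1")
  expect_s4_class(aln, "CodonAlignment")
  expect_equal(unname(Biostrings::width(alignmentRows(aln))), c(6L, 6L))

  aln2 <- backtranslate(c(a = "M-K", b = "MQK"),
                        c(a = "ATGAAA", b = "ATGCAAAAA"), "c2")
  expect_equal(as.character(alignmentRows(aln2)[["a"]]), "ATG---AAA")

  expect_error(backtranslate(c(a = "MK"), c(a = "ATGCCC"), "c3"),
               "mismatch for species a")
})

test_that("codon alignment round-trips: stripping gaps reproduces the CDS", {
  cds <- c(a = "ATGAAACAACCC", b = "ATGAAACCC")
  prots <- vapply(cds, function(x) as.character(translateCDS(x)), character(1))
  aln <- backtranslate(alignProteins(prots), cds, "rt")
  for (sp in names(cds)) {
    stripped <- gsub("-", "", as.character(alignmentRows(aln)[[sp]]), fixed = TRUE)
    expect_identical(stripped, unname(cds[sp]))
  }
  # gaps occur only in whole-codon triples (validity would reject otherwise)
  expect_true(validObject(aln))
})

test_that("mean divergence is the mean pairwise p-distance with pairwise deletion", {
  expect_equal(meanDivergence(makeAln(c(a = "AAAAAA", b = "AAAAAA"))), 0)
  expect_equal(meanDivergence(makeAln(c(a = "AAAAAA", b = "AAAAAT"))), 1 / 6)
  # 3 rows: mean of the three pairwise distances.
  # construct 150-column rows with prescribed pairwise distances:
  # b differs from a at 3 cols, c differs from a at 6 cols (disjoint),
  # so b vs c differ at 9 cols
  a <- rep("A", 150); b <- a; cc <- a
  b[1:3] <- "T"; cc[4:9] <- "T"
  aln3 <- makeAln(c(a = paste(a, collapse = ""),
                    b = paste(b, collapse = ""),
                    c = paste(cc, collapse = "")))
  expect_equal(meanDivergence(aln3), mean(c(3, 6, 9) / 150))
  # permutation invariance
  aln3p <- makeAln(c(c = paste(cc, collapse = ""),
                     a = paste(a, collapse = ""),
                     b = paste(b, collapse = "")))
  expect_equal(meanDivergence(aln3), meanDivergence(aln3p))
  # gap/N columns excluded per pair
  alnG <- makeAln(c(a = "AAANNN", b = "TAA---"))
  expect_equal(meanDivergence(alnG), 1 / 3)
  expect_error(meanDivergence(makeAln(c(a = "NNN", b = "---"))), "undefined")
})

test_that("divergence filter is strict at the threshold", {
  mk <- function(d, id) {
    n <- 300
    a <- rep("A", n); b <- a; b[seq_len(d * n)] <- "T"
    makeAln(c(x = paste(a, collapse = ""), y = paste(b, collapse = "")), id)
  }
  alns <- list(mk(0.04, "low"), mk(0.10, "at"), mk(0.12, "high"))
  fl <- filterClusters(alns, threshold = 0.10)
  expect_equal(vapply(fl$kept, clusterId, character(1)), "low")
  expect_setequal(fl$discarded$cluster_id, c("at", "high"))
  expect_equal(fl$discarded$divergence[fl$discarded$cluster_id == "at"], 0.10)
})
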