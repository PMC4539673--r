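test_that("merged calls produce the Venn-style summary and are order-invariant", {
  calls <- data.frame(
    cluster_id = c("c1", "c1", "c2", "c2", "c2", "c3", "c4"),
    method = c("paml", "treesaap", "paml", "treesaap", "mk", "mk", "paml"),
    branch = c("b1", "b1", "b1", "b2", "x~y", "x~y", "b2"),
    positive = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  m <- mergeCalls(calls)
  expect_equal(m$summary$n_any, 3L)       # c1, c2, c3
  expect_equal(m$summary$n_exactly1, 1L)  # c3 (mk only)
  expect_equal(m$summary$n_exactly2, 1L)  # c1
  expect_equal(m$summary$n_all3, 1L)      # c2
  expect_equal(m$summary$n_any,
               m$summary$n_exactly1 + m$summary$n_exactly2 + m$summary$n_all3)
  # order invariance and idempotence
  m2 <- mergeCalls(calls[sample(nrow(calls)), ])
  expect_equal(m$summary, m2$summary)
  expect_equal(m$perCluster, m2$perCluster)
  # duplicates are dropped with a warning
  expect_warning(m3 <- mergeCalls(rbind(calls, calls[1, ])), "duplicate")
  expect_equal(m3$summary, m$summary)
})

test_that("synthetic planted truth is recovered by the union bookkeeping", {
  set.seed(2)
  planted <- paste0("c", 1:6)
  rows <- do.call(rbind, lapply(planted, function(id)
    data.frame(cluster_id = id,
               method = sample(c("paml", "treesaap", "mk"), 1),
               branch = "b1", positive = TRUE)))
  rows <- rbind(rows, data.frame(cluster_id = paste0("z", 1:4),
                                 method = "paml", branch = "b1",
                                 positive = FALSE))
  m <- mergeCalls(rows)
  expect_setequal(m$perCluster$cluster_id, planted)
  expect_equal(m$summary$n_any, length(planted))
})

test_that("the homogeneity test matches direct chi-squared arithmetic", {
  # equal counts: chi2 = 0, p = 1
  h <- categoryHomogeneityTest(setNames(rep(4, 6), paste0("b", 1:6)))
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  expect_equal(h$df, 5L)
  # all mass on one branch of six: chi2 = 30, df = 5
  h2 <- categoryHomogeneityTest(setNames(c(6, 0, 0, 0, 0, 0), paste0("b", 1:6)))
  expect_equal(h2$chi2, 30)
  expect_equal(h2$df, 5L)
  expect_equal(h2$p, pchisq(30, 5, lower.tail = FALSE))
  # cross-check against the stats implementation
  cnt <- c(3, 1, 4, 1, 5, 9)
  h3 <- categoryHomogeneityTest(setNames(cnt, paste0("b", 1:6)))
  ref <- suppressWarnings(chisq.test(cnt))
  expect_equal(h3$chi2, unname(ref$statistic))
  expect_equal(h3$p, unname(ref$p.value))
  # zero totals are undefined
  h4 <- categoryHomogeneityTest(setNames(rep(0, 6), paste0("b", 1:6)))
  expect_true(is.na(h4$chi2) && is.na(h4$p))
  expect_equal(h4$df, 5L)
})

test_that("per-category homogeneity uses branch-resolved methods only", {
  calls <- data.frame(
    cluster_id = c("c1", "c2", "c3", "c4"),
    method = c("paml", "paml", "treesaap", "mk"),
    branch = c("b1", "b2", "b1", "x~y"),
    positive = TRUE)
  ann <- list(c1 = "GO:1", c2 = "GO:1", c3 = "GO:1", c4 = "GO:1")
  out <- categoryHomogeneityAcrossBranches(calls, ann, "GO:1",
                                           branchClasses = c("b1", "b2"))
  expect_equal(out$total, 3)   # the MK call is excluded
  expect_equal(out$df, 1L)
})
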