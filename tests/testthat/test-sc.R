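mkExpr <- function(nGenes, nCells, seed = 1, geneSd = 1, cellSd = 0.5) {
  withr::with_seed(seed, {
    mu <- rnorm(nGenes, 2, geneSd)
    m <- matrix(rnorm(nGenes * nCells, mu, cellSd), nrow = nGenes,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("c%03d", seq_len(nCells))))
    m
  })
}

test_that("signature scores are zero on a constant matrix", {
  m <- matrix(3, 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:20)))
  s <- signatureScore(m, c("g01", "g07"), nBins = 5, nCtrl = 20, seed = 1)
  expect_equal(unname(s), rep(0, 20))
})

test_that("a planted +1 log-unit signature shift is recovered", {
  m <- mkExpr(200, 100, seed = 2)
  sig <- rownames(m)[c(3, 50, 120, 160, 190)]
  shifted <- m
  half <- colnames(m)[1:50]
  shifted[sig, half] <- shifted[sig, half] + 1
  s <- signatureScore(shifted, sig, seed = 7)
  diffMeans <- mean(s[half]) - mean(s[setdiff(colnames(m), half)])
  expect_equal(diffMeans, 1, tolerance = 0.15)  # Monte-Carlo control draw
})

test_that("scores are equivariant to cell permutation and global shifts", {
  m <- mkExpr(100, 30, seed = 3)
  sig <- rownames(m)[1:4]
  s <- signatureScore(m, sig, seed = 5)
  perm <- sample(ncol(m))
  sPerm <- signatureScore(m[, perm], sig, seed = 5)
  expect_equal(sPerm, s[perm])
  ## adding a constant to every gene leaves scores unchanged
  sShift <- signatureScore(m + 2.5, sig, seed = 5)
  expect_equal(sShift, s)
})

test_that("missing signature genes are reported by name", {
  m <- mkExpr(20, 5, seed = 4)
  expect_error(signatureScore(m, c("g001", "nope1", "nope2"), seed = 1),
               "nope1, nope2")
})

mkCounts <- function(cells, groups, sites, ref, alt) {
  data.frame(cell = cells, group = groups, site_id = sites,
             ref_reads = as.integer(ref), alt_reads = as.integer(alt),
             stringsAsFactors = FALSE)
}

test_that("mutant-cell proportions use covered tumor cells as denominator", {
  ## 10 covered tumor cells, 3 with a mutant read
  counts <- mkCounts(sprintf("c%02d", 1:10), "PBS", "Kat2a_V192I",
                     ref = c(2, 3, 1, 4, 2, 5, 1, 2, 3, 2),
                     alt = c(1, 0, 0, 2, 0, 0, 0, 1, 0, 0))
  prop <- mutantCellProportion(counts, "Kat2a_V192I",
                               sprintf("c%02d", 1:10))
  expect_equal(prop$covered, 10L)
  expect_equal(prop$mutant, 3L)
  expect_equal(prop$proportion, 0.3)

  ## a cell with reads only at a non-signature site leaves the denominator
  extra <- rbind(counts,
                 mkCounts("c11", "PBS", "Other_G1A", ref = 3, alt = 2))
  prop2 <- mutantCellProportion(extra, "Kat2a_V192I", sprintf("c%02d", 1:11))
  expect_equal(prop2$covered, 10L)

  ## non-tumor cells are excluded even when covered
  prop3 <- mutantCellProportion(counts, "Kat2a_V192I", sprintf("c%02d", 1:5))
  expect_equal(prop3$covered, 5L)
  expect_equal(prop3$mutant, 2L)

  ## zero-coverage groups are undefined, not zero
  g2 <- rbind(counts, mkCounts("d01", "combined", "Kat2a_V192I", 0, 0))
  prop4 <- mutantCellProportion(g2, "Kat2a_V192I",
                                c(sprintf("c%02d", 1:10), "d01"))
  expect_true(is.na(prop4$proportion[prop4$group == "combined"]))
})

test_that("proportions are invariant to row order and zero-count duplication", {
  counts <- mkCounts(c("c1", "c1", "c2", "c3"), "PBS",
                     c("s1", "s2", "s1", "s2"),
                     ref = c(1, 0, 2, 1), alt = c(0, 2, 0, 0))
  base <- mutantCellProportion(counts, c("s1", "s2"), c("c1", "c2", "c3"))
  shuffled <- counts[c(4, 2, 3, 1), ]
  dup <- rbind(counts, mkCounts("c2", "PBS", "s2", 0, 0))
  expect_equal(mutantCellProportion(shuffled, c("s1", "s2"),
                                    c("c1", "c2", "c3")), base)
  expect_equal(mutantCellProportion(dup, c("s1", "s2"),
                                    c("c1", "c2", "c3")), base)
})

test_that("Fisher comparisons match direct hypergeometric enumeration", {
  prop <- data.frame(group = c("PBS", "combined"),
                     covered = c(100L, 100L), mutant = c(30L, 5L),
                     proportion = c(0.30, 0.05))
  out <- compareProportions(prop, reference = "PBS")
  ## oracle: two-sided Fisher p by summing hypergeometric probabilities
  ## no larger than that of the observed table
  m <- 35; n <- 165; k <- 100
  probs <- dhyper(0:35, m, n, k)
  pOracle <- sum(probs[probs <= dhyper(5, m, n, k) * (1 + 1e-7)])
  expect_equal(out$p_value, pOracle, tolerance = 1e-10)
  expect_false(out$degenerate)

  ## identical groups give p = 1
  same <- data.frame(group = c("PBS", "vaccine"), covered = c(100L, 100L),
                     mutant = c(30L, 30L), proportion = c(0.3, 0.3))
  expect_equal(compareProportions(same, "PBS")$p_value, 1)

  ## swapping group labels leaves the two-sided p unchanged
  swapped <- prop[2:1, ]
  expect_equal(compareProportions(swapped, "combined")$p_value,
               out$p_value)
})

test_that("degenerate tables report p = 1 with a flag", {
  prop <- data.frame(group = c("PBS", "combined"), covered = c(50L, 60L),
                     mutant = c(0L, 0L), proportion = c(0, 0))
  out <- compareProportions(prop, "PBS")
  expect_equal(out$p_value, 1)
  expect_true(out$degenerate)
})

test_that("score comparisons summarize per group and test against the reference", {
  withr::with_seed(6, {
    scores <- c(rnorm(40, 1), rnorm(40, 0))
    groups <- rep(c("PBS", "combined"), each = 40)
    out <- compareScores(scores, groups, reference = "PBS")
    expect_identical(out$group, c("PBS", "combined"))
    expect_identical(out$n, c(40L, 40L))
    expect_true(is.na(out$p_value[1]))
    expect_lt(out$p_value[2], 0.01)
    expect_equal(out$p_value[2],
                 wilcox.test(scores[41:80], scores[1:40])$p.value)
  })
})
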