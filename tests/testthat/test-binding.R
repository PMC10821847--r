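## hand-built predictor with known weights and background
mkPredictor <- function(weights, bgPeptides, name = "mock-SMM") {
  k <- nrow(weights)
  colnames(weights) <- AA20
  p <- new("PssmPredictor", name = name, allele = "H-2-Kb",
           weights = setNames(list(weights), k),
           backgroundPeptides = setNames(list(bgPeptides), k),
           backgroundScores = setNames(list(numeric(1)), k))
  p@backgroundScores[[as.character(k)]] <-
    sort(vapply(bgPeptides, function(pep)
      sum(weights[cbind(seq_len(k), match(strsplit(pep, "")[[1]], AA20))]),
      numeric(1), USE.NAMES = FALSE))
  p
}

randomPeptides <- function(n, k) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, k, replace = TRUE), collapse = ""), character(1))
}

test_that("PSSM scores are position sums of weights", {
  withr::with_seed(1, {
    bg <- randomPeptides(100, 2)
    w0 <- matrix(0, 2, 20)
    p0 <- mkPredictor(w0, bg)
    expect_equal(pssmScore(p0, c("AC", "WY", "KK")), c(0, 0, 0))
    w <- matrix(rnorm(40), 2, 20, dimnames = list(NULL, AA20))
    p <- mkPredictor(w, bg)
    expect_equal(pssmScore(p, "AC"), unname(w[1, "A"] + w[2, "C"]))
    ## a position-symmetric matrix makes the score permutation-invariant
    wsym <- matrix(rep(rnorm(20), each = 2), 2, 20)
    psym <- mkPredictor(wsym, bg)
    expect_equal(pssmScore(psym, "AC"), pssmScore(psym, "CA"))
    expect_error(pssmScore(p, "ACD"), "length")
  })
})

test_that("percentile ranks hit 0 and 100 at the extremes and match a naive recount", {
  withr::with_seed(2, {
    k <- 8
    bg <- randomPeptides(500, k)
    w <- matrix(rnorm(20 * k), k, 20)
    p <- mkPredictor(w, bg)
    ## planted bonus beats the whole background -> rank 0
    p@planted <- "AAAAAAAA"
    expect_equal(percentileRank(p, "AAAAAAAA"), 0)
    ## a peptide below every background score -> rank 100
    low <- p
    low@backgroundScores[["8"]] <- sort(abs(rnorm(500)) + 1000)
    expect_equal(percentileRank(low, "CCCCCCCC"), 100)
    ## naive O(B) recount oracle
    query <- randomPeptides(200, k)
    got <- percentileRank(p, query)
    sc <- pssmScore(p, query)
    bgScores <- p@backgroundScores[["8"]]
    naive <- vapply(sc, function(s)
      100 * sum(bgScores >= s) / length(bgScores), numeric(1))
    expect_equal(got, naive)
  })
})

test_that("per-peptide medians use even-count means and the 2% cutoff is inclusive", {
  ranks <- matrix(c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0), nrow = 1,
                  dimnames = list("AAAAAAAA", paste0("p", 1:8)))
  m <- new("PredictorRankMatrix", ranks = ranks)
  med <- peptideMedians("AAAAAAAA", m)
  expect_equal(med$median_rank, 2.25)

  v <- SomaticVariantSet("X1", 1L, "A", "C", 0.5, 50L, 10)
  pep <- data.frame(source_id = "X1_A1C", kind = "mutant", form = "short",
                    start = 1L, end = 8L, mut_offset = 1L,
                    sequence = "AAAAAAAA")
  cons <- consensusRank(v, pep, m)
  expect_false(cons$passes)  # 2.25 > 2.0

  all2 <- new("PredictorRankMatrix",
              ranks = matrix(2, 1, 8, dimnames = dimnames(ranks)))
  expect_true(consensusRank(v, pep, all2)$passes)  # boundary is inclusive
})

test_that("consensus medians are predictor-order invariant and match a sort oracle", {
  withr::with_seed(3, {
    peps <- randomPeptides(50, 8)
    ranks <- matrix(runif(50 * 8, 0, 100), 50, 8,
                    dimnames = list(peps, paste0("p", 1:8)))
    ranks[sample(length(ranks), 60)] <- NA  # partial predictor coverage
    m <- new("PredictorRankMatrix", ranks = ranks)
    med <- peptideMedians(peps, m)
    ## sort-based oracle for the median of available ranks
    oracle <- vapply(peps, function(pp) {
      x <- sort(ranks[pp, ][!is.na(ranks[pp, ])])
      n <- length(x)
      if (n < 4) return(NA_real_)  # below coverage floor -> unscored
      if (n %% 2 == 1) x[(n + 1) / 2] else mean(x[n / 2 + 0:1])
    }, numeric(1), USE.NAMES = FALSE)
    expect_equal(med$median_rank, oracle)
    expect_identical(med$scored, !is.na(oracle))
    perm <- sample(8)
    mPerm <- new("PredictorRankMatrix", ranks = ranks[, perm])
    expect_equal(peptideMedians(peps, mPerm)$median_rank, med$median_rank)
  })
})

test_that("a mutation's best median is min-monotone in its peptide set", {
  withr::with_seed(4, {
    peps <- randomPeptides(6, 8)
    ranks <- matrix(runif(6 * 8, 0, 100), 6, 8,
                    dimnames = list(peps, paste0("p", 1:8)))
    m <- new("PredictorRankMatrix", ranks = ranks)
    v <- SomaticVariantSet("X1", 1L, "A", "C", 0.5, 50L, 10)
    mkPep <- function(seqs) data.frame(source_id = "X1_A1C",
                                       kind = "mutant", form = "short",
                                       start = 1L, end = 8L, mut_offset = 1L,
                                       sequence = seqs)
    full <- consensusRank(v, mkPep(peps), m)
    med <- peptideMedians(peps, m)
    nonBest <- med$peptide[which.max(med$median_rank)]
    dropped <- consensusRank(v, mkPep(setdiff(peps, nonBest)), m)
    expect_equal(dropped$best_median_rank, full$best_median_rank)
    subset3 <- consensusRank(v, mkPep(peps[1:3]), m)
    expect_gte(subset3$best_median_rank, full$best_median_rank)
  })
})

test_that("mutations with no scored peptide are flagged and excluded", {
  v <- SomaticVariantSet(c("X1", "Y1"), c(1L, 1L), c("A", "A"),
                         c("C", "C"), c(0.5, 0.5), c(50L, 50L), c(10, 10))
  pep <- data.frame(source_id = c("X1_A1C", "Y1_A1C"), kind = "mutant",
                    form = "short", start = 1L, end = 8L, mut_offset = 1L,
                    sequence = c("AAAAAAAA", "CCCCCCCC"))
  ranks <- matrix(1, 1, 8,
                  dimnames = list("AAAAAAAA", paste0("p", 1:8)))
  m <- new("PredictorRankMatrix", ranks = ranks)
  expect_warning(cons <- consensusRank(v, pep, m), "no scored peptide")
  expect_true(cons$unscored[cons$mutation_id == "Y1_A1C"])
  expect_false(cons$passes[cons$mutation_id == "Y1_A1C"])
  expect_true(cons$passes[cons$mutation_id == "X1_A1C"])
})

test_that("prioritization sorts by rank with tpm, vaf and id tie-breaks", {
  n <- 60
  ids <- sprintf("g%02d_A1C", seq_len(n))
  v <- SomaticVariantSet(sprintf("g%02d", seq_len(n)), rep(1L, n),
                         rep("A", n), rep("C", n),
                         vaf = rep(0.5, n), depth = rep(50L, n),
                         tpm = withr::with_seed(5, round(rlnorm(n, 2), 4)))
  cons <- data.frame(mutation_id = ids, best_peptide = "AAAAAAAA",
                     best_median_rank = 1.0, n_peptides = 1L, n_scored = 1L,
                     unscored = FALSE, passes = TRUE)
  top <- prioritize(cons, v, ThresholdConfig(topN = 20))
  expect_identical(nrow(top), 20L)
  expect_identical(top$mutation_id,
                   ids[order(-v$tpm, v$id)][1:20])  # equal rank -> by tpm

  few <- prioritize(cons[1:5, ], v, ThresholdConfig(topN = 20))
  expect_identical(nrow(few), 5L)

  ## equal median and tpm: higher VAF wins
  v2 <- SomaticVariantSet(c("a1", "b1"), c(1L, 1L), c("A", "A"),
                          c("C", "C"), vaf = c(0.2, 0.4),
                          depth = c(50L, 50L), tpm = c(10, 10))
  cons2 <- data.frame(mutation_id = c("a1_A1C", "b1_A1C"),
                      best_peptide = "AAAAAAAA", best_median_rank = 1.0,
                      n_peptides = 1L, n_scored = 1L, unscored = FALSE,
                      passes = TRUE)
  expect_identical(prioritize(cons2, v2)$mutation_id[1], "b1_A1C")
})

test_that("planted strong binders are recovered exactly by the mock ensemble", {
  prot <- randomProteome(30, lenMin = 80, lenMax = 150, seed = 8)
  vs <- randomVariants(prot, names(prot)[1:20], seed = 8)
  ens <- mockEnsemble(prot, lengths = c(8L, 9L), B = 2000L, seed = 8)
  pep <- buildPeptides(vs, prot)
  short <- pep[pep$form == "short", ]
  plantedIds <- variantIds(vs)[c(2, 9, 17)]
  epitopes <- vapply(plantedIds, function(id)
    short$sequence[short$source_id == id][1], character(1),
    USE.NAMES = FALSE)
  ens <- plantBinder(ens, epitopes)
  ranks <- scoreEpitopes(ens, short$sequence)
  cons <- consensusRank(vs, pep, ranks)
  expect_setequal(cons$mutation_id[cons$passes], plantedIds)
  expect_equal(cons$best_median_rank[cons$passes], rep(0, 3))
  expect_identical(
    vapply(plantedIds, function(id)
      cons$best_peptide[cons$mutation_id == id], character(1),
      USE.NAMES = FALSE),
    epitopes)
})

test_that("rank matrices round-trip through the long TSV format", {
  withr::with_seed(9, {
    peps <- randomPeptides(10, 8)
    ranks <- matrix(round(runif(80, 0, 100), 3), 10, 8,
                    dimnames = list(peps, paste0("mock-p", 1:8)))
    ranks[2, 3] <- NA
    m <- new("PredictorRankMatrix", ranks = ranks)
    path <- tempfile(fileext = ".tsv")
    writeRankMatrix(m, path)
    back <- readRankMatrix(path)
    expect_equal(rankMatrix(back)[peps, ], ranks)
  })
})
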