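test_that("the same seed yields a byte-identical bundle", {
  cfg <- tinySimConfig(seed = 13)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  b1 <- simulateStudy(cfg, d1)
  b2 <- simulateStudy(cfg, d2)
  ## run_config.yaml embeds the output directory; all data files must match
  dataFiles <- setdiff(names(b1$files), "config")
  for (f in dataFiles) {
    expect_identical(unname(tools::md5sum(b1$files[[f]])),
                     unname(tools::md5sum(b2$files[[f]])),
                     info = f)
  }
  ## a different seed changes the data
  b3 <- simulateStudy(tinySimConfig(seed = 14), file.path(tempfile(), "c"))
  expect_false(identical(unname(tools::md5sum(b1$files$variants)),
                         unname(tools::md5sum(b3$files$variants))))
})

test_that("each pipeline stage recovers the generator's truth sets", {
  cfg <- tinySimConfig(seed = 7)
  out <- tempfile()
  b <- simulateStudy(cfg, out)
  truth <- b$truth
  thr <- ThresholdConfig(topN = 6)

  variants <- addExpression(readVariants(b$files$variants),
                            readExpression(b$files$expression))
  filt <- filterExpressed(variants, thr)
  expect_setequal(variantIds(filt$kept), unlist(truth$expressed_ids))
  ## per-variant failed rules match the planting record
  pv <- perVariant(filt$report)
  expect_identical(pv$failed_rules,
                   unname(unlist(truth$failed_rules[pv$id])))

  proteome <- readProteome(b$files$proteome)
  pep <- buildPeptides(filt$kept, proteome,
                       MhcAllele(preferredLengths = c(8L, 9L)), thr)
  ranks <- readRankMatrix(b$files$ranks)
  cons <- consensusRank(filt$kept, pep, ranks, thr)
  expect_setequal(cons$mutation_id[cons$passes], unlist(truth$binder_ids))
  ## planted binders score rank 0 under every predictor
  expect_equal(cons$best_median_rank[cons$passes],
               rep(0, length(truth$binder_ids)))

  top <- prioritize(cons, filt$kept, thr)
  expect_identical(top$mutation_id, unlist(truth$top_ids))

  sel <- selectImmunogenic(readElispot(b$files$elispot), thr)
  expect_setequal(sel$mutation_id, unlist(truth$synthesized_ids))
  expect_setequal(sel$mutation_id[sel$selected],
                  unlist(truth$immunogenic_ids))
})

test_that("planted epitopes pass consensus while random epitopes rank uniformly", {
  prot <- randomProteome(40, lenMin = 100, lenMax = 200, seed = 31)
  ens <- mockEnsemble(prot, lengths = 8L, B = 2000L, seed = 31)
  withr::with_seed(32, {
    epitope <- paste(sample(AA20, 8, replace = TRUE), collapse = "")
  })
  planted <- plantBinder(ens, epitope)
  rk <- rankMatrix(scoreEpitopes(planted, epitope))
  expect_true(all(rk == 0))
  ## ranks of random peptides under one predictor are roughly uniform
  withr::with_seed(33, {
    rand <- vapply(1:400, function(i)
      paste(sample(AA20, 8, replace = TRUE), collapse = ""), character(1))
  })
  rks <- percentileRank(ens@predictors[[1]], rand)
  ks <- suppressWarnings(ks.test(rks, "punif", 0, 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate and infeasible configurations are rejected or trivial", {
  expect_error(tinySimConfig <- simConfig(nBinders = 30, nExpressed = 20),
               "funnel")
  expect_error(simConfig(nVariants = 900, nGenes = 800), "nGenes")
  expect_error(simConfig(scSiteCoverage = 1.5), "probabilities")

  ## all variants planted to pass -> the filter keeps everything
  cfg <- simConfig(seed = 3, nGenes = 40, nVariants = 30, nExpressed = 30,
                   nBinders = 5, nTop = 4, nSynthesized = 3,
                   nImmunogenic = 2, scDetectableSites = 2,
                   backgroundSize = 200, scCellsPerGroup = 20, scNGenes = 30,
                   proteinLenMin = 60L, proteinLenMax = 100L)
  b <- simulateStudy(cfg, tempfile())
  variants <- addExpression(readVariants(b$files$variants),
                            readExpression(b$files$expression))
  expect_identical(passCount(filterExpressed(variants)$report), 30L)
})

test_that("simulated marginals track their configured distributions", {
  cfg <- simConfig(seed = 17, nGenes = 600, nVariants = 100,
                   nExpressed = 50, nBinders = 10, nTop = 5,
                   nSynthesized = 4, nImmunogenic = 3,
                   backgroundSize = 200, scCellsPerGroup = 20,
                   scNGenes = 30, proteinLenMin = 60L, proteinLenMax = 100L)
  b <- simulateStudy(cfg, tempfile())
  ## genes without a variant draw TPM from the untruncated log-normal
  tpm <- readExpression(b$files$expression)
  variants <- readVariants(b$files$variants)
  free <- tpm[setdiff(names(tpm), variants$gene)]
  logs <- log(free)
  expect_equal(mean(logs), cfg@tpmMeanlog, tolerance = 0.25)
  expect_equal(sd(logs), cfg@tpmSdlog, tolerance = 0.25)
  ## planted variants respect their truncation sides
  v <- addExpression(variants, tpm)
  expressed <- variantIds(v) %in% unlist(b$truth$expressed_ids)
  expect_true(all(v$vaf[expressed] >= 0.10))
  expect_true(all(v$depth[expressed] >= 20))
  expect_true(all(v$tpm[expressed] >= 1))
  failed <- Filter(nzchar, b$truth$failed_rules)
  for (id in names(failed)) {
    rules <- strsplit(failed[[id]], ",")[[1]]
    row <- v[variantIds(v) == id, ]
    if ("vaf" %in% rules) expect_lt(row$vaf, 0.10)
    if ("depth" %in% rules) expect_lt(row$depth, 20)
    if ("tpm" %in% rules) expect_lt(row$tpm, 1)
  }
})

test_that("per-group mutant fractions and signature shifts are planted as configured", {
  cfg <- tinySimConfig(seed = 23)
  b <- simulateStudy(cfg, tempfile())
  counts <- readCellCounts(b$files$cell_counts)
  tumor <- readLines(b$files$tumor_cells)
  sites <- readLines(b$files$sites)
  prop <- mutantCellProportion(counts, sites, tumor)
  for (g in cfg@scGroups) {
    gt <- b$truth$sc$groups[[g]]
    expect_identical(prop$covered[prop$group == g],
                     gt$covered_tumor_cells)
    expect_identical(prop$mutant[prop$group == g], gt$mutant_tumor_cells)
  }
  expr <- readExpressionMatrix(b$files$sc_expression)
  sig <- readLines(b$files$signature_genes)
  expect_true(all(sig %in% rownames(expr)))
})
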