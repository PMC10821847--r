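## Rejection sampling from a truncated generator; the planted funnel needs
## every draw on a known side of its threshold.
.rtrunc <- function(n, draw, ok) {
  if (n == 0L) return(draw(0L))
  x <- draw(n)
  bad <- !ok(x)
  tries <- 0L
  while (any(bad)) {
    x[bad] <- draw(sum(bad))
    bad <- !ok(x)
    tries <- tries + 1L
    if (tries > 10000L)
      stop("truncated sampling failed: the configured distribution puts ",
           "almost no mass on the required side of the threshold")
  }
  x
}

.randomProteins <- function(n, lenMin, lenMax) {
  lens <- sample(lenMin:lenMax, n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(.AA20, L, replace = TRUE), collapse = ""), character(1))
}

## all 2^3 - 1 non-empty failing-rule subsets
.FAIL_SUBSETS <- list("vaf", "depth", "tpm", c("vaf", "depth"),
                      c("vaf", "tpm"), c("depth", "tpm"),
                      c("vaf", "depth", "tpm"))

#' Simulate a complete study bundle with planted ground truth
#'
#' Generates every input the pipeline consumes -- proteome FASTA, variant
#' and expression TSVs, a percentile-rank matrix from a planted mock
#' predictor ensemble, ELISPOT counts, per-cell allele counts with group
#' labels, a dense single-cell log-expression matrix -- plus a truth JSON
#' recording which variants were planted to survive each funnel stage.
#' Defaults reproduce the study-shaped funnel 762 -> 224 -> 60 -> 20 ->
#' 16 -> 7. VAF is Beta-distributed, depth negative-binomial, TPM
#' log-normal, ELISPOT counts negative-binomial straddling the 100-spot
#' cutoff, and per-cell site coverage is sparse with group-dependent
#' mutant-allele fractions and a group-dependent parent-gene signature
#' shift. The bundle is a pure function of `cfg`: the same seed yields a
#' byte-identical bundle.
#'
#' @param cfg a [SimConfig-class].
#' @param outdir output directory (created if needed).
#' @param thresholds the [ThresholdConfig-class] the planting must agree
#'   with (filter cutoffs, top-N, ELISPOT cutoff).
#' @return Invisibly, a list with `files` (named paths, including
#'   `config`, a ready-to-run YAML for [runAll()]) and `truth` (the truth
#'   list also written as JSON).
#' @export
simulateStudy <- function(cfg = simConfig(), outdir,
                          thresholds = ThresholdConfig()) {
  stopifnot(is(cfg, "SimConfig"), is(thresholds, "ThresholdConfig"))
  validObject(cfg)
  thresholds@topN <- cfg@nTop  # the funnel shape owns the top-N width
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  withr::with_seed(cfg@seed, {
    ## ---- proteome and variants -------------------------------------
    genes <- sprintf("G%04d", seq_len(cfg@nGenes))
    prots <- .randomProteins(cfg@nGenes, cfg@proteinLenMin, cfg@proteinLenMax)
    names(prots) <- genes
    proteome <- Proteome(prots)

    vGenes <- sample(genes, cfg@nVariants)
    vLen <- nchar(prots[vGenes])
    vPos <- vapply(vLen, function(L) sample.int(L, 1L), integer(1))
    vRef <- substring(prots[vGenes], vPos, vPos)
    vAlt <- vapply(vRef, function(r) sample(setdiff(.AA20, r), 1L),
                   character(1), USE.NAMES = FALSE)
    ids <- formatMutationId(vGenes, vRef, vPos, vAlt)

    expressedIdx <- sort(sample.int(cfg@nVariants, cfg@nExpressed))
    isExpressed <- seq_len(cfg@nVariants) %in% expressedIdx

    drawVaf <- function(n) stats::rbeta(n, cfg@vafShape1, cfg@vafShape2)
    drawDepth <- function(n) stats::rnbinom(n, size = cfg@depthDispersion,
                                            mu = cfg@depthMean)
    drawTpm <- function(n) stats::rlnorm(n, cfg@tpmMeanlog, cfg@tpmSdlog)

    vaf <- depth <- tpm <- numeric(cfg@nVariants)
    failedRules <- rep("", cfg@nVariants)
    nPass <- sum(isExpressed)
    vaf[isExpressed] <- .rtrunc(nPass, drawVaf,
                                function(x) x >= thresholds@minVaf)
    depth[isExpressed] <- .rtrunc(nPass, drawDepth,
                                  function(x) x >= thresholds@minDepth)
    tpm[isExpressed] <- .rtrunc(nPass, drawTpm,
                                function(x) x >= thresholds@minTpm)
    nFail <- cfg@nVariants - nPass
    if (nFail > 0L) {
      subset <- sample.int(length(.FAIL_SUBSETS), nFail, replace = TRUE)
      failIdx <- which(!isExpressed)
      for (j in seq_along(failIdx)) {
        i <- failIdx[j]
        rules <- .FAIL_SUBSETS[[subset[j]]]
        vaf[i] <- .rtrunc(1L, drawVaf, function(x)
          ("vaf" %in% rules) == (x < thresholds@minVaf))
        depth[i] <- .rtrunc(1L, drawDepth, function(x)
          ("depth" %in% rules) == (x < thresholds@minDepth))
        tpm[i] <- .rtrunc(1L, drawTpm, function(x)
          ("tpm" %in% rules) == (x < thresholds@minTpm))
        failedRules[i] <- paste(rules, collapse = ",")
      }
    }
    variants <- SomaticVariantSet(vGenes, vPos, vRef, vAlt, vaf,
                                  as.integer(depth), tpm)

    ## gene-level TPM table: variant genes carry their planted value,
    ## the rest draw freely
    tpmTable <- stats::setNames(drawTpm(cfg@nGenes), genes)
    tpmTable[vGenes] <- tpm

    ## ---- planted binders and the mock ensemble ---------------------
    binderIdx <- sort(sample(expressedIdx, cfg@nBinders))
    kPlant <- cfg@epitopeLengths[1L]
    plantedEpitope <- rep(NA_character_, cfg@nVariants)
    for (i in binderIdx) {
      mut <- prots[[vGenes[i]]]
      substr(mut, vPos[i], vPos[i]) <- vAlt[i]
      lo <- max(1L, vPos[i] - kPlant + 1L)
      hi <- min(vPos[i], nchar(mut) - kPlant + 1L)
      st <- if (hi > lo) sample(lo:hi, 1L) else lo
      plantedEpitope[i] <- substr(mut, st, st + kPlant - 1L)
    }
    ensSeed <- sample.int(.Machine$integer.max - 1L, 1L)
    ensemble <- mockEnsemble(proteome, lengths = cfg@epitopeLengths,
                             B = cfg@backgroundSize,
                             nPredictors = cfg@nPredictors, seed = ensSeed)
    ensemble <- plantBinder(ensemble, plantedEpitope[binderIdx])

    allele <- MhcAllele(preferredLengths = cfg@epitopeLengths)
    peptides <- buildPeptides(variants, proteome, allele,
                              cfg = thresholds)
    shorts <- unique(peptides$sequence[peptides$form == "short"])
    ranks <- scoreEpitopes(ensemble, shorts)

    ## ---- truth top-N: planted binders all get best median rank 0,
    ## so prioritization reduces to the tpm/vaf/id tie-break ----------
    bd <- data.frame(id = ids[binderIdx], tpm = tpm[binderIdx],
                     vaf = vaf[binderIdx], stringsAsFactors = FALSE)
    ordTop <- order(-bd$tpm, -bd$vaf, bd$id, method = "radix")
    topIds <- bd$id[ordTop][seq_len(cfg@nTop)]

    synthesizedIds <- sort(sample(topIds, cfg@nSynthesized))
    immunogenicIds <- sort(sample(synthesizedIds, cfg@nImmunogenic))

    ## ---- ELISPOT counts --------------------------------------------
    drawSpots <- function(mu, ok) {
      for (try in 1:10000) {
        x <- stats::rnbinom(cfg@elispotReplicates,
                            size = cfg@elispotDispersion, mu = mu)
        if (ok(mean(x))) return(x)
      }
      stop("ELISPOT planting failed: configured mean too close to cutoff")
    }
    elispotRows <- lapply(synthesizedIds, function(id) {
      immuno <- id %in% immunogenicIds
      mutSpots <- if (immuno)
        drawSpots(cfg@elispotImmunogenicMean,
                  function(m) m > thresholds@minSpots)
      else
        drawSpots(cfg@elispotNonImmunogenicMean,
                  function(m) m <= thresholds@minSpots)
      wtSpots <- stats::rnbinom(cfg@elispotReplicates,
                                size = cfg@elispotDispersion,
                                mu = cfg@elispotWtMean)
      ctrlSpots <- stats::rnbinom(cfg@elispotReplicates,
                                  size = cfg@elispotDispersion,
                                  mu = cfg@elispotCtrlMean)
      data.frame(mutation_id = id,
                 arm = rep(c("mut", "wt", "ctrl"),
                           each = cfg@elispotReplicates),
                 replicate = rep(seq_len(cfg@elispotReplicates), 3L),
                 spots = as.integer(c(mutSpots, wtSpots, ctrlSpots)),
                 stringsAsFactors = FALSE)
    })
    elispot <- do.call(rbind, elispotRows)

    ## ---- single-cell bundle ----------------------------------------
    siteIds <- sort(sample(immunogenicIds, cfg@scDetectableSites))
    groups <- cfg@scGroups
    cellRows <- list()
    cellMeta <- list()
    for (g in groups) {
      n <- cfg@scCellsPerGroup
      cellId <- sprintf("%s_c%05d", g, seq_len(n))
      tumor <- stats::runif(n) < cfg@scTumorFraction
      cov <- matrix(stats::runif(n * length(siteIds)) < cfg@scSiteCoverage,
                    nrow = n)
      anyCov <- rowSums(cov) > 0L
      isMut <- anyCov & (stats::runif(n) < cfg@scMutantFraction[[g]])
      rows <- lapply(which(anyCov), function(i) {
        sIdx <- which(cov[i, ])
        reads <- 1L + stats::rpois(length(sIdx), 0.7)
        alt <- integer(length(sIdx))
        if (isMut[i]) {
          pick <- sample(seq_along(sIdx), 1L)
          alt[pick] <- sample.int(reads[pick], 1L)
        }
        data.frame(cell = cellId[i], group = g, site_id = siteIds[sIdx],
                   ref_reads = reads - alt, alt_reads = alt,
                   stringsAsFactors = FALSE)
      })
      cellRows <- c(cellRows, rows)
      cellMeta[[g]] <- data.frame(cell = cellId, group = g, tumor = tumor,
                                  covered = anyCov, mutant = isMut,
                                  stringsAsFactors = FALSE)
    }
    cellCounts <- do.call(rbind, cellRows)
    cellMeta <- do.call(rbind, cellMeta)
    rownames(cellMeta) <- NULL
    tumorCells <- cellMeta$cell[cellMeta$tumor]

    ## ---- single-cell expression matrix with shifted signature ------
    sigGenes <- parseMutationId(immunogenicIds)$gene
    otherGenes <- sample(setdiff(genes, sigGenes),
                         cfg@scNGenes - length(sigGenes))
    exprGenes <- c(sigGenes, otherGenes)
    tumorMeta <- cellMeta[cellMeta$tumor, , drop = FALSE]
    baseMean <- stats::rnorm(length(exprGenes), mean = 2, sd = 1)
    expr <- matrix(stats::rnorm(length(exprGenes) * nrow(tumorMeta),
                                mean = baseMean, sd = 0.5),
                   nrow = length(exprGenes),
                   dimnames = list(exprGenes, tumorMeta$cell))
    shift <- cfg@scSignatureShift[tumorMeta$group]
    expr[sigGenes, ] <- expr[sigGenes, , drop = FALSE] +
      rep(shift, each = length(sigGenes))

    ## ---- write the bundle ------------------------------------------
    path <- function(f) file.path(outdir, f)
    files <- c(proteome = path("proteome.fasta"),
               variants = path("variants.tsv"),
               expression = path("expression.tsv"),
               ranks = path("ranks.tsv"),
               elispot = path("elispot.tsv"),
               cell_counts = path("cell_counts.tsv"),
               cell_groups = path("cell_groups.tsv"),
               tumor_cells = path("tumor_cells.txt"),
               sc_expression = path("sc_expression.tsv"),
               signature_genes = path("signature_genes.txt"),
               sites = path("sites.txt"),
               truth = path("truth.json"),
               config = path("run_config.yaml"))
    writeProteome(proteome, files[["proteome"]])
    ## TPM enters the pipeline via the expression table, not the variant TSV
    vOut <- SomaticVariantSet(vGenes, vPos, vRef, vAlt, vaf,
                              as.integer(depth), NA_real_)
    writeVariants(vOut, files[["variants"]])
    writeExpression(tpmTable, files[["expression"]])
    writeRankMatrix(ranks, files[["ranks"]])
    writeElispot(elispot, files[["elispot"]])
    writeCellCounts(cellCounts, files[["cell_counts"]])
    utils::write.table(cellMeta[, c("cell", "group")],
                       files[["cell_groups"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(tumorCells, files[["tumor_cells"]])
    writeExpressionMatrix(round(expr, 6), files[["sc_expression"]])
    writeLines(sigGenes, files[["signature_genes"]])
    writeLines(siteIds, files[["sites"]])

    truth <- list(
      seed = cfg@seed,
      funnel = list(variants = cfg@nVariants, expressed = cfg@nExpressed,
                    binders = cfg@nBinders, top = cfg@nTop,
                    synthesized = cfg@nSynthesized,
                    immunogenic = cfg@nImmunogenic),
      expressed_ids = ids[expressedIdx],
      failed_rules = stats::setNames(as.list(failedRules), ids),
      binder_ids = ids[binderIdx],
      planted_epitopes = stats::setNames(
        as.list(plantedEpitope[binderIdx]), ids[binderIdx]),
      top_ids = topIds,
      synthesized_ids = synthesizedIds,
      immunogenic_ids = immunogenicIds,
      sc = list(
        sites = siteIds,
        signature_genes = sigGenes,
        groups = lapply(stats::setNames(groups, groups), function(g) {
          mg <- cellMeta[cellMeta$group == g & cellMeta$tumor, ]
          list(mutant_fraction = cfg@scMutantFraction[[g]],
               signature_shift = cfg@scSignatureShift[[g]],
               covered_tumor_cells = sum(mg$covered),
               mutant_tumor_cells = sum(mg$mutant))
        })))
    jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)

    runCfg <- list(
      seed = cfg@seed,
      reference_group = groups[[1L]],
      allele = list(name = allele@name,
                    lengths = as.integer(cfg@epitopeLengths)),
      thresholds = list(min_vaf = thresholds@minVaf,
                        min_depth = thresholds@minDepth,
                        min_tpm = thresholds@minTpm,
                        max_median_rank = thresholds@maxMedianRank,
                        top_n = thresholds@topN,
                        min_spots = thresholds@minSpots,
                        long_peptide_len = thresholds@longPeptideLen),
      inputs = as.list(files[c("variants", "expression", "proteome",
                               "ranks", "elispot", "cell_counts",
                               "cell_groups", "tumor_cells",
                               "sc_expression", "signature_genes",
                               "sites")]))
    yaml::write_yaml(runCfg, files[["config"]])
    npLog("simulate", "bundle written to %s (funnel %d -> %d -> %d -> %d -> %d -> %d)",
          outdir, cfg@nVariants, cfg@nExpressed, cfg@nBinders, cfg@nTop,
          cfg@nSynthesized, cfg@nImmunogenic)
    invisible(list(files = as.list(files), truth = truth))
  })
}
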