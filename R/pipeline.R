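.readLinesFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readLines(path)
  x[nzchar(x)]
}

.md5 <- function(paths) {
  out <- as.list(unname(tools::md5sum(paths)))
  names(out) <- basename(paths)
  out
}

#' Run the whole prioritization pipeline from a YAML configuration
#'
#' Orchestrates filter -> peptides -> rank -> consensus -> prioritize ->
#' ELISPOT -> single-cell quantification as one reproducible run. Stages
#' communicate only through documented TSV/FASTA/JSON files, so any stage
#' input can be swapped for a real tool's output (e.g. genuine predictor
#' ranks in place of the mock ensemble). A failing stage aborts with the
#' stage name after writing a partial manifest.
#'
#' The YAML config carries `seed`, a `thresholds` block (snake_case
#' [ThresholdConfig()] keys), an `allele` block (`name`, `lengths`), an
#' `inputs` block with paths (`variants`, `expression`, `proteome`
#' required; `ranks`, `elispot`, `cell_counts`, `cell_groups`,
#' `tumor_cells`, `sc_expression`, `signature_genes`, `sites` optional),
#' an optional `mock` block (`background_size`, `n_predictors`) used when
#' no `ranks` file is given, and `reference_group` for the single-cell
#' comparisons.
#'
#' @param configPath path to the YAML run configuration.
#' @param outdir output directory for stage outputs and `manifest.json`.
#' @return Invisibly, the manifest list: config snapshot, input
#'   checksums, per-stage record counts (the screening funnel, checked to
#'   be non-increasing), output checksums, package version and seed.
#' @export
runAll <- function(configPath, outdir) {
  cfg <- yaml::read_yaml(configPath)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  thresholds <- thresholdConfigFromList(cfg$thresholds %||% list())
  seed <- as.integer(cfg$seed %||% 1L)
  inputs <- cfg$inputs %||% list()
  manifest <- list(package = "neoprior",
                   version = as.character(utils::packageVersion("neoprior")),
                   seed = seed, config = cfg,
                   stages_completed = character(), funnel = list())
  outPath <- function(f) file.path(outdir, f)
  finish <- function() {
    existing <- Filter(file.exists,
                       list.files(outdir, full.names = TRUE,
                                  pattern = "\\.(tsv|json)$"))
    existing <- setdiff(existing, outPath("manifest.json"))
    manifest$outputs <<- .md5(existing)
    jsonlite::write_json(manifest, outPath("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      manifest$error <<- list(stage = name,
                              message = conditionMessage(e))
      finish()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages_completed <<- c(manifest$stages_completed, name)
    res
  }
  need <- function(key) {
    p <- inputs[[key]]
    if (is.null(p)) stop("config inputs$", key, " is required")
    if (!file.exists(p)) stop("input file missing: ", p)
    p
  }
  manifest$inputs <- .md5(unlist(Filter(function(p)
    is.character(p) && file.exists(p), inputs)))

  ## ---- filter -------------------------------------------------------
  filtered <- stage("filter", {
    variants <- readVariants(need("variants"))
    tpm <- readExpression(need("expression"))
    filterExpressed(addExpression(variants, tpm), thresholds)
  })
  kept <- filtered$kept
  writeVariants(kept, outPath("kept_variants.tsv"))
  writeFilterReport(filtered$report, outPath("filter_report.json"))
  manifest$funnel$variants <- filtered$report@inputCount
  manifest$funnel$expressed <- filtered$report@passCount

  ## ---- peptides -----------------------------------------------------
  allele <- MhcAllele(name = cfg$allele$name %||% "H-2-Kb",
                      preferredLengths = cfg$allele$lengths %||% c(8L, 9L))
  pep <- stage("peptides", {
    proteome <- readProteome(need("proteome"))
    buildPeptides(kept, proteome, allele, thresholds)
  })
  writePeptides(pep, outPath("peptides.tsv"))

  ## ---- ranks: provided matrix or the mock ensemble -------------------
  ranks <- stage("rank", {
    if (!is.null(inputs$ranks)) {
      readRankMatrix(need("ranks"))
    } else {
      mock <- cfg$mock %||% list()
      ens <- mockEnsemble(readProteome(need("proteome")),
                          lengths = allele@preferredLengths,
                          B = mock$background_size %||% 10000L,
                          nPredictors = mock$n_predictors %||% 8L,
                          seed = seed)
      r <- scoreEpitopes(ens, pep$sequence[pep$form == "short"])
      writeRankMatrix(r, outPath("ranks.tsv"))
      r
    }
  })

  ## ---- consensus and prioritization ----------------------------------
  consensus <- stage("consensus", consensusRank(kept, pep, ranks, thresholds))
  utils::write.table(consensus, outPath("consensus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$funnel$consensus_pass <- sum(consensus$passes)

  top <- stage("prioritize", prioritize(consensus, kept, thresholds))
  utils::write.table(top, outPath("prioritized.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$funnel$prioritized <- nrow(top)

  ## ---- ELISPOT (optional) --------------------------------------------
  if (!is.null(inputs$elispot)) {
    sel <- stage("elispot", {
      elispot <- readElispot(need("elispot"))
      list(selection = selectImmunogenic(elispot, thresholds),
           cross = crossReactivity(elispot, thresholds))
    })
    utils::write.table(sel$selection, outPath("elispot_selected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sel$cross, outPath("cross_reactivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    assayed <- sel$selection$mutation_id
    manifest$funnel$synthesized <- sum(assayed %in% top$mutation_id)
    manifest$funnel$selected <-
      sum(sel$selection$selected & assayed %in% top$mutation_id)
    selectedIds <- sel$selection$mutation_id[sel$selection$selected]
  } else selectedIds <- character()

  ## ---- single-cell quantification (optional) -------------------------
  if (!is.null(inputs$cell_counts)) {
    refGroup <- cfg$reference_group %||% "PBS"
    sc <- stage("sc", {
      counts <- readCellCounts(need("cell_counts"))
      tumorCells <- .readLinesFile(need("tumor_cells"))
      sites <- if (!is.null(inputs$sites)) .readLinesFile(need("sites"))
               else intersect(selectedIds, counts$site_id)
      prop <- mutantCellProportion(counts, sites, tumorCells,
                                   minAlt = thresholds@minAltReads)
      out <- list(proportions = prop,
                  prop_tests = compareProportions(prop, refGroup))
      if (!is.null(inputs$sc_expression)) {
        expr <- readExpressionMatrix(need("sc_expression"))
        sig <- .readLinesFile(need("signature_genes"))
        cellGroups <- utils::read.delim(need("cell_groups"),
                                        stringsAsFactors = FALSE)
        grp <- stats::setNames(cellGroups$group, cellGroups$cell)[
          colnames(expr)]
        if (anyNA(grp)) stop("cells in expression matrix missing from cell_groups")
        scores <- signatureScore(expr, sig, seed = seed)
        out$scores <- data.frame(cell = colnames(expr), group = unname(grp),
                                 score = unname(scores),
                                 stringsAsFactors = FALSE)
        out$score_tests <- compareScores(scores, unname(grp), refGroup)
      }
      out
    })
    utils::write.table(sc$proportions, outPath("sc_mutant_proportion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sc$prop_tests, outPath("sc_proportion_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sc$scores)) {
      utils::write.table(sc$scores, outPath("sc_signature_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(sc$score_tests, outPath("sc_score_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## the screening funnel must shrink monotonically
  funnel <- unlist(manifest$funnel)
  if (is.unsorted(rev(funnel)))
    stop("funnel is not non-increasing: ",
         paste(names(funnel), funnel, sep = "=", collapse = ", "))
  finish()
  npLog("run", "funnel: %s",
        paste(names(funnel), funnel, sep = "=", collapse = " -> "))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
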