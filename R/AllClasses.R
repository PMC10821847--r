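#' @import methods
#' @import S4Vectors
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom withr with_seed
NULL

## The 20 standard amino acids; peptides and proteins are validated against
## this alphabet (non-standard residues such as X/U are tolerated in input
## proteins but peptides containing them are never scored or designed).
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Somatic missense variant set
#'
#' A `DataFrame` subclass holding one row per somatic missense variant with
#' the columns `gene`, `protein_pos` (1-based residue index), `ref_aa`,
#' `alt_aa`, `vaf`, `depth`, `tpm` (may be `NA` until expression is joined)
#' and the canonical `id` of the form `"<gene>_<ref><pos><alt>"`.
#'
#' @export
setClass("SomaticVariantSet", contains = "DFrame")

.validSomaticVariantSet <- function(object) {
  need <- c("gene", "protein_pos", "ref_aa", "alt_aa", "vaf", "depth",
            "tpm", "id")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  msg <- character()
  if (nrow(object) == 0L)
    return(TRUE)
  if (!all(object$ref_aa %in% .AA20) || !all(object$alt_aa %in% .AA20))
    msg <- c(msg, "ref_aa/alt_aa must be standard one-letter amino acids")
  if (any(object$ref_aa == object$alt_aa))
    msg <- c(msg, "ref_aa must differ from alt_aa")
  if (any(object$protein_pos < 1L))
    msg <- c(msg, "protein_pos must be >= 1")
  if (any(object$vaf < 0 | object$vaf > 1, na.rm = TRUE))
    msg <- c(msg, "vaf must lie in [0, 1]")
  if (any(object$depth < 0L))
    msg <- c(msg, "depth must be non-negative")
  if (any(object$tpm < 0, na.rm = TRUE))
    msg <- c(msg, "tpm must be non-negative")
  want <- paste0(object$gene, "_", object$ref_aa, object$protein_pos,
                 object$alt_aa)
  if (!all(object$id == want))
    msg <- c(msg, "id must equal <gene>_<ref><pos><alt>")
  if (length(msg)) msg else TRUE
}
setValidity("SomaticVariantSet", .validSomaticVariantSet)

#' Proteome: one amino-acid sequence per gene
#'
#' An `AAStringSet` subclass with unique, non-empty gene symbols as names.
#' One protein per gene; isoforms are out of scope.
#'
#' @export
setClass("Proteome", contains = "AAStringSet")

setValidity("Proteome", function(object) {
  nm <- names(object)
  if (is.null(nm) || any(!nzchar(nm)))
    return("all records must carry a gene symbol")
  if (anyDuplicated(nm))
    return(paste("duplicate gene symbol(s):",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (any(Biostrings::width(object) == 0L))
    return("sequences must be non-empty")
  TRUE
})

#' MHC class I allele
#'
#' Identifies the allele peptides are scored against and the epitope lengths
#' it preferentially presents. The default, H-2-Kb (the C57BL/6 mouse
#' allele), canonically binds 8-9-mers.
#'
#' @export
setClass("MhcAllele",
  representation(name = "character", preferredLengths = "integer"),
  prototype(name = "H-2-Kb", preferredLengths = c(8L, 9L)))

setValidity("MhcAllele", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  k <- object@preferredLengths
  if (length(k) == 0L || any(k < 8L | k > 11L))
    return("preferredLengths must be non-empty, each in [8, 11]")
  TRUE
})

#' Pipeline thresholds
#'
#' One object holds every cutoff the pipeline applies, so the filter chain,
#' consensus classification, prioritization and ELISPOT selection share a
#' single source of truth. Defaults: VAF >= 0.10, depth >= 20, TPM >= 1,
#' median percentile rank <= 2, top 20 candidates, > 100 ELISPOT spots,
#' 17-aa long peptides.
#'
#' @export
setClass("ThresholdConfig",
  representation(minVaf = "numeric", minDepth = "integer", minTpm = "numeric",
                 maxMedianRank = "numeric", topN = "integer",
                 minSpots = "numeric", longPeptideLen = "integer",
                 minPredictors = "integer", minAltReads = "integer",
                 crossAlpha = "numeric", ctrlSdMult = "numeric"),
  prototype(minVaf = 0.10, minDepth = 20L, minTpm = 1.0,
            maxMedianRank = 2.0, topN = 20L, minSpots = 100,
            longPeptideLen = 17L, minPredictors = 4L, minAltReads = 1L,
            crossAlpha = 0.05, ctrlSdMult = 3))

setValidity("ThresholdConfig", function(object) {
  vals <- c(object@minVaf, object@minDepth, object@minTpm,
            object@maxMedianRank, object@topN, object@minSpots,
            object@longPeptideLen, object@minPredictors, object@minAltReads,
            object@crossAlpha, object@ctrlSdMult)
  if (any(vals < 0)) return("all thresholds must be non-negative")
  if (object@longPeptideLen %% 2L == 0L)
    return("longPeptideLen must be odd (mutation-centered window)")
  TRUE
})

#' Mock position-scoring matrix predictor
#'
#' A stand-in for an external MHC binding predictor. Each supported epitope
#' length carries a k x 20 weight matrix; a peptide's raw score is the sum
#' of position-specific weights, calibrated to a percentile rank against a
#' background of proteome k-mers. A set of planted sequences receives a
#' fixed score bonus, emulating epitopes the predictor calls strong binders.
#'
#' @export
setClass("PssmPredictor",
  representation(name = "character", allele = "character",
                 weights = "list", backgroundPeptides = "list",
                 backgroundScores = "list", planted = "character",
                 plantBonus = "numeric"),
  prototype(planted = character(), plantBonus = 1e6))

setValidity("PssmPredictor", function(object) {
  ks <- names(object@weights)
  if (length(ks) == 0L) return("at least one epitope length required")
  if (!identical(ks, names(object@backgroundScores)) ||
      !identical(ks, names(object@backgroundPeptides)))
    return("weights, backgroundPeptides and backgroundScores must share names")
  for (k in ks) {
    w <- object@weights[[k]]
    if (!is.matrix(w) || nrow(w) != as.integer(k) ||
        !identical(colnames(w), .AA20))
      return(sprintf("weights[['%s']] must be a %s x 20 matrix over the standard alphabet", k, k))
    if (length(object@backgroundScores[[k]]) == 0L)
      return("background must be non-empty")
    if (is.unsorted(object@backgroundScores[[k]]))
      return("backgroundScores must be sorted ascending")
  }
  TRUE
})

#' Ensemble of mock predictors
#' @export
setClass("PssmEnsemble", representation(predictors = "list"))

setValidity("PssmEnsemble", function(object) {
  p <- object@predictors
  if (length(p) == 0L) return("ensemble must contain >= 1 predictor")
  if (!all(vapply(p, is, logical(1), class2 = "PssmPredictor")))
    return("all elements must be PssmPredictor objects")
  if (anyDuplicated(vapply(p, function(x) x@name, character(1))))
    return("predictor names must be unique")
  TRUE
})

#' Percentile-rank matrix
#'
#' Ranks in `[0, 100]` (lower = stronger predicted binder), one row per
#' peptide sequence and one column per predictor; `NA` marks an unscored
#' cell.
#'
#' @export
setClass("PredictorRankMatrix", representation(ranks = "matrix"))

setValidity("PredictorRankMatrix", function(object) {
  r <- object@ranks
  if (is.null(rownames(r)) || is.null(colnames(r)))
    return("ranks must carry peptide rownames and predictor colnames")
  if (anyDuplicated(rownames(r))) return("duplicate peptide rows")
  if (any(r < 0 | r > 100, na.rm = TRUE))
    return("ranks must lie in [0, 100]")
  TRUE
})

#' Filter-chain report
#'
#' Per-variant outcome of the expression-aware filter: which of the vaf /
#' depth / tpm rules failed, plus the input and pass counts of the funnel
#' stage.
#'
#' @export
setClass("FilterReport",
  representation(inputCount = "integer", passCount = "integer",
                 perVariant = "data.frame"))

setValidity("FilterReport", function(object) {
  pv <- object@perVariant
  if (!all(c("id", "kept", "failed_rules") %in% colnames(pv)))
    return("perVariant needs columns id, kept, failed_rules")
  if (object@passCount != sum(pv$kept))
    return("passCount must equal the number of kept variants")
  if (!identical(pv$kept, !nzchar(pv$failed_rules)))
    return("kept must be TRUE exactly when failed_rules is empty")
  TRUE
})

#' Synthetic-study configuration
#'
#' Defines every distribution and planted truth of the simulated study:
#' the variant funnel sizes, the Beta/negative-binomial/log-normal marginals
#' of VAF, depth and TPM, the mock predictor ensemble, over-dispersed
#' ELISPOT counts straddling the 100-spot cutoff, and the sparse per-cell
#' mutant-allele coverage with group-dependent mutant fractions and a
#' group-dependent parent-gene signature shift. Generation is a pure
#' function of this object.
#'
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    nGenes = "integer", proteinLenMin = "integer", proteinLenMax = "integer",
    nVariants = "integer", nExpressed = "integer", nBinders = "integer",
    nTop = "integer", nSynthesized = "integer", nImmunogenic = "integer",
    vafShape1 = "numeric", vafShape2 = "numeric",
    depthMean = "numeric", depthDispersion = "numeric",
    tpmMeanlog = "numeric", tpmSdlog = "numeric",
    epitopeLengths = "integer", nPredictors = "integer",
    backgroundSize = "integer",
    elispotReplicates = "integer", elispotImmunogenicMean = "numeric",
    elispotNonImmunogenicMean = "numeric", elispotWtMean = "numeric",
    elispotCtrlMean = "numeric", elispotDispersion = "numeric",
    scGroups = "character", scMutantFraction = "numeric",
    scSignatureShift = "numeric", scCellsPerGroup = "integer",
    scSiteCoverage = "numeric", scTumorFraction = "numeric",
    scNGenes = "integer", scDetectableSites = "integer"),
  prototype(
    seed = 1L,
    nGenes = 800L, proteinLenMin = 150L, proteinLenMax = 600L,
    nVariants = 762L, nExpressed = 224L, nBinders = 60L,
    nTop = 20L, nSynthesized = 16L, nImmunogenic = 7L,
    vafShape1 = 2, vafShape2 = 8,
    depthMean = 60, depthDispersion = 5,
    tpmMeanlog = 1, tpmSdlog = 1.5,
    epitopeLengths = c(8L, 9L), nPredictors = 8L,
    backgroundSize = 10000L,
    elispotReplicates = 3L, elispotImmunogenicMean = 300,
    elispotNonImmunogenicMean = 20, elispotWtMean = 8,
    elispotCtrlMean = 5, elispotDispersion = 10,
    scGroups = c("PBS", "vaccine", "checkpoint", "combined"),
    scMutantFraction = c(PBS = 0.30, vaccine = 0.15, checkpoint = 0.15,
                         combined = 0.05),
    scSignatureShift = c(PBS = 1, vaccine = 0.5, checkpoint = 0.5,
                         combined = 0),
    scCellsPerGroup = 600L, scSiteCoverage = 0.45, scTumorFraction = 0.9,
    scNGenes = 300L, scDetectableSites = 3L))

setValidity("SimConfig", function(object) {
  msg <- character()
  funnel <- c(object@nImmunogenic, object@nSynthesized, object@nTop,
              object@nBinders, object@nExpressed, object@nVariants)
  if (is.unsorted(funnel))
    msg <- c(msg, "funnel must satisfy immunogenic <= synthesized <= top <= binders <= expressed <= variants")
  if (object@nVariants > object@nGenes)
    msg <- c(msg, "need nGenes >= nVariants (one variant per gene)")
  probs <- c(object@scMutantFraction, object@scSiteCoverage,
             object@scTumorFraction)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (!setequal(names(object@scMutantFraction), object@scGroups) ||
      !setequal(names(object@scSignatureShift), object@scGroups))
    msg <- c(msg, "scMutantFraction and scSignatureShift must be named by scGroups")
  if (object@proteinLenMin < 8L)
    msg <- c(msg, "proteins must be at least 8 residues")
  if (object@scNGenes < object@nImmunogenic)
    msg <- c(msg, "scNGenes must cover the signature genes")
  if (object@scDetectableSites > object@nImmunogenic)
    msg <- c(msg, "scDetectableSites cannot exceed nImmunogenic")
  if (length(msg)) msg else TRUE
})
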