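#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' `variantIds()` returns canonical mutation ids; `rankMatrix()` the raw
#' peptide-by-predictor rank matrix; `predictorNames()` the ensemble / matrix
#' predictor names; `passCount()` and `perVariant()` the filter-report
#' contents.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setMethod("variantIds", "SomaticVariantSet", function(x) x$id)

#' @rdname accessors
#' @export
setGeneric("rankMatrix", function(x) standardGeneric("rankMatrix"))

#' @rdname accessors
#' @export
setMethod("rankMatrix", "PredictorRankMatrix", function(x) x@ranks)

#' @rdname accessors
#' @export
setGeneric("predictorNames", function(x) standardGeneric("predictorNames"))

#' @rdname accessors
#' @export
setMethod("predictorNames", "PredictorRankMatrix",
          function(x) colnames(x@ranks))

#' @rdname accessors
#' @export
setMethod("predictorNames", "PssmEnsemble",
          function(x) vapply(x@predictors, function(p) p@name, character(1)))

#' @rdname accessors
#' @export
setGeneric("passCount", function(x) standardGeneric("passCount"))

#' @rdname accessors
#' @export
setMethod("passCount", "FilterReport", function(x) x@passCount)

#' @rdname accessors
#' @export
setGeneric("perVariant", function(x) standardGeneric("perVariant"))

#' @rdname accessors
#' @export
setMethod("perVariant", "FilterReport", function(x) x@perVariant)

setMethod("show", "SomaticVariantSet", function(object) {
  cat(sprintf("SomaticVariantSet with %d variant(s)\n", nrow(object)))
  callNextMethod()
})

setMethod("show", "Proteome", function(object) {
  cat(sprintf("Proteome with %d protein(s), widths %d..%d\n",
              length(object),
              if (length(object)) min(Biostrings::width(object)) else 0L,
              if (length(object)) max(Biostrings::width(object)) else 0L))
})

setMethod("show", "MhcAllele", function(object) {
  cat(sprintf("MhcAllele %s (epitope lengths: %s)\n", object@name,
              paste(object@preferredLengths, collapse = ", ")))
})

setMethod("show", "ThresholdConfig", function(object) {
  cat("ThresholdConfig\n",
      sprintf("  filter: vaf >= %g, depth >= %d, tpm >= %g\n",
              object@minVaf, object@minDepth, object@minTpm),
      sprintf("  consensus: median rank <= %g%% (>= %d predictors), top %d\n",
              object@maxMedianRank, object@minPredictors, object@topN),
      sprintf("  elispot: mean spots > %g; long peptide %d aa\n",
              object@minSpots, object@longPeptideLen), sep = "")
})

setMethod("show", "PssmPredictor", function(object) {
  cat(sprintf("PssmPredictor %s [%s], lengths {%s}, background %s, %d planted\n",
              object@name, object@allele,
              paste(names(object@weights), collapse = ","),
              paste(lengths(object@backgroundScores), collapse = ","),
              length(object@planted)))
})

setMethod("show", "PssmEnsemble", function(object) {
  cat(sprintf("PssmEnsemble of %d predictor(s): %s\n",
              length(object@predictors),
              paste(predictorNames(object), collapse = ", ")))
})

setMethod("show", "PredictorRankMatrix", function(object) {
  cat(sprintf("PredictorRankMatrix: %d peptide(s) x %d predictor(s), %d unscored cell(s)\n",
              nrow(object@ranks), ncol(object@ranks),
              sum(is.na(object@ranks))))
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d / %d variant(s) kept\n",
              object@passCount, object@inputCount))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig (seed %d): funnel %d -> %d -> %d -> %d -> %d -> %d\n",
              object@seed, object@nVariants, object@nExpressed,
              object@nBinders, object@nTop, object@nSynthesized,
              object@nImmunogenic))
})
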