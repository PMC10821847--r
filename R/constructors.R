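#' Construct a somatic variant set
#'
#' @param gene gene symbols (no underscores).
#' @param protein_pos 1-based mutated residue positions.
#' @param ref_aa,alt_aa single-letter reference / alternate amino acids.
#' @param vaf variant allele fractions in `[0, 1]`.
#' @param depth read depths (non-negative integers).
#' @param tpm transcripts-per-million of the parent gene; `NA` until joined
#'   from an expression table (see [addExpression()]).
#'
#' @return A [SomaticVariantSet-class] with canonical ids
#'   `"<gene>_<ref><pos><alt>"`.
#' @examples
#' SomaticVariantSet("Mapkbp1", 204, "W", "C", vaf = 0.31, depth = 45,
#'                   tpm = 12.2)
#' @export
SomaticVariantSet <- function(gene = character(), protein_pos = integer(),
                              ref_aa = character(), alt_aa = character(),
                              vaf = numeric(), depth = integer(),
                              tpm = NA_real_) {
  n <- length(gene)
  if (grepl("_", paste(gene, collapse = "")))
    stop("gene symbols must not contain '_'")
  df <- DataFrame(gene = as.character(gene),
                  protein_pos = as.integer(protein_pos),
                  ref_aa = as.character(ref_aa),
                  alt_aa = as.character(alt_aa),
                  vaf = as.numeric(vaf),
                  depth = as.integer(depth),
                  tpm = rep_len(as.numeric(tpm), n))
  df$id <- if (n) paste0(df$gene, "_", df$ref_aa, df$protein_pos, df$alt_aa)
           else character()
  new("SomaticVariantSet", df)
}

.asVariantSet <- function(df) {
  SomaticVariantSet(df$gene, df$protein_pos, df$ref_aa, df$alt_aa,
                    df$vaf, df$depth,
                    if ("tpm" %in% names(df)) df$tpm else NA_real_)
}

#' Construct a proteome
#'
#' @param x a named character vector of amino-acid sequences or an
#'   `AAStringSet`; names are gene symbols and must be unique.
#' @return A [Proteome-class].
#' @examples
#' Proteome(c(Mapkbp1 = "MRHIKFCYLW"))
#' @export
Proteome <- function(x) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  new("Proteome", x)
}

#' Construct an MHC allele descriptor
#'
#' @param name allele identifier.
#' @param preferredLengths epitope lengths the allele presents, each in
#'   `[8, 11]`. H-2-Kb canonically presents 8-9-mers.
#' @export
MhcAllele <- function(name = "H-2-Kb", preferredLengths = c(8L, 9L)) {
  new("MhcAllele", name = name,
      preferredLengths = as.integer(preferredLengths))
}

#' Construct the shared threshold configuration
#'
#' Defaults are the pipeline's published operating point: VAF >= 10%,
#' depth >= 20 reads, TPM >= 1, median percentile rank <= 2%, top 20
#' candidates, strictly more than 100 ELISPOT spots, 17-aa long peptides.
#'
#' @param minVaf,minDepth,minTpm inclusive expression-filter cutoffs.
#' @param maxMedianRank inclusive consensus cutoff, in percent.
#' @param topN number of prioritized candidates retained.
#' @param minSpots ELISPOT selection cutoff (strict `>`).
#' @param longPeptideLen odd synthesis-peptide length.
#' @param minPredictors minimum predictor coverage for a peptide median.
#' @param minAltReads reads required to call a mutant allele detected in a
#'   cell.
#' @param crossAlpha,ctrlSdMult cross-reactivity test level and the
#'   control-guard SD multiplier.
#' @export
ThresholdConfig <- function(minVaf = 0.10, minDepth = 20L, minTpm = 1.0,
                            maxMedianRank = 2.0, topN = 20L, minSpots = 100,
                            longPeptideLen = 17L, minPredictors = 4L,
                            minAltReads = 1L, crossAlpha = 0.05,
                            ctrlSdMult = 3) {
  new("ThresholdConfig", minVaf = minVaf, minDepth = as.integer(minDepth),
      minTpm = minTpm, maxMedianRank = maxMedianRank,
      topN = as.integer(topN), minSpots = minSpots,
      longPeptideLen = as.integer(longPeptideLen),
      minPredictors = as.integer(minPredictors),
      minAltReads = as.integer(minAltReads), crossAlpha = crossAlpha,
      ctrlSdMult = ctrlSdMult)
}

#' Construct a synthetic-study configuration
#'
#' All arguments default to the prototype values of [SimConfig-class],
#' which encode the study-shaped funnel (762 variants, 224 expressed, 60
#' consensus binders, top 20, 16 synthesized, 7 immunogenic) and realistic
#' marginals for VAF, depth, TPM, ELISPOT counts and single-cell coverage.
#'
#' @param seed integer seed; the whole bundle is a pure function of it.
#' @param ... any `SimConfig` slot to override, by name.
#' @export
simConfig <- function(seed = 1L, ...) {
  args <- list(...)
  slots <- slotNames("SimConfig")
  bad <- setdiff(names(args), slots)
  if (length(bad))
    stop("unknown SimConfig field(s): ", paste(bad, collapse = ", "))
  proto <- getSlots("SimConfig")
  for (nm in names(args)) {
    if (proto[[nm]] == "integer") args[[nm]] <- as.integer(args[[nm]])
  }
  do.call(new, c(list("SimConfig", seed = as.integer(seed)), args))
}
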