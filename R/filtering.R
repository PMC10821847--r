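#' Expression-aware somatic variant filter
#'
#' Keeps variants with RNA-level support: VAF, read depth and parent-gene
#' TPM must all meet their (inclusive) thresholds. Every rule is evaluated
#' for every variant, so the report lists all failed rules, not just the
#' first. A variant with missing TPM (gene absent from the expression
#' table) fails the `tpm` rule, with a warning naming the genes: absence of
#' expression evidence fails the expression rule.
#'
#' @param variants a [SomaticVariantSet-class] with `tpm` joined (see
#'   [addExpression()]).
#' @param cfg a [ThresholdConfig-class]; `minVaf`, `minDepth` and `minTpm`
#'   are used.
#' @return A list with elements `kept` (the passing
#'   [SomaticVariantSet-class], input order preserved) and `report`
#'   (a [FilterReport-class]).
#' @examples
#' v <- SomaticVariantSet(c("A1", "B1"), c(10, 20), c("W", "G"),
#'                        c("C", "A"), vaf = c(0.10, 0.09),
#'                        depth = c(20L, 100L), tpm = c(1, 50))
#' filterExpressed(v, ThresholdConfig())$report
#' @export
filterExpressed <- function(variants, cfg = ThresholdConfig()) {
  stopifnot(is(variants, "SomaticVariantSet"), is(cfg, "ThresholdConfig"))
  noTpm <- is.na(variants$tpm)
  if (any(noTpm))
    warning("no expression entry for gene(s): ",
            paste(unique(variants$gene[noTpm]), collapse = ", "),
            "; tpm rule failed for those variants")
  okVaf <- !is.na(variants$vaf) & variants$vaf >= cfg@minVaf
  okDepth <- variants$depth >= cfg@minDepth
  okTpm <- !noTpm & variants$tpm >= cfg@minTpm
  failed <- cbind(vaf = !okVaf, depth = !okDepth, tpm = !okTpm)
  kept <- okVaf & okDepth & okTpm
  failedRules <- apply(failed, 1L, function(f)
    paste(colnames(failed)[f], collapse = ","))
  if (nrow(variants) == 0L) failedRules <- character()
  report <- new("FilterReport",
                inputCount = nrow(variants),
                passCount = sum(kept),
                perVariant = data.frame(id = as.character(variants$id),
                                        kept = as.logical(kept),
                                        failed_rules = as.character(failedRules),
                                        stringsAsFactors = FALSE))
  npLog("filter", "kept %d/%d variants (vaf >= %g, depth >= %d, tpm >= %g)",
        sum(kept), nrow(variants), cfg@minVaf, cfg@minDepth, cfg@minTpm)
  list(kept = variants[kept, , drop = FALSE], report = report)
}

#' Serialize a filter report to JSON
#'
#' @param report a [FilterReport-class].
#' @param path output path.
#' @export
writeFilterReport <- function(report, path) {
  stopifnot(is(report, "FilterReport"))
  pv <- report@perVariant
  per <- lapply(seq_len(nrow(pv)), function(i) {
    fr <- pv$failed_rules[i]
    list(kept = pv$kept[i],
         failed_rules = if (nzchar(fr)) strsplit(fr, ",")[[1L]]
                        else character())
  })
  names(per) <- pv$id
  jsonlite::write_json(list(input_count = report@inputCount,
                            pass_count = report@passCount,
                            per_variant = per),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
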