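## Per-stage progress lines go to stderr so TSV/JSON on stdout stay clean.
npLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Parse and format canonical mutation ids
#'
#' A mutation id is `"<gene>_<ref><pos><alt>"`, e.g. `"Mapkbp1_W204C"`:
#' gene symbol (digits allowed, underscores not), reference amino acid,
#' 1-based protein position, alternate amino acid. `parseMutationId()` and
#' `formatMutationId()` are mutually inverse on valid ids.
#'
#' @param id character vector of ids.
#' @return `parseMutationId()`: a data.frame with columns `gene`, `ref_aa`,
#'   `protein_pos`, `alt_aa` (one row per id). `formatMutationId()`: a
#'   character vector.
#' @examples
#' parseMutationId("Mapkbp1_W204C")
#' formatMutationId("Naa80", "G", 150, "A")
#' @export
parseMutationId <- function(id) {
  stopifnot(is.character(id))
  m <- regmatches(id, regexec("^([^_]+)_([A-Za-z*])([0-9]+)([A-Za-z*])$", id))
  bad <- lengths(m) != 5L
  if (any(bad))
    stop("malformed mutation id: '", id[which(bad)[1L]],
         "' (expected <gene>_<ref><pos><alt>)")
  p <- do.call(rbind, m)
  out <- data.frame(gene = p[, 2L], ref_aa = p[, 3L],
                    protein_pos = as.integer(p[, 4L]), alt_aa = p[, 5L],
                    stringsAsFactors = FALSE)
  badAa <- !(out$ref_aa %in% .AA20) | !(out$alt_aa %in% .AA20)
  if (any(badAa))
    stop("non-standard amino acid in id '", id[which(badAa)[1L]], "'")
  same <- out$ref_aa == out$alt_aa
  if (any(same))
    stop("reference equals alternate amino acid in id '",
         id[which(same)[1L]], "'")
  if (any(out$protein_pos < 1L))
    stop("protein position must be >= 1 in id '",
         id[which(out$protein_pos < 1L)[1L]], "'")
  out
}

#' @rdname parseMutationId
#' @param gene,ref_aa,protein_pos,alt_aa id components (vectorized).
#' @export
formatMutationId <- function(gene, ref_aa, protein_pos, alt_aa) {
  paste0(gene, "_", ref_aa, as.integer(protein_pos), alt_aa)
}

.checkRange <- function(x, lo, hi, what, lineNo) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad))
    stop(sprintf("line %d: %s = %s outside [%s, %s]",
                 lineNo[bad[1L]], what, x[bad[1L]], lo, hi))
}

#' Read and write somatic variant tables
#'
#' The canonical interchange format is TSV with header columns `gene`,
#' `protein_change` (e.g. `W204C`), `vaf`, `depth` and optionally `tpm`.
#' A minimal VCF dialect is also read: the INFO field must carry the keys
#' `GENE`, `PCHANGE`, `VAF` and `DP`. Row order is preserved and every
#' validation error names the offending file line.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return A [SomaticVariantSet-class].
#' @export
readVariants <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") .readVariantsTsv(path) else .readVariantsVcf(path)
}

.readVariantsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("gene", "protein_change", "vaf", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(SomaticVariantSet())
  lineNo <- seq_len(nrow(df)) + 1L  # header is line 1
  pc <- parseMutationId(paste0(df$gene, "_", df$protein_change))
  .checkRange(df$vaf, 0, 1, "vaf", lineNo)
  .checkRange(df$depth, 0, Inf, "depth", lineNo)
  if ("tpm" %in% names(df)) .checkRange(df$tpm, 0, Inf, "tpm", lineNo)
  SomaticVariantSet(pc$gene, pc$protein_pos, pc$ref_aa, pc$alt_aa,
                    df$vaf, df$depth,
                    if ("tpm" %in% names(df)) df$tpm else NA_real_)
}

.readVariantsVcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(SomaticVariantSet())
  lineNo <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- lengths(fields) < 8L
  if (any(short))
    stop(sprintf("line %d: fewer than 8 VCF columns", lineNo[short][1L]))
  info <- vapply(fields, `[[`, character(1), 8L)
  getKey <- function(key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    val <- vapply(m, function(x) if (length(x) == 2L) x[[2L]] else NA_character_,
                  character(1))
    if (anyNA(val))
      stop(sprintf("line %d: missing INFO key %s", lineNo[is.na(val)][1L], key))
    val
  }
  gene <- getKey("GENE")
  pchange <- getKey("PCHANGE")
  vaf <- as.numeric(getKey("VAF"))
  depth <- as.integer(getKey("DP"))
  .checkRange(vaf, 0, 1, "VAF", lineNo)
  .checkRange(depth, 0, Inf, "DP", lineNo)
  pc <- parseMutationId(paste0(gene, "_", pchange))
  SomaticVariantSet(pc$gene, pc$protein_pos, pc$ref_aa, pc$alt_aa,
                    vaf, depth)
}

#' @rdname readVariants
#' @param variants a [SomaticVariantSet-class] to write (TSV only).
#' @export
writeVariants <- function(variants, path) {
  stopifnot(is(variants, "SomaticVariantSet"))
  df <- data.frame(gene = variants$gene,
                   protein_change = paste0(variants$ref_aa,
                                           variants$protein_pos,
                                           variants$alt_aa),
                   vaf = variants$vaf, depth = variants$depth,
                   tpm = variants$tpm)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a proteome FASTA
#'
#' Thin wrappers over Biostrings with gene-symbol uniqueness enforced;
#' write-then-read is an identity on records.
#'
#' @param path FASTA file path.
#' @param width line-wrap width for the writer.
#' @return `readProteome()`: a [Proteome-class].
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  Proteome(aa)
}

#' @rdname readProteome
#' @param proteome a [Proteome-class].
#' @export
writeProteome <- function(proteome, path, width = 60L) {
  stopifnot(is(proteome, "Proteome"))
  Biostrings::writeXStringSet(proteome, path, width = width)
  invisible(path)
}

#' Read / write a gene-level expression table (columns `gene`, `tpm`)
#' @param path TSV path.
#' @return named numeric vector of TPM, names = gene symbols.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "tpm") %in% names(df)))
    stop("expression table needs columns gene, tpm")
  if (anyDuplicated(df$gene))
    stop("duplicate gene(s) in expression table: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  bad <- which(!is.na(df$tpm) & df$tpm < 0)
  if (length(bad)) stop(sprintf("line %d: negative tpm", bad[1L] + 1L))
  stats::setNames(df$tpm, df$gene)
}

#' @rdname readExpression
#' @param tpm named numeric vector.
#' @export
writeExpression <- function(tpm, path) {
  utils::write.table(data.frame(gene = names(tpm), tpm = as.numeric(tpm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join gene-level TPM onto a variant set
#'
#' Variants whose gene is absent from the expression table keep `tpm = NA`;
#' the filter stage treats a missing TPM as failing the expression rule.
#'
#' @param variants a [SomaticVariantSet-class].
#' @param tpm named numeric vector as returned by [readExpression()].
#' @export
addExpression <- function(variants, tpm) {
  stopifnot(is(variants, "SomaticVariantSet"))
  SomaticVariantSet(variants$gene, variants$protein_pos, variants$ref_aa,
                    variants$alt_aa, variants$vaf, variants$depth,
                    tpm = unname(tpm[variants$gene]))
}

#' Read a threshold configuration from YAML
#'
#' Keys are the snake_case forms of [ThresholdConfig()] arguments
#' (`min_vaf`, `min_depth`, `min_tpm`, `max_median_rank`, `top_n`,
#' `min_spots`, `long_peptide_len`, `min_predictors`, `min_alt_reads`,
#' `cross_alpha`, `ctrl_sd_mult`); absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @export
readThresholdConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  thresholdConfigFromList(cfg)
}

## snake_case list -> ThresholdConfig (shared by YAML reader and runAll)
thresholdConfigFromList <- function(cfg) {
  map <- c(min_vaf = "minVaf", min_depth = "minDepth", min_tpm = "minTpm",
           max_median_rank = "maxMedianRank", top_n = "topN",
           min_spots = "minSpots", long_peptide_len = "longPeptideLen",
           min_predictors = "minPredictors", min_alt_reads = "minAltReads",
           cross_alpha = "crossAlpha", ctrl_sd_mult = "ctrlSdMult")
  bad <- setdiff(names(cfg), names(map))
  if (length(bad))
    stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
  do.call(ThresholdConfig, stats::setNames(cfg, map[names(cfg)]))
}

#' Read / write ELISPOT spot-count tables
#'
#' Long format with columns `mutation_id`, `arm` (`mut`, `wt` or `ctrl`),
#' `replicate`, `spots` and optionally `pool`.
#'
#' @param path TSV path.
#' @return data.frame in the same long format, validated.
#' @export
readElispot <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mutation_id", "arm", "replicate", "spots")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing ELISPOT column(s): ", paste(miss, collapse = ", "))
  badArm <- which(!df$arm %in% c("mut", "wt", "ctrl"))
  if (length(badArm))
    stop(sprintf("line %d: unknown arm '%s'", badArm[1L] + 1L,
                 df$arm[badArm[1L]]))
  bad <- which(is.na(df$spots) | df$spots < 0 | df$spots != round(df$spots))
  if (length(bad))
    stop(sprintf("line %d: spots must be a non-negative integer", bad[1L] + 1L))
  df$spots <- as.integer(df$spots)
  df
}

#' @rdname readElispot
#' @param elispot validated long-format data.frame.
#' @export
writeElispot <- function(elispot, path) {
  utils::write.table(elispot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write per-cell allele counts at mutation sites
#'
#' Long format with columns `cell`, `group`, `site_id`, `ref_reads`,
#' `alt_reads`; a cell covers a site when `ref_reads + alt_reads >= 1`.
#'
#' @param path TSV path.
#' @export
readCellCounts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell", "group", "site_id", "ref_reads", "alt_reads")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing cell-count column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$ref_reads < 0 | df$alt_reads < 0)
  if (length(bad))
    stop(sprintf("line %d: negative read count", bad[1L] + 1L))
  df
}

#' @rdname readCellCounts
#' @param counts validated long-format data.frame.
#' @export
writeCellCounts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a percentile-rank matrix
#'
#' Long TSV with columns `peptide`, `predictor`, `rank`; missing
#' (peptide, predictor) pairs become `NA` cells (unscored).
#'
#' @param path TSV path.
#' @return a [PredictorRankMatrix-class].
#' @export
readRankMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "predictor", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing rank-matrix column(s): ", paste(miss, collapse = ", "))
  peps <- unique(df$peptide)
  preds <- unique(df$predictor)
  m <- matrix(NA_real_, length(peps), length(preds),
              dimnames = list(peps, preds))
  m[cbind(match(df$peptide, peps), match(df$predictor, preds))] <- df$rank
  new("PredictorRankMatrix", ranks = m)
}

#' @rdname readRankMatrix
#' @param x a [PredictorRankMatrix-class].
#' @export
writeRankMatrix <- function(x, path) {
  stopifnot(is(x, "PredictorRankMatrix"))
  r <- x@ranks
  df <- data.frame(peptide = rep(rownames(r), times = ncol(r)),
                   predictor = rep(colnames(r), each = nrow(r)),
                   rank = as.vector(r))
  df <- df[!is.na(df$rank), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a dense log-expression matrix (genes x cells)
#'
#' TSV with first column `gene` and one column per cell; values are
#' normalized log-scale expression.
#'
#' @param path TSV path.
#' @return numeric matrix, genes in rows, cells in columns.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene") stop("first column must be 'gene'")
  if (anyDuplicated(df$gene)) stop("duplicate gene names")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  if (!all(is.finite(m))) stop("expression matrix must be finite")
  m
}

#' @rdname readExpressionMatrix
#' @param m genes x cells matrix with dimnames.
#' @export
writeExpressionMatrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
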