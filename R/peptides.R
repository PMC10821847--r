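.getProtein <- function(proteome, gene) {
  if (!gene %in% names(proteome))
    stop("gene not in proteome: ", gene)
  as.character(proteome[[gene]])
}

.checkReference <- function(seqchr, v) {
  L <- nchar(seqchr)
  if (v$protein_pos > L)
    stop(sprintf("position %d beyond end of %s (length %d)",
                 v$protein_pos, v$gene, L))
  found <- substr(seqchr, v$protein_pos, v$protein_pos)
  if (found != v$ref_aa)
    stop(sprintf("reference mismatch in %s at %d: expected %s, found %s",
                 v$gene, v$protein_pos, v$ref_aa, found))
}

.variantRow <- function(v) {
  ## accept a 1-row SomaticVariantSet or a plain list/row
  if (is(v, "SomaticVariantSet")) {
    stopifnot(nrow(v) == 1L)
    v <- as.list(as.data.frame(v))
  }
  v
}

#' Apply a missense mutation to its protein
#'
#' @param proteome a [Proteome-class].
#' @param v a single-row [SomaticVariantSet-class] (or a list with fields
#'   `gene`, `protein_pos`, `ref_aa`, `alt_aa`).
#' @return The mutant protein sequence (character scalar), differing from
#'   the wild type at exactly `protein_pos`.
#' @export
applyMutation <- function(proteome, v) {
  v <- .variantRow(v)
  wt <- .getProtein(proteome, v$gene)
  .checkReference(wt, v)
  mut <- wt
  substr(mut, v$protein_pos, v$protein_pos) <- v$alt_aa
  mut
}

.hasNonStandard <- function(pep) {
  !grepl(paste0("^[", paste(.AA20, collapse = ""), "]+$"), pep)
}

.peptideRow <- function(source_id, kind, form, start, end, mut_offset, seq) {
  data.frame(source_id = source_id, kind = kind, form = form,
             start = start, end = end, mut_offset = mut_offset,
             sequence = seq, stringsAsFactors = FALSE)
}

#' Design the mutant / wild-type long-peptide pair for synthesis
#'
#' The synthesis form is a `longPeptideLen`-residue (default 17) peptide
#' centered on the mutated residue, with `(len - 1) / 2` flanking residues
#' on each side. Near a terminus the window is truncated asymmetrically:
#' all available residues are kept on the short side and the other side is
#' never extended beyond its own flank, so the interval is
#' `[max(1, pos - flank), min(L, pos + flank)]`. The wild-type partner
#' covers the identical interval of the unmutated protein, so the pair
#' differs at exactly the mutated offset.
#'
#' @inheritParams applyMutation
#' @param cfg a [ThresholdConfig-class] (`longPeptideLen` is used).
#' @return data.frame with the mutant and wild-type rows (columns
#'   `source_id`, `kind`, `form`, `start`, `end`, `mut_offset`,
#'   `sequence`).
#' @export
designLongPeptide <- function(proteome, v, cfg = ThresholdConfig()) {
  v <- .variantRow(v)
  wt <- .getProtein(proteome, v$gene)
  .checkReference(wt, v)
  L <- nchar(wt)
  if (L < 8L) stop("protein shorter than 8 residues: ", v$gene)
  flank <- (cfg@longPeptideLen - 1L) %/% 2L
  start <- max(1L, v$protein_pos - flank)
  end <- min(L, v$protein_pos + flank)
  mut <- applyMutation(proteome, v)
  id <- formatMutationId(v$gene, v$ref_aa, v$protein_pos, v$alt_aa)
  mutSeq <- substr(mut, start, end)
  wtSeq <- substr(wt, start, end)
  if (.hasNonStandard(wtSeq) || .hasNonStandard(mutSeq)) {
    warning("long peptide for ", id,
            " contains non-standard residues; dropped")
    return(.peptideRow(character(), character(), character(), integer(),
                       integer(), integer(), character()))
  }
  off <- v$protein_pos - start + 1L
  rbind(.peptideRow(id, "mutant", "long", start, end, off, mutSeq),
        .peptideRow(id, "wildtype", "long", start, end, off, wtSeq))
}

#' Enumerate MHC-I epitope windows spanning a mutation
#'
#' For each preferred epitope length `k` of the allele, every `k`-mer
#' window of the mutant protein that contains the mutated position is
#' returned in left-to-right order. For length `k` and protein length `L`
#' the window count is
#' `min(pos, L - k + 1) - max(1, pos - k + 1) + 1` (fewer windows near a
#' terminus, never an error). Windows containing non-standard residues are
#' dropped with a warning, as they cannot be synthesized or scored.
#'
#' @inheritParams applyMutation
#' @param allele an [MhcAllele-class].
#' @return data.frame of short mutant candidates (columns as in
#'   [designLongPeptide()]).
#' @examples
#' prot <- Proteome(c(X = strrep("A", 20)))
#' v <- SomaticVariantSet("X", 10, "A", "C", 0.5, 30L, 5)
#' enumerateEpitopes(prot, v, MhcAllele("H-2-Kb", 8))
#' @export
enumerateEpitopes <- function(proteome, v, allele = MhcAllele()) {
  v <- .variantRow(v)
  wt <- .getProtein(proteome, v$gene)
  .checkReference(wt, v)
  mut <- applyMutation(proteome, v)
  L <- nchar(mut)
  pos <- v$protein_pos
  id <- formatMutationId(v$gene, v$ref_aa, v$protein_pos, v$alt_aa)
  out <- lapply(allele@preferredLengths, function(k) {
    lo <- max(1L, pos - k + 1L)
    hi <- min(pos, L - k + 1L)
    if (hi < lo) return(NULL)
    starts <- lo:hi
    .peptideRow(id, "mutant", "short", starts, starts + k - 1L,
                pos - starts + 1L,
                substring(mut, starts, starts + k - 1L))
  })
  out <- do.call(rbind, c(out, list(.peptideRow(character(), character(),
                                                character(), integer(),
                                                integer(), integer(),
                                                character()))))
  ns <- .hasNonStandard(out$sequence)
  if (any(ns)) {
    warning(sum(ns), " epitope window(s) of ", id,
            " contain non-standard residues; dropped")
    out <- out[!ns, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Build the full peptide table for a set of variants
#'
#' Long mutant/wild-type synthesis pairs plus all short epitope windows for
#' every variant, as one TSV-ready data.frame.
#'
#' @param variants a [SomaticVariantSet-class].
#' @inheritParams enumerateEpitopes
#' @inheritParams designLongPeptide
#' @export
buildPeptides <- function(variants, proteome, allele = MhcAllele(),
                          cfg = ThresholdConfig()) {
  stopifnot(is(variants, "SomaticVariantSet"))
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- as.list(as.data.frame(variants[i, ]))
    rbind(designLongPeptide(proteome, v, cfg),
          enumerateEpitopes(proteome, v, allele))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- .peptideRow(character(), character(), character(), integer(),
                       integer(), integer(), character())
  rownames(out) <- NULL
  npLog("peptides", "%d peptide(s) for %d variant(s)", nrow(out),
        nrow(variants))
  out
}

#' @rdname buildPeptides
#' @param peptides peptide table as returned by [buildPeptides()].
#' @param path output TSV path.
#' @export
writePeptides <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname buildPeptides
#' @export
readPeptides <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_id", "kind", "form", "start", "end", "mut_offset",
            "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing peptide column(s): ", paste(miss, collapse = ", "))
  df
}
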