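## Names of the eight published predictors the mock ensemble stands in for.
.MOCK_NAMES <- c("NetMHCpan", "NetMHC", "NetMHCcons", "PickPocket",
                 "MHCflurry", "SMM", "SMMPBMC", "MHCnuggetsI")

.residueIndex <- function(peptides, k) {
  idx <- match(unlist(strsplit(peptides, "", fixed = TRUE)), .AA20)
  if (anyNA(idx)) stop("non-standard residue in peptide")
  matrix(idx, ncol = k, byrow = TRUE)
}

.scoreMatrix <- function(w, peptides) {
  k <- nrow(w)
  im <- .residueIndex(peptides, k)
  sc <- numeric(length(peptides))
  for (j in seq_len(k)) sc <- sc + w[j, im[, j]]
  sc
}

#' Raw PSSM score of peptides under one mock predictor
#'
#' The raw score is the sum of position-specific weights over the
#' peptide's residues, plus a fixed bonus for sequences in the predictor's
#' planted strong-binder set. Deterministic; higher = stronger.
#'
#' @param p a [PssmPredictor-class].
#' @param peptides character vector; each length must be one the predictor
#'   supports.
#' @return numeric vector of raw scores.
#' @export
pssmScore <- function(p, peptides) {
  stopifnot(is(p, "PssmPredictor"))
  ks <- nchar(peptides)
  bad <- !as.character(ks) %in% names(p@weights)
  if (any(bad))
    stop(sprintf("predictor %s does not support peptide length %d",
                 p@name, ks[bad][1L]))
  out <- numeric(length(peptides))
  for (k in unique(ks)) {
    sel <- ks == k
    out[sel] <- .scoreMatrix(p@weights[[as.character(k)]], peptides[sel])
  }
  out + p@plantBonus * (peptides %in% p@planted)
}

#' Percentile rank of peptides under one mock predictor
#'
#' `rank = 100 * #\{background scores >= score\} / B`: the fraction of
#' background proteome peptides scoring at least as well, so lower means
#' stronger and ties count against the candidate. A peptide beating the
#' entire background gets rank 0.
#'
#' @inheritParams pssmScore
#' @return numeric vector of ranks in `[0, 100]`.
#' @export
percentileRank <- function(p, peptides) {
  sc <- pssmScore(p, peptides)
  ks <- as.character(nchar(peptides))
  out <- numeric(length(peptides))
  for (k in unique(ks)) {
    bg <- p@backgroundScores[[k]]
    if (length(bg) == 0L) stop("empty background for length ", k)
    sel <- ks == k
    nBelow <- findInterval(sc[sel], bg, left.open = TRUE)
    out[sel] <- 100 * (length(bg) - nBelow) / length(bg)
  }
  out
}

.sampleBackground <- function(proteome, k, B) {
  seqs <- as.character(proteome)
  avail <- nchar(seqs) - k + 1L
  seqs <- seqs[avail >= 1L]
  avail <- avail[avail >= 1L]
  if (!length(seqs)) stop("no protein long enough for ", k, "-mers")
  out <- character(0)
  while (length(out) < B) {
    n <- B - length(out)
    pi <- sample.int(length(seqs), n, replace = TRUE, prob = avail)
    st <- floor(stats::runif(n) * avail[pi]) + 1L
    pep <- substring(seqs[pi], st, st + k - 1L)
    out <- c(out, pep[!.hasNonStandard(pep)])
  }
  out[seq_len(B)]
}

.rebuildBackground <- function(p) {
  for (k in names(p@weights)) {
    sc <- .scoreMatrix(p@weights[[k]], p@backgroundPeptides[[k]])
    p@backgroundScores[[k]] <- sort(sc)
  }
  p
}

#' Build a mock predictor ensemble calibrated on a proteome background
#'
#' Creates `nPredictors` independent PSSM predictors (named after the
#' eight published algorithms, prefixed `"mock-"`), each with i.i.d.
#' standard-normal weight matrices per epitope length and a shared
#' background of `B` proteome k-mers for percentile calibration. Under
#' these predictors the rank of a random peptide is approximately uniform
#' on (0, 100], so an 8-predictor median rank almost never reaches the 2%
#' cutoff by chance; planted binders (see [plantBinder()]) do.
#'
#' @param proteome a [Proteome-class] supplying background peptides.
#' @param lengths epitope lengths to support.
#' @param B background size per length (>= 100; 10000 recommended).
#' @param nPredictors ensemble size (default 8).
#' @param seed integer; the ensemble is a pure function of
#'   `(seed, proteome)`.
#' @param allele allele name attached to each predictor.
#' @return a [PssmEnsemble-class].
#' @export
mockEnsemble <- function(proteome, lengths = c(8L, 9L), B = 10000L,
                         nPredictors = 8L, seed = 1L, allele = "H-2-Kb") {
  stopifnot(is(proteome, "Proteome"), B >= 100L)
  nm <- .MOCK_NAMES
  if (nPredictors > length(nm))
    nm <- c(nm, paste0("extra", seq_len(nPredictors - length(nm))))
  nm <- paste0("mock-", nm[seq_len(nPredictors)])
  lengths <- as.integer(lengths)
  withr::with_seed(seed, {
    bg <- lapply(lengths, function(k) .sampleBackground(proteome, k, B))
    names(bg) <- as.character(lengths)
    preds <- lapply(nm, function(name) {
      w <- lapply(lengths, function(k)
        matrix(stats::rnorm(k * 20L), nrow = k, ncol = 20L,
               dimnames = list(NULL, .AA20)))
      names(w) <- as.character(lengths)
      p <- new("PssmPredictor", name = name, allele = allele, weights = w,
               backgroundPeptides = bg,
               backgroundScores = lapply(bg, function(x) numeric(1)))
      .rebuildBackground(p)
    })
    new("PssmEnsemble", predictors = preds)
  })
}

#' Plant strong-binder epitopes into a mock ensemble
#'
#' Adds the given sequences to every predictor's planted set, so each
#' scores above the whole background and receives percentile rank ~0
#' under all predictors. Background calibration is untouched: planted
#' sequences are tumor-specific mutant peptides absent from the wild-type
#' proteome background.
#'
#' @param ensemble a [PssmEnsemble-class].
#' @param epitopes character vector of mutant epitope sequences whose
#'   lengths the ensemble supports.
#' @return the adjusted [PssmEnsemble-class].
#' @export
plantBinder <- function(ensemble, epitopes) {
  stopifnot(is(ensemble, "PssmEnsemble"))
  supported <- names(ensemble@predictors[[1L]]@weights)
  bad <- !as.character(nchar(epitopes)) %in% supported
  if (any(bad))
    stop("unsupported epitope length: ", nchar(epitopes[bad][1L]))
  ensemble@predictors <- lapply(ensemble@predictors, function(p) {
    p@planted <- union(p@planted, epitopes)
    p
  })
  ensemble
}

#' Score peptides with every predictor of an ensemble
#'
#' @param ensemble a [PssmEnsemble-class].
#' @param peptides character vector (duplicates collapsed).
#' @return a [PredictorRankMatrix-class] of percentile ranks.
#' @export
scoreEpitopes <- function(ensemble, peptides) {
  stopifnot(is(ensemble, "PssmEnsemble"))
  peptides <- unique(peptides)
  m <- vapply(ensemble@predictors,
              function(p) percentileRank(p, peptides),
              numeric(length(peptides)))
  if (length(peptides) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(peptides, predictorNames(ensemble))
  npLog("mock-rank", "scored %d peptide(s) x %d predictor(s)",
        nrow(m), ncol(m))
  new("PredictorRankMatrix", ranks = m)
}

#' Per-peptide median percentile rank
#'
#' The median of a peptide's available predictor ranks (mean of the two
#' central values for an even count). Peptides scored by fewer than
#' `minPredictors` predictors (default 4 of 8) are flagged unscored and
#' carry `NA`.
#'
#' @param peptides character vector of peptide sequences.
#' @param ranks a [PredictorRankMatrix-class].
#' @param cfg a [ThresholdConfig-class] (`minPredictors` is used).
#' @return data.frame with columns `peptide`, `median_rank`,
#'   `n_predictors`, `scored`.
#' @export
peptideMedians <- function(peptides, ranks, cfg = ThresholdConfig()) {
  stopifnot(is(ranks, "PredictorRankMatrix"))
  peptides <- unique(peptides)
  r <- ranks@ranks
  hit <- match(peptides, rownames(r))
  med <- rep(NA_real_, length(peptides))
  n <- integer(length(peptides))
  ok <- !is.na(hit)
  if (any(ok)) {
    sub <- r[hit[ok], , drop = FALSE]
    n[ok] <- rowSums(!is.na(sub))
    med[ok] <- apply(sub, 1L, stats::median, na.rm = TRUE)
  }
  scored <- n >= cfg@minPredictors
  med[!scored] <- NA_real_
  data.frame(peptide = peptides, median_rank = med, n_predictors = n,
             scored = scored, stringsAsFactors = FALSE)
}

#' Median-rank consensus per mutation
#'
#' For every mutation, takes the minimum over its short mutant epitope
#' windows of the per-peptide median predictor rank (the best-epitope
#' convention), and classifies the mutation as a predicted binder when
#' that best median is at or below `maxMedianRank` (inclusive, default
#' 2%). Mutations with no scored peptide are flagged unscored, excluded
#' from the pass set, and reported with a warning.
#'
#' @param variants a [SomaticVariantSet-class] (the filter-passing set).
#' @param peptides peptide table from [buildPeptides()]; only rows with
#'   `form == "short"` and `kind == "mutant"` are used.
#' @param ranks a [PredictorRankMatrix-class].
#' @param cfg a [ThresholdConfig-class].
#' @return data.frame with one row per mutation: `mutation_id`,
#'   `best_peptide`, `best_median_rank`, `n_peptides`, `n_scored`,
#'   `unscored`, `passes`. Ties for the best peptide break to the
#'   lexicographically smallest sequence.
#' @export
consensusRank <- function(variants, peptides, ranks,
                          cfg = ThresholdConfig()) {
  stopifnot(is(variants, "SomaticVariantSet"))
  short <- peptides[peptides$form == "short" & peptides$kind == "mutant", ,
                    drop = FALSE]
  med <- peptideMedians(short$sequence, ranks, cfg)
  short$median_rank <- med$median_rank[match(short$sequence, med$peptide)]
  ids <- variantIds(variants)
  rows <- lapply(ids, function(id) {
    pp <- short[short$source_id == id, , drop = FALSE]
    sc <- pp[!is.na(pp$median_rank), , drop = FALSE]
    if (nrow(sc) == 0L)
      return(data.frame(mutation_id = id, best_peptide = NA_character_,
                        best_median_rank = NA_real_,
                        n_peptides = nrow(pp), n_scored = 0L,
                        unscored = TRUE, passes = FALSE,
                        stringsAsFactors = FALSE))
    best <- min(sc$median_rank)
    cand <- sort(sc$sequence[sc$median_rank == best])[1L]
    data.frame(mutation_id = id, best_peptide = cand,
               best_median_rank = best, n_peptides = nrow(pp),
               n_scored = nrow(sc), unscored = FALSE,
               passes = best <= cfg@maxMedianRank, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$unscored))
    warning(sum(out$unscored), " mutation(s) had no scored peptide: ",
            paste(utils::head(out$mutation_id[out$unscored], 5L),
                  collapse = ", "))
  npLog("consensus", "%d/%d mutation(s) pass median rank <= %g%%",
        sum(out$passes), nrow(out), cfg@maxMedianRank)
  out
}

#' Prioritize predicted binders
#'
#' Passing mutations sorted by ascending best median rank, with ties
#' broken by descending TPM, then descending VAF, then lexicographic id;
#' the first `min(topN, n_passing)` are returned.
#'
#' @param consensus output of [consensusRank()].
#' @param variants the [SomaticVariantSet-class] carrying `tpm` and `vaf`.
#' @param cfg a [ThresholdConfig-class] (`topN` is used).
#' @return data.frame of the prioritized mutations with a 1-based
#'   `priority` column.
#' @export
prioritize <- function(consensus, variants, cfg = ThresholdConfig()) {
  pass <- consensus[consensus$passes, , drop = FALSE]
  i <- match(pass$mutation_id, variantIds(variants))
  if (anyNA(i))
    stop("consensus mutation(s) missing from variant set: ",
         paste(pass$mutation_id[is.na(i)], collapse = ", "))
  pass$tpm <- variants$tpm[i]
  pass$vaf <- variants$vaf[i]
  ord <- order(pass$best_median_rank, -pass$tpm, -pass$vaf,
               pass$mutation_id, method = "radix")
  top <- pass[ord, , drop = FALSE][seq_len(min(cfg@topN, nrow(pass))), ,
                                   drop = FALSE]
  top$priority <- seq_len(nrow(top))
  rownames(top) <- NULL
  npLog("prioritize", "top %d of %d passing mutation(s)", nrow(top),
        nrow(pass))
  top
}
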