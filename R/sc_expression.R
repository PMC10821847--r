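#' Binned-control gene-signature score per cell
#'
#' The module-score construction used throughout single-cell work: genes
#' are binned into `nBins` strata by their mean expression across cells;
#' for each signature gene, `nCtrl` control genes are drawn from its
#' stratum (with replacement when the stratum is small); the score of a
#' cell is its mean signature expression minus its mean expression over
#' the pooled control draw. Expression is expected on a normalized log
#' scale. Deterministic given `seed`; adding a constant to every gene
#' leaves scores unchanged.
#'
#' @param expr genes x cells numeric matrix of log-scale expression with
#'   dimnames.
#' @param signature character vector of signature genes; all must be rows
#'   of `expr`.
#' @param nBins number of expression strata (default 25).
#' @param nCtrl control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draw.
#' @return named numeric vector of per-cell scores.
#' @export
signatureScore <- function(expr, signature, nBins = 25L, nCtrl = 100L,
                           seed = 1L) {
  stopifnot(is.matrix(expr), nBins >= 2L)
  miss <- setdiff(signature, rownames(expr))
  if (length(miss))
    stop("signature gene(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  geneMeans <- rowMeans(expr)
  nBins <- min(as.integer(nBins), nrow(expr))
  bin <- cut(rank(geneMeans, ties.method = "first"), breaks = nBins,
             labels = FALSE)
  names(bin) <- rownames(expr)
  ## controls come from the matching expression stratum but never from the
  ## signature itself, so a planted signature shift is not diluted
  ctrlPool <- withr::with_seed(seed, {
    unlist(lapply(signature, function(g) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], signature)
      if (length(pool) == 0L)
        pool <- setdiff(names(bin), signature)
      if (length(pool) == 0L)
        stop("no non-signature genes available as controls")
      sample(pool, nCtrl, replace = length(pool) < nCtrl)
    }), use.names = FALSE)
  })
  sigMean <- colMeans(expr[signature, , drop = FALSE])
  ctrlMean <- colMeans(expr[ctrlPool, , drop = FALSE])
  sigMean - ctrlMean
}

#' Proportion of tumor cells with a detected mutant allele
#'
#' Per treatment group, the denominator is the tumor cells covering at
#' least one of the given mutation sites (`ref + alt >= 1` read); the
#' numerator is those with at least `minAlt` mutant-supporting reads at
#' one or more of the sites. Cells outside `tumorCells`, and reads at
#' sites not listed, are ignored. Groups with an empty denominator are
#' reported with proportion `NA`.
#'
#' @param counts long-format per-cell allele counts (see
#'   [readCellCounts()]).
#' @param sites character vector of mutation site ids to pool.
#' @param tumorCells character vector of tumor cell ids.
#' @param minAlt reads required to call the mutant allele detected
#'   (default 1).
#' @return data.frame per group: `covered`, `mutant`, `proportion`.
#' @export
mutantCellProportion <- function(counts, sites, tumorCells,
                                 minAlt = 1L) {
  stopifnot(length(sites) > 0L)
  sub <- counts[counts$site_id %in% sites &
                counts$cell %in% tumorCells &
                (counts$ref_reads + counts$alt_reads) >= 1L, , drop = FALSE]
  groupOf <- unique(counts[, c("cell", "group")])
  if (anyDuplicated(groupOf$cell))
    stop("cell(s) assigned to more than one group")
  covered <- unique(sub$cell)
  altBy <- tapply(sub$alt_reads, sub$cell, max)
  mutant <- names(altBy)[altBy >= minAlt]
  groups <- unique(counts$group)
  rows <- lapply(groups, function(g) {
    cellsG <- groupOf$cell[groupOf$group == g]
    nCov <- sum(covered %in% cellsG)
    nMut <- sum(mutant %in% cellsG)
    data.frame(group = g, covered = nCov, mutant = nMut,
               proportion = if (nCov > 0L) nMut / nCov else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  npLog("sc-mutprop", "%s",
        paste(sprintf("%s %d/%d", out$group, out$mutant, out$covered),
              collapse = "; "))
  out
}

.fisher2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2L)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(p = 1, degenerate = TRUE))
  list(p = stats::fisher.test(tab)$p.value, degenerate = FALSE)
}

#' Compare per-group mutant-cell proportions against a reference group
#'
#' Each non-reference group is compared to the reference by a two-sided
#' Fisher exact test (or chi-square) on the 2x2 table of mutant vs
#' non-mutant covered cells. Degenerate tables (a zero margin) are
#' reported as p = 1 with a flag.
#'
#' @param proportions output of [mutantCellProportion()].
#' @param reference reference group label (e.g. `"PBS"`).
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return data.frame per non-reference group with the test p-value and a
#'   `degenerate` flag.
#' @export
compareProportions <- function(proportions, reference = "PBS",
                               method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (!reference %in% proportions$group)
    stop("reference group not present: ", reference)
  if (nrow(proportions) < 2L) stop("need >= 2 groups")
  ref <- proportions[proportions$group == reference, ]
  others <- proportions[proportions$group != reference, , drop = FALSE]
  rows <- lapply(seq_len(nrow(others)), function(i) {
    g <- others[i, ]
    if (method == "fisher") {
      ft <- .fisher2x2(g$mutant, g$covered - g$mutant,
                       ref$mutant, ref$covered - ref$mutant)
      p <- ft$p; degen <- ft$degenerate
    } else {
      tab <- matrix(c(g$mutant, g$covered - g$mutant,
                      ref$mutant, ref$covered - ref$mutant), nrow = 2L)
      degen <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
      p <- if (degen) 1
           else suppressWarnings(stats::chisq.test(tab)$p.value)
    }
    data.frame(group = g$group, reference = reference,
               proportion = g$proportion,
               reference_proportion = ref$proportion, p_value = p,
               degenerate = degen, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare per-cell signature scores against a reference group
#'
#' Two-sided Wilcoxon rank-sum (default) or Welch t-test of each
#' non-reference group's scores against the reference group's.
#'
#' @param scores named numeric vector of per-cell scores.
#' @param groups character vector of group labels, parallel to `scores`.
#' @param reference reference group label.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return data.frame per non-reference group: group summaries (mean, SD,
#'   n) and the test p-value; the reference summary is attached as the
#'   first row with p `NA`.
#' @export
compareScores <- function(scores, groups, reference = "PBS",
                          method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  stopifnot(length(scores) == length(groups))
  if (!reference %in% groups) stop("reference group not present: ", reference)
  if (length(unique(groups)) < 2L) stop("need >= 2 groups")
  refScores <- scores[groups == reference]
  summ <- function(g, x, p) data.frame(group = g, mean = mean(x),
                                       sd = stats::sd(x), n = length(x),
                                       p_value = p, stringsAsFactors = FALSE)
  rows <- list(summ(reference, refScores, NA_real_))
  for (g in setdiff(unique(groups), reference)) {
    x <- scores[groups == g]
    p <- if (method == "wilcoxon")
      suppressWarnings(stats::wilcox.test(x, refScores)$p.value)
    else stats::t.test(x, refScores)$p.value
    rows <- c(rows, list(summ(g, x, p)))
  }
  do.call(rbind, rows)
}
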