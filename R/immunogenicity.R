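.armMatrix <- function(elispot, arm) {
  sub <- elispot[elispot$arm == arm, , drop = FALSE]
  split(sub$spots, sub$mutation_id)
}

#' Select immunogenic peptides from ELISPOT counts
#'
#' A peptide is selected when its mean spot count under mutant-peptide
#' stimulation strictly exceeds `minSpots` (default 100): a mean of
#' exactly 100 is not selected.
#'
#' @param elispot long-format ELISPOT table (see [readElispot()]).
#' @param cfg a [ThresholdConfig-class] (`minSpots` is used).
#' @return data.frame with columns `mutation_id`, `mut_mean`, `n_rep`,
#'   `selected`, ordered as first seen in the table.
#' @export
selectImmunogenic <- function(elispot, cfg = ThresholdConfig()) {
  mut <- .armMatrix(elispot, "mut")
  ids <- unique(elispot$mutation_id[elispot$arm == "mut"])
  mm <- vapply(mut[ids], mean, numeric(1))
  out <- data.frame(mutation_id = ids, mut_mean = unname(mm),
                    n_rep = unname(lengths(mut[ids])),
                    selected = unname(mm) > cfg@minSpots,
                    stringsAsFactors = FALSE)
  npLog("elispot", "%d/%d peptide(s) selected (mean spots > %g)",
        sum(out$selected), nrow(out), cfg@minSpots)
  out
}

.welch <- function(x, y) {
  out <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(out)) list(statistic = NA_real_, p.value = NA_real_)
  else list(statistic = unname(out$statistic), p.value = out$p.value)
}

#' Mutant-vs-wild-type cross-reactivity assessment
#'
#' Operationalizes "no significant immunogenic cross-reactivity": a
#' peptide is flagged cross-reactive when the wild-type arm itself clears
#' the selection cutoff (`wt_mean > minSpots`), or when the mutant and
#' wild-type responses are statistically indistinguishable (two-sided
#' Welch t-test, p >= `crossAlpha`) while the wild-type response rises
#' above the negative-control level (`wt_mean > ctrl_mean +
#' ctrlSdMult * ctrl_sd`). Peptides without a wild-type arm are flagged
#' `not assessed`. The verdict does not depend on replicate order.
#'
#' @inheritParams selectImmunogenic
#' @return data.frame per mutation id: `mut_mean`, `wt_mean`,
#'   `ctrl_mean`, `ratio` (`wt_mean / mut_mean`; 0 with a flag when both
#'   arms are all-zero), `t_statistic`, `p_value`, `cross_reactive`,
#'   `assessed`, `flag`.
#' @export
crossReactivity <- function(elispot, cfg = ThresholdConfig()) {
  mut <- .armMatrix(elispot, "mut")
  wt <- .armMatrix(elispot, "wt")
  ctrl <- .armMatrix(elispot, "ctrl")
  ids <- unique(elispot$mutation_id[elispot$arm == "mut"])
  rows <- lapply(ids, function(id) {
    m <- mut[[id]]
    w <- wt[[id]]
    cc <- ctrl[[id]]
    base <- data.frame(mutation_id = id, mut_mean = mean(m),
                       wt_mean = NA_real_,
                       ctrl_mean = if (length(cc)) mean(cc) else NA_real_,
                       ratio = NA_real_, t_statistic = NA_real_,
                       p_value = NA_real_, cross_reactive = NA,
                       assessed = FALSE, flag = "", stringsAsFactors = FALSE)
    if (is.null(w) || length(w) < 2L || length(m) < 2L) {
      base$flag <- "not assessed"
      return(base)
    }
    base$assessed <- TRUE
    base$wt_mean <- mean(w)
    if (base$mut_mean == 0 && base$wt_mean == 0) {
      base$ratio <- 0
      base$flag <- "both arms zero"
    } else {
      base$ratio <- base$wt_mean / base$mut_mean
    }
    tt <- .welch(m, w)
    base$t_statistic <- tt$statistic
    base$p_value <- tt$p.value
    ## no control arm: the control guard cannot exonerate, so it holds
    ctrlGuard <- if (length(cc))
      base$wt_mean > mean(cc) + cfg@ctrlSdMult * stats::sd(cc)
    else TRUE
    nonSig <- is.na(tt$p.value) || tt$p.value >= cfg@crossAlpha
    base$cross_reactive <- (base$wt_mean > cfg@minSpots) ||
      (nonSig && ctrlGuard)
    base
  })
  do.call(rbind, rows)
}
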