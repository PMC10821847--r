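AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomProteome <- function(n, lenMin = 60, lenMax = 120, seed = 1) {
  withr::with_seed(seed, {
    lens <- sample(lenMin:lenMax, n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
    names(seqs) <- sprintf("G%03d", seq_len(n))
    Proteome(seqs)
  })
}

## one random valid variant per listed gene of a proteome
randomVariants <- function(proteome, genes = names(proteome), seed = 1) {
  withr::with_seed(seed, {
    seqs <- as.character(proteome[genes])
    pos <- vapply(nchar(seqs), function(L) sample.int(L, 1L), integer(1))
    ref <- substring(seqs, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1L),
                  character(1), USE.NAMES = FALSE)
    SomaticVariantSet(genes, pos, ref, alt,
                      vaf = round(runif(length(genes)), 3),
                      depth = sample(5:100, length(genes), replace = TRUE),
                      tpm = round(rlnorm(length(genes), 1, 1.5), 3))
  })
}

## brute-force oracle: all k-mer windows of seq containing position pos
bruteWindows <- function(seq, pos, k) {
  L <- nchar(seq)
  starts <- seq_len(max(L - k + 1L, 0L))
  starts <- starts[starts <= pos & pos <= starts + k - 1L]
  if (length(starts) == 0L) return(character())
  substring(seq, starts, starts + k - 1L)
}

## tiny study configuration reused across simulator/pipeline tests
tinySimConfig <- function(seed = 7) {
  simConfig(seed = seed, nGenes = 80, nVariants = 50, nExpressed = 25,
            nBinders = 10, nTop = 6, nSynthesized = 5, nImmunogenic = 3,
            backgroundSize = 500, scCellsPerGroup = 60, scNGenes = 40,
            proteinLenMin = 60L, proteinLenMax = 150L)
}

## long-format ELISPOT table from per-id replicate lists
elispotTable <- function(mut, wt = NULL, ctrl = NULL) {
  rows <- list()
  add <- function(lst, arm) {
    for (id in names(lst))
      rows[[length(rows) + 1L]] <<- data.frame(
        mutation_id = id, arm = arm,
        replicate = seq_along(lst[[id]]), spots = as.integer(lst[[id]]),
        stringsAsFactors = FALSE)
  }
  add(mut, "mut")
  if (!is.null(wt)) add(wt, "wt")
  if (!is.null(ctrl)) add(ctrl, "ctrl")
  do.call(rbind, rows)
}
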