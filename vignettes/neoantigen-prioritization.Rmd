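---
title: "Neoantigen prioritization: models, parameters and design choices"
author: "neoprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The screening problem

A tumor-specific missense mutation is a vaccine candidate only if it
clears a chain of increasingly biological hurdles: the mutant allele
must actually be expressed, some peptide window around the mutated
residue must be presented on MHC class I, the synthesized long peptide
must elicit a T-cell response, and that response must not cross-react
with the wild-type protein. neoprior implements this funnel for the
mouse H-2-Kb setting (LLC tumors in C57BL/6 mice) and any analogous
single-allele design, together with the downstream single-cell readouts
that ask whether vaccination actually depletes the tumor cells that
express the targeted mutations.

This vignette documents the models and the choices behind them. It
states no number that the test suite or `scripts/acceptance.R` does not
itself compute.

# Expression-aware filtering

A variant passes when `vaf >= 0.10`, `depth >= 20` and
`tpm >= 1`, all three read as inclusive comparisons. The thresholds
live in a single `ThresholdConfig` object consumed by every stage, so
there is one source of truth for the funnel. Two deliberate choices:

* **Every rule is evaluated for every variant.** The per-variant report
  lists all failed rules rather than short-circuiting, because the
  report is the primary diagnostic when a funnel looks wrong.
* **Missing expression fails the expression rule.** A variant whose
  gene is absent from the TPM table is rejected with failed rule `tpm`
  and a warning. The filter demands positive evidence of expression;
  absence of evidence is not a pass.

VAF is treated as a given per-variant number; whether it was derived
from DNA or RNA reads is upstream of this package.

# Peptide design

Protein positions are 1-based throughout, matching the `W204C`
notation, and windows are closed intervals. The synthesis form is a
17-residue peptide centered on the mutation (flank = 8 on each side).
Near a terminus the window is truncated *asymmetrically*: the short
side keeps whatever residues exist and the long side never extends
beyond its own flank of 8, i.e. the interval is
`[max(1, pos - 8), min(L, pos + 8)]`. The alternative — recentering to
always reach 17 residues — was rejected because it changes the local
context presented to the immune system for no biological reason; the
truncated window preserves the maximal *natural* flanking context.

Epitope windows are every k-mer containing the mutated position, for k
in the allele's preferred lengths. H-2-Kb defaults to `c(8, 9)` since
Kb canonically presents 8–9-mers (the validated tetramer epitope in
this setting is an 8-mer); the length set is configurable up to 11.
For protein length L the window count for length k is
`min(pos, L - k + 1) - max(1, pos - k + 1) + 1`, which the tests verify
against a brute-force substring scan. Peptides containing non-standard
residues (X, U) are dropped with a warning: they can be neither
synthesized nor scored.

# Percentile-rank consensus

External predictors communicate only through a long TSV of
`(peptide, predictor, rank)` rows, with ranks on the percentile scale:
the percentage of background peptides scoring at least as well, lower =
stronger. This makes heterogeneous tools commensurable and keeps the
package free of external binaries.

The built-in mock ensemble consists of eight position-scoring-matrix
predictors (named after the eight published algorithms, prefixed
`mock-`), each with i.i.d. standard-normal weights per supported length
and a shared background of B proteome k-mers. The rank of a peptide is
`100 * #{background >= score} / B`; ties count *against* the candidate,
the conservative reading. With B = 10,000 the rank of a random peptide
is uniform on (0, 100] to within sampling error (checked by a
Kolmogorov–Smirnov test), so the median over eight independent
predictors essentially never reaches 2% by chance — which is what makes
exact planted-set recovery a meaningful test.

**Planting strong binders.** `plantBinder()` adds chosen epitopes to
each predictor's memorized strong-binder set; a planted sequence
receives a fixed score bonus that beats the entire background, hence
rank 0 under every predictor. An earlier design that boosted the
weight-matrix cells of the epitope's residues was discarded: with tens
of planted epitopes, chimeric background peptides can combine boosted
cells from different epitopes and outscore the planted ones, so exact
recovery is not guaranteed. The memorized-set formulation mimics how
real predictors behave on genuinely strong binders while keeping the
background calibration untouched (planted mutant peptides are absent
from the wild-type proteome by construction).

**Aggregation.** Per peptide, the median of available predictor ranks
(mean of the two central values for even counts); per mutation, the
minimum over its windows — the standard best-epitope convention. The 2%
cutoff is inclusive. Peptides scored by fewer than `minPredictors`
(default 4 of 8) predictors are flagged unscored rather than given a
fragile median; mutations with no scored peptide are excluded from the
pass set with a warning. Prioritization sorts passing mutations by best
median rank, breaking ties by descending TPM (better-expressed targets
first), then descending VAF, then id for determinism.

# ELISPOT selection and cross-reactivity

Selection is per peptide on the *mean* spot count across replicates,
strictly greater than 100 — a mean of exactly 100 is excluded. Raw
counts are used; negative-control counts are reported alongside rather
than subtracted, since the published cutoff is stated on raw spot
numbers. Cross-reactivity is a compound rule: a peptide is flagged when
the wild-type arm itself clears the selection cutoff, or when a
two-sided Welch t-test cannot distinguish the arms (p ≥ 0.05) *and* the
wild-type mean rises above control mean + 3 SD. Both guards are
configurable. A missing wild-type arm yields "not assessed", never a
silent pass.

# Single-cell quantification

**Signature score.** The per-cell enrichment of the parent genes of the
vaccine mutations is the binned-control module score: genes are binned
into 25 strata by mean expression, 100 control genes are drawn per
signature gene from its stratum (seeded, with replacement when the
stratum is small), and the score is signature mean − control mean on
log-scale expression. The published analysis names no method, so this
conventional construction was chosen; bin count and control count are
exposed. One deliberate deviation from some implementations: control
genes are drawn from the stratum *excluding the signature itself*.
Including signature genes among their own controls shrinks a planted
shift by roughly the signature's share of its bins, which both blunts
the test-suite's planted-effect oracle and biases real scores toward
zero in small panels.

**Mutant-cell proportion.** Per treatment group, the denominator is
tumor cells covering (ref + alt ≥ 1 read) at least one of the queried
mutation sites and the numerator is those with ≥ 1 mutant-supporting
read at ≥ 1 site — per-cell pooling across sites, following the
"cells with read covering at least one of these sites" inclusion rule.
The detection threshold (`minAltReads = 1`) is configurable. Tumor-cell
identity is an input label; deriving it (CNV inference, clustering) is
out of scope. Groups are compared against a reference (default PBS) by
a two-sided Fisher exact test on the 2×2 mutant × group table, and
signature scores by a two-sided Wilcoxon rank-sum test. The published
figures do not name their tests, so both are package decisions and both
have configurable alternatives (chi-square, Welch t); reproducing the
paper-reported p-values exactly is not a correctness criterion.
Degenerate tables (a zero margin) report p = 1 with a flag.

# The synthetic study

`simulateStudy()` generates every input with planted truth and is a
pure function of its `SimConfig`; identical seeds give byte-identical
bundles. Defaults encode the study-shaped funnel
762 → 224 → 60 → 20 → 16 → 7 together with marginals a sequencing
practitioner would call realistic:

* VAF ~ Beta(2, 8), depth ~ NegBin(mean 60, size 5), TPM ~
  LogNormal(meanlog 1, sdlog 1.5). Funnel membership is planted by
  truncated sampling: a variant destined to pass draws each quantity
  from the distribution conditioned above its threshold; a failing
  variant draws a uniformly chosen non-empty subset of rules from below.
  The truth JSON records the exact failed-rule set per variant, making
  the generator a complete oracle for the filter.
* Proteins are i.i.d. uniform over the 20 residues — no codon or
  composition model, which is sufficient for peptide-window arithmetic
  and background calibration, and is the main respect in which the
  synthetic data are easier than real proteomes (no low-complexity
  regions, no shared domains, essentially no repeated k-mers).
* ELISPOT counts are negative-binomial (size 10) with means 300
  (immunogenic) and 20 (non-immunogenic) straddling the 100-spot
  cutoff; replicate sets are redrawn in the rare case a mean lands on
  the wrong side, so the planted labels are exact truth.
* Single-cell coverage: each cell covers each of the 3 detectable sites
  with probability 0.45 (so ~83% of cells cover ≥ 1 site), with
  per-site depth 1 + Poisson(0.7) — sparse, as 3' scRNA-seq mutation
  detection really is. Group mutant fractions default to 0.30 (PBS),
  0.15, 0.15, 0.05 (combined), and the parent-gene signature is shifted
  by +1, +0.5, +0.5, 0 log-units respectively, a vaccination effect
  large enough to be detected at a few hundred cells per group.

Passing tests on this bundle therefore demonstrates correct funnel
logic, calibration and recovery machinery — not that the pipeline would
reproduce the published counts from raw sequencing data, which depend
on the study's own reads and assays.

# Numerical and degenerate-input conventions

* All thresholds are inclusive except the ELISPOT `> 100`, which the
  source states as "more than".
* Background rank ties count against the candidate (rank uses `>=`).
* Best-peptide ties resolve to the lexicographically smallest sequence;
  prioritization ties resolve TPM → VAF → id. Everything downstream of
  a seed is deterministic, including control-gene draws.
* Empty inputs produce empty, well-typed outputs; malformed rows fail
  with line-numbered errors; a reference-residue mismatch between a
  variant and its protein names the gene, position, expected and found
  residues.
* The orchestrator (`runAll()`) checks that the funnel counts are
  non-increasing across stages and aborts naming the failing stage,
  writing a partial manifest with input/output checksums.

# Problem sizes

The shipped tests exercise the oracles at sizes chosen to make the
statistics meaningful while keeping the suite quick on a laptop: 1,000
variants for the filter oracle, 500 random (L, pos, k) triples for
window enumeration, B = 10,000 backgrounds with 1,000 query peptides
for rank calibration, 200 mutations with 30 planted binders for
consensus recovery, the full 762-variant bundle for the end-to-end
funnel, ~500 covered cells per group for the single-cell recovery, and
1,000 label permutations for the Wilcoxon type-I check.

# Known limitations

* One protein per gene; isoforms, indels and frameshifts are not
  modeled (all seven validated vaccine targets in the motivating
  setting are single-residue substitutions).
* The mock ensemble is a calibration device, not a binding model: its
  ranks carry no peptide chemistry. Real prioritization should feed
  genuine predictor output through the rank-matrix interface.
* No proteasomal-cleavage, TAP-transport or MHC-II modeling.
* Cross-reactivity is assessed per peptide against its own wild-type
  arm; pool deconvolution designs are out of scope.
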