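---
title: "Methods: HS epitope inference and glycotyping"
author: "HSglycotyper authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HSglycotyper)
```

# Overview

HSglycotyper covers four connected computations around scFv-based
heparan sulfate (HS) profiling: (i) a digital coding system for HS
chains and its translation into a pseudo-amino-acid alphabet, (ii)
IC50-weighted inference of the HS epitope an scFv binds, as a position
weight matrix (PWM), (iii) glycotype analytics on mean-fluorescence-
intensity (MFI) tables, and (iv) gene-signature scores used to connect
sorted fractions to lineage identity. This vignette is the package's
account of each method, its assumptions, and the choices made where the
underlying conventions were genuinely open.

# The quintuplet code and the pseudo-amino-acid alphabet

An HS disaccharide has five modifiable sites: the hexuronic acid's
epimer state (GlcA vs IdoA) and 2-*O*-sulfation, and the glucosamine's
N-position state (N-acetyl, N-sulfate, or free amine), 3-*O*-sulfation
and 6-*O*-sulfation. The package writes each disaccharide as an
11-digit string with one dedicated digit per site and constant
structural digits elsewhere:

| digit | meaning | values |
|---|---|---|
| 1 | uronic ring marker | `1` (constant) |
| 2 | epimer | `1` GlcA, `2` IdoA |
| 3 | 2-*O*-sulfation | `0`/`1` |
| 4 | reserved | `0` (constant) |
| 5 | linkage marker | `4` (constant) |
| 6 | glucosamine ring marker | `2` (constant) |
| 7 | N-state | `0` NH2, `1` NAc, `2` NS |
| 8 | 3-*O*-sulfation | `0`/`1` |
| 9 | reserved | `0` (constant) |
| 10 | 6-*O*-sulfation | `0`/`1` |
| 11 | linkage marker | `4` (constant) |

The authoritative digit semantics of the published coding system are
not restated in full anywhere machine-readable, so this layout is a
documented stand-in: it preserves the defining properties (11 digits
per disaccharide, five independent variable fields, 48 = 2·3·2·2·2
distinct states, concatenation for chains) and is defined in exactly
one place (`R/hs-code.R`) so the digit assignment can be reconciled
with the published convention without touching any caller. Encoding
and decoding are exact inverses over all 48 states, which the test
suite checks exhaustively.

Because at most 48 disaccharide types exist and real panels use far
fewer, the distinct types occurring in a dataset (at most 20) are
mapped bijectively onto the standard 20-letter amino-acid alphabet.
Letters are assigned in lexicographic order of the code strings, so the
map depends only on the *set* of types, not on input order — a
determinism requirement for reproducible alignments. Oligos then become
short "pseudo-protein" sequences that standard alignment machinery can
process.

A small human-readable dialect (`IdoA2S-GlcNS6S-...`, en dash
accepted) is parsed by a strict grammar; unknown tokens are errors,
never guesses, because silent misparsing of a sugar token would corrupt
every downstream count.

# IC50-weighted epitope inference

The input is a panel of HS oligosaccharides of defined sequence with
competitive-ELISA IC50 values (μg/ml of oligo that half-inhibits scFv
binding to heparin; lower = stronger epitope match). The procedure:

1. **Weighting.** Each oligo enters the multiple sequence file
   `max(1, round(reference / IC50))` times, with `reference = 100` by
   default (IC50 25 → 4 copies, IC50 1 → 100 copies). Rounding is
   half-away-from-zero; the two canonical worked examples are exact
   under any rounding, so the choice only matters at halves. The floor
   of one copy keeps weak but measured oligos represented — the
   alternative (dropping oligos with IC50 above the reference) would
   silently change the alphabet; whether non-inhibiting oligos should
   instead be excluded entirely is not settled, so inclusion at floor
   weight is the package's documented default.
2. **Alignment.** Pseudo-sequences are aligned by a progressive star
   alignment over affine-gap Needleman–Wunsch (match +1, mismatch −1,
   gap open −2, gap extend −1, a gap of length L costing
   `open + (L−1)·extend`). The center sequence maximizes the summed
   pairwise score (ties to first input); others are merged under "once
   a gap, always a gap". Tie-breaks in the traceback are fixed
   (match, then gap in the second sequence, then in the first), so the
   output is fully deterministic. For a dozen sequences of 4–10
   letters any sensible progressive scheme gives equivalent column
   structure; a `gapless` mode stacks equal-length panels without
   aligning. The pairwise scores are verified in the tests against
   both an exhaustive enumeration oracle and an independent
   Biostrings alignment with the same scoring.
3. **PWM.** Column letter frequencies are copy-weighted counts over
   the column's non-gap mass, exactly equal (oracle-tested) to naive
   counting over the physically copy-expanded sequence multiset.
   Information content per column is `I_j = log2(K) − H_j` in bits,
   with `K` the alphabet size of the dataset's map. Gap handling
   follows the common logo convention of normalizing over non-gap
   mass, with the gap fraction reported separately; all-gap columns
   carry zero frequency and information and are flagged rather than
   erroring, since they legitimately arise at alignment edges. The
   small-sample entropy correction `e_n = (K−1)/(2·ln2·n)` is
   implemented but off by default (logo tools differ on whether they
   apply it, and at 100+ weighted copies it is negligible anyway);
   when on, corrected information is clamped at zero.
4. **Back-translation.** Letters are replaced by their 11-digit codes;
   frequencies and information are untouched, and logo heights are
   `frequency × column information`, so heights per column sum to the
   column's information.

`scoreOligo()` provides the matching direction: the best ungapped
window sum of `log2(p / (1/K))` with probabilities floored at a
pseudocount of `1e-3` (≈ −8.6 bits per absent letter at K = 20 — harsh
enough to dominate, finite enough to compare). It exists for the
synthetic IC50 model and recovery tests, not as a calibrated binding
predictor.

# Glycotype analytics

`MFIExperiment` wraps a `SummarizedExperiment` (rows = scFvs, columns =
population × replicate samples). Conventions, each isolated in one
function:

* **Summaries** are arithmetic replicate mean ± sample SD (n−1);
  single replicates get SD 0 and a flag. A geometric-mean option
  exists for log-distributed MFIs.
* **Percentiles** (`mfiPercentile`) use average ranks with endpoints
  0 and 100 (`(rank−1)/(n−1)·100`), making heatmaps invariant to any
  strictly increasing intensity transform. "Average percentile" can
  mean percentiles computed per replicate and then averaged, or
  percentiles of replicate means; both paths are provided and
  per-replicate is the default.
* **Control handling.** The negative-control scFv (default label
  `MPB49`, an antibody with no known HS epitope) can be subtracted
  (clamped at zero, clamp count recorded in metadata) or divided out;
  neither is applied by default because the control is conventionally
  used as a visual reference rather than a normalizer.
* **Gates** (`gateHighLow`) sort descending, label the top
  `round(fHigh·n)` cells high and bottom `round(fLow·n)` low
  (half-away-from-zero; if rounding makes the two gates overlap, the
  low gate yields), with ties broken by stable input order — on
  continuous fluorescence values ties are measure-zero, so this only
  matters for degenerate inputs. Defaults are the 50/50 fractionation;
  35–45% gates are expressed through the fraction arguments.
* **Distributions** divide each scFv's per-population mean by its sum
  over the listed populations (rows sum to 1); all-zero profiles are
  NA with a warning.
* **Dissimilarity** is Euclidean or correlation (1 − Pearson) distance
  with average-linkage clustering, both deterministic.

# Signature scores

* The preranked statistic is `−log10(p_adj) · sign(log2FC)`. The
  logarithm base is 10; since preranked GSEA is rank-driven, base only
  rescales. p-values below `1e-300` are clamped and flagged;
  non-positive p-values are a domain error unless clamping is enabled
  explicitly.
* Signatures are the top-N (default 20) up- and downregulated genes,
  with cutoff ties broken lexicographically so selection is
  row-order-free.
* The module score divides each cell's expression by that cell's mean
  housekeeping expression and takes `mean(up) − mean(down)`. Several
  combination rules are defensible here; this
  mean-difference form is the simplest one that is linear in each set
  and exactly invariant to per-cell scaling, and it lives in a single
  function. An optional `zscale` flag standardizes scores across cells
  for display on embeddings; the core statistic is unscaled.
* qPCR uses the Pfaffl efficiency-corrected ratio
  `E_t^ΔCt_t / E_r^ΔCt_r`, efficiencies in (1, 2], with ΔCt oriented
  `Ct(control) − Ct(sample)` (stated explicitly because the
  orientation flips the ratio's direction). At E = 2 it reduces to
  `2^ΔΔCt`, which the tests check.

# The synthetic-data generators

Every input has a seeded generator whose defaults mirror the scale of
the real experiments: 12 oligos of 4–10 disaccharides, a planted
epitope of 4 units, a 12-type disaccharide pool; 8 HS scFvs plus one
control, 6 populations, 3 replicates; 1,000-cell bimodal intensity
mixtures; 200-cell expression matrices with 20 + 20 planted signature
genes, 160 background genes and 5 housekeeping genes.

Choices worth stating:

* **Panel realism.** Carrier probability defaults to 1 and per-site
  corruption to 0, because real panels consist of oligos of *defined*
  sequence — measurement noise belongs to the IC50, not the chemistry.
  Both are parameters for stress tests.
* **Score→IC50 link.** An invention for testing only: the oligo's
  match score against the planted PWM is mapped through a decreasing
  affine-logistic link onto [1, 100] μg/ml, multiplied by lognormal
  noise `exp(σZ)` (σ = 0.25 by default, a plausible inter-assay spread
  for ELISA-derived IC50s), and clamped to [0.5, 200]. With σ = 0 the
  link is strictly antitone, so rank information is preserved exactly.
* **Cell mixtures** are two-component lognormals (default meanlogs
  log 100 and log 1000, sdlog 0.4, weights ½/½) — well separated, as
  a sortable bimodal channel is in practice.
* **Expression** is lognormal with symmetric ±`effect/2` log2 shifts
  for planted genes; the DE table is *computed from the simulated
  matrix* (per-gene Welch t-tests on log2 values, BH adjustment), so
  its p-values and fold-changes are consistent with the planted truth
  by construction rather than by decree.

What the generators do **not** emulate: spectral spillover and
compensation, autofluorescence, acquisition-time drift, doublets,
scRNA-seq count sparsity and dropout, or correlated gene modules.
Passing tests on synthetic data therefore demonstrate the correctness
and calibration of the *computations*, not robustness to every
artifact of real cytometry or sequencing data.

# Verification strategy and problem sizes

The test suite favors oracle equivalence over spot values: PWMs are
checked against literal copy-expansion counting (200 random instances
of ≤ 6 sequences × ≤ 8 columns), pairwise alignments against an
exhaustive recursion and against an independent aligner, summaries and
distance matrices against naive loops, and the codec exhaustively over
all 48 states. End-to-end, 12-oligo panels are run through panel →
IC50 → weighted MSF → PWM: with σ = 0 the planted consensus is
recovered at every epitope column in each of 20 seeds; with σ = 0.25
the average per-column recovery across 20 seeds must stay ≥ 80%. Null
calibration of the module score uses 40 zero-effect simulations at 50
cells per group. These sizes keep the full suite under half a minute
on one core while leaving each stochastic check enough replicates to
be meaningful.

# Known limitations

* The 11-digit layout is a stand-in pending reconciliation with the
  published coding reference; only the layout table above would change.
* Star alignment is a heuristic; for large, gappy panels a full
  progressive tree (or external ClustalW) could place gaps differently.
  At panel scale (~12 short sequences) this is immaterial.
* `scoreOligo` is a log-odds convenience, not a binding model; IC50
  prediction from structure is out of scope.
* No FCS parsing, compensation, or scatter gating: the package starts
  from exported MFI values and per-cell channel intensities.
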