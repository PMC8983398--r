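---
title: "Methods: longitudinal clonotype tracking and repertoire profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal clonotype tracking and repertoire profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrackr)
```

`clonotrackr` analyses longitudinal paired single-cell gene-expression + VDJ
data from one or more individuals. This vignette documents the model and the
procedure, the parameters that matter, the numerical conventions, the design
decisions taken where a choice was genuinely open, and what the packaged
simulator does and does not emulate.

## Clonotype identity

All cross-time-point matching, subtraction, and counting rests on one
definition: the **clonotype key**, the lexicographically sorted concatenation
of `chain:v_gene:j_gene:cdr3` components over a cell's *productive* chains.
The key is a pure function of the chain set — input order never matters — and
several schemes are exposed through `build_clonotype_keys()`:

- `paired_nt` (default): paired chains, CDR3 at nucleotide resolution. This
  is the strictest reading of "cells sharing the same VDJ sequence" and the
  vendor default, so it is the default here; it minimises false merging of
  convergent clonotypes.
- `paired_aa`: CDR3 at amino-acid resolution (more permissive, groups
  nucleotide variants encoding the same junction).
- `single_chain:<CHAIN>`: chain-level keys, used for chain-resolved analyses
  such as heavy-chain overlap ratios and isotype composition.

Two conventions matter for correctness. First, when a cell carries several
productive contigs of the same chain, the contig with the highest UMI count
wins, ties broken by the lexicographically smallest `cdr3_nt` — fully
deterministic. Second, a cell with only one recovered chain keeps a
*single-chain* key and is flagged `partial`; since a partial key can never
equal a full paired key, chain dropout cannot manufacture false persistence.
Barcode suffixes (`-1` etc.) are stripped on both sides of the GEX/VDJ join
because upstream tools emit them inconsistently.

## Persistence, subtraction, and post-vaccination classes

For each individual, a clonotype's `k` is the number of distinct time points
with at least one carrying cell. `k = 1` defines a *sporadic* ("unique")
clonotype, `k ≥ 2` a *sustained* ("overlapped") one. These are pure set
operations, and the test suite holds them equal to an independent brute-force
oracle on hundreds of random cohorts.

Around vaccination, the **baseline** is the union of clonotype keys over all
pre-dose samples of the individual; for a second vaccination study the whole
repertoire observed during the earlier study is additionally unioned into the
subtraction chain. `subtract_baseline()` removes every cell whose key is in
that union and asserts, on every call, that the remaining key set is disjoint
from it. `classify_post_vaccination()` partitions post-dose clonotypes into
`ovl_pre` (seen pre-dose — this takes precedence regardless of post-series
recurrence), `not_pre_unique` (one post time point), and `not_pre_ovl_k`
(k ≥ 2 post time points).

## Dynamic clonotypes

No standard rule exists for calling a clonotype "increased" or "decreased"
over a time course, so the package implements a fully parameterised
fold-change rule and echoes the parameters in every output. Frequencies are
computed among keyed cells of the clonotype's receptor class (TCR or BCR) so
that calls are invariant to sequencing depth. With first observation at t₀:

- **increased**: max frequency at any later time point ≥ `fold` × frequency
  at t₀, and peak absolute count ≥ `min_cells`;
- **decreased**: frequency at t₀ ≥ `fold` × the minimum later frequency
  (drops to zero count qualify), and the t₀ count ≥ `min_cells`.

Defaults are `fold = 2`, `min_cells = 3`; single-time-point clonotypes are
excluded. A clonotype can satisfy both rules (a dip followed by a surge); the
spec of the result requires disjoint sets, so such a clonotype is assigned to
the direction with the larger fold magnitude, a drop to zero (infinite fold)
outranking any finite rise and an exact tie going to `increased`. The
`min_cells` support threshold is the one deliberate departure from pure scale
invariance: it suppresses calls driven by one or two cells.

"Vaccination-responsive" clonotypes are the `not_pre` clonotypes seen at at
least `t_min` time points; `t_min = 3` by default, read as k ≥ 3, with a
`strict` option for k > 3 since "more than three time points" is ambiguous in
common usage.

## Diversity and usage

The Shannon index is computed on clonotype frequencies in natural log, with
no pseudocount and no rarefaction: H = −Σ pᵢ ln pᵢ. Raw H confounds richness
with evenness, so H/ln(n) is reported alongside. Because diversity is often
compared across samples of different depth, a seeded fixed-depth resampling
mode is available but off by default — entropy on the full sample is the
primary statistic, and resampling is a comparability device, not a
correction. BCR diversity is conventionally chain-resolved; heavy-chain
(single-chain IGH) keys are the documented choice for it, with paired keys
available through the same interface.

V-gene usage rows are frequencies among productive contigs of one chain, with
the cohort-wide union of observed segments as a fixed, zero-filled column
set. Isotype composition classifies IGH cells by C gene within each
persistence group, counting contigs without a C call as `unassigned` so rows
still sum to 1.

## Composition statistics

QC filtering uses the standard strict gate `n_features > 200`,
`n_features < 4000`, `percent_mt < 8`; boundary values are excluded and the
per-criterion removal counts are reported. Group comparison of per-sample
cell-type proportions uses the Welch (unequal-variance) t test — the safer
default when only "t test" is specified — two-sided, with Benjamini–Hochberg
adjustment across the family of cell types tested together; the family
boundary is always one call. Unpaired comparison is the default, with
`paired = TRUE` exposed for matched time-point designs. Degenerate inputs are
defined rather than erroring: two identical constant groups give t = 0,
p = 1; distinct constant groups give p = 0.

Marker-expression comparisons use the two-sided Wilcoxon rank-sum test on
per-cell log-normalised expression (counts scaled to 10,000 per cell, then
log1p — the conventional normalization of the surrounding toolchain), with
BH adjustment across genes tested together.

Fresh-versus-frozen concordance correlates per-cell-type pseudobulk profiles
(log1p of mean raw counts) between conditions, per gene across cell types.
Genes below r = 0.6 (configurable; no published criterion exists for this
threshold) are flagged, as are *degenerate* genes whose profile is constant
in either condition — a silenced gene has no defined correlation but is
certainly discordant. Identical profiles get r = 1 by convention.

## The cohort simulator

`simulate_cohort()` generates the statistical structure the analysis assumes,
with planted ground truth for recovery testing. Its defaults are the study
conditions the package documents:

- **Composition**: per-sample Dirichlet draws with concentration
  `alpha × baseline` (default α = 400, a realistic sample-to-sample
  wobble of a few percentage points). The default baseline puts lymphocytes
  at 77% and monocytes at 18% — inside the 70–90% and 10–20% ranges typical
  of healthy adult PBMC — and the within-T subtype weights give a CD4:CD8
  ratio near 2:1.
- **Clone sizes**: discrete power law P(s) ∝ s^(−γ) truncated at
  `cells_per_sample`, γ = 2.5 by default — the standard heavy-tailed
  repertoire assumption, under which the top clonotypes claim only a small
  share of cells.
- **Persistence**: each individual owns a persistent clone pool (default 35%
  of repertoire cells) with memory/effector phenotypes; each pool clone
  re-emits its drawn size at every time point, so planted persistence is
  exact and persistent trajectories are flat. Naive ("sporadic") clonotypes
  are drawn fresh per time point with globally collision-checked CDR3
  sequences of 10–18 in-frame sense codons, so sporadic ground truth can
  never collide with planted clones.
- **Vaccination**: at dose days the monocyte component of the expected
  composition is multiplied by `monocyte_fold` before renormalization
  (expected monocyte fraction f·b/(1 + (f−1)·b)); induced clonotypes are new
  T clonotypes emitting `induced_base_cells × multiplier(t)` cells along the
  induction trajectory — zero before the first dose, rising after dose 1 and
  boosted after dose 2 by default.
- **Markers**: negative-binomial counts for a 10-gene PBMC marker panel with
  per-cell-type means; CD69 is elevated (mean 4 versus 0.5) in cells of
  induced clonotypes, making activation-marker comparisons testable.
- **Dropout**: each T/B cell loses its whole VDJ record with probability
  `dropout_rate_vdj` (default 0.15, per cell rather than per chain); a small
  rate of non-productive extra contigs exercises productive filtering.

Everything is reproducible from `seed` (the simulator runs inside an isolated
RNG scope), and the planted truth records persistent and induced keys,
expected per-sample compositions, and the Dirichlet-drawn V-gene usage
weights.

What the simulator does **not** emulate: sequence-level VDJ recombination
biology (no junctional indels, no allelic structure), somatic hypermutation
and B-cell lineage structure, transcriptome-wide expression, doublets and
ambient contamination, and convergent recombination (identical CDR3s arising
independently — deliberately excluded so ground truth is exact). Passing the
recovery tests therefore shows the *procedures* are correct under the assumed
statistical structure, not that real repertoires satisfy that structure;
on real data, convergent recombination and chain dropout will blur the
sporadic/sustained boundary in ways the partial-key flag only partly
mitigates.

## Problem sizes and numerical conventions

The test-suite and acceptance scales were chosen as the smallest sizes at
which the probabilistic assertions have comfortable margins: oracle
equivalence on 200 random cohorts of ≤ 200 cells and ≤ 6 time points;
subtraction soundness fuzzed over 1000 cohorts; recovery on a 2000-cell,
5-time-point vaccination cohort with 50 induced clonotypes rising 5×;
composition calibration over 200 replicates of 8-vs-8 samples; power-law
fidelity on one 5000-cell, dropout-free sample (dropout thins clone sizes
and would bias the truncated-zeta MLE, so generator fidelity is measured
without it). Ties anywhere a ranking is produced are broken deterministically
(count, then earlier first observation, then key). Composition rows are
normalised exactly; all row-sum invariants are asserted at 1e-9.

In the statistical-calibration check, one truly different cell type among
five is constructed with a sixth "filler" type absorbing the compositional
shift: proportions are compositional, so without the filler, raising one
type would mechanically depress all others and no type would be truly null.
Under BH with one strong effect the per-null-type rejection rate is at or
below the nominal 5% (FDR control is conservative for nulls), so the
calibration test bounds the null rate from above only.

## Known limitations

- Clonotype matching fields and CDR3 resolution vary across studies; results
  are comparable only within one keying scheme, which is why baseline key
  sets carry scheme metadata and subtraction refuses mismatched schemes.
- The dynamic-call rule is descriptive, not a statistical test; it reports
  no error rates and its counts depend on `fold` and `min_cells`, which is
  why both parameters are echoed in every output table.
- Entropy comparisons across samples of very different keyed-cell depth
  should use the seeded resampling mode; raw H is depth-sensitive through
  richness.
- The pipeline consumes cell-type labels; annotation quality is upstream of
  everything reported per cell type.
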