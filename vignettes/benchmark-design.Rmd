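---
title: "Benchmark design and methods"
author: "hydroxybench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model behind `hydroxybench`, the parameters that
matter, the numerical conventions, and the design decisions that were
genuinely open — the information a maintainer needs to judge whether a
result of the pipeline means what it appears to mean.

## The evaluation model

The unit of everything is the **site window**: `W` residues centred on a
candidate proline, over the 20 canonical one-letter codes plus the gap
character `-`. Gaps play two roles: they substitute non-canonical letters
(B, Z, J, U, O, X, ...) and they pad windows whose proline lies within
`(W-1)/2` residues of a sequence end. The centre character is never a gap.
`W` defaults to 13 and is deliberately a parameter, not a constant:
published hydroxylation predictors use context windows up to 21 residues,
and the benchmark must be able to match any of them.

Assessment is **site-centric**: every candidate proline is an independent
example, even when several lie on the same protein. This is the convention
under which the six metrics (Sn, Sp, WACC, F1, PREC, MCC) are computed from
the confusion counts of each replica.

The central threat this benchmark design addresses is **homology leakage**:
two windows that are near-copies of each other must never end up as a
positive and an evaluation negative. Hence the pipeline clusters *all*
candidate sites — positives and negatives together — by window similarity,
and removes every negative that shares a cluster with at least one positive.

## Similarity, distance, clustering

Window similarity is the columnwise BLOSUM62 sum. Because windows are
pre-aligned by construction (same length, centred), there is no alignment
search; the only subtlety is gap accounting. A **gap run** is a maximal
stretch of columns in which at least one of the two windows has a gap; the
run costs `gapOpen + (len - 1) * gapExtend` (defaults −5 and −1) once,
jointly for both windows, and its columns are excluded from the substitution
sum. The joint-run reading is the minimal affine interpretation for
pre-aligned windows; charging each window's runs separately would double the
penalty whenever both windows are terminal, without changing any ordering
the pipeline relies on.

Scores become distances by affine negation, `d = S_max − s`, with `S_max`
the maximum score over all pairs including self-pairs. A reciprocal
transform is not usable here: BLOSUM sums are frequently zero or negative.
Negation keeps every distance non-negative and inverts the similarity
ranking exactly (rank correlation −1), which is all a hierarchical
clustering consumes. One consequence worth knowing: distances are relative
to the dataset through `S_max`, so cut heights are comparable only within
one distance matrix.

Clustering is UPGMA (average linkage), implemented in the package rather
than delegated to `stats::hclust`, for one reason: **deterministic
tie-breaking**. BLOSUM sums are integers, so tied merge heights are common,
and `hclust` does not document which tied pair it merges first. Here, among
all pairs within `1e-9` of the minimal inter-cluster distance, the pair
with the lexicographically smallest (min representative, max
representative) is merged, where a cluster's representative is the smallest
original site index it contains. The tolerance absorbs floating-point noise
from the Lance–Williams update (exact ties differ only at ~1e-16 between
update orders; genuinely distinct average distances on integer matrices are
at least `1/(n_i n_j)` apart). The test suite checks exact agreement with a
brute-force average-linkage oracle on random instances, and with
`hclust(method = "average")` on tie-free (jittered) matrices.

The **cut height** is the one clustering parameter with no canonical value:
the clustering protocol this package implements does not come with a
published threshold. The default,
`cutHeight = S_max − 0.7 · median(self scores)`, is calibrated so that
windows sharing roughly 70% of their self-similarity co-cluster — tight
enough that collagen repeat windows from different proteins merge (they are
the near-duplicates the negative filter exists for), loose enough that
unrelated motif families stay apart. The height actually used is stored in
the clustering object, in `split_summary.tsv` provenance and in
`resolved_config.yaml`; treat it as a reportable setting, never as a hidden
constant. Flat clusters join merges with height `<= cutHeight`, so a cut at
exactly 0 still unifies identical windows.

## Splits and replicas

Positives are partitioned by evidence source: `Literature` (curated
single-protein experiments), `MS-HeLa` and `MS-Kim` (the two
mass-spectrometry surveys), `MS` their deduplicated union, and each split
crossed with the per-protein collagen flag. The non-collagen complements
(`Literature-noncollagen`, `MS-noncollagen`) are emitted in addition to the
canonical seven because signalling-type sites are the scientifically hard
case: collagen sites in MS data are "new but easy", and a memorizing
predictor is expected to recognize them, so the novel-motif phenomenon is
measured on `MS-noncollagen`.

The confidence filter (default 0.8) applies to MS-HeLa positives — the
antibody-enriched experiment with per-site score probabilities — and drops
sub-threshold positives from *every* split; a dropped site does not become
a negative, since it was observed modified, just not confidently enough.
Whether the same filter should also cover MS-Kim is genuinely unclear from
the protocol it emulates; it is exposed as `filterKimToo` and off by
default.

Every split shares the single filtered negative pool. Each of the
`nReplicas = 1000` replicas draws `floor(frac · P)` positives
(`frac = 0.7`) and the same number of negatives, both without replacement;
negatives are re-drawn independently for every replica. `floor` rather than
`round` keeps the draw conservative and within the pool for any `P`.
Replica `r` uses a seed derived from `(master, r)`, so any single replica is
reproducible without regenerating the rest. Error bars are sample (n−1)
standard deviations over replicas.

Annotation conflicts (the same site labelled positive by one source and
negative by another) are resolved at assembly time, not at load time: a
site is positive if any retained row says so, and belongs to each split
whose source reports it (so a site seen by both MS experiments counts once
in `MS`).

## Metrics conventions

All 0/0 ratios are reported as 0: precision with no positive calls, MCC
with a zero denominator. This keeps replica aggregation total and preserves
the reading that a worse-than-random predictor has *negative* MCC rather
than propagating NaNs. Consensus votes are strict majorities; a tie is a
negative call, consistent with using the consensus to suppress false
positives. ROC/PR curves sweep the unique score values with ties grouped;
the ROC area uses the trapezoid rule; an all-identical score vector yields
a single-point curve reported as AUC 0.5 with a warning.

## The profile baseline

One positional profile per positive cluster (a cluster with at least one
positive member), built from **all** member windows, negatives included —
mirroring the fact that negatives inside positive clusters are excluded
from the pool but still describe the motif neighbourhood. Columns count 21
symbols; the gap is a first-class emission, because padding position is
informative for sequence-terminal sites. Counts are smoothed with
`pseudocount × background` and converted to log2 odds against the proteome
residue composition (gap background 0.01). The pseudocount default is 0.02:
profiles must stay sharp enough that a single-seed profile scores its own
seed far into the null tail, which is what makes the baseline's calls
insensitive to the exact E-value threshold.

Full profile HMMs with insert/delete states would add nothing here —
windows are fixed-length and pre-aligned, so a positional score matrix
carries identical information; the scan contract (window in, E-value and
call out) is backend-agnostic if an external profile-HMM engine is ever
plugged in.

E-values are `databaseSize × P_null(score ≥ s)`, with the null fitted as a
Gumbel (location/scale by method of moments) on the pooled scores of
`nNull = 10000` background-sampled windows against every profile. The
Gumbel's exponential tail is heavier than the near-normal pooled score
distribution, which makes the E-values deliberately conservative: a typical
random window's best hit lands at E of order the database size, while seed
members land many orders of magnitude below 1. The decision threshold
(default E ≤ 1.0, permissive because 13-column sites are short) therefore
barely moves the calls when swept down to 10⁻³. This calibration is a
modelling choice of this package; an external profile-search tool's
E-values would not match it numerically, only qualitatively.

The baseline's purpose is bounded: its training sites overlap the
evaluation positives by construction, so it is an upper limit for predictor
performance and a demonstration that filtered negatives are separable from
positives — not a usable predictor for new sites.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical label structure* of a
hydroxylation benchmark:

- collagen-like proteins as `(X-Y-Gly)` triplet repeats (so the repeat
  reads ...X-Pro-Gly... with the hydroxylation-prone position directly
  before the glycine), X a proline with probability 0.28 and Y with 0.38 —
  the observed rates in collagen motifs — and Y-prolines true positives
  with probability 0.85;
- non-proline X/Y residues drawn from a narrow alanine-dominated pool, so
  repeat windows from different proteins are mutual near-duplicates and
  collapse into few clusters, as real collagen sites do;
- non-collagen proteins of background composition carrying two 6-residue
  signalling motifs in disorder-marked intervals: an "old" motif whose
  positives are tagged `Literature`, and a "novel" motif tagged as MS —
  this tag–motif linkage is what lets a training/evaluation experiment
  expose memorization;
- source mixtures that put collagen positives preferentially in
  `Literature` (0.5/0.15/0.35 across Literature/HeLa/Kim), per-site
  confidence scores (Beta-distributed, HeLa lowest), and an overall
  positive-proline prevalence targeted at ~10% (the configuration is
  rejected with a diagnostic if its analytic expectation strays more than
  0.05 from the target);
- **annotation incompleteness** `h`: each true positive is independently
  re-labelled negative with probability `h` in the emitted annotations; the
  unthinned truth goes to a separate manifest that the pipeline never
  reads, so tests can measure how many "false positives" of a correct
  predictor are actually unlabeled positives.

It does *not* emulate mass-spectrometry physics (digestion, spectra,
peptide-level detectability), real collagen domain architecture, or
phylogenetic correlation between proteins. Consequently, green tests on
synthetic data certify the machinery — filtering, resampling, metric
arithmetic, the memorization/generalization contrast — not the absolute
performance any real predictor would achieve on real proteomes.

The simulated predictor calls a site with probability
`λ · 1[memorized] + (1−λ) · g · 1[motif present]`, then flips the call with
noise `ε`. "Memorized" means the window's best similarity to any
training-positive window is at least `τ` — defined *relative* to the
window's self-score (`max score / self score ≥ τ`, default 0.9) rather than
on the raw score scale, because terminal padded windows have small
self-scores and an absolute threshold would make a predictor fail to
recognize its own training window. With the relative form, λ = 1, ε = 0 on
seen data gives sensitivity exactly 1 for every window, padded or not.

## Problem sizes and runtime choices

The default benchmark is 12 collagen + 150 non-collagen proteins, roughly
3,000 candidate prolines and 300 positives — large enough that the MS split
yields balanced replicas above 100 sites (where the random baseline's WACC
concentrates tightly around 0.5) and that clustering ~3,000 windows, the
quadratic step, completes in well under a minute. Null calibration uses
10,000 background windows; 1,000 replicas per split follow the evaluation
protocol. These sizes are the package's chosen study conditions and are all
configurable through `runConfig()`.

## Known limitations

- The dendrogram cut height is a calibrated default, not a recovered value;
  different cuts change cluster granularity, hence the negative pool and
  the profile count. It is always recorded in outputs.
- E-values are internally calibrated and comparable only within one
  database; they are not exchangeable with any external search tool's.
- The generator's two-motif design makes "novel" binary; real novelty is
  graded, and a predictor could partially generalize in ways this simulator
  cannot express.
- No significance testing between predictors is provided; the evaluation
  reports mean ± sd over replicas only.
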