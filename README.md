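# hydroxybench

Homology-aware benchmarking of post-translational modification (PTM) site
predictors, with proline hydroxylation (Hyp) as the model system.

PTM predictors are routinely published with high self-reported accuracy, yet
their ability to find *new* modification sites is rarely checked by an
independent party. Proline hydroxylation makes the failure mode easy to see:
collagen sites follow the stereotyped (Gly-X-Y)n triple-helix repeat and are
easy to recognize, while signalling sites (HIF1α-type oxygen-sensing targets)
are sparse, motif-specific and concentrated in intrinsically disordered
regions. A model that has effectively memorized its training windows looks
excellent on training-era data and collapses to random on novel motifs.

`hydroxybench` provides the full evaluation machinery needed to measure this,
for experimentalists' tool choices and for predictor developers' sanity
checks:

- **Site windows** — every candidate proline is represented as a fixed-length
  window (default W = 13) centred on the proline; gaps (`-`) substitute
  non-canonical residues and pad windows at sequence ends.
- **Window similarity** — `s(a, b) = Σ_i B62(a_i, b_i)` summed over aligned
  columns (BLOSUM62), with an affine penalty per gap run (−5 open, −1
  extend). Distances are `d = S_max − s`, and sites are clustered with UPGMA
  (average linkage).
- **Homology-aware negative filtering** — negatives falling in a cluster
  that contains any hydroxylated proline are removed, so evaluation
  negatives are never near-duplicates of known positives.
- **Balanced replica evaluation** — each of 1,000 replicas draws
  `floor(0.7 · P)` positives and the same number of negatives (negatives
  re-drawn per replica). Site-centric confusion counts give Sn, Sp,
  WACC = (Sn + Sp)/2, F1, PREC and MCC, reported as mean ± sd over replicas,
  plus PR/ROC curves for score-bearing predictors.
- **Baselines** — a Bernoulli(0.5) random baseline, a strict-majority
  consensus, and a cluster-seeded positional-profile scanner (one 21-symbol
  log-odds profile per positive cluster, E-value calibrated against a Gumbel
  null) that serves as an upper bound because its training sites overlap the
  evaluation set.
- **Dataset characterization** — positional residue frequencies around the
  modified proline, per-site feature content (disorder, secondary structure,
  low complexity, proline fraction), and sites-per-protein densities.
- **Synthetic benchmark generator** — collagen-like repeat proteins with
  hydroxylation concentrated at Y-position prolines, non-collagen proteins
  with motif-borne sites in disorder-marked intervals, ~10% positive-proline
  prevalence, per-site confidence scores, configurable annotation
  incompleteness, and simulated predictors with a tunable
  memorization/generalization trade-off.

## Worked example

```r
library(hydroxybench)

st <- runPipeline("demo_out", runConfig(nReplicas = 200L, seed = 3L))
#> simulate: 162 proteins, 3113 candidate prolines, 299 positives
#> build-dataset: 3113 site windows of width 13 (0 rejected rows)
#> cluster: 2856 clusters at cut height 45.00
#> replicas: 4 x 200 replicas (Literature, MS, MS-collagen, MS-noncollagen);
#>   40 negatives removed
#> evaluate: 16 predictor x split combinations
#> baseline-profile: 188 profiles, calibrated on 10000 null windows
#> characterize: residue frequencies, site content, site density

m <- st$metrics
m[m$metric == "MCC" & m$split %in% c("Literature", "MS-noncollagen"),
  c("method", "split", "mean", "sd")]
#>          method          split    mean     sd
#>          random     Literature  0.0179 0.0539
#>       memorizer     Literature  0.9595 0.0166
#>     generalizer     Literature  0.7224 0.0277
#>       consensus     Literature  0.8675 0.0209
#>   naive-profile     Literature  0.7725 0.0341
#>          random MS-noncollagen  0.0301 0.0728
#>       memorizer MS-noncollagen -0.0928 0.0611
#>     generalizer MS-noncollagen  0.0230 0.0797
#>       consensus MS-noncollagen -0.0202 0.0759
#>   naive-profile MS-noncollagen  0.7717 0.0503
```

Reading the output: the *memorizer* (a simulated predictor that only
recognizes windows nearly identical to its training positives) scores
MCC ≈ 0.96 on the training-era `Literature` split and ≈ 0 on the
novel-motif `MS-noncollagen` split — high self-reported performance, random
on new sites. The *random* baseline sits at MCC ≈ 0 and WACC ≈ 0.5
everywhere; the *consensus* follows the method average; and the
*naive-profile* baseline, whose seeds overlap the evaluation positives by
construction, stays high on both splits — an upper bound, not a usable
predictor.

Every output directory also contains `resolved_config.yaml` (the exact
configuration and seed that produced it), split manifests, the profile
database, and the characterization tables.

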