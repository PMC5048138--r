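---
title: "Predicting phosphothreonine sites from sequence, structure and physicochemical context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phosphothreonine sites from sequence, structure and physicochemical context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosT)
```

## The problem

Phosphorylation of threonine is among the most common protein
post-translational modifications. Given a threonine in a protein, phosT
asks: does its local context look like the context of experimentally
confirmed phosphothreonines? The unit of analysis is a 31-residue window
centered on the candidate threonine, with signed offsets −15…+15 (center
= 0). Each window carries its residues, a 3-state secondary-structure
string (H helix, E strand, C coil) and per-residue solvent accessibility.
Positions beyond a protein terminus are padded with `X`, which every
encoder treats as neutral.

## The model

### Position conservation

For a set of windows, the residue distribution at offset $l$ is summarized
by its relative entropy against a uniform background $p_0 = 0.05$:

$$M(l) = \sum_{i=1}^{20} f_i(l)\, \log_2 \frac{f_i(l)}{p_0},$$

where $f_i(l)$ is the frequency of residue $i$ at offset $l$ (padding `X`
is excluded from numerator and denominator). $M(l) = 0$ exactly when the
column is background-distributed; a single-residue column attains
$\log_2 20 \approx 4.32$ bits. Phosphothreonine contexts show elevated
$M(l)$ relative to non-phosphorylated threonine contexts, most strongly
immediately downstream of the center (+1), where proline is heavily
enriched.

### PWM difference scoring (feature group F1)

Positive and negative window sets each yield a position weight matrix of
log-odds weights. With residue counts $n_{xl}$, column totals $N_l$,
pseudocount weight $\alpha$ and background $p_0$:

$$w(x, l) = \log_2 \frac{n_{xl} + \alpha\, p_0 N_l}
{\left(N_l + \alpha N_l \sum_x p_0\right) p_0}.$$

A background-distributed column has all-zero weights at $\alpha = 0$; the
default $\alpha = 1$ keeps every weight finite on sparse training sets (a
few hundred windows cannot populate all 20 × 31 cells). A query window is
scored per offset by the difference of the two matrices at its observed
residue:

$$F(l) = w_{\mathrm{pos}}(x_l, l) - w_{\mathrm{neg}}(x_l, l),$$

the central threonine excluded and `X` scoring 0. $F$ is evaluated
per window (not as a class-level profile) because only a per-window score
yields per-sample features; training on label-swapped classes negates $F$
exactly.

### Feature groups and window sizes

Four groups are encoded, each over its own even window size $w$ ($w/2$
flanking residues per side, center excluded):

| group | content | values per offset | default $w$ | dims |
|---|---|---|---|---|
| F1 | PWM difference score $F(l)$ | 1 | 12 | 12 |
| F2 | secondary structure + accessibility | 2 | 12 | 24 |
| F3 | rigidity, flexibility, irreplaceability | 3 | 24 | 72 |
| F4 | hydrophobicity, hydrophilicity, mass, pk1, pk2, pI | 6 | 18 | 108 |

The total dimension is $w_1 + 2 w_2 + 3 w_3 + 6 w_4$; the defaults give
216. Secondary structure is encoded as one scalar per position (H = 0,
E = 0.5, C = 1, X = 0.5) — the doubling "2 values per offset" comes from
pairing it with accessibility, scaled to [0, 1] by the dataset-wide
maximum. Property values are min-max scaled per property over the 20
residues; `X` encodes as 0.5, the scale midpoint, so padding is neutral.

The nine properties ship in `inst/extdata/aa_properties.tsv`. Mass, pk1,
pk2 and pI come from standard amino-acid chemistry; hydrophobicity is
Kyte–Doolittle; hydrophilicity is Hopp–Woods; flexibility is the
Bhaskaran–Ponnuswamy average flexibility index. Rigidity and
irreplaceability are *constructed proxies* (the complement of the
flexibility scale and the inverse of Dayhoff relative mutability,
respectively) standing in for scales that are not publicly reprinted; the
file documents this and can be edited, and any result that leans on those
two columns inherits their uncertainty.

`optimize_window_size()` sweeps one group's $w$ over 10…30 (step 2),
scoring each candidate by jackknife auROC with the group encoded alone,
and returns the argmax (ties to the smaller size). Per-group optimal sizes
are a first-class output of the method: composition signal concentrates
within a few residues of the center while property signal extends further.

### Balancing, selection and evaluation

Unphosphorylated threonines vastly outnumber phosphorylated ones (at the
scale this package is modeled on, 151 positives against 2158 negatives).
`cluster_undersample()` balances a class by k-means clustering its encoded
windows into $k$ clusters (fixed seed, `nstart = 5`) and keeping the
member nearest each centroid, ties to the lowest input index. Cluster
representatives preserve the composition of the class better than uniform
subsampling; $k = 100$ per class is the benchmark default.

Features are ranked by mRMR with the MID criterion: each feature is
discretized into three states at mean ± population SD (inclusive cuts —
strict cuts would collapse binary features to a single state), relevance
is plug-in mutual information with the label, and the greedy score of a
candidate is relevance minus mean MI with the already-selected set, ties
to the lower index. Incremental feature selection then evaluates every
nested prefix of the ranking (n features → n subsets) by jackknife auROC
and reports the peak, ties to the smaller prefix.

The classifier is an RBF-kernel SVM (libsvm via e1071, `scale = FALSE`
since all features are already on comparable scales). Evaluation is
jackknife (leave-one-out); auROC is computed by trapezoid over tie-grouped
thresholds, which equals the pairwise rank statistic with ties counted ½.
The default operating point is $C = 2^5$, $\gamma = 2^{-8}$ ($\gamma$ near
$1/216$, the usual heuristic for ~200 features on [0, 1] scales);
`grid_search()` exhausts the conventional grid $C \in 2^{-5..15}$,
$\gamma \in 2^{-15..-5}$ (231 pairs, jackknife-scored, ties toward the
smaller pair) when tuning is wanted. Tuning is done once on the full
matrix and reused across IFS prefixes.

**Leakage control.** The F1 features of a window depend on PWMs trained on
labeled windows, so inside every jackknife fold the PWM pair is rebuilt
with the held-out window removed (implemented by count-matrix downdating;
the other groups are window-intrinsic and computed once). Evaluations that
instead encode F1 once on the full set — as a naive reading of the
protocol would — are optimistic; `jackknife_windows()` is the
leakage-free path and is what the package reports.

## The synthetic data generator

Real phosphosite datasets are built from UniProt/PDB-derived annotations
that cannot be redistributed here, so the generator emulates the class
structure such data shows and makes every stage testable:

- **Composition**: positive flanks draw from per-offset motif effects —
  by default proline at +1 with probability 0.30 (matching the >25%
  enrichment reported for real phosphothreonines) plus weaker preferences
  at −13, −11, −4, +3 and +8 — then from a uniform background; negatives
  draw background only.
- **Structure**: coil probability for positives decays exponentially from
  0.7 at the center to the 0.4 background (decay length 5 residues);
  negatives sit at background. Non-coil states split H:E = 60:40.
- **Accessibility**: Gaussian baseline (mean 0.3, SD 0.1, clamped to
  [0, 1]) plus a center-peaked shift of 0.25 for positives.

Signal modes scale these effects: `strong` (as stated), `weak` (halved),
`null` (removed — the classes are then exchangeable, a negative control).
Each protein is a concatenation of 31-residue site segments with
threonine occurring only at segment centers (background sampling excludes
T and renormalizes), so `build_dataset()` recovers exactly the requested
site counts; `paper_scale_preset()` gives 151 positives and 2158 negatives
over 115 proteins. Effects are parameterized per offset so tests can plant
signal at known positions and check that the window-size sweep recovers a
small window.

What the generator does *not* emulate: homology between proteins (no
redundancy-reduction step is needed or provided), kinase-specific motifs,
correlated residues, real secondary-structure segment statistics
(helices/strands have no length persistence), or real accessibility
units. Passing tests therefore demonstrate that the pipeline recovers
planted signal of realistic magnitude and reports chance on null data —
not that any particular accuracy will be attained on real proteins.

## Numerical and design choices

- Log base 2 everywhere (bits); $M(l) = 0$ and all orderings are
  base-invariant.
- 1-based inclusive coordinates at every file boundary; signed
  center-relative offsets internally.
- Terminus handling: near-terminus windows are X-padded rather than
  discarded; every encoder maps `X` to a neutral value (score 0, ss 0.5,
  acc 0, property 0.5).
- Unannotated residues default to coil with zero accessibility, counted
  and reported.
- Accessibility units are taken as annotated (the TSV is unit-agnostic)
  and normalized only at encoding time, by the dataset-wide maximum.
- Determinism: all stochastic steps (generation, k-means) run under
  caller-supplied seeds and restore the caller's RNG state; identical
  configs give identical artifacts, and `run_pipeline()` caches stages on
  an md5 hash of the config.
- Ties break deterministically everywhere: lowest input index (cluster
  representatives, mRMR), smallest size/k (window sweep, IFS), smallest
  C then γ (grid search).
- Degenerate inputs: all-X profile columns are flagged and excluded
  rather than treated as zeros; α = 0 PWMs with empty cells error unless
  −∞ is explicitly allowed; constant features discretize to all-mid and
  carry zero relevance.

A note on jackknife behavior worth knowing when reading outputs: with
uninformative features the leave-one-out estimate is slightly pessimistic
(removing a sample tilts the training majority against its class; in the
extreme of identical feature rows the auROC is exactly 0, not 0.5), and
leave-one-out scores are correlated, so null-data auROC estimates have
noticeably more spread than an i.i.d. intuition suggests.

## Problem sizes used in the shipped checks

The test suite exercises the full method at the benchmark scale the
package is designed around: 100 + 100 windows per evaluation, five seeds
for each stochastic claim (signal recovery, null control, window-size
recovery), paper-scale generation (151/2158 → 100 + 100 after balancing)
for the structural claims, and small instances (≤ 30 samples, ≤ 8
features) for the brute-force oracle equivalences. These sizes are the
package's own benchmark conditions; larger runs only sharpen the same
comparisons.

## Known limitations

- The rigidity and irreplaceability property columns are constructed
  proxies (see above).
- The grid-search protocol wraps the same jackknife used for reporting
  (no nested cross-validation), matching the method this package
  re-implements; treat tuned-and-reported auROC as mildly optimistic.
- mRMR relevance uses three-state discretization; features whose
  information lies in fine-grained tails can be under-ranked.
- The generator's independence assumptions (no residue–residue
  correlation) make synthetic benchmarks easier than real data of equal
  nominal effect size.
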