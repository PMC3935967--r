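---
title: "Topology-focused model quality assessment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-focused model quality assessment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(meftop)
```

## The problem

Template-based structure prediction ranks candidate models of a target
protein by a threading score, standardized within the candidate pool as a
Z-score. For well-templated targets this works; for low-homology targets —
the *dawn region*, conventionally targets whose best Z-score is below 6 —
the threading score becomes weakly informative and the top-ranked model is
frequently native-unlike even when native-like models (TM-score > 0.4)
exist in the pool. `meftop` implements a single-model quality assessment
method for exactly this regime: it scores each candidate by how well the
model's own topology agrees with what can be predicted from the target
sequence alone, and folds that assessment back into the ranking.

## The model

Three scores are involved:

* **Z-score**: the per-pool standardization of the raw threading score,
  `Z_k = (S_k - mean(S)) / sd(S)` with the population standard deviation.
  The package consumes raw scores; it does not run a threading engine.
* **P-score**: an epsilon-SVR (RBF kernel) regression estimate of the
  model's TM-score from a 37-dimensional feature vector (below). Training
  instances are weighted by their TM-score label — a better model carries
  more weight — realized as integer replication `max(1, round(10 * TM))`
  on the libsvm path (`e1071`), which makes a TM = 0.8 model weigh exactly
  twice a TM = 0.4 model. Features are min–max scaled to [0, 1] with
  ranges learned on the training split only. Prediction evaluates the
  support-vector expansion `f(x) = sum_i coef_i K(sv_i, x) - b` directly,
  so a serialized scorer (plain JSON, doubles printed with 17 significant
  digits) reproduces predictions bit for bit.
* **M-score**: the combination `M = Z + n·P`. The weight `n` is selected
  on validation decoy pools by maximizing Top1% over the grid 0.5–10 in
  steps of 0.5 (ties: lower average rank, then smaller `n`).

A cost function `F = mean(rank of native) − n·mean(Z_svm) + λ·missed` is
provided (`cost_f()`, `tune_scorer()`) for hyperparameter selection with
natives included in the ranked pools; `Z_svm` standardizes the P-score
within each pool, `missed` counts targets whose native is not ranked
first, and λ defaults to 1. The package's default SVR setting
(C = 10, γ = 1/37, ε = 0.1) is a fixed configuration chosen once; the
grid machinery is exposed for users who want to re-tune.

## The 37 features

Model-side states come from internal annotators: a deterministic
Kabsch–Sander-style hydrogen-bond assigner collapsed to 3 states
(helix classes → H, strand/bridge classes → E, else C; residues flanking a
chain break, CA–CA > 4.5 Å, are forced to coil), and a neighbour-count
burial proxy thresholded at 25% relative accessibility. Sequence-side
states and contact probabilities come from a target profile (plain-text
reader, or the synthetic generator).

1. **Traditional 1D (14)** — fractions of H/E/C and exposed/buried states
   on each side (10), plus cosine, Pearson correlation, Gaussian kernel
   (γ = 1) and dot product of the two 5-component composition vectors (4).
2. **Traditional 2D (10)** — per-residue contact order and contact number
   profiles from the predicted probability map and from the model contact
   map (SCM–SCM distance strictly below 8 or 12 Å, sequence separation
   ≥ 6), compared by cosine and correlation at both thresholds (8), plus
   the overall contact match `f_res` at both thresholds (2). `f_res`
   averages `C_ij·N_ij + (1−C_ij)(1−N_ij)` over eligible pairs; the
   average is over the *pair count*, so `f_res` is bounded in [0, 1] and
   equals 1 at exact binary agreement.
3. **SSE contact (6)** — SSEs are maximal runs of ≥ 4 identical H/E
   states. Model and target SSEs are matched greedily in sequence order by
   minimal start difference (earlier target wins ties; no crossing pairs);
   unmatched SSEs are dropped. Features: the strength agreement `f_SSE`
   (a bounded L1 form, `1 − Σ|C_S−N_S| / Σ max(C_S, N_S, ε)`, over
   row-length-normalized SSE contact strengths, both orientations), cosine
   and correlation of per-SSE total contact strengths, a Gaussian
   similarity (σ = 4 Å) of SSE pair distances (model: minimum SCM–SCM
   distance; sequence: `D = D0 + k(Dm−D0)(P0−p)` with D0 = 3.8 Å, Dm = 8 Å,
   P0 = 1, k = 1, clipped to [3.8, 20]), and two length ratios
   (pooled `Σmin/Σmax` and mean per-pair `min/max`).
4. **Topology (7)** — radius-of-gyration agreement with the globular power
   law `R_pred = 2.2·L^0.38` (Gaussian with σ = 0.2·R_pred, and min/max
   ratio); three hydrophobic-core ratios (radius, residue count, SSE
   count) comparing the largest single-linkage cluster (6.5 Å) of
   hydrophobic SCMs ({A,V,L,I,M,F,W,C}) against sequence-side
   expectations; and two local fragment potentials over 5-residue windows
   with an H/E majority (Gaussian of the CA(i)–CA(i+4) span deviation from
   6.2 Å/12.4 Å ideals, σ = 2 Å, and the fraction of windows whose CA
   virtual torsion is canonical: 45–65° for helix, within 30° of ±180°
   for strand).

Degenerate cases resolve to fixed conventions throughout: cosine of a zero
vector is 0, correlation of a constant vector is 0, contact order of a
contact-free residue is 0, `f_SSE` with no correspondence is 0 and with no
contacts on either side is 1, and any non-finite sub-feature is replaced
by 0 during assembly.

### A threshold tension worth knowing about

The model-side SSE contact strength counts residue pairs under **8.5 Å**
while the sequence side sums probabilities of the **< 8 Å** class. These
are the published operating points and both are kept as defaults, but they
mean that even a perfect model scored against an error-free profile can
have `f_SSE < 1`: pairs in the 8.0–8.5 Å shell count on one side only.
`assemble_features(..., sse_model_threshold = 8)` matches the two classes
and restores the exact identity; the consistency tests use that
configuration and additionally check a high floor under the 8.5 Å default.
Real profile noise dwarfs this shell effect.

### Calibrated constants

Two expectation constants have no external anchor and were calibrated once
on the package's own fold family (and are arguments, not magic numbers):
the expected fraction of sequence hydrophobics in the core, ρ = 0.9 — the
generator points nearly every hydrophobic side chain inward, so real-world
values near 0.6 systematically under-predict the core — and the core
radius coefficient k_hc = 2.35, the median of `radius / count^0.38` over
the generated natives. The gyration-law constants (2.2, 0.38) follow the
standard globular fit and are left untouched.

## TM-score

`tm_score()` is a self-contained implementation for equal-length CA
traces: `d0 = 1.24·(L−15)^{1/3} − 1.8` floored at 0.5; every contiguous
window of length ≥ 4 seeds a Kabsch least-squares superposition that is
iteratively refined on the subset of residues within `max(d0, 3)` Å (the
cutoff grows by 0.5 Å while fewer than 3 residues qualify) until the
subset is stable, and the best full-length score over all seeds is kept.
The seed set is exhaustive on purpose — scrambled models can have narrow
superposition basins reachable from only one window — and the search
kernel is compiled (RcppArmadillo), costing a few milliseconds per call
at the chain lengths the package targets. Tests hold it within 0.01 of an
independently coded brute-force oracle on ≤ 40-residue toys.
Sequence-alignment-based TM for unequal lengths is out of scope.

Selection metrics: Top1% uses the strict `TM > 0.4` native-likeness rule;
average rank sorts each pool by true TM descending with ties averaged.

## What the synthetic generator emulates — and what it does not

`build_native()` assembles idealized folds: helices (φ = −57°, ψ = −47°)
and strands (φ = −139°, ψ = 135°) built from ideal internal coordinates,
packed as rigid blocks on an arc with alternating axis directions
(consecutive strands spin-scanned into genuine backbone hydrogen-bond
register at ~4.2 Å spacing, as judged by the package's own energy
function), joined by interpolated loops, with inward-facing side chains
assigned hydrophobic identities. `make_decoys()` perturbs SSE blocks
rigidly with grade-scaled rotations/translations, occasionally swaps two
blocks (scrambling the topology while preserving local structure — the
characteristic error of low-homology threading models), jitters atoms and
rebuilds loops. `make_raw_scores()` emulates a threading score as
`S = 10·TM + N(0, z_noise)`.

Default study conditions (`make_fixture_set()`): profile noise of 8% SS
flips, 12% RSA flips, 15% missed-contact rate, 3% background contact
probability and 0.05 Gaussian jitter — moderately reliable sequence
predictors; decoy grades skewed toward heavy perturbation so native-like
models are a minority of each pool (roughly a quarter), as in real
dawn-region decoy sets; and `z_noise = 8`, chosen so that Z-score
selection is degraded into the dawn regime (Top1% at or below 60% on the
evaluation cohort) while retaining a weak positive signal. The default
study (`run_synthetic_study()`) trains on 16 targets × 30 decoys and
evaluates on 50 targets × 50 decoys — sizes chosen to keep the full
experiment in the minutes range on one CPU while leaving Top1% stable to
a few percentage points.

What passing on these fixtures does **not** show: the folds are small
(30–60 residues), single-chain, loop-crude and side-chain-free beyond an
SCM pseudo-atom; profile errors are independent per residue/pair, unlike
the structured errors of real secondary-structure and contact predictors;
and the raw-score model is linear in TM with Gaussian noise, unlike real
threading scores. Results on these fixtures demonstrate that the pipeline
is implemented coherently and that the re-ranking direction holds under
dawn-like conditions — not that real-data performance numbers transfer.

## Known limitations

* Single chain, equal-length model/native correspondence, no mmCIF.
* The internal SS assigner reproduces the published pathway's *role*; it
  is not a byte-for-byte DSSP replacement. Users who run DSSP themselves
  can import its states with `read_dssp_ss()` and overwrite `$ss`.
* The hydrophobic-core comparison's sequence-side expectations are the
  least constrained part of the method; they are exposed as parameters.
* The SVR replication weights quantize TM to one decimal; sub-0.05 label
  differences do not change a weight.
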