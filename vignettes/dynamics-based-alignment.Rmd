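---
title: "Dynamics-based protein alignment with distance-fluctuation fingerprints"
author: "dfmalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics-based protein alignment with distance-fluctuation fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfmalign)
```

## The model

`dfmalign` compares the backbone dynamics of two proteins without any
prior sequence or structure alignment. The pipeline has four stages.

**1. Dynamic Fingerprint Matrix (DFM).** A conformational ensemble —
frames × residues × 3 Cα coordinates — is reduced to the matrix `F` whose
entry `F[i, j]` is the standard deviation of the Cα(i)–Cα(j) distance over
the frames. Pairwise distances are invariant to rigid motion of each
frame, so the fingerprint needs no superposition and no choice of a
"native" reference structure; this is its central advantage over
RMSF-style analyses. Row `k` (`dynamicProfile()`) describes how every
residue moves relative to residue `k`; row means
(`averageFluctuationProfile()`) give a reference-free flexibility profile
that tracks conventional RMSF closely on ensembles without net
conformational drift.

**2. Pairwise Match Score (PMS).** Under an alignment, equivalent
fingerprint entries `a` and `b` are compared through their relative
difference and a logistic score

$$ d = \frac{|a-b|}{(a+b)/2}, \qquad
   s(d) = s_- + \frac{s_+ - s_-}{1 + e^{\lambda (d - x_0)}} . $$

The shift is solved in closed form, $x_0 = t - \log(s_+/{-s_-})/\lambda$,
so that `s(t) = 0` exactly: pairs differing by less than the cut-off `t`
contribute positively, by more negatively, with the steepness `λ`
controlling how sharply the verdict switches. The total alignment score
sums `s` over all *unordered* pairs of match columns; the Single Match
Score (SMS) of a column is its summed PMS against all other columns and
equals exactly the score lost by deleting it.

**3. Search.** The optimal monotone alignment maximizes the total score
over an exponentially large space (the problem is NP-hard).
`anneal()` runs multiple-restart Metropolis simulated annealing; the exact
optimum is available from `exhaustiveOptimum()` for instances up to about
a million candidate alignments and anchors the test suite.

**4. Significance.** The optimal score of two *unrelated* proteins is a
maximum over many weakly dependent alignment scores and is well described
by a type I extreme value (Gumbel) distribution whose location `μ` and
scale `σ` grow with problem size `L = L_A · L_B`. `calibrateEVD()`
estimates `μ(L)` and `σ(L)` by annealing submatrices of reference
fingerprints at several sizes, fitting a Gumbel per size bin by maximum
likelihood and regressing the per-bin parameters on `L`. `pValue()` then
reports the upper-tail probability
`p = 1 − exp(−exp(−(S − μ(L))/σ(L)))`; `p < 0.05` (strict) is called
significant.

## Assumptions

* One chain, one Cα per residue, identical residue ordering in every
  frame; residues missing a Cα in any frame are dropped from all frames.
* The ensemble is treated as *the* distribution of conformations:
  fingerprints use the population standard deviation (divide by the
  number of frames). The sample convention (`n − 1`) is available via
  `computeDFM(..., varianceConvention = "sample")`; at trajectory-scale
  frame counts the two differ negligibly.
* Alignments are monotone (both index vectors strictly increasing), as
  for match columns of any gapped pairwise alignment. Consequently a
  circular permutation of one protein relative to the other cannot be
  matched as a single block — only its collinear fragments can.
* Gaps carry no explicit penalty; skipping residues costs exactly the
  foregone positive match scores.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sPlus`, `sMinus` | `1`, `−1` | PMS ceiling and floor (dimensionless). Symmetric defaults make `x0 = t`. |
| `cutoff` (`t`) | `0.25` | relative difference below which entries count as similar; 0.25 reads as "within 25 %". |
| `lambda` | `40` | logistic steepness; `λ·t = 10` keeps `s(0) > 0.999` while remaining smooth. |
| `relDiffMethod` | `"mean"` | normalizer of `d`; `"mean"` is symmetric and bounded in `[0, 2]`; `"max"` (bounded `[0, 1]`) provided as an alternative. |
| `chi0` | `0.8` | target initial acceptance of downhill moves; the initial temperature is `T0 = mean downhill drop / log(1/chi0)` from an accept-everything pilot walk (`calibrateT0()`), falling back to `T0 = 1` when the pilot never goes downhill. |
| `plateauMinAccepts` | `50·min(n_A, n_B)` | accepted moves required per temperature. |
| `coolingFactor` | `0.95` | exponential decay per plateau. |
| `stopAcceptance` | `0.02` | terminate a restart when the per-plateau acceptance ratio falls below this. |
| `stallPlateaus` | `25` | also terminate after this many consecutive plateaus without improvement of the incumbent (see below). |
| `nRestarts` | `5` | independent restarts; the best alignment ever visited anywhere is returned. |
| `pruneNegativeSMS` | `TRUE` | iteratively delete the most negative-SMS column until none remain; each deletion raises the score, and the optimal alignment provably contains no negative-SMS column. |

All appear as flags of the command-line driver as well. The annealing
schedule values are engineering choices — the method's contract is only
that the search approximates the maximum; the test suite checks it
against exhaustive enumeration on small instances (≥ 95 % exact over
random batteries) and against planted ground truth at realistic sizes.

## Numerical and design choices

* **Zero-distance guard.** `relDiff(0, 0) = 0` by definition, so two
  residue pairs that are both perfectly rigid count as perfectly similar.
* **Diagonal pairs excluded.** Both collapsed diagonals are identically
  zero; including them would add the same constant to every alignment of
  a given length. Sums run over unordered pairs `i < j`; the
  SMS decomposition identity `S = ½ Σ SMS` holds exactly under this
  convention, and the extreme-value calibration uses the same convention
  by construction.
* **Alignments with fewer than two columns score 0** (no pairs exist).
* **Exhaustive tie-breaks.** Among equal-scoring alignments the search
  prefers more columns, then the lexicographically smallest pair list;
  ties at score exactly zero keep the empty alignment (a zero-score
  column pair conveys no signal).
* **Stall termination.** The acceptance-ratio stop alone is not
  sufficient: near-empty alignments admit insert/remove moves of exactly
  zero score change, which are always accepted and can hold the raw
  acceptance ratio above threshold indefinitely on dissimilar inputs.
  A restart therefore also stops after `stallPlateaus` plateaus without
  any improvement of the best score visited.
* **Incremental scoring.** A single-column insertion or removal changes
  the score by exactly that column's SMS; the compiled chain uses this
  O(k) update and recomputes the returned best score from scratch, and
  the tests assert the incremental and full scores agree.
* **Initial state.** Each restart starts from a uniform random monotone
  matching with `k ~ uniform{0, …, min(n_A, n_B)/2}` columns.
* **Gumbel fitting.** Maximum likelihood with method-of-moments starting
  values (`σ0 = sd·√6/π`, `μ0 = mean − γσ0`); degenerate (constant)
  samples and samples of fewer than 10 scores are rejected.
* **Calibration submatrices** are contiguous principal blocks at random
  offsets: contiguity preserves the banded near-diagonal texture of real
  fingerprints, which random subsets would destroy.
* **Size transform.** `μ` and `σ` are regressed on `L` by default
  (`sizeTransform = "identity"`); a `log(L)` regression is available,
  since alignment-score locations classically scale with log size. Both
  are recorded in the serialized model. With a single size bin the model
  degrades to constants.
* **Extrapolation** beyond the calibrated `L` range warns but computes;
  a non-positive extrapolated `σ(L)` is an error.
* **Indices** are 1-based inside R; alignment files on disk carry 0-based
  `res_a`/`res_b` columns for interoperability with other tooling, plus
  human-readable residue labels.
* **Reproducibility.** Every stochastic entry point (generator, annealer,
  calibration, batch driver) takes a seed and is bitwise reproducible;
  the compiled chain consumes R's own RNG stream. The batch driver
  derives one seed per pair from the master seed and the pair's names, so
  results are independent of input order and restartable.

## The synthetic generator

`generateEnsemble()` draws frames as a reference backbone (ideal helix
geometry by default; extended and random-walk curves available) plus
correlated Gaussian displacements. An elastic-network-style precision
matrix `Q = I + coupling · Lap` (graph Laplacian of the contact graph
within `contactCutoff = 10 Å` on the reference curve) is inverted and
rescaled so each residue's per-axis displacement SD equals its `mobility`
entry (Å). The default mobility profile alternates rigid
secondary-structure-like stretches (≈ 0.35 Å) with loop-like peaks
(≈ 1.5 Å) on a ten-residue period — the heterogeneity that makes
fingerprints alignable in a non-trivial way. Frames are i.i.d. by
default; an AR(1) memory (`ar1`) is available since real trajectory
frames are autocorrelated, and it preserves the marginal covariance.

`generateHomologPair()` plants ground truth: protein B keeps A's
least-mobile residues (the conserved core) in order, with core mobilities
perturbed multiplicatively (`1 + ε`, `ε ~ N(0, perturbation²)`), and
inserts extra residues into gaps chosen with probability proportional to
flanking mobility — insertions land in loops, as in real homologs.
`syntheticReferenceSet()` varies the profile family's period, phase and
per-residue jitter to produce mutually unrelated reference fingerprints
for null calibration.

What the generator does *not* emulate: physical force fields, solvent,
anharmonic transitions between metastable states, and conformational
drift. Passing tests on this family therefore demonstrates the machinery
(fingerprint computation, search, calibration) under controlled,
realistic statistical structure — not force-field-level realism. One
consequence worth knowing: all members of the default family share a
banded quasi-periodic texture, so even "unrelated" synthetic pairs reach
sizable raw scores and the calibrated null is correspondingly heavy. This
mirrors the situation with real proteins of a common fold and is exactly
why scores are converted to size-calibrated p-values rather than compared
raw.

## Problem sizes used by the tests

The validation suite and the acceptance script run at desk scale, chosen
as the smallest sizes at which each property is meaningfully exercised:
exhaustive-oracle batteries at 4–6 residues (≤ `C(12,6)` alignments),
planted-core recovery at 40 residues × 4 000 frames with a 30-residue
core and 10 % mobility perturbation (recovery ≥ 80 % of planted pairs,
median over seeds), and null calibration from six 70-residue references
at submatrix sizes {20, 40, 60} (15 alignments per size bin). Gumbel
parameter recovery uses 50 000 draws; type-I calibration 2 000 null
scores.

## Known limitations

* Monotone alignments only: circularly permuted architectures are
  detected at best as fragments, never as a single match.
* One chain at a time; no side-chain or all-atom fingerprints; no
  time-windowed fingerprints (slow drift inflates distance SDs
  indiscriminately).
* The p-value model is as good as its reference set: calibrating on
  fingerprints whose texture differs grossly from the query family biases
  p-values in either direction. User-supplied real reference fingerprints
  are accepted through the same `calibrateEVD()` path.
* Raw scores between pairs of different sizes are incomparable by
  construction; always compare p-values.
* No multiple-testing correction is applied across all-vs-all matrices;
  the 0.05 threshold is per pair.
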