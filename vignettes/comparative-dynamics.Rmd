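---
title: "Comparative dynamics for embedded-domain discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative dynamics for embedded-domain discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynatile)
```

## The problem

Bacterial ferredoxins are small (roughly 50–80 residue) iron–sulfur
electron carriers whose 2×(β–α–β) fold recurs, heavily disguised, inside
large multidomain oxidoreductases. After billions of years of duplication,
fusion and divergence, sequence identity and even backbone geometry of
these embedded copies can erode past the reach of alignment- or
superposition-based detection. The premise of this package is that the
*collective motions* of a domain — being tied directly to function — are
more conserved than either sequence or static structure, so that
similarity of low-frequency dynamics can flag homologous fragments that
the other two signals miss. dynatile combines all three signals, then uses
the one piece of hard chemistry available — cysteine thiolates ligating
iron–sulfur clusters at a narrow range of bond lengths — to discard
spurious matches.

## The model, stage by stage

**Elastic network and normal modes.** Each structure is reduced to its
Cα atoms, connected by identical springs (`gamma`, default 1.0
kcal/(mol·Å²)) wherever two atoms lie within the cutoff `cutoff`
(default 15 Å). The Hessian of this network is assembled from the standard
anisotropic super-elements `-γ (d ⊗ d)/|d|²` and diagonalized densely
(`eigen`); problem sizes in this package's tests are a few hundred
residues, where a dense symmetric solver is both exact and fast. The six
eigenvalues within `1e-8 × max(λ)` of zero are the rigid-body motions of a
connected network and are discarded — a different count is reported as a
warning, since it indicates a disconnected or mechanically degenerate
network. The next `n_modes` (default 10) lowest modes are retained: these
large-amplitude, low-frequency motions are the ones argued to be under
functional selection. Whether rigid-body modes are excluded *before*
counting the retained ten is not universal across toolchains; dynatile
excludes them first, which is the prevailing convention, and exposes
`n_modes` for users who want otherwise.

**Cross-correlation.** From the retained modes the residue–residue
covariance is `cov_ij = Σ_k (1/λ_k) u_{k,i}·u_{k,j}`, normalized to
`C_ij = cov_ij / √(cov_ii cov_jj)` so the diagonal is exactly 1 and
entries are comparable between proteins of different size and stiffness.
Because the Hessian depends only on internal geometry, `C` is invariant
under global rotation and translation of the input coordinates — a
property the test suite checks to 1e-8 — which is what lets tiles be
compared with *no superposition step anywhere in the pipeline*.

**Tiling and the three similarities.** Every contiguous window (tile) of
length `L` (6 ≤ L ≤ N; six residues being the smallest window that still
spans a β-strand or a helical turn on a Cα trace) contributes its diagonal
correlation block. For a query tile and a target tile of equal length the
package computes:

* *dynamical similarity*: cosine of the angle between the two flattened
  blocks, in [−1, 1];
* *structural similarity*: the Frobenius distance between the blocks,
  mapped through the continuous Gower transform `s = 1 − d/d_max`, where
  `d_max` is the largest distance among tile pairs **of the same length in
  the same run**. Normalizing per length matters: the Frobenius distance
  grows with matrix size, and a single global `d_max` would compress the
  similarity scale of short tiles toward 1. A degenerate length class in
  which all pairs are identical (`d_max ≈ 0`, e.g. a full-length
  self-comparison) is assigned similarity 1 rather than 0/0;
* *sequence similarity*: Smith–Waterman local alignment score (BLOSUM62,
  zero gap-opening and gap-extension costs — the default of the alignment
  toolkit this mirrors; a stricter −11/−1 scheme can be passed through
  `gap_opening`/`gap_extension`), normalized by the mean of the two tiles'
  self-alignment scores and expressed in percent.

Each tile's correlation block is taken from *its own protein's* matrix
(the diagonal-block reading): the two proteins are independent elastic
networks with no joint covariance, so a cross-protein off-diagonal block
is not defined without arbitrary identifications. An off-diagonal variant
within one protein would measure coupling between two segments rather
than similarity of two segments, which is a different question.

**Weighting by Bayesian optimization.** The composite score is
`S = w_cos·s_cos + w_frob·s_frob + w_sw·(s_sw/100)`; the sequence term is
rescaled to [0, 1] first so no metric dominates by units. Weights are
chosen on the simplex to maximize the mean Pearson correlation of `S` with
each individual metric — a compromise score that stays faithful to all
three signals at once. The optimizer is a zero-mean Gaussian process with
a squared-exponential kernel; hyperparameters (signal variance, length
scale; initialized at 1 and 0.2) are refit by marginal likelihood at each
guided step, and candidates are scored by expected improvement in its
maximization form. The budget defaults to 15 uniform-simplex random
iterations followed by 100 guided ones (115 total). Two properties of this
objective are worth knowing. First, it is smooth and rather flat near its
optimum, which is why the 115-step budget reliably lands within 1e-3 of an
exhaustive 0.02-step grid (the acceptance suite verifies this). Second,
the optimum does *not* suppress an uninformative metric: the weighted sum
must contain a column to correlate with it, so even a pure-noise metric
retains weight comparable to the informative ones. The weighting is a
calibration of scales, not a feature selector; the geometric filter below
is what provides specificity.

**Landscape, chemistry filter, islands.** The scored pairs are arranged
into a (tile length × target center) matrix holding, per cell, the best
weighted score over query tiles; the triangular "sawtooth" boundary
appears because long tiles admit fewer centers. Each cell is then kept
only if its target tile contains at least one cysteine whose SG atom lies
within `[r_min, r_max]` (inclusive; default 2.18–2.35 Å, the span of
typical Fe–S coordination bonds) of any iron site, measured from the SG
because the thiolate sulfur, not the backbone, is the first-shell ligand.
The filter is deliberately independent of the similarity values: it
encodes chemistry, not score. Maximal runs of surviving center columns are
labeled islands A, B, … left to right; each island is one candidate
embedded domain, and path search never crosses the blocked borders between
islands.

**Optimal path and converged length.** Within an island, a dynamic
program walks the length rows in ascending order; a cell at center `j` may
extend any cell at centers `j−2 … j+2` in the previous row, masked cells
are impassable (−∞), and ties break toward the smallest column so results
are bit-reproducible. The traceback starts from the maximum of the deepest
reachable row. Along the resulting path, the cell value as a function of
tile length is fit with a degree-5 polynomial, differentiated
analytically, Gaussian-smoothed (σ = 2 length units) and rolling-averaged
(window 5); the converged length is the smallest `L` whose smoothed
derivative magnitude drops below `eps = 0.005`. If the derivative never
settles, the length maximizing the fitted curve is reported with
`converged = FALSE` rather than guessing. The per-path (rather than
global) treatment lets islands with clean structural homology converge
short while degraded matches keep extending.

**Ranking and mapping.** Independently of the landscape path, tile pairs
can be composite-ranked (dense best-first rank per metric, summed), passed
through the published screening thresholds — cosine ≥ 0.5, sequence ≥ 50%,
lengths restricted to 6…⌊N/2⌋, best 20% per length class — and final
matches are converted from model numbering back to chain + author residue
numbers, written as a TSV table and a PyMOL highlight script. The 20%
head is taken once per table (the output is flagged, and re-filtering is a
no-op) so that the filter is a stable subset operation.

## The synthetic-data generator

Because the original study's inputs are large deposited structures, the
package ships a generator that builds Cα-only toy structures with planted
ground truth: idealized helices (rise 1.5 Å, ~100°/residue, radius 2.3 Å,
consecutive Cα ≈ 3.8 Å), hairpins of extended strands, cysteines with SG
2.8 Å off the Cα, and irons planted 2.25 Å from each SG — inside the
filter window by construction. `make_embedded_fixture()` concatenates
`n_copies` of such a domain with cysteine-free linkers and returns the
planted ranges. Two generator choices deserve a note:

* *Linkers are compact jittered helical segments*, not extended threads.
  A straight thread of nodes behaves as a floppy mechanism whose torsional
  modes dip below the rigid-body tolerance and contaminate the mode count;
  a coiled linker keeps the network stiff while still separating the
  copies beyond the spring cutoff.
* *Noise respects the cofactor chemistry.* `perturb_structure()` displaces
  each residue by an i.i.d. Gaussian vector scaled so the expected
  coordinate RMSD matches the request, and the SG follows its Cα rigidly;
  fixture irons are placed after the noise. The noise therefore tests the
  dynamics and scoring stages, not the filter's tolerance to broken
  bonds — deliberately, since in real structures the Fe–S bond geometry is
  a property of the deposited model, not of measurement noise one would
  add synthetically.

What the fixtures do *not* emulate: real secondary-structure packing,
side-chain chemistry beyond the SG atom, crystallographic artifacts
(altlocs, insertion codes appear only in hand-written test files), and the
sheer size of real oxidoreductase targets (N ≈ 2000–4000). Passing tests
on fixtures demonstrates the machinery is correct, not that every real
target will yield clean islands.

A further physical caveat encoded in the tests: an embedded copy of a
domain does **not** reproduce the isolated query's correlation block
exactly, because the copy is elastically coupled to the rest of the chain.
Perfect scores arise only in true self-comparison; embedded copies are
recovered through the island structure, which is the designed behavior.

## Numerical choices and degenerate inputs

* Rigid-body tolerance `1e-8 × max(λ)`; eigen-residuals are tested to
  `1e-6‖H‖`.
* Coincident Cα nodes within the cutoff are a hard error (zero-length
  springs are undefined).
* GP kernel matrices get a 1e-10 jitter, escalated ×100 on Cholesky
  failure and capped; hyperparameter refits that fail fall back to the
  previous values.
* Zero tile vectors (possible only with a pathological all-zero
  correlation block) raise an error rather than returning NaN cosine.
* `d > d_max` (possible only if `d_max` came from a subset) clamps to
  similarity 0 with a warning.
* Empty filter output, empty islands, and empty match lists are valid
  results, reported with warnings, not errors.

## Problem sizes

The shipped tests and the reproduction script run on a 30-residue query
against two-copy embedded targets of 90 residues, 10 replicates at 0.3 Å
noise, plus a 200-row score table for the optimizer-vs-grid comparison and
50 random landscapes for the path oracle. These sizes were chosen so that
every oracle (path enumeration, simplex grid) is exhaustively computable
and the whole suite completes in minutes on a laptop; all stages scale to
real query/target sizes (the dense eigendecomposition is the practical
bound, comfortable to N of a few thousand).

## Known limitations

* Harmonic, uniform-spring dynamics only: no mass weighting, no Gaussian
  (isotropic) variant, no anharmonic sampling; cofactors contribute no
  nodes to the network.
* Matches are ungapped contiguous windows; a domain split by a long
  insertion is reported as separate islands rather than one discontinuous
  match.
* No significance model is attached to a match; the cysteine–iron filter
  is the specificity mechanism.
* Weights are optimized per query–target pair; a pooled multi-target mode
  would require pooling score tables externally.
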