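---
title: "Methods: the spectral sequence-set distance, its decision rules, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the spectral sequence-set distance, its decision rules, and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsetdist)
```

## The model

A *heterogeneous sequence-set* is one observation consisting of several
sequences with no assumed common ancestry or shared composition — the
segments of a viral genome are the motivating case. seqsetdist treats
each such set as a composite data point and compares sets, not
sequences.

The pipeline has three stages.

1. **Feature extraction.** Every sequence is mapped to the vector of
   (overlapping) occurrence counts of a word set Ω over the alphabet —
   by default the four DNA 1-grams, so p = 4. A transformation function
   φ may re-map the counts: `phi_identity()` (the linear feature
   space), `phi_power(2)` (quadratic, each count squared), or an
   arbitrary `phi_composite()`. Raw counts, not frequencies, are the
   default feature: the length-factor experiments below depend on
   counts growing with sequence length (a `frequencies = TRUE` option
   exists).

2. **Set representation.** The set is summarized by the p′ × p′
   variance-covariance structure of its transformed feature vectors.
   Heterogeneity is the point: each sequence enters as a separate row,
   and the covariance captures how the sequences of the set spread in
   feature space. No distributional assumption is made.

3. **The distance.** For two structures the distance is
   δ(Ψ₁, Ψ₂) = max<sub>‖κ‖=1</sub> |κ′(Ψ₁ − Ψ₂)κ|, attained at the
   eigenvector of the extreme eigenvalue of the symmetric difference;
   δ equals the spectral norm of Ψ₁ − Ψ₂. We implement the
   largest-*magnitude* eigenvalue reading: it is the only reading under
   which the value is non-negative for every pair and the triangle
   inequality holds rigorously (‖·‖₂ is a matrix norm), and it makes
   δ a true metric on covariance structures. Because no inverse is
   taken, singular structures — singleton sets, constant features,
   p′ > n — are first-class inputs.

## Decision rules and their statistics

Classification of a query set against labeled classes Ξ₁, …, Ξ_k uses
the sample of distances from the query to every member of each class.
Three statistics are offered; the class minimizing the chosen statistic
wins.

* **mean** (default): the sample mean has expectation ξᵢ and variance
  ϑᵢ/|Ξᵢ|. Its Chebyshev bound Pr(|δ̄ − ξ| < ρ) ≥ 1 − ϑ/(nρ²) tends to
  1 with class size — the mean rule is consistent.
* **median**: same expectation (symmetric distributions), but larger
  variance — asymptotically πϑ/(2n) under normality. Its Chebyshev
  comparison bound 1 − ϑ/ρ² does not improve with n.
* **min**: smallest possible statistic (useful when a near-duplicate
  of the query is expected in one class) but the most variable and
  least robust of the three.

`rule_variance_experiment()` makes the ordering empirical: with
normal(ξ = 5, ϑ = 1) samples of size n = 30 and 10,000 replicates, the
mean statistic's empirical variance sits at ϑ/n and below the median's
(checked in the test suite; the acceptance script reports the numbers).
`chebyshev_bound()` returns the raw bound, which may be negative —
deliberately so, since a vacuous bound is informative about rule
quality. For the min and median the bound uses the sample variance ϑ
verbatim as a comparison formula; it is not a sharp bound for order
statistics, and the output labels it as the comparison form.

Ties in the argmin (within 1e-12) go to the first class in input
order with an explicit `tie` flag; the sample variance uses divisor
n − 1 (0 for a single member); the median of an even-length sample
averages the two middle order statistics.

## The simulator and what it emulates

`estimate_composition()` fits each sequence a multinomial base
composition (ML relative frequencies; a pseudocount option exists but
is off by default, so a base absent from the prototype never appears in
generated data). `generate_seq_set()` redraws every sequence i.i.d.
from its composition at length `round(factor × original length)`
(floor 1). The length factor n′ is the central dial of the
experimental design: the empirical composition of a generated sequence
converges to its prototype composition as n′ → ∞, which
`convergence_diagnostic()` quantifies as the median total-variation
distance between generated and prototype compositions (TV = half the
L1 distance). Typical designs compare the worst case n′ = 1 with
n′ = 100, use n′ = 200 for limiting dispersion maps, and draw m = 20
replicate sets per prototype.

The generator is i.i.d. multinomial per sequence — deliberately the
minimal model consistent with composition convergence. It does *not*
emulate codon structure, dinucleotide bias, local composition
heterogeneity along a sequence (which `sliding_window_composition()`
reveals in real data), indels, or phylogenetic correlation between
sets. Passing tests therefore demonstrate that the pipeline recovers
*composition-structure* signal under controlled noise; they do not by
themselves establish performance on real genomes, where within-sequence
heterogeneity and between-set correlation are present.

**Reproducibility.** Every generated sequence draws from an RNG
substream keyed by `(seed, replicate, sequence index)` via
`substream_seed()` (a 31-bit multiplicative mix), so collections are
order-independent and byte-identical across runs with the same seed.

### The synthetic class profiles

`synthetic_profile()` builds the class prototypes used in the
recovery experiments: sequence i of a class with base composition b
gets probabilities ∝ b ⊙ (1 + τ·dᵢ), with dᵢ a fixed quasi-random
contrast pattern (golden-ratio lattice) and tilt τ = 0.3 by default.
Two design points matter:

* The tilt is **multiplicative** in the base composition. The default
  set representation is the *centered* covariance, which removes the
  mean count vector; class identity must therefore live in the
  *spread* of per-sequence compositions. A multiplicative tilt makes
  the between-sequence covariance ≈ τ²L²·diag(b)·C·diag(b) carry the
  class signature (an additive, base-independent tilt would make all
  classes' centered structures identical in expectation — a
  representable but degenerate design). This mirrors real segmented
  genomes, where segments are relative enrichments of a genome-wide
  composition.
* τ = 0.3 gives per-sequence compositions spanning roughly ±30%
  relative enrichment around the class base — comparable to the
  spread of nucleotide compositions across influenza segments — and is
  fixed once for all experiments.

The recovery experiments use two (or three) classes with bases such as
(0.4, 0.3, 0.2, 0.1) vs (0.1, 0.2, 0.3, 0.4), 8 sequences of 1 kb per
set, 10 sets per class, at length factor 100: sizes chosen so the whole
suite (including 10,000-replicate Monte-Carlo blocks) runs in about a
minute while the factor-100 counts (~10⁵ bases/sequence) are deep in
the convergent regime.

## Numerical choices

* **Symmetrization.** Covariance estimates and the difference inside
  `delta()` are explicitly symmetrized as (M + M′)/2 before the
  symmetric eigensolver.
* **Exact symmetry of δ.** `delta(A, B)` and `delta(B, A)` feed the
  solver the bitwise-identical matrix: the difference's sign is
  canonicalized (first nonzero entry in column-major order made
  positive) and the reported eigenvalue sign mapped back. Without
  this, LAPACK on M and −M can disagree in the last ulp.
* **Diagonal fast path.** If the (symmetrized) difference is exactly
  diagonal, the eigenvalues are its entries; `delta()` reads them off
  directly, making the closed form max|a_ll − b_ll| exact rather than
  exact-up-to-an-ulp.
* **Sign and tie conventions.** The reported eigenvector's first
  nonzero component is positive; when the extreme positive and
  negative eigenvalues tie in magnitude, the positive pair (in
  canonical orientation) is reported.
* **Degenerate covariance.** A single-sequence set has the zero matrix
  as its centered structure (not an error), so singleton sets remain
  comparable — δ then measures against the zero structure.
* **Centered vs uncentered.** `centered = TRUE` (sample covariance,
  divisor n − 1) is the default: real count data violate the
  zero-mean idealization under which the variance-covariance structure
  equals E[φ(X)φ(X)′]. The uncentered second moment `crossprod(F)/n`
  is retained as an option to match that algebra exactly.
* **2D projection.** Classical (Torgerson) MDS is implemented directly
  — double-centering, top-2 eigenpairs, √λ scaling — rather than
  delegated, to pin down the degenerate-input contract (non-positive
  eigenvalues give an exactly zero axis; an all-zero distance matrix
  gives all points at the origin) and the orientation convention
  (first nonzero coordinate per axis positive). `stats::cmdscale()`
  serves as the independent cross-check in the tests.
* **Clustering determinism.** `stats::hclust` on the precomputed δ
  matrix with average linkage (default); cluster numbers are
  re-assigned by first appearance in label order. The medoid of a
  dispersion map breaks ties by lexicographically smallest id.
* **I/O.** Distance matrices are written at 15 significant digits so a
  TSV round trip reproduces values far below the 1e-9 contract;
  FASTA output is wrapped at a fixed width and written in binary mode
  for byte determinism. Residues are uppercased on input; symbols
  outside the alphabet are dropped and counted per record rather than
  raising errors, since the feature vector counts alphabet words only.

## Open design choices

The serialization of a collection (one FASTA file = one set, one
directory = one class), the clustering algorithm (agglomerative,
average linkage), the concrete form of a dispersion map
(medoid-referenced distances plus embedding coordinates), and the
operationalization of composition convergence (TV distance on base
frequencies) are this package's choices: the underlying framework
specifies none of them. Dimension-raising composite transforms
(p′ > p) are supported but exercised only lightly — the standard
experiments use p′ = p.

## Limitations

* With 1-gram features, p′ = 4: sets differing only in higher-order
  word structure (e.g. dinucleotide order with identical base
  composition) are invisible; use `k_grams(alphabet, 2)` or larger
  word sets, at the cost of larger and noisier covariance estimates
  for small sets.
* δ compares covariance structures only; under the centered default,
  two sets whose sequences *spread* identically but around different
  mean compositions are close. The uncentered option (or a composite
  transform appending raw counts) restores mean sensitivity.
* The Chebyshev bounds for min/median are comparison formulas, not
  sharp order-statistic bounds.
* The simulator's i.i.d. model understates real within-sequence
  heterogeneity; limiting dispersion maps inherit that idealization.
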