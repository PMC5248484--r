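---
title: "Methods: normalized edit-distance embeddings of DNA sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalized edit-distance embeddings of DNA sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nedmap)
```

## Overview

`nedmap` visualizes collections of variable-length DNA sequences —
typified by standardized synthetic-biology parts, whose lengths span
hundreds to thousands of bases — by embedding a pairwise
*normalized edit-distance* matrix in two or three dimensions. This
vignette documents the model, the tunable parameters, the numerical
choices, and what the bundled synthetic benchmark does and does not
demonstrate.

## Distance model

The weighted edit distance between sequences $x_i$ and $x_j$ is computed
by the standard prefix dynamic program over a
$(|x_i|+1)\times(|x_j|+1)$ table with boundary $T[p,0]=p\,w_{del}$,
$T[0,q]=q\,w_{ins}$ and interior minimum over the deletion, insertion
and (mis)match branches. The weight quadruple
$(w_{ins}, w_{del}, w_{sub}, w_{mat})$ defaults to $(1,1,1,0)$ — the
Levenshtein distance. `edit_weights()` enforces $w_{mat}\le w_{sub}$:
otherwise the match branch would never be taken and the normalization
bound below would fail. The DP kernel is written in C++ (Rcpp); the
test suite pins it to a memo-free exhaustive edit-script enumeration on
all short strings over a two-letter alphabet and to base R's
generalized distance routine.

Raw edit distances confound dissimilarity with length: two unrelated
1000-base sequences are hundreds of operations apart simply because
they are long. We therefore divide by the longer length,

$$n_d(x_i, x_j) = \frac{d(x_i, x_j)}{\max(|x_i|, |x_j|)},$$

which lies in $[0,1]$ under default weights, is $0$ iff the sequences
are identical, and is $1$ when every position of the longer sequence
must be edited. **Caveat:** this normalization does not preserve the
triangle inequality in general, so $n_d$ is treated as a
dissimilarity, not a metric; the package asserts metric properties
(symmetry, identity, triangle inequality, the bound
$d \le \max(|x_i|,|x_j|)$) only for the *unnormalized* distance.

Input sequences are uppercased; symbols outside {A, T, C, G} are
rejected by default, with `"strip"` (remove them) and `"as-mismatch"`
(keep them, but they never match — not even themselves) available for
real-world FASTA files containing IUPAC ambiguity codes. Empty
sequences are rejected at load time, which also removes the undefined
$0/0$ case of $n_d$.

## Isomap on the distance matrix

1. **kNN graph.** Each point keeps its $K$ nearest neighbours (ties
   broken by distance, then index, for determinism); the directed
   selection is symmetrized by *union*, the standard choice that
   preserves connectivity better than intersection. Default
   $K = \mathrm{round}(0.30\,n)$, clamped to $[1, n-1]$ — the usual
   30-%-of-dataset setting for this kind of data.
2. **Geodesics.** All-pairs shortest paths on the graph, by
   Floyd–Warshall (reference implementation in the package). A
   per-source Dijkstra backend (igraph) is provided and must agree to
   $10^{-12}$; the suite checks this on random connected graphs.
3. **Eigen-embedding.** Geodesics are squared entrywise and
   double-centered into a Gram-like matrix, then eigendecomposed;
   coordinate $p$ is $\sqrt{\lambda_p}\,v_p$ for the $p$-th largest
   eigenvalue, so each embedding column's squared norm equals its
   eigenvalue.

**Centering variants.** `center_gram()` exposes two forms of the
additive constant: the textbook `"classical"` double centering
$-\tfrac12 J S^2 J$ (grand-mean last term), and a `"product"` variant
whose last term is the product of row sums $D_iD_j/n^2$. The default is
`"classical"` because it is the form that provably recovers a planted
Euclidean configuration from its distance matrix — the package's
MDS-limit test fails under the product form — while `"product"` is
retained as a selectable alternative.

**Indefiniteness.** Edit-distance geodesics are generally non-Euclidean,
so the centered matrix can have negative eigenvalues. Only strictly
positive eigenvalues are ever used ($\sqrt{\lambda}$ must be real); if
fewer than $k$ exist the error names the achievable dimension.

**Disconnection.** Whenever $K$ is smaller than the size of a tight,
well-separated group, that group's neighbour lists stay internal and
the kNN graph splits into one component per group — this *always*
happens for clearly distinct sequence families at the 30 % default, so
it is the common case, not a corner case. The default policy
`"connect"` therefore bridges components with the smallest available
original distances (one MST-style edge per merge), keeping all points
and preserving the between-group separation in the geodesics.
`"error"` (fail with a suggestion to increase $K$) and `"largest"`
(embed the largest component, reporting dropped ids) remain available;
silently dropping entire families would corrupt the visualization,
which is why `"largest"` is not the default.

## Laplacian Eigenmaps on the distance matrix

Affinities are the Gaussian kernel
$S_{ij} = \exp(-M_{ij}^2 / 2\sigma^2)$ applied to the *full* matrix —
no kNN sparsification — with bandwidth $\sigma = 0.3$ by default, a
value matched to the $[0,1]$ scale of $n_d$ (within-family distances
$\lesssim 0.1$ keep affinity $\approx 1$; between-family distances
$\gtrsim 0.5$ fall below $0.25$). Affinities for very distant pairs can
underflow to exact floating-point zero; this is an artifact of double
precision, not a thresholding rule (an optional `affinity_floor`
defaults to 0 = keep all).

The embedding eigendecomposes the *unnormalized* Laplacian
$G = D - S$, $D = \mathrm{diag}(\text{row sums})$, directly — the
generalized problem $Gv=\lambda Dv$ of the original spectral-embedding
literature is available via `generalized = TRUE`. Eigenvalues are
sorted ascending; the constant eigenvector(s) at eigenvalue 0 (exactly
one for a strictly positive kernel) carry no coordinates and are
discarded; the embedding is the next $k$ eigenvectors, unit length,
*without* eigenvalue scaling. $G$ is positive semidefinite with zero
row sums by construction, and both invariants are asserted in tests, as
is exact scale equivariance: $(cM, c\sigma)$ leaves $S$, $G$ and the
embedding unchanged.

## Determinism

Eigenvectors are defined only up to sign (and numerically, up to the
LAPACK build), so every returned eigenvector is flipped to make its
largest-magnitude entry positive. Together with the serial
upper-triangle distance sweep, deterministic tie-breaking in the kNN
selection, and seeded K-means, identical inputs and configuration
produce byte-identical artifact files; the suite verifies this
end-to-end.

## Clustering validation

K-means (Lloyd's algorithm, Euclidean distance) follows the classical
five-step procedure: sample $K$ data points as initial centroids,
assign to nearest, recompute means, repeat until the centroids are an
exact fixed point, with a 300-iteration cap guarding floating-point
cycling. The within-cluster sum of squares is asserted non-increasing
at every iteration. An emptied cluster is re-seeded at the point
farthest from its centroid rather than silently reducing $K$. The best
of 10 random restarts (by WCSS) is kept; a single seed governs all
initialization draws and is recorded in the report. The implementation
is cross-checked against `stats::kmeans(algorithm = "Lloyd")` in the
suite.

Accuracy against known labels is $\mathrm{sum}(c_i)/N$ with clusters
matched to labels *one-to-one* so that the total number of correctly
assigned samples is maximal. The matching is solved exactly as an
assignment problem (bitmask dynamic programming over the smaller side
of the contingency table) and verified against exhaustive permutation
enumeration; a many-to-one majority-vote accuracy is reported alongside
for diagnostics because the one-to-one convention is a choice, not a
law. Accuracy is invariant to any relabeling of clusters or classes.

## Synthetic benchmark

`synth_families()` emulates the regime of interest — several sequence
"types" with distinct length scales, high within-type similarity and
between-type dissimilarity — with the simplest generative model that
gives tunable separation: one uniform-random ancestor per family, and
members derived by per-position substitution (rate `sub_rate`, to a
uniformly random different base), per-position single-base indels
(`indel_rate`; delete or insert with equal probability), and a uniform
$\pm$`length_jitter` resizing. Defaults: three families of 60 members
with ancestor lengths 200/300/400 nt, `sub_rate = 0.02`,
`indel_rate = 0.01`, `length_jitter = 0.05` — mild divergence typical
of closely related variants, at a problem size (n = 180) that keeps the
full distance–embedding–validation pipeline to a couple of seconds on
one CPU.

What the benchmark shows: both embedding routes, at their default
parameters, place mutually dissimilar families in separable regions —
planted-family K-means accuracy reaches 1.0 for $k = 2$ and $k = 3$.
What it does not show: real part collections contain shared motifs,
composite parts that blend types, heterogeneous within-type divergence
and mislabeled records, so accuracies on real registries are expected
to be well below the synthetic ceiling; passing the planted-recovery
tests demonstrates correctness of the machinery, not real-data
performance. The generator draws independent random ancestors, whose
normalized distances concentrate near the random-string regime
($\approx 0.5$–0.6), which is the easy end of the between-type
spectrum.

## Numerical choices and limitations

* Distance matrices are validated to be symmetric (tolerance $10^{-9}$)
  with an exactly zero diagonal; the centered Gram matrix is explicitly
  symmetrized before eigendecomposition.
* Dense `eigen(symmetric = TRUE)` is used throughout: the contract is
  full-spectrum correctness at $n$ up to a few thousand, not sparse
  scalability.
* The trivial-eigenvector count in the Laplacian route is detected by
  eigenvalue magnitude *and* eigenvector constancy, with at least one
  always discarded.
* Distance TSV, embedding CSV and FASTA writers emit full-precision
  (`%.17g`) values and fixed layouts so write–read–write round-trips
  are byte-identical.
* Out of scope: alignment tracebacks and affine gaps; landmark/Nyström
  Isomap approximations and out-of-sample extension; normalized or
  random-walk Laplacians and diffusion maps; registry scraping.
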