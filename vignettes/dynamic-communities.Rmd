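---
title: "Detecting and comparing dynamic communities with elastic networks"
author: "dyncomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing dynamic communities with elastic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncomm)
```

## The model

A protein's equilibrium fluctuations can be approximated by an elastic
network: nodes (one C$\alpha$ per residue, or every heavy atom) joined by
identical Hookean springs whenever they lie within a distance cutoff
$r_c$. The Gaussian network model (GNM) further assumes isotropic Gaussian
fluctuations, so everything follows from the contact Kirchhoff matrix
$\Gamma$: $\Gamma_{ij} = -\gamma$ if $i \ne j$ and $\|x_i - x_j\| \le r_c$
(the cutoff is inclusive), $0$ otherwise, and
$\Gamma_{ii} = -\sum_{j \ne i}\Gamma_{ij}$. $\Gamma$ is a graph Laplacian:
singular, with one zero mode (the uniform vector) when the contact graph is
connected. Its pseudo-inverse over the $m$ lowest-frequency nonzero modes,
$\Gamma^{-1} = \sum_{i=1}^{m} \lambda_i^{-1} V_i V_i^{\top}$, is the
fluctuation covariance up to a constant, and the normalized cross-correlation
between nodes $i$ and $j$ is

$$\mathrm{DCC}_{\mathrm{GNM}}(i,j) =
  \frac{\Gamma^{-1}(i,j)}{\sqrt{\Gamma^{-1}(i,i)\,\Gamma^{-1}(j,j)}}.$$

From a trajectory the analogous quantity is the time average
$\mathrm{DCC}_{\mathrm{MD}}(i,j) = \langle \Delta r_i \cdot \Delta r_j
\rangle_t / \sqrt{\langle\|\Delta r_i\|^2\rangle_t
\langle\|\Delta r_j\|^2\rangle_t}$ with
$\Delta r_i(t) = r_i(t) - \langle r_i \rangle_t$. No mass weighting and no
frame superposition are applied — the formula is used exactly as written,
which means correlations computed from an unaligned trajectory conflate
internal motion with any rigid-body drift present in the input. Frames are
therefore expected to be pre-aligned if rigid-body motion matters; the
estimator itself is order-invariant (a pure time average).

*Dynamic communities* are blocks of residues that move cohesively. They are
obtained by transforming correlations to dissimilarities, $d = 1 -
\mathrm{DCC} \in [0, 2]$, clustering with WPGMA (weighted pair-group method
with arithmetic mean: the merged cluster's distance to any third cluster is
the unweighted mean of its two children's distances), and cutting the
dendrogram into $N_c$ communities by undoing the last $N_c - 1$ merges.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| $r_c$ (C$\alpha$) | 7.5 Å | spring cutoff for residue-level networks |
| $r_c$ (heavy atom) | 3.5 Å | spring cutoff for all-atom networks |
| mode subsets | 5, 10, 20, 30, 50 | low-frequency modes for $\Gamma^{-1}$ |
| $N_c$ | 2–10 | community counts evaluated |
| $\gamma$ | 1 | spring stiffness; cancels in normalized DCC |

The 7.5 Å residue-level cutoff sits in the range where C$\alpha$ contact
networks of globular proteins are well connected without being saturated;
the grid {6, 6.5, 7, 7.5, 8} is accepted by every function that takes
`rc`, but no automatic selection criterion is implemented — choosing $r_c$
per protein is a modelling decision, not something this package can decide
from a single structure. The stiffness $\gamma$ is exposed for completeness
only: it scales eigenvalues and cancels exactly in the normalized
correlations (the package guarantees this bitwise by diagonalizing the
integer unit-stiffness Laplacian and rescaling).

Low-frequency modes carry the collective, domain-scale motions; high
frequency modes describe local fluctuations and mostly add noise to the
correlation matrix, which is why the subset grid stops at 50 and why
agreement metrics typically converge by 20–30 modes. For proteins with
fewer than 51 nodes the grid is clipped to the $N-1$ available nonzero
modes with a warning.

## Comparing two correlation analyses

Three complementary metrics quantify agreement between correlation matrices
over the same nodes:

1. **Cohen's kappa between partitions.** For each $N_c$, communities are
   detected from both matrices and compared with
   $K = (p_o - p_e)/(1 - p_e)$. Community labels from independent
   clusterings are arbitrary, so the labels of one partition are first
   permuted to maximize the confusion-matrix trace (an exact assignment,
   solved by dynamic programming over label subsets — exact for
   $N_c \le 10$). Among tied assignments the one maximizing the matched
   marginal product is chosen; this makes the resulting kappa invariant to
   how either clustering happened to number its labels, which a bare
   max-trace rule does not guarantee. `kappaProfile()` reports kappa per
   $N_c$ and $Kappa_{max}$, taking the smallest $N_c$ on ties.
2. **Closeness centrality correlation.** Each protein becomes a complete
   weighted graph with edge weights $1 - \mathrm{DCC}$; closeness is the
   reciprocal of the summed shortest-path distances (Dijkstra, via igraph).
   The two centrality profiles are compared with Pearson correlation by
   default; Spearman is available as an option since the choice between
   them is a convention, not a property of the data.
3. **RMSIP.** Both matrices are decomposed by SVD and the $n$ leading
   singular vectors compared:
   $\mathrm{RMSIP} = \sqrt{\tfrac1n \sum_{ij} (V_i \cdot U_j)^2}$, which is
   1 for identical subspaces, 0 for orthogonal ones, and invariant to
   rotations of either basis within its own span. The vectors come from the
   DCC matrices themselves, not from a trajectory covariance, so the metric
   compares the *correlation structures* directly.

## Numerical choices

- **Inclusive cutoff**: contacts at exactly $r_c$ are connected. Some
  convention must be fixed for reproducibility; this one matches the
  defining inequality $R_{ij} \le r_c$.
- **Zero-mode tolerance**: eigenvalues below $10^{-10}\lambda_{max}$ count
  as zero. One zero mode means a connected network; more than one is
  reported as an error telling the user to raise $r_c$ or extract the
  largest connected component, because correlations of a disconnected
  network are meaningless.
- **WPGMA ties**: among pairs at (numerically) minimal distance — equal up
  to $10^{-12}$, absorbing last-ulp asymmetries of mathematically equal
  entries — the pair with the lexicographically smallest (minimum leaf
  index, then the other leaf index) merges first. Clustering libraries
  leave this to internals; a documented rule makes partitions reproducible
  across platforms. Consequently, partition-level agreement with other
  tools is expected only where no ties occur.
- **Cut semantics**: "cut into $N_c$ clusters" replays the first $N - N_c$
  merges rather than thresholding a height, so it is well defined even if
  merge heights were non-monotone (they cannot be for WPGMA, whose update
  is an average of distances each at least the current minimum, but the
  cut does not rely on that).
- **Canonical labels**: community 1 contains the lowest-index node, and so
  on, making partitions comparable across runs and serializations.
- **Degenerate inputs**: a node invisible to the chosen modes (zero
  diagonal in $\Gamma^{-1}$) and a trajectory node with zero variance are
  errors naming the node, not silent NaNs. A node at distance zero from
  all others gets infinite closeness with a warning.

## The mutant screen

For mutant-vs-wild-type comparisons the network keeps **all heavy atoms**
(hydrogens and heteroatoms excluded) with $r_c = 3.5$ Å, so a substituted
side chain actually changes the network. The atom-level DCC is reduced to
residue level by extracting the C$\alpha$ rows and columns — the
least-assumption reduction that keeps one node per residue; averaging over
all atom pairs of each residue pair is available as an alternative
(`method = "average"`), and the two agree exactly on block-constant input.
Wild-type and mutant are compared on their common residues (by chain,
residue number and insertion code; structures sharing fewer than half
their residues are rejected), and each mutant's kappa-vs-wild-type curve
is recorded per mode subset and $N_c$, with medians per stability class.

The packaged T4 lysozyme table divides 16 Arg96-region mutants at
$\Delta\Delta G = -2.6$ kcal/mol; the two boundary mutants fall on
opposite sides, so classes are carried as explicit data rather than
recomputed from the threshold ( `classifyStability()` returns `NA` exactly
at the boundary for the same reason). Running the real screen requires the
17 PDB entries, which are not distributed with the package;
`runMutscan()` takes any manifest of local files.

## What the synthetic fixtures emulate — and what they do not

`makeBeadProtein()` builds compact bead clusters (3.8 Å spacing, the
C$\alpha$ virtual bond length) joined by a single-contact linker, giving a
known two-block community structure: dense intra-domain connectivity,
minimal inter-domain coupling. `sampleGNMTrajectory()` draws i.i.d. frames
from the exact GNM covariance (per Cartesian axis, scaled so RMS
fluctuations are about 1 Å — the magnitude is realistic but cancels in
normalized correlations). Because the trajectory estimator is a pure time
average, independent frames are statistically sufficient: time correlation
would only slow convergence, not change the limit. By construction,
MD-style and GNM-style analyses provably agree on these fixtures, which is
what makes them useful as ground truth.

That is also their limitation. Real MD trajectories are anharmonic,
time-correlated, possibly under-sampled, and their correlations differ
from any harmonic model in the scale of inter-residue couplings. Passing
the fixture-based tests demonstrates that the estimators, the clustering
and the metrics are implemented correctly — not that GNM agrees with MD
for real proteins, which is an empirical question requiring real
trajectories. Problem sizes in the tests (fixtures of 20 beads, up to
20,000 frames, oracle sweeps over hundreds of small random instances) were
chosen as the smallest sizes at which the statistical contracts are sharp.

## A complete run

```{r example, eval = FALSE}
fx <- makeBeadProtein(fixtureSpec(seed = 1))
ms <- decomposeModes(buildKirchhoff(fx$model))
traj <- sampleGNMTrajectory(ms, coords(fx$model), nFrames = 20000,
                            seed = 1)
compareCorrelations(dccGNM(ms, 10, resKeys = resKeys(fx$model)),
                    dccMD(traj))
```

## Known limitations

- GNM is isotropic: it cannot resolve directional motion, only coupling
  magnitudes (the anisotropic variant is out of scope).
- No trajectory superposition is offered; rigid-body motion in the input
  contaminates the correlations.
- Selecting the "true" number of communities is unsolved; the package
  evaluates a range and reports $Kappa_{max}$ rather than pretending to
  know $N_c$.
- mmCIF and binary trajectory formats (DCD/XTC) are not read; inputs are
  PDB, multi-model PDB and plain frame tables.
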