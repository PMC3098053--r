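---
title: "Matching reduced SSE vector representations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching reduced SSE vector representations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ssematch)
```

## The model

A protein chain is reduced to an ordered list of typed unit vectors: one
vector per secondary-structure element (SSE), pointing along the element's
axis in the N-to-C direction, typed as `helix` or `strand`, and carrying
the element's residue length. Everything else -- loops, side chains, the
spatial *position* of each element -- is deliberately discarded. What
remains is a set of typed points on the unit sphere plus their order along
the sequence. The representation is tiny (a 20-SSE protein is 20 vectors),
which is what makes database-scale pre-filtering cheap.

Two representations $X$ ($N_x$ vectors $v_i$) and $Y$ ($N_y$ vectors
$w_j$) are compared by rotating $X$ as a whole. At a rotation $R$, every
same-type pair $(i, j)$ gets a Gaussian angular similarity

$$D_{ij}(R) = \mathbf{1}[\mathrm{type}_i = \mathrm{type}_j]\;
  \exp\!\left(-\theta_{ij}^2 / \delta^2\right),
  \qquad \theta_{ij} = \angle(R\,v_i,\, w_j) \in [0, \pi],$$

optionally multiplied by a length-mismatch factor
$\exp(-(\Delta L_{ij}/\mathrm{len\_tol})^2)$. The width $\delta$ (radians)
sets how sloppy an angular match may be. The match function is

$$F(R; X, Y) = -\sum_{ij} D_{ij}(R) \in [-N_x N_y,\, 0],$$

and good relative orientations are deep local minima of $F$ over the
rotation group. Directions are *not* identified with their negatives:
parallel and antiparallel strands are structurally different, and the
N-to-C orientation keeps them apart.

Two properties anchor the scale of $F$. First, for a self comparison with
well-separated vectors and $\delta \to 0$, the minimum tends exactly to
$-N$ (each vector matches only itself, perfectly). Second, for a uniform
(Haar) random rotation the angle between a rotated and a fixed unit vector
has density $\sin\theta / 2$, so the mean of each pair's similarity is the
one-dimensional integral

$$\bar D(\delta) = \tfrac12 \int_0^\pi e^{-\theta^2/\delta^2}
  \sin\theta \, d\theta,$$

computed by quadrature. The mean of $F$ over rotations is therefore
$-\bar D(\delta) \sum_{ij} \mathbf{1}[\mathrm{type\ match}]$ (weights
include the length factor when enabled), semi-analytically; only the
standard deviation of $F$ is estimated by Monte Carlo, using normalized
4-dimensional Gaussian quaternions, which are exactly Haar-distributed.
That yields the **rotational z-score**

$$z = \frac{F - \langle F \rangle_R}{\mathrm{sd}_R(F)},$$

a size-adjusted significance: a minimum is kept only when $z \le$
`z_cut` (default $-2$). The z-score alone is a purely geometric
significance and deliberately ignores sequence order.

```{r}
X <- random_representation(8, seed = 7)
p <- match_params(delta = 0.3)
stats <- rotation_statistics(X, X, p)
c(mean_F = stats$mean_F, std_F = stats$std_F, mean_pair = stats$mean_pair)
```

## Finding the minima

$F$ is smooth in the rotation, parameterized by unit quaternions, and is
minimized by steepest descent on the unit-quaternion sphere: the gradient
of $F$ with respect to the quaternion is computed analytically, projected
onto the tangent space of the sphere, and followed with a backtracking
line search; the iterate is renormalized after every step, so the $F$
sequence is monotone non-increasing. The analytic gradient (rather than
finite differences of the rotation) was chosen because it costs one pass
over the $N_x N_y$ pairs -- about four times cheaper per iteration than
central differences -- and has no step-size artifacts near the minimum;
the test suite verifies it against central differences.

Descent needs starting points. Initial guesses are built from vector
pairs: for every ordered query pair $(i, j)$ with $i < j \le i + m$
(default $m = 3$, a sequence-locality truncation) and every same-type,
same-order target pair $(k, l)$ with $k < l \le k + m$, the unique
rotation mapping $v_i$ onto $w_k$ and the plane of $(v_i, v_j)$ onto the
plane of $(w_k, w_l)$ is constructed from orthonormal frames. Nearly
collinear generator pairs (internal angle below `collinear_eps`, 5
degrees) are skipped as ill-conditioned, and near-duplicate rotations
(within `dedup_eps`, 5 degrees) are merged. Optionally, nearly parallel
same-type directions can first be *grouped* (single-linkage at
`group_eps`) to shrink the enumeration on bundle-rich structures.

One implementation parameter moderates cost: descent runs only from the
`max_starts` (default 16) initial guesses with the deepest starting $F$.
The guess built from a correctly corresponding pair starts essentially at
the minimum, so it always survives this screening; the knob exists to
keep database scans fast and can be raised for exhaustive searches.

After descent, converged rotations are deduplicated (keeping the deeper
$F$), z-scored, filtered by `z_cut`, and returned in order of ascending
$z$ by `collect_minima()`.

## From geometry to correspondence

A rotation minimum says two vector sets overlap geometrically, but not
*which element corresponds to which*. The similarity matrix $D(R)$ at the
minimum is treated as a substitution matrix, and a standard pairwise
dynamic-programming alignment finds the order-preserving map $M$ (strictly
increasing in both indices) maximizing the summed similarity with a
constant gap-*opening* penalty (default $-1$) and free extension. The
reported total aligned score

$$T(D) = \sum_{(i,j) \in M} D_{ij}$$

is the pure sum over matched pairs, excluding penalties: it counts, in
units of "perfectly matched SSEs", how much of the structures agrees both
geometrically *and* topologically. The default `semiglobal` mode leaves
end gaps free (natural for substructure search); `global` and `local`
modes are available. The DP is verified in the tests against brute-force
enumeration of all order-preserving maps.

```{r}
Y <- apply_rotation(X, rotation_axis_angle(c(1, 1, 0), 60))
mins <- collect_minima(X, Y, p)
aln <- align_sses(similarity_matrix(X, Y, mins[[1]]$rotation, p))
aln
```

## Flexible (two-rotation) matches

A hinge motion between two conformers breaks the single-rotation model:
each rigid domain needs its own rotation. `flexible_search()` takes the
`top_k` significant minima and considers every pair of rotations separated
by at least `min_separation` (15 degrees). For a candidate pair it builds
the entrywise maximum $D^{\max}_{ij} = \max(D_{ij}(R_1), D_{ij}(R_2))$ --
each SSE pair is scored by whichever rotation fits it better -- aligns
$D^{\max}$, and requires (i) *complementarity*: each rotation must own at
least one matched pair (otherwise one rotation explains everything and the
match is rigid), and (ii) a real gain: the combined $T$ must exceed the
best single-rotation $T$ by `flex_margin` (default 0.5, half of one
perfectly matched SSE). Since $D^{\max} \ge D$ entrywise, a bare "greater
than" could fire on numerical dust for rigidly related pairs; the margin
demands a substantive second domain. Admissible candidates are ranked by
the heuristic score $\left((|z_1| + |z_2|)/2\right) \cdot T(D^{\max})$.

```{r}
hp <- hinge_pair(12, split_index = 6, hinge_angle = 70, noise_sigma = 3,
                 seed = 11)
flexible_search(hp$a, hp$b, match_params(delta = 0.3))
```

## Parameters at a glance

| Parameter | Default | Units | Role |
|---|---|---|---|
| `delta` | 0.5 | radians | Gaussian width of the angular similarity; 0.3 (with `len_tol`) for conformer searches, 0.1 for exact-match tests |
| `len_tol` | off | residues | length-mismatch tolerance (Gaussian) |
| `m` | 3 | -- | sequence-locality truncation of initial-guess pairs |
| `gap_open` | -1 | score | gap-opening penalty; extension free |
| `align_mode` | semiglobal | -- | end-gap handling |
| `z_cut` | -2 | SD | significance threshold on rotation minima |
| `mc_samples` | 1000 | -- | Monte-Carlo size for $\mathrm{sd}_R(F)$ |
| `dedup_eps`, `collinear_eps` | 5 | degrees | rotation dedup / degenerate-pair filters |
| `max_starts` | 16 | -- | descent starts after screening by starting $F$ |
| `group_eps` | off | degrees | direction grouping before guess enumeration |
| `top_k`, `min_separation`, `flex_margin` | 10, 15, 0.5 | --, degrees, score | flexible-match search |

## Synthetic generators and their realism

The package ships generators used throughout the tests:
`random_representation()` (uniform directions on the sphere, types
Bernoulli, lengths uniform over 6--20 residues for helices and 3--10 for
strands), `perturb()` (each vector tilted by $|\mathcal N(0, \sigma)|$
about a random perpendicular axis), `hinge_pair()` (a block of vectors
rotated by a planted hinge angle, then perturbed), `decoy_database()`, and
`ideal_sse_pdb()` (ideal-geometry C-alpha traces with matching
HELIX/SHEET records, so the reduction pipeline can be exercised
end-to-end from file input).

These emulate sizes and noise levels, **not** protein realism: real folds
have strongly correlated SSE directions (helix bundles, sheets are nearly
parallel/antiparallel families) and packing constraints, while the decoys
are directionally independent. Consequences cut both ways. Scans against
uniform decoys are *easier* than against real folds for self-retrieval
(no decoy family mimics the query), and *harder* for observing the known
failure mode of ranking by z-score alone: with an exact copy of the query
in the database, the self match's z is far beyond what independent random
decoys reach by chance, whereas on real folds large structures with
correlated bundles can out-score small queries on pure geometry. Results
on these generators characterize the implementation (recovery, ranking,
statistics), not biological performance.

## Numerical choices

* **Quaternions over rotation matrices** for the search: 4 parameters, a
  smooth constraint surface, trivial renormalization, and exactly
  Haar-uniform sampling from normalized 4D Gaussians.
* **Semi-analytic mean, Monte-Carlo standard deviation** for the
  z-score: the mean has a one-dimensional quadrature form (above), while
  the variance couples pairs and is cheaper to estimate than to derive;
  1000 samples give the mean of $F$ to a few percent of its SD, and the
  Monte-Carlo mean is cross-checked against the quadrature mean in the
  tests.
* **Angle clamping**: dot products are clamped to $[-1, 1]$ before
  `acos`; the $\theta/\sin\theta$ factor in the gradient is guarded at
  $\theta \to 0$ (limit 1) and $\theta \to \pi$ (killed by the Gaussian
  for practical $\delta$).
* **Deterministic everything**: all stochastic steps run under a seed
  from `match_params()` and restore the caller's RNG state; scan reports
  are byte-identical across runs.

## Limitations

* SSE assignment is taken from HELIX/SHEET records or an external table;
  no geometric assignment (DSSP-style) is attempted. Structures without
  annotations need one of those sources.
* The representation ignores SSE positions entirely, so it is a
  *pre-filter*: structures passing it should be confirmed by full
  coordinate superposition.
* The alignment is order-preserving by construction; circular
  permutations and domain swaps will not align even when geometry agrees.
* Flexible search models exactly two rigid bodies; multi-hinge motions
  surface, at best, as the dominant two.
* Scan cost grows with the product of SSE counts; `group_eps` and
  `max_starts` trade completeness for speed on bundle-rich structures.
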