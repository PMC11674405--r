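---
title: "Graph spaces: embedding connectome nodes in invariant coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph spaces: embedding connectome nodes in invariant coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphspace)
```

## The model

A connectome is an undirected network whose nodes are parcellated brain
regions. Every nodal graph invariant (degree, betweenness, ...) assigns a
score to each node. `graphspace` treats each invariant as one axis of a
Euclidean space: after max-normalizing each invariant, a node becomes a
point whose coordinates are its normalized scores. With ten invariants,
each of a subject's $n$ regions is a point in a 10-dimensional *graph
space*.

Comparisons then reduce to geometry. The distance between homologous
regions of two subjects $x$ and $y$ is the Euclidean distance

$$d(x_i, y_i) = \sqrt{\sum_{k} (x_{i,k} - y_{i,k})^2},$$

where $k$ indexes invariants and $i$ a region. Aggregating $d$ over all
unordered subject pairs yields a pairs $\times$ regions distance table;
column means give per-region intersubject variability, row means a single
global distance per subject pair.

## The ten invariants and their conventions

`graph_properties()` lists the axes in their conventional order. The
implementation follows the defining formulas; where a formula admits
several community conventions the choice is stated here.

1. **Degree** — number of neighbors (nonzero entries), whatever the
   weights.
2. **Betweenness** — $\sum_{s \ne i \ne t} \sigma_{st}(i)/\sigma_{st}$
   over *unordered* pairs, endpoints excluded, unnormalized.
3. **Closeness** — inverse of the summed shortest-path length to every
   *reachable* node; isolated nodes score 0 with a warning.
4. **Eigenvector** — leading eigenvector of the adjacency, sign-fixed
   nonnegative, unit $L_2$ norm.
5. **Clustering** — realized fraction of edges among a node's neighbors,
   on the binary support; degree $< 2$ gives 0.
6. **Participation** — $1 - \sum_m (d_i(m)/d_i)^2$ over modules $m$.
7. **Within-module degree z-score** — within-module degree standardized
   by its module's mean and *population* SD; zero-spread modules
   (including singletons) give $z = 0$.
8. **PageRank** — fixed point of
   $C(i) = 1 - d + d\sum_s a_{is} C(s)/\deg(s)$ with damping $d = 0.85$,
   iterated to a $10^{-10}$ residual. In this scaling every node of a
   regular graph scores exactly 1. Dangling nodes score $1 - d$ and their
   outflow term is skipped.
9. **Average shortest path** — reciprocal of per-node global efficiency
   $E(i) = \frac{1}{n(n-1)} \sum_s 1/l_{is}$. The $1/(n(n-1))$
   normalization is kept as the default (a `per_node` variant with the
   common $1/(n-1)$ scaling is available); the two differ by the constant
   $n$, which the max-normalization cancels.
10. **Subgraph** — $\sum_j (x_j^i)^2 e^{\lambda_j}$, the diagonal of the
    matrix exponential of the adjacency.

**Weight semantics.** A connectome carries a `weight_kind`:

* `length` — weights *are* distances (e.g. fiber lengths in mm). Path
  measures use them directly; smaller is closer.
* `similarity` — weights are strengths/correlations. Path measures use
  reciprocal magnitude $1/|w|$ (the standard strength-to-length
  conversion; configurable in `invariant_config()`). Spectral measures
  (eigenvector, PageRank, subgraph) use $|w|$ by default, because signed
  matrices break the Perron–Frobenius structure those measures rely on.
* `binary` — unit lengths.

**Modules.** The participation coefficient and within-module z need a
partition. No particular community algorithm is canonical here, so three
modes are exposed (`detect_modules()`): Louvain modularity maximization
with a fixed seed and deterministic tie-breaking, the parcellation's RSN
labels, or a user-supplied partition passed through verbatim. The mode is
a configuration choice and is recomputed identically for null networks.

**Normalization.** Each property vector is divided by its maximum, scaling
the top node to 1. The rule is applied per subject and per property (a
pooled variant across subjects was considered and rejected as the default:
per-subject scaling keeps each subject's embedding self-contained, which
is what makes subject-pair distances comparable across ensembles). Two
degenerate cases are handled explicitly: an all-zero vector stays zero
(with a warning), and a negative maximum — possible only for the
within-module z-score — is divided through as printed, which can leave
values outside $[0, 1]$; this keeps the rule a single formula rather than
a case analysis.

## Connectome construction

`build_group_connectomes()` reproduces the four-model construction:

* consensus mask = dyads connected (nonzero streamline count) in *every*
  subject;
* group density = density of the mean fiber-length matrix under that mask;
* `Length-SCWEI` = each subject's length matrix thresholded to the group
  density keeping the *smallest* lengths (the most physically proximate,
  hence most reproducible, connections); `SCBIN` is its binarization —
  thresholding always precedes binarization;
* `FCWEI` = each functional matrix thresholded on |r| at the same density,
  *retaining the original signed correlations* on surviving edges (path
  measures then use $1/|r|$); `FCBIN` is its binarization.

Numerical conventions: density counts the $n(n-1)/2$ possible undirected
edges (no diagonal); the target edge count is round-half-up, applied
identically at group and subject level; ties at the cut are broken by
lexicographic $(i, j)$ order, making outputs byte-reproducible.
Thresholding may disconnect a graph; nothing is reconnected (a
`threshold = FALSE` mode passes matrices through untouched), and
unreachable pairs contribute 0 to efficiency sums and are excluded from
closeness sums, with warnings.

## Distances and their summaries

`intersubject_distances()` canonicalizes the subject-pair set (sorted
ids, $i < j$), so tables are identical whatever the input order.
`region_summary()` reports each region's mean, population SD, and mean/SD
ratio across pairs; an undefined ratio (zero SD) is `NA`, never 0.
`global_distance_sweep()` repeats threshold → invariants → embed →
distance across a density grid, averaging nodes first and then pairs (the
order is immaterial for plain means but is fixed for documentation);
densities at which the pipeline degenerates are flagged `NA` rather than
aborting the sweep.

## Null models and significance

Two randomization schemes calibrate observed distances:

* **Degree-preserving (Random 1)** — Maslov–Sneppen double-edge swaps;
  "five rewires" is interpreted as 5 swap-*attempt* passes per edge, the
  convention of the standard toolbox routines, and is a parameter. Degree
  sequences are conserved exactly, and weights travel with their edges.
* **Strength-preserving (Random 2)** — the support is rewired as above,
  then the original weight multiset is reassigned: weights in descending
  magnitude are placed on the free edge with the largest product of
  residual strengths, residuals shrinking as weights commit. Degrees are
  exact, total weight is conserved to machine precision, and node
  strengths correlate above 0.9 with the original. Signed matrices are
  handled through magnitudes. Re-ranking happens after every assignment
  by default; a batch frequency is exposed for speed.

For each region, the null distribution is the set of graph-space
distances between every unordered pair of null networks, each embedded
with the same pipeline configuration as the observed data — partitions
and invariants are recomputed per null network, so nothing observed leaks
into the null. The empirical p is the fraction of null distances
*strictly greater* than the observed mean intersubject distance; no
add-one smoothing is applied (fidelity to the defining "percentage above"
statistic over conservatism), so $p = 0$ is attainable. The comparison
uses the per-region *mean* observed distance, the natural reading of a
single observed line against a null histogram. Downstream, p-values are
Benjamini–Hochberg-binarized at an explicit level `q` (0.05 is only a
default and is echoed in outputs), and a complementary z screen
standardizes the observed value against the null mean and population SD
with a 1.96 gate.

## Classification

Nodes carry one of two superclass labels from the parcellation
(`subRSNs1`: limbic, frontoparietal, default mode, subcortical,
cerebellum; `subRSNs2`: visual, somatomotor, dorsal and ventral
attention). `prepare_dataset()` splits *subjects* — never rows — 70/30 by
default, stacking node coordinates into row matrices, so train and test
sides share no subject.

Three classifier families mirror the usual SVM/kernel/linear trio:
`"svm"` is a linear-kernel SVM, `"gaussian_kernel"` an RBF-kernel SVM
(both via `e1071`), and `"linear"` logistic regression. Hyperparameters
(cost; kernel scale for the RBF) are chosen on a small logged grid —
cost $\in \{0.1, 1, 10\}$, $\gamma \in \{0.5, 1, 2\}/p$ — by internal
5-fold cross-validation *within the training side only*, with
deterministic fold assignment and first-maximum tie-breaking; the chosen
values are recorded in each report. Tuning is re-run per feature subset
(re-optimizing once per model was the alternative; per-subset matches the
sweep semantics of comparing subsets on their own best footing). For
large sweeps `tune = FALSE` fixes cost 1 and $\gamma = 1/p$. AUC comes
from decision scores on the test side.

`dimension_sweep()` samples five distinct random property subsets per
dimension (2–9; dimension 10 is the single full set) under a fixed seed;
`combo_sweep()` enumerates all $\binom{10}{k}$ subsets, whose counts
(45, 120, 210, 252, 210, 120, 45, 10, 1 for $k = 2..10$) are exact
consequences of the procedure.

## Latent projections

`pca_latent()` is a column-centered PCA; loadings are orthonormal and
serve as biplot arrows for how each invariant contributes to a latent
axis. `laplacian_latent()` builds a *union* (symmetrized), unweighted
k-nearest-neighbor graph (k = 10 by default; neither the graph dialect
nor k is canonical, so both are recorded in the output) on graph-space
distances and uses the eigenvectors of the unnormalized Laplacian
$L = D - A$ for the smallest nonzero eigenvalues as coordinates,
dropping the constant kernel vector. A normalized-Laplacian variant sits
behind a flag. A disconnected kNN graph is flagged (component membership
is returned) but still embedded.

## The synthetic generator

`synthetic_spec()` describes a nine-block stochastic block model over 219
nodes by default (a 200-region cortical parcellation plus 19
subcortical/cerebellar regions), with blocks mapped to the nine RSNs and
the two superclasses wired differently: `subRSNs1` blocks are dense
within-module, `subRSNs2` blocks relatively denser between modules. This
emulates the two qualitative features the framework's analyses assume —
subnetwork block structure, and a superclass contrast between within- and
between-module connectivity that makes the two node bands separable in
graph space. Intersubject variation is a single dial $\varepsilon$: each
subject resamples every dyad from the block probabilities with
probability $\varepsilon$, so $\varepsilon = 0$ collapses the ensemble to
one network and increasing $\varepsilon$ provably increases expected
intersubject distance. Weighted variants attach lognormal
fiber-length-like weights (meanlog $\log 50$, sdlog 0.4 — positive,
right-skewed, millimeter-like) or $|r|$ correlation weights from a shared
3-factor latent model, both perturbed per subject in proportion to
$\varepsilon$. `simulate_tractography_pair()` produces coupled
streamline-count and length ensembles (identical supports, counts
$\ge 1$ Poisson-distributed) for exercising the group-model builder.

The default block probabilities (within 0.5/0.15, between 0.05/0.12 for
the two superclasses) give brain-like overall densities near 0.1 *at the
219-node scale*. They are per-dyad rates, so small test graphs need
proportionally denser settings to stay connected; test fixtures use
30-ish-node specs with within 0.9/0.55 and between 0.25/0.5 for that
reason. What the generator does **not** emulate: spatial geometry,
hemispheric symmetry, heavy-tailed degree distributions, measurement
noise correlated across dyads, or any biophysics of tractography and
BOLD. Passing tests therefore demonstrate that the machinery recovers
planted structure under the model's assumptions, not that real
connectomes satisfy those assumptions.

## Numerical choices

* **Symmetry tolerance** $10^{-9}$ on input matrices; the worst offending
  entry is named in the error.
* **Subgraph centrality overflow** — weighted matrices with large
  spectral radius (fiber lengths of tens of mm push $\lambda_{\max}$ into
  the thousands) overflow $e^{\lambda}$. The computation runs in log
  space; when raw values are unrepresentable the scores are returned
  pre-scaled to a maximum of 1, with a warning. The embedding is
  unaffected because it max-normalizes anyway.
* **PageRank** iterates to a $10^{-10}$ max-norm residual from the
  all-ones start.
* **Ties** — threshold cuts, CV-grid maxima and subset sampling all break
  ties deterministically (lexicographic order / first maximum / fixed
  seed).
* **Degenerate inputs** — empty-edge densities, single-class training
  labels, sub-3-node correlation scopes, zero null SDs and zero-variance
  PCA columns each produce a specific error, `NA`, or warning rather than
  silent propagation.
* **Seeds** — every stochastic step (generator, subject split, fold
  assignment, subset sampling, rewiring) takes an explicit seed and
  restores the caller's RNG state.

## Problem sizes

The test suite validates invariants against independent brute-force
oracles (Floyd–Warshall path censuses with path counting, triple-loop
clustering, truncated-series matrix exponentials, linear-solve PageRank)
on 50 random connected graphs of 6–12 nodes, binary and weighted, at
$10^{-8}$; statistical and recovery properties run on ensembles of 24–30
nodes and 4–6 subjects over 10 seeds, sizes at which every claimed
contrast is already decisive. The combinatorial contracts (4,950 subject
pairs; 15,330/6,570 split rows; 120/252/1 subsets; 499,500 null
distances) are exercised at their full stated sizes, since they cost
little. The acceptance script additionally runs the complete pipeline at
the full 219-node, 100-subject scale.

## Known limitations

* Pure-R rewiring loops make 1,000-network null ensembles comfortable at
  tens of nodes but slow at hundreds; the strength-preserving re-ranking
  is $O(m^2)$ at its default full-fidelity setting (use
  `rerank_frequency` to batch).
* Eigenvector centrality on disconnected graphs concentrates on the
  dominant component (a warning is raised); the other components' scores
  are near zero, which the max-normalization preserves.
* Hold-out (not K-fold) evaluation is intentional, matching the design
  being implemented; K-fold would reduce variance of the reported
  accuracies.
* The linear classifier is unregularized logistic regression; perfectly
  separable training sets produce the usual separation warnings, which
  are suppressed, and decision scores remain usable for AUC.
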