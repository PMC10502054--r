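---
title: "Topological classification of simulated multicellular patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological classification of simulated multicellular patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`TopoCellSort` simulates mixtures of motile cells as self-propelled
particles in a square periodic box and asks whether the spatial patterns
they form — driven purely by differential adhesion — can be recognized
without supervision from topological summaries of the cell positions.

Each cell i obeys overdamped dynamics

$$x_i^{t+\Delta t} = x_i^t + \frac{\Delta t}{\eta}\Big(P_i^t +
\sum_{j \ne i} F_{ij}^t\Big),$$

with friction $\eta = 1$, time step $\Delta t = 0.02$, and a
self-propulsion force $P_i$ of fixed magnitude $0.005$ whose direction is
redrawn uniformly every 2500 steps (per-cell phase offsets prevent
synchronized "tumbles"). Cells within the neighbourhood radius
$r_{max} = 1.5$ interact through the gradient of a Morse potential

$$U(r) = -J_{ij}\left[e^{-r/l_A} - \tfrac14 e^{-r/l_R}\right],
\qquad l_A = 14,\; l_R = 0.5,$$

whose single well sits at $r^\ast \approx 1.009$ — the preferred spacing
of adjacent cells. The pair magnitude $J_{ij} = J(T(i), T(j))$ depends
only on the two cell types: for two types ("blue", "orange") the model is
controlled by the triple $(J_{BB}, J_{OO}, J_{BO})$ of homotypic and
heterotypic adhesion strengths. Two hundred cells (60% blue, 40% orange)
are placed uniformly with a minimum separation of 1 in the
$[-20, 20]^2$ box. Depending on the relative adhesion strengths, the
population disperses, sorts into monotype clusters, intermixes, or forms
stripes, hexagonally arranged spots, core–shell arrangements or
labyrinths.

With proliferation enabled, each cell carries a division clock
(80 000 steps per cycle, initialized uniformly at random so divisions are
staggered) and divides only while it has at most four neighbours within
$r_{max}$ — contact inhibition. One daughter keeps the mother's position
and polarization; the other is placed 0.25 length units away in a random
direction with the opposite polarization. The neighbour definition
reuses $r_{max}$ because it is the only interaction radius in the model;
the cap of four is configurable because the boundary case is genuinely
ambiguous (one source statement excludes "more than four", another
"four or more" — we allow exactly four).

Numerical notes: forces for one step are accumulated over all pairs
before any position is updated (synchronous update); pair separations use
the minimum-image convention, which is the natural reading of periodic
boundaries; coincident cells (never generated in practice, as the
potential is repulsive at short range and finite at zero) exert no force
on each other because the direction is undefined. A cell-list grid at
$r_{max}$ granularity makes stepping O(N). All randomness flows through
R's RNG, so a configuration plus seed reproduces a run bit for bit.

# Topological featurization

Cell positions of one channel (blue cells, orange cells, or all cells)
are summarized by persistent homology of the Vietoris–Rips filtration on
Euclidean distances: dimension 0 tracks when isolated cells merge into
connected components, dimension 1 tracks loops that enclose empty
regions. The engine is implemented in the package (union-find for
dimension 0, GF(2) boundary-matrix reduction over the triangle boundary
for dimension 1) and is checked, on small instances, against a completely
independent plain-R full-boundary-matrix reduction and against
single-linkage dendrogram heights.

The filtration is capped at 3.0 — twice the interaction cutoff — because
the structural scales of interest (cell spacing near 1, loops a few cell
diameters wide) fall well below it, and the cap bounds the simplex count.
Components and loops still alive at the cap are recorded as intervals
ending at the cap by default ("cap" convention), which keeps the
dimension-0 interval count equal to the number of points; the "drop"
convention is available.

Diagrams are vectorized as **persistence images**: each interval
contributes a Gaussian weighted by its lifespan (end − start). For
dimension 0 every interval starts at 0, so centring the Gaussians at the
interval *start* would stack all mass at one location; the package
therefore centres dimension-0 Gaussians at the interval *end* (the merge
scale), producing an informative 1-D profile. For dimension 1 the diagram
is transformed to (start, persistence) coordinates and rasterized in 2-D.
The lifespan weight is used as displayed in the defining formula; the
alternative distance-to-diagonal weight differs only by the constant
$\sqrt2$, which no downstream stage can detect. Defaults — bandwidth
$\sigma = 0.1$ filtration units, domain $[0, 3]$, 100 pixels (1-D) and
20×20 pixels (2-D) — resolve features at the inter-cell spacing scale.
Images can be normalized by their maximum intensity, which removes the
dependence of absolute intensity on the number of cells; an all-zero
image is left unchanged. **Persistence curves** (Betti, life, and a
Gaussian variant that sums lifespan-weighted Gaussian densities centred
at interval midpoints) are provided as the cheaper alternative
featurization, and classical order parameters — the pair-correlation
function g(r) and the hexatic bond-orientational statistic $\psi_6$ —
as the non-topological baseline.

# Embedding, clustering, scoring

Feature vectors (one per simulated condition) are standardized per
column, reduced to a 20-dimensional latent space, clustered with Ward
linkage, and the dendrogram is cut at the number of phases in the
taxonomy. Accuracy against ground truth is computed under the optimal
one-to-one cluster-to-phase assignment (Hungarian algorithm, verified
against exhaustive enumeration for small cluster counts), making the
score invariant to arbitrary relabelings.

Four reducers are available: PCA (deterministic), UMAP (via `uwot`), a
diffusion-potential embedding (Gaussian affinities with adaptive
bandwidth, row-normalized and diffused, classical MDS on log-potential
distances), and a dense autoencoder written in the package: a symmetric
tanh network (defaults 256–64 hidden units around the 20-d linear
bottleneck) trained full-batch with Adam on mean squared reconstruction
error. Sample sizes here are tens to hundreds of conditions, so
full-batch training is stable and fast; the first/final loss pair is
attached to the embedding so convergence can be asserted. A soft-margin
RBF support vector machine with stratified five-fold cross-validation
provides the supervised cross-check.

# Ground truth: the regime rule table

The phase taxonomy (12 labels i–xii at constant population size; 10
labels v–vii, ix–xv with proliferation) originates from manual annotation
of simulation endpoints. As a reproducible surrogate, the package ships
an ordered rule table (`inst/extdata/regime_rules.json`) of predicates
over $(J_{BB}, J_{OO}, J_{BO})$ transcribing the threshold statements
that delimit each regime (e.g. dispersed phases require heterotypic and
homotypic adhesion below 0.03; labyrinths require orange–orange adhesion
comparable to heterotypic with weaker blue–blue). First match wins, a
catch-all guarantees totality, and the file is data so users can refine
boundaries. Parameter triples near regime boundaries are genuinely
ambiguous — the original annotation acknowledges mixtures there — so the
table resolves them by the order in which the regimes are described.

# The synthetic pattern generator

`generatePattern()` builds the canonical pattern classes directly
(dispersed, sorted, intermixed, checkerboard, stripes, hexagonal spots,
core–shell, labyrinth) with exact geometry at zero noise and Gaussian
positional jitter otherwise. It exists so every downstream stage can be
exercised deterministically in seconds. It emulates the *geometry* of
simulation endpoints, not their physics: lattice-based fixtures are more
regular than any simulated pattern, blob-based fixtures have sharper
boundaries, and there is no analogue of partially coarsened intermediate
states. Tests passing on fixtures therefore demonstrate that the
featurization–embedding–clustering chain distinguishes well-formed
pattern classes; they do not by themselves establish accuracy on noisy,
partially equilibrated simulations.

# Problem sizes and the desk-scale protocol

The published experiments sweep 512 adhesion triples (constant
population; 8 values per axis) and 216 triples (proliferation; 6 values
per axis) with three replicates of 200 cells for 5 000 000 steps each —
weeks of compute. The package's desk-scale protocol
(`runReducedProtocol()`) uses 4 values per axis (64 triples, the values
of the four representative parameter-plane slices), 100 cells, one
replicate and 200 000 steps, with the box shrunk to halfwidth
$20\sqrt{100/200} \approx 14.14$ so the number density matches the
published conditions. At this scale the full pipeline runs in minutes.

The price of the shortened runs is equilibration. Adhesive binding is
fast (a pair falls into the Morse well within a few thousand steps), but
pattern formation proceeds by cluster diffusion and merging, which is
slow: simulated populations that are essentially sorted after
5 000 000 steps (same-type 4-nearest-neighbour purity above 0.95) are
still fine-grained mixtures of 2–8-cell clusters at 200 000 steps
(purity near 0.55), and reported equilibration times with proliferation
are of order 8–10 cell cycles (≥ 640 000 steps). Desk-scale
classification accuracies are therefore substantially lower than
published full-scale values, and the package reports them as what they
are: the same pipeline applied to earlier, less developed configurations.
Accuracy recovers as `nSteps` grows toward the published duration, which
can be verified with the same function given more compute.

# Known limitations

* The regime rule table is a surrogate for manual annotation; accuracy
  against it measures agreement with the transcribed phase map, not with
  the original authors' eyes.
* Dimension-1 features of sparse dispersed patterns are nearly empty, so
  channels with few cells carry little H1 signal — one reason orange-only
  classification trails blue-only and both-channel classification.
* The model itself omits cell shape, interfacial tension and
  contractility; patterns requiring those mechanisms are out of reach.
* The order-parameter baseline uses the standard pair-correlation and
  hexatic definitions; the exact order parameters used for published
  baseline accuracies are not specified in the available text, so those
  numbers are not exactly reproducible.

# A worked example

```{r, eval = FALSE}
library(TopoCellSort)

cfg <- simulationConfig(nCells = 100, nSteps = 2e5,
                        boxHalfwidth = 20 * sqrt(0.5), seed = 1)
pop <- runSimulation(cfg, adhesionTable(JBB = 0.25, JOO = 0.25, JBO = 0))
neighborPurity(pop)

dgs <- computeDiagrams(positions(pop), cellTypes(pop), channel = "both")
img <- persistenceImage(dgs$H1)

res <- runReducedProtocol(proliferation = FALSE, baseSeed = 1,
    featureSets = list(H1_both = list(channels = "both", dims = 1)))
res$accuracies
```
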