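# TopoCellSort

Unsupervised, topology-based classification of multicellular spatial
patterns formed by two interacting cell types under differential adhesion.

Mixtures of motile cells sort, intermix, stripe, or arrange into
hexagonal spots and core–shell clusters depending on how strongly each
cell type adheres to itself versus the other type. Recognizing these
patterns automatically — without hand-crafted features or labels — is the
problem this package addresses, for computational biologists studying
tissue self-organization and for anyone who needs to classify labeled 2-D
point patterns.

The package has two halves:

1. **An agent-based simulator.** Cells are self-propelled particles in a
   periodic box obeying overdamped dynamics
   `x_i(t+Δt) = x_i(t) + (Δt/η)(P_i + Σ_j F_ij)`, with a constant-magnitude
   polarization force `P_i` redrawn every 2500 steps, and pair forces from
   a Morse potential `U(r) = −J_ij [exp(−r/l_A) − ¼ exp(−r/l_R)]`
   (`l_A = 14`, `l_R = 0.5`, cutoff `r_max = 1.5`) whose magnitude
   `J_ij = J(T(i), T(j))` depends on the cell-type pair — the
   `(J_BB, J_OO, J_BO)` adhesion triple is the control parameter.
   Optional contact-inhibited proliferation: cells divide on an internal
   80 000-step clock unless more than four neighbours sit within `r_max`.
2. **A topological classification pipeline.** Vietoris–Rips persistent
   homology of the cell positions per channel (blue, orange, or both) is
   vectorized as dimension-0/1 persistence images
   `PI = Σ (end−start)·g(center, σ)` (or Betti/life/Gaussian persistence
   curves; pair-correlation g(r) and hexatic ψ₆ order parameters are the
   classical baseline), embedded to a 20-d latent space (autoencoder,
   PCA, UMAP, diffusion potential), Ward-clustered with the dendrogram cut
   at the phase-taxonomy size, and scored against an adhesion-regime rule
   table by optimal cluster-to-phase assignment.

The persistence engine (union-find for components, GF(2) boundary-matrix
reduction for loops), the autoencoder, the Hungarian assignment and the
regime rule table are implemented in the package; standard statistics go
through base R and e1071.

## Worked example

```r
library(TopoCellSort)

# sort two cell types: strong homotypic, zero heterotypic adhesion
cfg <- simulationConfig(nCells = 60, nSteps = 5e6,
                        boxHalfwidth = 20 * sqrt(60 / 200), seed = 7)
pop <- runSimulation(cfg, adhesionTable(JBB = 0.25, JOO = 0.25, JBO = 0))
neighborPurity(pop)
#> [1] 0.9583333

# loops of a hexagonal-spot fixture, seen by persistent homology
pat <- generatePattern("hex_spots", nCells = 400, seed = 1)
dgs <- computeDiagrams(pat, channel = "both")
dgs$H1
#> PersistenceDiagram: H1, channel 'both', 159 intervals (cap 3)
```

`neighborPurity` is the mean fraction of same-type cells among each
cell's four nearest neighbours: 0.5–0.6 for a mixed configuration, 0.96
here, i.e. the two types have sorted into essentially pure clusters. The
H1 diagram records topological loops: each interval is a loop that
appears at filtration scale `start` and fills in at `end`; the hexagonal
arrangement of spots produces many mid-scale loops, which is exactly the
signature the persistence images hand to the classifier.

End-to-end, `runReducedProtocol()` simulates a sweep over adhesion
triples, featurizes each endpoint, embeds, clusters, and reports accuracy
against the regime rule table (see `?runReducedProtocol`).

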