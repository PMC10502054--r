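#' Adhesion sweep grids
#'
#' Default axis values of the two parameter sweeps. At constant population
#' size each of J_BB, J_OO, J_BO takes 8 values including two near-zero
#' entries, giving 512 parameter triples; with proliferation the two
#' near-zero values are excluded (low-adhesion simulations do not reach a
#' steady state on comparable timescales), giving 6 values per axis and 216
#' triples. \code{reduced = TRUE} selects the 4-value-per-axis subgrids used
#' by the desk-scale classification protocol (the values of the four
#' representative parameter-plane slices).
#'
#' @param proliferation scenario switch.
#' @param reduced use the 4-value reduced axes.
#' @return Numeric vector of axis values.
#' @export
sweepAxisValues <- function(proliferation = FALSE, reduced = FALSE) {
    if (proliferation) {
        if (reduced) c(0.05, 0.09, 0.13, 0.25)
        else c(0.05, 0.09, 0.13, 0.17, 0.21, 0.25)
    } else {
        if (reduced) c(0, 0.05, 0.13, 0.25)
        else c(0, 0.001, 0.05, 0.09, 0.13, 0.17, 0.21, 0.25)
    }
}

#' @param values axis values; defaults to [sweepAxisValues()].
#' @rdname sweepAxisValues
#' @return For \code{sweepGrid}, a data.frame of all (J_BB, J_OO, J_BO)
#'   triples.
#' @export
sweepGrid <- function(proliferation = FALSE, reduced = FALSE,
                      values = sweepAxisValues(proliferation, reduced)) {
    g <- expand.grid(J_BB = values, J_OO = values, J_BO = values,
                     KEEP.OUT.ATTRS = FALSE)
    g[order(g$J_BB, g$J_OO, g$J_BO), , drop = FALSE] -> g
    rownames(g) <- NULL
    g
}

#' Run every simulation of a sweep manifest
#'
#' Executes one simulation per manifest row (seeded per row) and returns
#' the final configurations in memory; optionally also writes each to its
#' manifest path.
#'
#' @param manifest from [sweepManifest()].
#' @param config a [simulationConfig()]; its seed is replaced by each row's
#'   seed.
#' @param writeFiles write positions tables to the manifest paths.
#' @param verbose print one progress line per condition.
#' @return List of [CellPopulation-class], one per row, with the manifest
#'   as attribute "manifest".
#' @export
runSweep <- function(manifest, config, writeFiles = FALSE, verbose = FALSE) {
    pops <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
        row <- manifest[i, ]
        cfg <- config
        cfg@seed <- row$seed
        pop <- runSimulation(cfg, adhesionTable(row$J_BB, row$J_OO,
                                                row$J_BO))
        if (writeFiles) {
            dir.create(dirname(row$output_path), recursive = TRUE,
                       showWarnings = FALSE)
            writePositions(pop, row$output_path)
        }
        pops[[i]] <- pop
        if (verbose)
            message(sprintf("[%d/%d] J=(%g,%g,%g) N=%d", i, nrow(manifest),
                            row$J_BB, row$J_OO, row$J_BO, nCells(pop)))
    }
    attr(pops, "manifest") <- manifest
    pops
}

#' Featurize every configuration of a sweep
#'
#' Applies [buildFeatureVector()] to each final configuration and stacks
#' the results into a samples-by-features matrix.
#'
#' @param populations list of [CellPopulation-class] or data.frames
#'   (x, y, cell_type).
#' @param ... passed to [buildFeatureVector()].
#' @return Feature matrix with attribute "provenance".
#' @export
featurizeSweep <- function(populations, ...) {
    rows <- lapply(populations, function(p) {
        df <- if (is(p, "CellPopulation"))
            data.frame(x = p@positions[, 1], y = p@positions[, 2],
                       cell_type = as.character(p@types))
        else p
        buildFeatureVector(df, ...)
    })
    out <- do.call(rbind, rows)
    attr(out, "provenance") <- attr(rows[[1]], "provenance")
    out
}

#' Embed, cluster and score one feature set
#'
#' The downstream half of the pipeline: reduce the feature matrix to
#' \code{latentDim} dimensions, Ward-cluster at the taxonomy size, and
#' score against ground-truth labels under optimal label assignment.
#'
#' @param features samples-by-features matrix.
#' @param truth ground-truth phase labels (factor or character).
#' @param method embedding method for [reduceDimension()].
#' @param latentDim embedding width (default 20).
#' @param nClusters dendrogram cutoff; defaults to the number of distinct
#'   truth labels.
#' @param seed RNG seed for the embedding.
#' @param ... further arguments for [reduceDimension()].
#' @return List: accuracy, clusterLabels, embedding.
#' @export
classifySweep <- function(features, truth, method = "autoencoder",
                          latentDim = 20, nClusters = NULL, seed = 1, ...) {
    truth <- factor(truth)
    if (is.null(nClusters)) nClusters <- nlevels(droplevels(truth))
    emb <- reduceDimension(features, method = method,
                           latentDim = latentDim, seed = seed, ...)
    cl <- clusterHierarchical(emb, nClusters)
    list(accuracy = accuracyVsTruth(cl, truth), clusterLabels = cl,
         embedding = emb)
}

#' Reduced-sweep classification protocol
#'
#' Runs the complete desk-scale protocol for one scenario: simulate the
#' reduced sweep (4 values per adhesion axis, one replicate), featurize the
#' final configurations as persistence images for each requested channel
#' set, then embed (autoencoder, 20-d), Ward-cluster at the taxonomy size
#' and score against the regime-rule labels. The reduced protocol keeps the
#' published number density by shrinking the box to halfwidth
#' \code{20 * sqrt(nCells / 200)}.
#'
#' @param proliferation scenario switch.
#' @param nCells initial cell count (default 100).
#' @param nSteps steps per simulation (default 2e5).
#' @param baseSeed integer seed controlling the whole protocol.
#' @param featureSets named list; each element is a list with elements
#'   \code{channels} and \code{dims} (and optionally \code{normalize})
#'   passed to [buildFeatureVector()].
#' @param method,latentDim embedding settings.
#' @param verbose progress output.
#' @return List with elements \code{accuracies} (named numeric, one per
#'   feature set), \code{truth}, \code{manifest}, \code{populations}.
#' @export
runReducedProtocol <- function(proliferation = FALSE, nCells = 100,
        nSteps = 2e5, baseSeed = 1,
        featureSets = list(H1_both = list(channels = "both", dims = 1)),
        method = "autoencoder", latentDim = 20, verbose = FALSE) {
    grid <- sweepGrid(proliferation, reduced = TRUE)
    manifest <- sweepManifest(grid, replicates = 1, baseSeed = baseSeed)
    cfg <- simulationConfig(nCells = nCells, nSteps = nSteps,
        boxHalfwidth = 20 * sqrt(nCells / 200),
        proliferationEnabled = proliferation)
    pops <- runSweep(manifest, cfg, verbose = verbose)
    truth <- regimeLabel(grid$J_BB, grid$J_OO, grid$J_BO, proliferation)
    acc <- vapply(names(featureSets), function(nm) {
        fs <- featureSets[[nm]]
        feats <- featurizeSweep(pops, channels = fs$channels,
            dims = fs$dims,
            normalize = isTRUE(fs$normalize))
        classifySweep(feats, truth, method = method, latentDim = latentDim,
                      nClusters = length(taxonomyLabels(proliferation)),
                      seed = baseSeed)$accuracy
    }, numeric(1))
    list(accuracies = acc, truth = truth, manifest = manifest,
         populations = pops)
}
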