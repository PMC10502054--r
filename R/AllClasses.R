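#' Simulation configuration
#'
#' Parameters of the self-propelled particle model. Defaults reproduce the
#' published study conditions: a \eqn{[-20, 20]^2} periodic box, friction
#' \eqn{\eta = 1}, time step \eqn{\Delta t = 0.02}, polarization force
#' magnitude \eqn{|P| = 0.005} redrawn every 2500 steps, Morse potential with
#' attraction length \eqn{l_A = 14}, repulsion length \eqn{l_R = 0.5},
#' repulsion scaled to 1/4 of the attraction, interaction cutoff
#' \eqn{r_{max} = 1.5}, and 200 cells (60\% blue, 40\% orange) initialized
#' with a minimum separation of 1. With proliferation enabled, cells divide
#' on an internal clock of 80000 steps, contact-inhibited when more than
#' four neighbours lie within \code{rMax}.
#'
#' @slot boxHalfwidth half-width of the square periodic domain.
#' @slot dt integration time step.
#' @slot eta friction coefficient.
#' @slot polarizationMagnitude magnitude of the self-propulsion force.
#' @slot repolarizationPeriod steps between polarization redraws.
#' @slot nSteps number of time steps to integrate.
#' @slot rMax interaction (and neighbourhood) cutoff distance.
#' @slot lA Morse attraction length scale.
#' @slot lR Morse repulsion length scale.
#' @slot repulsionRatio scaling of the repulsion term relative to attraction.
#' @slot nCells initial number of cells.
#' @slot typeFractions named proportions per cell type (must sum to 1).
#' @slot proliferationEnabled logical; division on/off.
#' @slot cellCycleSteps steps between divisions of one cell.
#' @slot maxNeighborsForDivision division proceeds iff the neighbour count is
#'   at most this value.
#' @slot minInitSeparation minimum pairwise distance at initialization.
#' @slot daughterOffset distance at which a new daughter cell is placed.
#' @slot seed integer RNG seed (NA to leave the RNG state untouched).
#' @export
setClass("SimulationConfig",
    representation(boxHalfwidth = "numeric", dt = "numeric", eta = "numeric",
        polarizationMagnitude = "numeric", repolarizationPeriod = "numeric",
        nSteps = "numeric", rMax = "numeric", lA = "numeric", lR = "numeric",
        repulsionRatio = "numeric", nCells = "numeric",
        typeFractions = "numeric", proliferationEnabled = "logical",
        cellCycleSteps = "numeric", maxNeighborsForDivision = "numeric",
        minInitSeparation = "numeric", daughterOffset = "numeric",
        seed = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (object@eta <= 0) msg <- c(msg, "eta must be > 0")
    if (object@rMax <= 0) msg <- c(msg, "rMax must be > 0")
    if (object@nCells < 1) msg <- c(msg, "nCells must be >= 1")
    if (object@cellCycleSteps < 1) msg <- c(msg, "cellCycleSteps must be >= 1")
    if (abs(sum(object@typeFractions) - 1) > 1e-8)
        msg <- c(msg, "typeFractions must sum to 1")
    if (is.null(names(object@typeFractions)))
        msg <- c(msg, "typeFractions must be named by cell type")
    if (length(msg)) msg else TRUE
})

#' @param boxHalfwidth,dt,eta,polarizationMagnitude,repolarizationPeriod,nSteps
#'   see slot documentation.
#' @param rMax,lA,lR,repulsionRatio,nCells,typeFractions,proliferationEnabled
#'   see slot documentation.
#' @param cellCycleSteps,maxNeighborsForDivision,minInitSeparation see slots.
#' @param daughterOffset,seed see slot documentation.
#' @return A \code{SimulationConfig} object.
#' @examples
#' cfg <- simulationConfig(nCells = 50, nSteps = 100, seed = 1)
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(boxHalfwidth = 20, dt = 0.02, eta = 1,
        polarizationMagnitude = 0.005, repolarizationPeriod = 2500,
        nSteps = 5e6, rMax = 1.5, lA = 14, lR = 0.5, repulsionRatio = 1 / 4,
        nCells = 200, typeFractions = c(blue = 0.6, orange = 0.4),
        proliferationEnabled = FALSE, cellCycleSteps = 80000,
        maxNeighborsForDivision = 4, minInitSeparation = 1,
        daughterOffset = 0.25, seed = NA_real_) {
    new("SimulationConfig", boxHalfwidth = boxHalfwidth, dt = dt, eta = eta,
        polarizationMagnitude = polarizationMagnitude,
        repolarizationPeriod = repolarizationPeriod, nSteps = nSteps,
        rMax = rMax, lA = lA, lR = lR, repulsionRatio = repulsionRatio,
        nCells = nCells, typeFractions = typeFractions,
        proliferationEnabled = proliferationEnabled,
        cellCycleSteps = cellCycleSteps,
        maxNeighborsForDivision = maxNeighborsForDivision,
        minInitSeparation = minInitSeparation,
        daughterOffset = daughterOffset, seed = as.numeric(seed))
}

#' Symmetric per-type-pair adhesion magnitudes
#'
#' Holds the matrix \eqn{J(T(i), T(j))} scaling the Morse potential for every
#' ordered pair of cell types.
#'
#' @slot J symmetric nonnegative matrix with cell-type dimnames.
#' @export
setClass("AdhesionTable", representation(J = "matrix"))

setValidity("AdhesionTable", function(object) {
    J <- object@J
    msg <- character()
    if (nrow(J) != ncol(J)) msg <- c(msg, "J must be square")
    if (any(J < 0)) msg <- c(msg, "adhesion magnitudes must be >= 0")
    if (!isTRUE(all.equal(J, t(J)))) msg <- c(msg, "J must be symmetric")
    if (is.null(rownames(J))) msg <- c(msg, "J must carry cell-type dimnames")
    if (length(msg)) msg else TRUE
})

#' @param JBB,JOO,JBO homotypic blue-blue, homotypic orange-orange and
#'   heterotypic blue-orange adhesion magnitudes (two-type shortcut).
#' @param J optionally, a full symmetric K x K matrix with type dimnames;
#'   overrides the scalar arguments.
#' @param types cell-type names for the two-type shortcut.
#' @return An \code{AdhesionTable}.
#' @examples
#' adhesionTable(JBB = 0.25, JOO = 0.25, JBO = 0)
#' @rdname AdhesionTable-class
#' @export
adhesionTable <- function(JBB = 0, JOO = 0, JBO = 0, J = NULL,
                          types = c("blue", "orange")) {
    if (is.null(J)) {
        J <- matrix(c(JBB, JBO, JBO, JOO), 2, 2,
                    dimnames = list(types, types))
    }
    new("AdhesionTable", J = J)
}

#' State of all cells at one instant
#'
#' @slot positions N x 2 matrix of coordinates inside the periodic box.
#' @slot polarizations N x 2 matrix of self-propulsion force vectors.
#' @slot types factor of per-cell type labels.
#' @slot divisionClocks steps since each cell last divided.
#' @slot repolarizationOffsets per-cell phase of the repolarization clock.
#' @slot stepIndex current absolute step index.
#' @slot boxHalfwidth half-width of the periodic box the cells live in.
#' @export
setClass("CellPopulation",
    representation(positions = "matrix", polarizations = "matrix",
        types = "factor", divisionClocks = "numeric",
        repolarizationOffsets = "integer", stepIndex = "numeric",
        boxHalfwidth = "numeric"))

setValidity("CellPopulation", function(object) {
    n <- nrow(object@positions)
    msg <- character()
    if (ncol(object@positions) != 2) msg <- c(msg, "positions must be N x 2")
    if (nrow(object@polarizations) != n || length(object@types) != n ||
        length(object@divisionClocks) != n ||
        length(object@repolarizationOffsets) != n)
        msg <- c(msg, "per-cell slots must agree in length")
    hw <- object@boxHalfwidth
    if (n > 0 && (any(object@positions < -hw) || any(object@positions >= hw)))
        msg <- c(msg, "coordinates must lie in [-boxHalfwidth, boxHalfwidth)")
    if (length(msg)) msg else TRUE
})

#' Persistence diagram for one homology dimension and one channel
#'
#' A multiset of (start, end) filtration scales at which topological features
#' appear and disappear. Dimension-0 intervals (connected components) all
#' start at 0; dimension-1 intervals (loops) start at the filtration scale
#' closing the loop. Features alive at \code{maxFiltration} are capped there
#' (or dropped, depending on the convention used to build the diagram).
#'
#' @slot intervals two-column matrix (start, end).
#' @slot dimension homology dimension, 0 or 1.
#' @slot channel which cell types were included.
#' @slot maxFiltration the Rips filtration cap.
#' @export
setClass("PersistenceDiagram",
    representation(intervals = "matrix", dimension = "integer",
        channel = "character", maxFiltration = "numeric"))

setValidity("PersistenceDiagram", function(object) {
    iv <- object@intervals
    msg <- character()
    if (ncol(iv) != 2) msg <- c(msg, "intervals must have two columns")
    if (nrow(iv) > 0 && any(iv[, 2] < iv[, 1]))
        msg <- c(msg, "interval end must be >= start")
    if (nrow(iv) > 0 && any(iv < 0)) msg <- c(msg, "intervals must be >= 0")
    if (!object@dimension %in% c(0L, 1L))
        msg <- c(msg, "dimension must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' Persistence image
#'
#' Raster of lifespan-weighted Gaussians: a 1-D intensity profile for
#' dimension 0, a 2-D raster over (start, persistence) for dimension 1.
#'
#' @slot values numeric vector (1-D) or matrix (2-D) of intensities.
#' @slot dimension homology dimension the image summarizes.
#' @slot xAxis,yAxis pixel-center coordinates (filtration units); yAxis has
#'   length 0 for 1-D images.
#' @slot sigma Gaussian bandwidth.
#' @slot normalized whether the image has been scaled to unit maximum.
#' @export
setClass("PersistenceImage",
    representation(values = "ANY", dimension = "integer", xAxis = "numeric",
        yAxis = "numeric", sigma = "numeric", normalized = "logical"))

setValidity("PersistenceImage", function(object) {
    v <- object@values
    msg <- character()
    if (any(v < 0)) msg <- c(msg, "intensities must be >= 0")
    if (object@normalized && any(v > 0) && abs(max(v) - 1) > 1e-12)
        msg <- c(msg, "a normalized nonzero image must have max intensity 1")
    if (length(msg)) msg else TRUE
})

#' Persistence curve
#'
#' Scalar summary of the diagram along its diagonal: at each t the intervals
#' with start <= t <= end are summarized by the variant's point function.
#'
#' @slot t diagonal parameter grid.
#' @slot values curve values.
#' @slot variant one of "betti", "life", "gaussian".
#' @slot bandwidth Gaussian bandwidth (gaussian variant only).
#' @export
setClass("PersistenceCurve",
    representation(t = "numeric", values = "numeric", variant = "character",
        bandwidth = "numeric"))

#' @describeIn CellPopulation-class number of cells.
#' @param object a \code{CellPopulation}.
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
setMethod("nCells", "CellPopulation", function(object) nrow(object@positions))

#' @describeIn CellPopulation-class N x 2 coordinate matrix.
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
setMethod("positions", "CellPopulation", function(object) object@positions)

#' @describeIn CellPopulation-class factor of cell-type labels.
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))
setMethod("cellTypes", "CellPopulation", function(object) object@types)

#' @describeIn PersistenceDiagram-class the (start, end) interval matrix.
#' @param object a \code{PersistenceDiagram}.
#' @export
setGeneric("intervals", function(object) standardGeneric("intervals"))
setMethod("intervals", "PersistenceDiagram", function(object)
    object@intervals)

#' @describeIn PersistenceImage-class raw intensity values.
#' @param object a \code{PersistenceImage}.
#' @export
setGeneric("imageValues", function(object) standardGeneric("imageValues"))
setMethod("imageValues", "PersistenceImage", function(object) object@values)

setMethod("show", "CellPopulation", function(object) {
    cat("CellPopulation:", nCells(object), "cells in [",
        -object@boxHalfwidth, ",", object@boxHalfwidth, ")^2 at step",
        object@stepIndex, "\n")
    print(table(object@types))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nCells, "cells, box halfwidth",
        object@boxHalfwidth, ",", object@nSteps, "steps, proliferation",
        ifelse(object@proliferationEnabled, "on", "off"), "\n")
})

setMethod("show", "AdhesionTable", function(object) {
    cat("AdhesionTable:\n")
    print(object@J)
})

setMethod("show", "PersistenceDiagram", function(object) {
    cat("PersistenceDiagram: H", object@dimension, ", channel '",
        object@channel, "', ", nrow(object@intervals), " intervals (cap ",
        object@maxFiltration, ")\n", sep = "")
})

setMethod("show", "PersistenceImage", function(object) {
    d <- if (is.matrix(object@values)) paste(dim(object@values),
                                             collapse = " x ")
         else length(object@values)
    cat("PersistenceImage: H", object@dimension, ", ", d, " pixels, ",
        ifelse(object@normalized, "normalized", "raw"), "\n", sep = "")
})

setMethod("show", "PersistenceCurve", function(object) {
    cat("PersistenceCurve (", object@variant, "): ", length(object@t),
        " grid points\n", sep = "")
})
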