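#' Morse interaction potential
#'
#' \eqn{U(r) = -J [\exp(-r/l_A) - \rho \exp(-r/l_R)]} with attraction length
#' \eqn{l_A}, repulsion length \eqn{l_R} and repulsion ratio \eqn{\rho}. The
#' potential is finite at r = 0 and has a single minimum at the equilibrium
#' pair separation (about 1.009 under the defaults).
#'
#' @param r separation distance(s), must be nonnegative.
#' @param J adhesion magnitude scaling the potential.
#' @param config a [simulationConfig()] supplying the length scales.
#' @return Potential energy, vectorized over \code{r}.
#' @examples
#' morsePotential(0, 0.1)  # -0.075 under the default 1/4 repulsion ratio
#' @export
morsePotential <- function(r, J, config = simulationConfig()) {
    if (any(r < 0)) stop("separation r must be >= 0")
    -J * (exp(-r / config@lA) - config@repulsionRatio * exp(-r / config@lR))
}

# radial derivative dU/dr; positive => net attraction (force toward partner)
morseDUdr <- function(r, J, config = simulationConfig()) {
    J * (exp(-r / config@lA) / config@lA -
         config@repulsionRatio * exp(-r / config@lR) / config@lR)
}

# minimum-image displacement from xi to xj on the periodic box
minimumImage <- function(xi, xj, boxHalfwidth) {
    L <- 2 * boxHalfwidth
    d <- xj - xi
    d - L * round(d / L)
}

#' Pairwise interaction force
#'
#' Force exerted on the cell at \code{xi} by the cell at \code{xj}: the
#' radial gradient of the Morse potential along the minimum-image separation
#' vector, exactly zero beyond the cutoff \code{rMax} and antisymmetric under
#' exchange of the two cells. Coincident positions have no defined direction;
#' the force is then zero (the potential is finite there, so nothing blows
#' up).
#'
#' @param xi,xj length-2 position vectors inside the box.
#' @param J adhesion magnitude for this type pair.
#' @param config a [simulationConfig()].
#' @return Length-2 force vector acting on the cell at \code{xi}.
#' @export
pairForce <- function(xi, xj, J, config = simulationConfig()) {
    d <- minimumImage(xi, xj, config@boxHalfwidth)
    r <- sqrt(sum(d^2))
    if (r > config@rMax || r == 0) return(c(0, 0))
    morseDUdr(r, J, config) * d / r
}

largestRemainderCounts <- function(n, fractions) {
    raw <- n * fractions
    counts <- floor(raw)
    short <- n - sum(counts)
    if (short > 0) {
        idx <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
        counts[idx] <- counts[idx] + 1
    }
    as.integer(counts)
}

#' Initialize a population
#'
#' Draws cell positions uniformly over the periodic box with rejection
#' sampling so that all pairwise (minimum-image) distances are at least
#' \code{minInitSeparation}; assigns exact per-type counts by
#' largest-remainder rounding of \code{typeFractions}; draws polarization
#' directions uniformly at fixed magnitude, repolarization phases uniformly
#' over the repolarization period, and (with proliferation enabled) division
#' clocks uniformly over the cell cycle so divisions are not synchronized.
#'
#' @param config a [simulationConfig()]. If \code{config@seed} is not NA the
#'   RNG is seeded first, making the draw reproducible.
#' @return A [CellPopulation-class] at step 0.
#' @export
initPopulation <- function(config) {
    validObject(config)
    if (!is.na(config@seed)) set.seed(config@seed)
    n <- as.integer(config@nCells)
    hw <- config@boxHalfwidth
    sep2 <- config@minInitSeparation^2
    pos <- matrix(0, n, 2)
    placed <- 0L
    attempts <- 0L
    maxAttempts <- max(10000L, 500L * n)
    while (placed < n) {
        if (attempts >= maxAttempts)
            stop("packing infeasible: could not place ", n, " cells at ",
                 "minimum separation ", config@minInitSeparation)
        attempts <- attempts + 1L
        cand <- runif(2, -hw, hw)
        ok <- TRUE
        if (placed > 0) {
            d <- minimumImage(matrix(cand, placed, 2, byrow = TRUE),
                              pos[seq_len(placed), , drop = FALSE], hw)
            ok <- all(rowSums(d^2) >= sep2)
        }
        if (ok) {
            placed <- placed + 1L
            pos[placed, ] <- cand
        }
    }
    counts <- largestRemainderCounts(n, config@typeFractions)
    types <- factor(rep(names(config@typeFractions), counts),
                    levels = names(config@typeFractions))
    theta <- runif(n, 0, 2 * pi)
    pol <- config@polarizationMagnitude * cbind(cos(theta), sin(theta))
    offsets <- as.integer(floor(runif(n, 0, config@repolarizationPeriod)))
    clocks <- if (config@proliferationEnabled)
        floor(runif(n, 0, config@cellCycleSteps)) else rep(0, n)
    new("CellPopulation", positions = pos, polarizations = pol,
        types = types, divisionClocks = clocks,
        repolarizationOffsets = offsets, stepIndex = 0,
        boxHalfwidth = hw)
}

orderAdhesion <- function(adhesion, typeLevels) {
    J <- adhesion@J
    if (!all(typeLevels %in% rownames(J)))
        stop("adhesion table lacks entries for types: ",
             paste(setdiff(typeLevels, rownames(J)), collapse = ", "))
    J[typeLevels, typeLevels, drop = FALSE]
}

callSimKernel <- function(pop, adhesion, config, nSteps, snapshotEvery = 0) {
    J <- orderAdhesion(adhesion, levels(pop@types))
    res <- .runSimCpp(pop@positions, as.integer(pop@types) - 1L,
        pop@polarizations, pop@divisionClocks, pop@repolarizationOffsets,
        J, config@boxHalfwidth, config@dt, config@eta,
        config@polarizationMagnitude,
        as.integer(config@repolarizationPeriod), config@rMax, config@lA,
        config@lR, config@repulsionRatio, nSteps, pop@stepIndex,
        config@proliferationEnabled, config@cellCycleSteps,
        as.integer(config@maxNeighborsForDivision), config@daughterOffset,
        snapshotEvery)
    out <- new("CellPopulation", positions = res$positions,
        polarizations = res$polarizations,
        types = factor(levels(pop@types)[res$types + 1L],
                       levels = levels(pop@types)),
        divisionClocks = res$clocks,
        repolarizationOffsets = as.integer(res$offsets),
        stepIndex = res$step_index, boxHalfwidth = config@boxHalfwidth)
    attr(out, "snapshots") <- res$snapshots
    out
}

#' Advance a population by one or more time steps
#'
#' One synchronous update of the equation of motion: forces are accumulated
#' over all neighbour pairs (minimum image, cutoff \code{rMax}) before any
#' position changes, each cell is displaced by
#' \eqn{(\Delta t/\eta)(P_i + \sum_j F_{ij})} and wrapped back into the box.
#' A cell's polarization direction is redrawn uniformly at the start of any
#' step where \code{(stepIndex + offset) \%\% repolarizationPeriod == 0}.
#' Division is attempted after the displacement when proliferation is on.
#'
#' @param pop a [CellPopulation-class].
#' @param adhesion an [adhesionTable()].
#' @param config a [simulationConfig()].
#' @param nSteps number of steps to advance (default 1).
#' @return The advanced [CellPopulation-class].
#' @export
stepPopulation <- function(pop, adhesion, config, nSteps = 1) {
    callSimKernel(pop, adhesion, config, nSteps)
}

#' Contact-inhibited division pass
#'
#' Every cell whose division clock has reached \code{cellCycleSteps} and
#' whose neighbour count (cells within \code{rMax}) does not exceed
#' \code{maxNeighborsForDivision} divides: one daughter keeps the mother's
#' position and polarization, the other is placed \code{daughterOffset} away
#' in a uniform random direction with the opposite polarization, and both
#' clocks reset to zero.
#'
#' @inheritParams stepPopulation
#' @return The population after divisions (unchanged if none occurred).
#' @export
attemptDivisions <- function(pop, config) {
    if (!config@proliferationEnabled) return(pop)
    ready <- which(pop@divisionClocks >= config@cellCycleSteps)
    if (!length(ready)) return(pop)
    counts <- .neighborCountsCpp(pop@positions, config@boxHalfwidth,
                                 config@rMax)
    dividing <- ready[counts[ready] <= config@maxNeighborsForDivision]
    if (!length(dividing)) return(pop)
    hw <- config@boxHalfwidth
    L <- 2 * hw
    theta <- runif(length(dividing), 0, 2 * pi)
    newPos <- pop@positions[dividing, , drop = FALSE] +
        config@daughterOffset * cbind(cos(theta), sin(theta))
    newPos <- newPos - L * floor((newPos + hw) / L)
    clocks <- pop@divisionClocks
    clocks[dividing] <- 0
    new("CellPopulation",
        positions = rbind(pop@positions, newPos),
        polarizations = rbind(pop@polarizations,
                              -pop@polarizations[dividing, , drop = FALSE]),
        types = factor(c(as.character(pop@types),
                         as.character(pop@types[dividing])),
                       levels = levels(pop@types)),
        divisionClocks = c(clocks, rep(0, length(dividing))),
        repolarizationOffsets = c(pop@repolarizationOffsets,
                                  pop@repolarizationOffsets[dividing]),
        stepIndex = pop@stepIndex, boxHalfwidth = hw)
}

#' Run a full simulation
#'
#' Initializes a population (seeded via \code{config@seed}) and integrates
#' the equations of motion for \code{config@nSteps} steps, attempting
#' contact-inhibited divisions after every step when proliferation is
#' enabled. Fully reproducible given the seed.
#'
#' @param config a [simulationConfig()].
#' @param adhesion an [adhesionTable()].
#' @param snapshotEvery if positive, record cell positions every this many
#'   steps; retrieve them from \code{attr(result, "snapshots")}.
#' @return Final [CellPopulation-class].
#' @examples
#' cfg <- simulationConfig(nCells = 30, nSteps = 200, boxHalfwidth = 8,
#'                         seed = 1)
#' pop <- runSimulation(cfg, adhesionTable(0.25, 0.25, 0))
#' @export
runSimulation <- function(config, adhesion, snapshotEvery = 0) {
    pop <- initPopulation(config)
    if (config@nSteps <= 0) return(pop)
    callSimKernel(pop, adhesion, config, config@nSteps, snapshotEvery)
}

#' Neighbour counts within the interaction radius
#'
#' @param pop a [CellPopulation-class].
#' @param config a [simulationConfig()] (supplies \code{rMax}).
#' @return Integer vector of per-cell neighbour counts.
#' @export
neighborCounts <- function(pop, config) {
    .neighborCountsCpp(pop@positions, config@boxHalfwidth, config@rMax)
}

#' Fraction of same-type cells among the k nearest neighbours
#'
#' Mean over cells of the proportion of each cell's k nearest neighbours
#' (periodic distance) sharing its type; a simple purity statistic for
#' sorted patterns.
#'
#' @param pop a [CellPopulation-class].
#' @param k number of nearest neighbours (default 4).
#' @return Scalar purity in [0, 1].
#' @export
neighborPurity <- function(pop, k = 4) {
    pos <- pop@positions
    n <- nrow(pos)
    stopifnot(n > k)
    L <- 2 * pop@boxHalfwidth
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    dx <- dx - L * round(dx / L)
    dy <- dy - L * round(dy / L)
    d <- sqrt(dx^2 + dy^2)
    diag(d) <- Inf
    same <- outer(pop@types, pop@types, "==")
    mean(vapply(seq_len(n), function(i) {
        nn <- order(d[i, ])[seq_len(k)]
        mean(same[i, nn])
    }, numeric(1)))
}
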