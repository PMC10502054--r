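test_that("population initialization honours counts, separation, determinism", {
    cfg <- simulationConfig(nCells = 200, nSteps = 0, seed = 11)
    pop <- initPopulation(cfg)
    expect_equal(as.vector(table(cellTypes(pop))), c(120, 80))
    d <- dist(positions(pop))  # interior distances bound periodic ones below
    # periodic minimum-image distances
    pos <- positions(pop)
    L <- 2 * cfg@boxHalfwidth
    dx <- outer(pos[, 1], pos[, 1], "-"); dx <- dx - L * round(dx / L)
    dy <- outer(pos[, 2], pos[, 2], "-"); dy <- dy - L * round(dy / L)
    dmin <- sqrt(dx^2 + dy^2); diag(dmin) <- Inf
    expect_gte(min(dmin), cfg@minInitSeparation)
    expect_equal(sqrt(rowSums(pop@polarizations^2)),
                 rep(cfg@polarizationMagnitude, 200))
    pop2 <- initPopulation(cfg)
    expect_identical(positions(pop), positions(pop2))
    expect_identical(cellTypes(pop), cellTypes(pop2))
})

test_that("infeasible packing raises an explicit error", {
    cfg <- simulationConfig(nCells = 50, boxHalfwidth = 2, seed = 1)
    expect_error(initPopulation(cfg), "packing infeasible")
})

test_that("Morse potential values and equilibrium separation", {
    expect_equal(morsePotential(5, 0), 0)
    expect_equal(morsePotential(0, 0.1), -0.075)
    expect_error(morsePotential(-1, 0.1), "r must be >= 0")
    # root of dU/dr on (0, rMax) by bisection on the analytic derivative
    cfg <- simulationConfig()
    dU <- function(r) exp(-r / cfg@lA) / cfg@lA -
        cfg@repulsionRatio * exp(-r / cfg@lR) / cfg@lR
    lo <- 0.5; hi <- 1.5
    for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (sign(dU(mid)) == sign(dU(lo))) lo <- mid else hi <- mid
    }
    rStar <- (lo + hi) / 2
    expect_equal(rStar, 1.009, tolerance = 1e-3)
    # the root is independent of J and pairForce vanishes there
    expect_equal(pairForce(c(0, 0), c(rStar, 0), 0.2), c(0, 0),
                 tolerance = 1e-10)
})

test_that("pair force: cutoff, antisymmetry, minimum image, coincidence", {
    cfg <- simulationConfig()
    expect_equal(pairForce(c(0, 0), c(1.6, 0), 0.25, cfg), c(0, 0))
    xi <- c(1.1, -0.4); xj <- c(0.6, 0.3)
    expect_equal(pairForce(xi, xj, 0.2, cfg), -pairForce(xj, xi, 0.2, cfg))
    # brute force over the 9 periodic images: (-19.5,0) vs (19.5,0) -> r = 1
    shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1)) * 40
    dists <- apply(shifts, 1, function(s)
        sqrt(sum((c(19.5, 0) + s - c(-19.5, 0))^2)))
    expect_equal(min(dists), 1)
    f <- pairForce(c(-19.5, 0), c(19.5, 0), 0.2, cfg)
    # at r = 1 < r*: net repulsion pushing away from the image across -x
    expect_true(f[1] > 0)
    expect_equal(f[2], 0)
    expect_equal(sqrt(sum(f^2)),
                 abs(TopoCellSort:::morseDUdr(1, 0.2, cfg)))
    expect_equal(pairForce(c(0, 0), c(0, 0), 0.5, cfg), c(0, 0))
})

test_that("stepping: displacement magnitude, cutoff inertness, wrap", {
    cfg <- simulationConfig(nCells = 1, polarizationMagnitude = 0.005)
    ad <- adhesionTable(0.25, 0.25, 0.25)
    pop <- makePopulation(matrix(c(0, 0), 1, 2),
                          pol = matrix(c(0.005, 0), 1, 2))
    p1 <- stepPopulation(pop, ad, cfg)
    expect_equal(sqrt(sum((positions(p1) - positions(pop))^2)), 1e-4)
    # two distant cells with zero polarization do not move
    pop2 <- makePopulation(rbind(c(0, 0), c(5, 0)), c("blue", "orange"))
    p2 <- stepPopulation(pop2, ad, cfg)
    expect_identical(positions(p2), positions(pop2))
    # periodic wrap: cell stepped past +halfwidth reappears near -halfwidth
    pop3 <- makePopulation(matrix(c(20 - 5e-5, 0), 1, 2),
                           pol = matrix(c(0.005, 0), 1, 2))
    p3 <- stepPopulation(pop3, ad, cfg)
    expect_lt(positions(p3)[1, 1], 0)
    expect_equal(positions(p3)[1, 1], -20 + 5e-5, tolerance = 1e-9)
})

test_that("pair forces cancel: centroid conserved and J=0, P=0 is a fixed point", {
    set.seed(3)
    cfg <- simulationConfig(nCells = 20, polarizationMagnitude = 0)
    pos <- matrix(runif(40, -3, 3), 20, 2)
    pop <- makePopulation(pos, sample(c("blue", "orange"), 20, TRUE))
    p1 <- stepPopulation(pop, adhesionTable(0.2, 0.15, 0.1), cfg,
                         nSteps = 200)
    expect_equal(colMeans(positions(p1)), colMeans(pos), tolerance = 1e-12)
    p0 <- stepPopulation(pop, adhesionTable(0, 0, 0), cfg, nSteps = 50)
    expect_identical(positions(p0), pos)
})

test_that("two interacting cells relax to the equilibrium separation", {
    cfg <- simulationConfig(polarizationMagnitude = 0)
    pop <- makePopulation(rbind(c(-0.65, 0), c(0.65, 0)))
    p <- stepPopulation(pop, adhesionTable(0.25, 0.25, 0.25), cfg,
                        nSteps = 50000)
    expect_equal(as.numeric(dist(positions(p))), 1.009, tolerance = 1e-3)
})

test_that("division gate: neighbour cap, clock, daughter polarization", {
    cfg <- simulationConfig(proliferationEnabled = TRUE,
                            cellCycleSteps = 80000)
    # centre cell with 5 neighbours within rMax and a full clock: blocked
    th <- 2 * pi * (0:4) / 5
    pos <- rbind(c(0, 0), cbind(cos(th), sin(th)))
    pop <- makePopulation(pos, clocks = c(80000, rep(0, 5)))
    expect_equal(nCells(attemptDivisions(pop, cfg)), 6)
    # isolated cell with a full clock divides, mirrored polarization
    pop2 <- makePopulation(matrix(c(0, 0), 1, 2),
                           pol = matrix(c(0.003, 0.004), 1, 2),
                           clocks = 80000)
    set.seed(1)
    p2 <- attemptDivisions(pop2, cfg)
    expect_equal(nCells(p2), 2)
    expect_equal(p2@polarizations[2, ], -p2@polarizations[1, ])
    expect_equal(p2@divisionClocks, c(0, 0))
    expect_lte(as.numeric(dist(positions(p2))), cfg@daughterOffset + 1e-12)
    # clock below the cycle: nothing happens
    pop3 <- makePopulation(matrix(c(0, 0), 1, 2), clocks = 79999)
    expect_equal(nCells(attemptDivisions(pop3, cfg)), 1)
})

test_that("run-level invariants: identity at 0 steps, conservation, determinism", {
    cfg <- simulationConfig(nCells = 40, nSteps = 0, boxHalfwidth = 8,
                            seed = 5)
    pop0 <- runSimulation(cfg, adhesionTable(0.1, 0.1, 0.1))
    expect_equal(pop0@stepIndex, 0)
    cfg@nSteps <- 3000
    pop <- runSimulation(cfg, adhesionTable(0.1, 0.1, 0.1))
    expect_equal(nCells(pop), 40)  # no proliferation path
    expect_equal(as.vector(table(cellTypes(pop))),
                 as.vector(table(cellTypes(pop0))))
    expect_true(all(positions(pop) >= -8 & positions(pop) < 8))
    pop2 <- runSimulation(cfg, adhesionTable(0.1, 0.1, 0.1))
    expect_identical(positions(pop), positions(pop2))
    # snapshot cadence
    cfg@nSteps <- 100
    pop3 <- runSimulation(cfg, adhesionTable(0.1, 0.1, 0.1),
                          snapshotEvery = 25)
    snaps <- attr(pop3, "snapshots")
    expect_length(snaps, 4)
    expect_equal(snaps[[4]]$step, 100)
    # proliferation grows the population under a short cycle
    cfgp <- simulationConfig(nCells = 10, nSteps = 2000, boxHalfwidth = 8,
        seed = 5, proliferationEnabled = TRUE, cellCycleSteps = 500)
    popp <- runSimulation(cfgp, adhesionTable(0, 0, 0))
    expect_gt(nCells(popp), 10)
})

test_that("homotypic adhesion sorts types: purity rises with run length", {
    cfg <- simulationConfig(nCells = 60, nSteps = 2e5,
        boxHalfwidth = 20 * sqrt(60 / 200), seed = 7)
    ad <- adhesionTable(0.25, 0.25, 0)
    popShort <- runSimulation(cfg, ad)
    base <- sum(prop.table(table(cellTypes(popShort)))^2)  # unsorted level
    expect_gt(neighborPurity(popShort), base)
    # at the full published duration the pattern is essentially sorted
    cfg@nSteps <- 5e6
    popFull <- runSimulation(cfg, ad)
    expect_gt(neighborPurity(popFull), 0.9)
    expect_gt(neighborPurity(popFull), neighborPurity(popShort))
})
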