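test_that("small-instance diagrams match hand enumeration", {
    # two points at distance d: one merge, no loop
    d2 <- computeDiagrams(rbind(c(0, 0), c(0.7, 0)))
    expect_equal(sortedIntervals(d2$H0),
                 cbind(start = c(0, 0), end = c(0.7, 3)))
    expect_equal(nrow(intervals(d2$H1)), 0)
    # unit square: single loop born at 1, filled at sqrt(2)
    sq <- computeDiagrams(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
    expect_equal(intervals(sq$H1),
                 cbind(start = 1, end = sqrt(2)), tolerance = 1e-12)
    # equilateral triangle: the 2-simplex enters with its last edge
    tri <- computeDiagrams(cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2)))
    expect_equal(nrow(intervals(tri$H1)), 0)
})

test_that("production path equals the brute-force reduction on small clouds", {
    for (s in 1:8) {
        set.seed(s)
        n <- sample(4:7, 1)
        pts <- matrix(runif(2 * n, 0, 2), n, 2)
        a <- computeDiagrams(pts, maxFiltration = 3)
        b <- computeDiagrams(pts, maxFiltration = 3, method = "bruteforce")
        expect_equal(sortedIntervals(a$H0), sortedIntervals(b$H0),
                     tolerance = 1e-12)
        expect_equal(sortedIntervals(a$H1), sortedIntervals(b$H1),
                     tolerance = 1e-12)
        # H0 merge scales also equal single-linkage dendrogram heights
        finite <- intervals(a$H0)[, 2]
        finite <- sort(finite[finite < 3])
        sl <- sort(hclust(dist(pts), method = "single")$height)
        expect_equal(finite, sl[sl <= 3], tolerance = 1e-12)
    }
})

test_that("H0 interval count equals the point count under the cap convention", {
    for (s in 1:4) {
        set.seed(100 + s)
        n <- 5 * s
        pts <- matrix(runif(2 * n, 0, 6), n, 2)
        dg <- computeDiagrams(pts)$H0
        expect_equal(nrow(intervals(dg)), n)
        dropped <- computeDiagrams(pts, infiniteConvention = "drop")$H0
        expect_lt(nrow(intervals(dropped)), n)
    }
})

test_that("H0 end values are stable under small perturbations", {
    set.seed(9)
    pts <- matrix(runif(30, 0, 4), 15, 2)
    delta <- 0.01
    pert <- pts + matrix(runif(30, -delta / sqrt(2), delta / sqrt(2)), 15, 2)
    e1 <- sort(intervals(computeDiagrams(pts)$H0)[, 2])
    e2 <- sort(intervals(computeDiagrams(pert)$H0)[, 2])
    expect_lte(max(abs(e1 - e2)), 2 * delta)
})

test_that("dimension-0 persistence image matches the weighted Gaussian", {
    emptyD <- new("PersistenceDiagram",
        intervals = matrix(numeric(0), 0, 2), dimension = 0L,
        channel = "both", maxFiltration = 3)
    expect_true(all(imageValues(persistenceImage(emptyD)) == 0))
    d <- 1.3
    one <- new("PersistenceDiagram", intervals = cbind(0, d),
               dimension = 0L, channel = "both", maxFiltration = 3)
    img <- persistenceImage(one, sigma = 0.1)
    expect_equal(imageValues(img), d * dnorm(img@xAxis, d, 0.1))
    # additivity over diagram union
    two <- new("PersistenceDiagram", intervals = rbind(c(0, d), c(0, 0.4)),
               dimension = 0L, channel = "both", maxFiltration = 3)
    other <- new("PersistenceDiagram", intervals = cbind(0, 0.4),
                 dimension = 0L, channel = "both", maxFiltration = 3)
    expect_equal(imageValues(persistenceImage(two)),
                 imageValues(persistenceImage(one)) +
                 imageValues(persistenceImage(other)))
})

test_that("dimension-1 persistence image peaks at (start, persistence)", {
    emptyD <- new("PersistenceDiagram",
        intervals = matrix(numeric(0), 0, 2), dimension = 1L,
        channel = "both", maxFiltration = 3)
    expect_true(all(imageValues(persistenceImage(emptyD)) == 0))
    b <- 0.8; e <- 2.1
    one <- new("PersistenceDiagram", intervals = cbind(b, e),
               dimension = 1L, channel = "both", maxFiltration = 3)
    img <- persistenceImage(one)
    peak <- which(imageValues(img) == max(imageValues(img)),
                  arr.ind = TRUE)
    expect_equal(img@xAxis[peak[1]], img@xAxis[which.min(abs(img@xAxis - b))])
    expect_equal(img@yAxis[peak[2]],
                 img@yAxis[which.min(abs(img@yAxis - (e - b)))])
    dup <- new("PersistenceDiagram", intervals = rbind(c(b, e), c(b, e)),
               dimension = 1L, channel = "both", maxFiltration = 3)
    expect_equal(imageValues(persistenceImage(dup)),
                 2 * imageValues(persistenceImage(one)))
})

test_that("image normalization scales to unit maximum and is idempotent", {
    v <- matrix(c(0.1, 0.4, 0.2, 0), 2, 2)
    img <- new("PersistenceImage", values = v, dimension = 1L,
               xAxis = c(1, 2), yAxis = c(1, 2), sigma = 0.1,
               normalized = FALSE)
    nrm <- normalizeImage(img)
    expect_equal(imageValues(nrm), v * 2.5)
    expect_equal(max(imageValues(nrm)), 1)
    expect_equal(imageValues(normalizeImage(nrm)), imageValues(nrm))
    zero <- new("PersistenceImage", values = v * 0, dimension = 1L,
                xAxis = c(1, 2), yAxis = c(1, 2), sigma = 0.1,
                normalized = FALSE)
    expect_equal(imageValues(normalizeImage(zero)), v * 0)
})

test_that("persistence curves: Betti and life hand counts, Gaussian guard", {
    dg <- new("PersistenceDiagram", intervals = rbind(c(0, 1), c(0, 2)),
              dimension = 0L, channel = "both", maxFiltration = 3)
    bc <- persistenceCurve(dg, "betti", tGrid = c(0.5, 1.5))
    expect_equal(bc@values, c(2, 1))
    lc <- persistenceCurve(dg, "life", tGrid = c(0.5, 1.5))
    expect_equal(lc@values, c(3, 2))
    expect_error(persistenceCurve(dg, "gaussian", tGrid = 0.5),
                 "bandwidth")
    emptyD <- new("PersistenceDiagram",
        intervals = matrix(numeric(0), 0, 2), dimension = 1L,
        channel = "both", maxFiltration = 3)
    gc <- persistenceCurve(emptyD, "gaussian", tGrid = c(0.5, 1.5),
                           bandwidth = 0.2)
    expect_equal(gc@values, c(0, 0))
})

test_that("Betti curve boundary values follow the infinite-interval convention", {
    set.seed(21)
    pts <- matrix(runif(24, 0, 5), 12, 2)
    dg <- computeDiagrams(pts)$H0
    ends <- intervals(dg)[, 2]
    nInf <- sum(ends == 3)
    tJust <- min(ends) / 2
    tLate <- (max(ends[ends < 3]) + 3) / 2
    bc <- persistenceCurve(dg, "betti", tGrid = c(tJust, tLate))
    expect_equal(bc@values[1], 12)     # every point its own component
    expect_equal(bc@values[2], nInf)   # only capped components remain
})

test_that("feature vectors concatenate blocks and respect channels", {
    pat <- generatePattern("checkerboard", nCells = 64, seed = 2)
    fv <- buildFeatureVector(pat, channels = "both", dims = c(0, 1))
    expect_length(fv, 100 + 400)
    prov <- attr(fv, "provenance")
    expect_equal(prov$length, c(100, 400))
    # orange-only channel ignores blue positions entirely
    orangeOnly <- pat[pat$cell_type == "orange", ]
    fvO <- buildFeatureVector(pat, channels = "orange", dims = 1)
    fvO2 <- buildFeatureVector(orangeOnly, channels = "both", dims = 1)
    expect_equal(as.numeric(fvO), as.numeric(fvO2))
    expect_identical(fv, buildFeatureVector(pat, channels = "both",
                                            dims = c(0, 1)))
    expect_error(buildFeatureVector(pat, channels = "green"),
                 "unknown channel")
    empty <- pat[0, ]
    expect_warning(computeDiagrams(empty, channel = "both"), "no points")
})
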