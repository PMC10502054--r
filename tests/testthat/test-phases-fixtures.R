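test_that("regime labels reproduce the published threshold statements", {
    expect_equal(as.character(regimeLabel(0.01, 0.01, 0)), "i")
    expect_equal(as.character(regimeLabel(0.09, 0.09, 0)), "iv")
    expect_equal(as.character(regimeLabel(0.13, 0.13, 0.05)), "v")
    # one-type clustering at zero heterotypic adhesion
    expect_equal(as.character(regimeLabel(0.09, 0.01, 0)), "ii")
    expect_equal(as.character(regimeLabel(0.01, 0.09, 0)), "iii")
    # thin stripes for weak homotypic under active heterotypic
    expect_equal(as.character(regimeLabel(0.001, 0.001, 0.05)), "vi")
    # blue spots in orange at near-zero blue-blue adhesion
    expect_equal(as.character(regimeLabel(0.001, 0.09, 0.05)), "viii")
    expect_error(regimeLabel(-0.1, 0, 0))
})

test_that("regime rules are total over both default grids and taxonomies", {
    gC <- sweepGrid(proliferation = FALSE)
    expect_equal(nrow(gC), 512)
    labC <- regimeLabel(gC$J_BB, gC$J_OO, gC$J_BO, proliferation = FALSE)
    expect_false(anyNA(labC))
    expect_true(all(labC %in% taxonomyLabels(FALSE)))
    gP <- sweepGrid(proliferation = TRUE)
    expect_equal(nrow(gP), 216)
    labP <- regimeLabel(gP$J_BB, gP$J_OO, gP$J_BO, proliferation = TRUE)
    expect_false(anyNA(labP))
    expect_true(all(labP %in% taxonomyLabels(TRUE)))
    # determinism
    expect_identical(labC,
        regimeLabel(gC$J_BB, gC$J_OO, gC$J_BO, proliferation = FALSE))
    # every phase of each taxonomy occurs on the reduced grids
    gcr <- sweepGrid(FALSE, reduced = TRUE)
    expect_setequal(as.character(unique(
        regimeLabel(gcr$J_BB, gcr$J_OO, gcr$J_BO))), taxonomyLabels(FALSE))
    gpr <- sweepGrid(TRUE, reduced = TRUE)
    expect_setequal(as.character(unique(
        regimeLabel(gpr$J_BB, gpr$J_OO, gpr$J_BO, TRUE))),
        taxonomyLabels(TRUE))
})

test_that("pattern fixtures realize their defining geometry at zero noise", {
    srt <- generatePattern("sorted", nCells = 100, noiseScale = 0, seed = 1)
    d <- as.matrix(dist(cbind(srt$x, srt$y)))
    diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    expect_true(all(srt$cell_type[nn] == srt$cell_type))
    chk <- generatePattern("checkerboard", nCells = 100, noiseScale = 0,
                           seed = 1)
    d <- as.matrix(dist(cbind(chk$x, chk$y)))
    diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    expect_true(all(chk$cell_type[nn] != chk$cell_type))
    hx <- generatePattern("hex_spots", nCells = 400, noiseScale = 0,
                          seed = 1)
    spots <- hx[hx$cell_type == "orange", ]
    p6 <- psi6(cbind(spots$x, spots$y))
    # interior spot centres sit on a perfect triangular lattice
    interior <- spots$x > quantile(spots$x, 0.25) &
        spots$x < quantile(spots$x, 0.75) &
        spots$y > quantile(spots$y, 0.25) & spots$y < quantile(spots$y, 0.75)
    expect_true(any(interior))
    expect_equal(mean(p6[interior]), 1, tolerance = 1e-8)
    expect_error(generatePattern("spiral"), "arg")
    expect_identical(generatePattern("stripes", nCells = 90, seed = 4),
                     generatePattern("stripes", nCells = 90, seed = 4))
})

test_that("fixture classes are separable in persistence-image space", {
    kinds <- c("hex_spots", "stripes", "sorted")
    feats <- list()
    cls <- c()
    for (k in kinds) for (s in 1:10) {
        pat <- generatePattern(k, nCells = 150, noiseScale = 0.05,
                               seed = 100 + s)
        feats[[length(feats) + 1]] <-
            buildFeatureVector(pat, channels = "both", dims = 1)
        cls <- c(cls, k)
    }
    X <- do.call(rbind, feats)
    D <- as.matrix(dist(X))
    within <- c(); between <- c()
    for (i in 1:29) for (j in (i + 1):30) {
        if (cls[i] == cls[j]) within <- c(within, D[i, j])
        else between <- c(between, D[i, j])
    }
    expect_gt(mean(between), mean(within))
    expect_gt(min(vapply(kinds, function(a) {
        ia <- which(cls == a)
        min(D[ia, -ia])
    }, numeric(1))), 0)
})
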