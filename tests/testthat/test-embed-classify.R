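test_that("PCA embedding: rank-1 data, width contract, argument checks", {
    set.seed(1)
    base <- runif(30)
    X <- outer(seq_len(25), base)  # rank 1
    p <- prcomp(X)
    expect_equal(p$sdev[1]^2 / sum(p$sdev^2), 1, tolerance = 1e-10)
    emb <- reduceDimension(X, "pca", latentDim = 20, standardize = FALSE)
    expect_equal(dim(emb), c(25, 20))
    expect_error(reduceDimension(X, "pca", latentDim = 31), "latentDim")
})

test_that("autoencoder reduces reconstruction loss and is reproducible", {
    set.seed(2)
    X <- matrix(rnorm(40 * 60), 40, 60)
    emb <- reduceDimension(X, "autoencoder", latentDim = 5, seed = 9,
                           aeHidden = c(32, 16), aeEpochs = 300)
    expect_equal(dim(emb), c(40, 5))
    loss <- attr(emb, "loss")
    expect_lt(loss["final"], loss["first"])
    emb2 <- reduceDimension(X, "autoencoder", latentDim = 5, seed = 9,
                            aeHidden = c(32, 16), aeEpochs = 300)
    expect_identical(unclass(emb), unclass(emb2))
})

test_that("diffusion-potential embedding separates well-separated groups", {
    set.seed(3)
    X <- rbind(matrix(rnorm(60, 0), 20, 3),
               matrix(rnorm(60, 8), 20, 3))
    emb <- reduceDimension(X, "phate", latentDim = 2, seed = 1)
    expect_equal(dim(emb), c(40, 2))
    emb2 <- reduceDimension(X, "phate", latentDim = 2, seed = 1)
    expect_identical(emb, emb2)
    cl <- clusterHierarchical(emb, 2)
    expect_equal(accuracyVsTruth(cl, rep(1:2, each = 20)), 1)
})

test_that("Ward clustering: blob split and degenerate cluster counts", {
    set.seed(4)
    blobs <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                   matrix(rnorm(40, 6, 0.3), 20, 2))
    truth <- rep(1:2, each = 20)
    # oracle: every within-blob distance is below every between-blob one
    d <- as.matrix(dist(blobs))
    within <- max(d[1:20, 1:20], d[21:40, 21:40])
    between <- min(d[1:20, 21:40])
    expect_gt(between, within)
    cl <- clusterHierarchical(blobs, 2)
    expect_equal(accuracyVsTruth(cl, truth), 1)
    expect_equal(length(unique(clusterHierarchical(blobs, 40))), 40)
    expect_equal(length(unique(clusterHierarchical(blobs, 1))), 1)
    expect_error(clusterHierarchical(blobs, 0), "nClusters")
    expect_error(clusterHierarchical(blobs, 41), "exceed")
})

test_that("assignment accuracy: identities, permutations, hand example", {
    expect_equal(accuracyVsTruth(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    expect_equal(accuracyVsTruth(c(2, 2, 3, 3), c("a", "a", "b", "b")), 1)
    expect_equal(accuracyVsTruth(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0.5)
    expect_error(accuracyVsTruth(1:3, 1:4), "equal length")
})

test_that("assignment accuracy equals the exhaustive oracle", {
    for (s in 1:10) {
        set.seed(30 + s)
        k <- sample(2:6, 1)
        n <- 40
        truth <- sample(k, n, TRUE)
        pred <- truth
        flip <- sample(n, 15)
        pred[flip] <- sample(k, 15, TRUE)
        pred <- sample(k)[pred]  # random relabeling
        expect_equal(accuracyVsTruth(pred, truth),
                     exhaustiveAccuracy(pred, truth))
    }
})

test_that("SVM cross-validation: separable data, permutation baseline, folds", {
    set.seed(6)
    X <- rbind(matrix(rnorm(100, 0, 0.2), 50, 2),
               matrix(rnorm(100, 5, 0.2), 50, 2))
    y <- rep(c("a", "b"), each = 50)
    acc <- svmCrossvalAccuracy(X, y, costValues = c(1, 10), seed = 3)
    expect_equal(unname(acc), c(1, 1))
    yShuf <- sample(y)
    accS <- svmCrossvalAccuracy(X, yShuf, costValues = 1, seed = 3)
    expect_lt(abs(accS - 0.5), 0.2)
    # partition property: every sample held out exactly once
    set.seed(3)
    fold <- integer(length(y))
    for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(sample(5), length(idx))
    }
    expect_equal(sort(unique(fold)), 1:5)
    expect_equal(sum(table(fold)), length(y))
    tiny <- factor(c(rep("a", 8), rep("b", 2)))
    expect_warning(svmCrossvalAccuracy(matrix(rnorm(20), 10, 2), tiny,
                                       costValues = 1, seed = 1),
                   "fewer samples")
})
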