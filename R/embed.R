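#' Reduce feature vectors to a low-dimensional embedding
#'
#' Dimensionality reduction of a samples-by-features matrix to
#' \code{latentDim} columns by PCA, UMAP, a diffusion-potential embedding,
#' or the package's autoencoder. Features are standardized (per-column zero
#' mean, unit variance; constant columns set to zero) before any method
#' unless \code{standardize = FALSE}. PCA is deterministic; the other
#' methods are reproducible given \code{seed}. When a linear method yields
#' fewer informative components than \code{latentDim} (rank-deficient
#' input), the remaining columns are zero-padded so the output always has
#' the requested width.
#'
#' @param features numeric matrix, one row per sample; no missing values.
#' @param method "pca", "umap", "phate" (diffusion potential + classical
#'   MDS) or "autoencoder".
#' @param latentDim embedding width (default 20; must not exceed the
#'   feature count).
#' @param seed integer seed for the stochastic methods.
#' @param standardize standardize columns first (default TRUE).
#' @param aeHidden hidden layer sizes of the symmetric autoencoder.
#' @param aeEpochs,aeLearningRate autoencoder training budget and Adam step
#'   size.
#' @return Matrix with \code{nrow(features)} rows and \code{latentDim}
#'   columns; for the autoencoder, the attribute "loss" holds the first and
#'   final epoch mean squared reconstruction error.
#' @export
reduceDimension <- function(features, method = c("pca", "umap", "phate",
                            "autoencoder"), latentDim = 20, seed = NULL,
                            standardize = TRUE, aeHidden = c(256, 64),
                            aeEpochs = 1500, aeLearningRate = 1e-3) {
    method <- match.arg(method)
    features <- as.matrix(features)
    stopifnot(nrow(features) >= 2, !anyNA(features))
    if (latentDim < 1 || latentDim > ncol(features))
        stop("latentDim must be between 1 and the feature length")
    X <- if (standardize) standardizeColumns(features) else features
    if (!is.null(seed)) set.seed(seed)
    switch(method,
        pca = {
            p <- prcomp(X, center = TRUE, scale. = FALSE)
            padColumns(p$x, latentDim)
        },
        umap = {
            if (!requireNamespace("uwot", quietly = TRUE))
                stop("method 'umap' requires the uwot package")
            uwot::umap(X, n_components = latentDim,
                       n_neighbors = min(15, nrow(X) - 1),
                       n_threads = 1, n_sgd_threads = 1)
        },
        phate = padColumns(diffusionPotentialEmbedding(X), latentDim),
        autoencoder = trainAutoencoder(X, latentDim, aeHidden, aeEpochs,
                                       aeLearningRate))
}

standardizeColumns <- function(X) {
    mu <- colMeans(X)
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
    Xs
}

padColumns <- function(X, k) {
    if (ncol(X) >= k) return(X[, seq_len(k), drop = FALSE])
    cbind(X, matrix(0, nrow(X), k - ncol(X)))
}

# Diffusion-potential embedding: Gaussian affinities with per-point
# adaptive bandwidth (distance to the kth neighbour), row-normalized to a
# Markov operator, diffused t steps; classical MDS on distances between log
# potentials.
diffusionPotentialEmbedding <- function(X, knn = 5, t = 8) {
    n <- nrow(X)
    D <- as.matrix(dist(X))
    eps <- apply(D, 1, function(r) sort(r)[min(knn + 1, n)])
    eps[eps == 0] <- min(eps[eps > 0], 1)
    K <- exp(-(D / eps)^2)
    K <- (K + t(K)) / 2
    P <- K / rowSums(K)
    Pt <- P
    for (i in seq_len(t - 1)) Pt <- Pt %*% P
    U <- -log(Pt + 1e-8)
    cmdscale(dist(U), k = min(n - 1, ncol(X)))
}

# Dense symmetric autoencoder trained with full-batch Adam on the mean
# squared reconstruction error; tanh hidden units, linear latent and output.
trainAutoencoder <- function(X, latentDim, hidden, epochs, lr) {
    n <- nrow(X); p <- ncol(X)
    sizes <- c(p, hidden, latentDim, rev(hidden), p)
    nl <- length(sizes) - 1
    latentLayer <- length(hidden) + 1  # output index of the bottleneck
    W <- vector("list", nl); b <- vector("list", nl)
    for (l in seq_len(nl)) {
        sdv <- sqrt(2 / (sizes[l] + sizes[l + 1]))
        W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sdv),
                         sizes[l], sizes[l + 1])
        b[[l]] <- numeric(sizes[l + 1])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
    linear <- c(latentLayer, nl)  # bottleneck and output layers are linear
    lossFirst <- NA_real_
    A <- vector("list", nl + 1)
    for (ep in seq_len(epochs)) {
        A[[1]] <- X
        for (l in seq_len(nl)) {
            Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
            A[[l + 1]] <- if (l %in% linear) Z else tanh(Z)
        }
        err <- A[[nl + 1]] - X
        loss <- mean(err^2)
        if (ep == 1) lossFirst <- loss
        delta <- 2 * err / length(err)
        for (l in rev(seq_len(nl))) {
            gW <- crossprod(A[[l]], delta)
            gb <- colSums(delta)
            if (l > 1) {
                delta <- delta %*% t(W[[l]])
                if (!((l - 1) %in% linear))
                    delta <- delta * (1 - A[[l]]^2)
            }
            mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
            vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
            mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
            vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
            cor1 <- 1 - beta1^ep; cor2 <- 1 - beta2^ep
            W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) /
                (sqrt(vW[[l]] / cor2) + epsA)
            b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) /
                (sqrt(vb[[l]] / cor2) + epsA)
        }
    }
    A[[1]] <- X
    for (l in seq_len(latentLayer)) {
        Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        A[[l + 1]] <- if (l %in% linear) Z else tanh(Z)
    }
    out <- A[[latentLayer + 1]]
    # final full-network loss for reporting
    Af <- out
    for (l in (latentLayer + 1):nl) {
        Z <- sweep(Af %*% W[[l]], 2, b[[l]], "+")
        Af <- if (l %in% linear) Z else tanh(Z)
    }
    attr(out, "loss") <- c(first = lossFirst, final = mean((Af - X)^2))
    out
}
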